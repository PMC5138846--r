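#' Default synthetic sample design (29 samples)
#'
#' Mirrors the study design the generators emulate: six tissues across
#' developmental stages (fibre, seed, seedling, leaf) sampled without
#' stress, plus three tissues (root, stem, leaf) each under control
#' (CK), osmotic (PEG) and salt (NaCl) treatment — 23 non-stress
#' samples and 9 stress-experiment samples, 29 in total.
#'
#' @return data.frame `sample_id`, `tissue`, `treatment`, `group`.
#' @export
defaultSampleDesign <- function() {
  rows <- list(
    c("Fibre_10dpa", "fibre", "none", "Fibre_10dpa"),
    c("Fibre_20dpa", "fibre", "none", "Fibre_20dpa"))
  for (st in c("10dpa", "20dpa", "30dpa", "40dpa"))
    for (r in 1:3)
      rows[[length(rows) + 1L]] <-
        c(sprintf("Seed_%s_r%d", st, r), "seed", "none",
          paste0("Seed_", st))
  for (h in c("5h", "15h", "30h"))
    rows[[length(rows) + 1L]] <-
      c(paste0("Seedling_", h), "seedling", "none",
        paste0("Seedling_", h))
  for (r in 1:3)
    rows[[length(rows) + 1L]] <-
      c(sprintf("Leaf_3cm_r%d", r), "leaf", "none", "Leaf_3cm")
  cap <- function(s) paste0(toupper(substr(s, 1, 1)), substring(s, 2))
  for (tis in c("root", "stem", "leaf"))
    for (tr in c("CK", "PEG", "NaCl"))
      rows[[length(rows) + 1L]] <-
        c(paste(cap(tis), tr, sep = "_"), tis, tr,
          paste(cap(tis), "stress", sep = "_"))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(out) <- c("sample_id", "tissue", "treatment", "group")
  out
}

#' Generate a synthetic FPKM matrix with planted structure
#'
#' Log-normal-like expression: each gene has a baseline log2 level;
#' genes in a planted module add (or, for negative members, subtract)
#' a shared per-sample latent activity (module activities are
#' decorrelated across modules so each planted module is a distinct
#' latent factor); Gaussian noise with SD `noiseSd` is added on the
#' log2 scale and FPKM = 2^log-expression. Planted differentially
#' expressed genes add `degEffect` log2 units in the designated
#' samples. Background genes carry independent noise only.
#'
#' @param nGenes total gene count (default 1000).
#' @param design sample design data.frame (`sample_id`, `tissue`,
#'   `treatment`, `group`); default [defaultSampleDesign()].
#' @param nModules number of planted co-expression modules (default 10).
#' @param moduleSize genes per module (default 15).
#' @param negFraction fraction of module members that are
#'   anti-correlated with the module activity (default 0.2).
#' @param noiseSd log2-scale noise SD (default 0.25).
#' @param degGenes number of planted DEGs (drawn from background
#'   genes), or a character vector of gene ids. Default 0.
#' @param degEffect planted log2 effect size (default 2, a 4-fold
#'   shift).
#' @param degSamples sample ids receiving the effect (default: the
#'   NaCl-treated samples of the design).
#' @param seed RNG seed (required for reproducibility; default 1).
#' @return list with `fpkm` (an [FPKMSet-class]) and `truth` (module
#'   assignments, member signs, planted DEGs, seed).
#' @export
generateExpression <- function(nGenes = 1000,
                               design = defaultSampleDesign(),
                               nModules = 10, moduleSize = 15,
                               negFraction = 0.2, noiseSd = 0.25,
                               degGenes = 0, degEffect = 2,
                               degSamples = NULL, seed = 1) {
  stopifnot(is.data.frame(design),
            all(c("sample_id", "tissue", "treatment", "group") %in%
                  colnames(design)))
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (nGenes < nModules * moduleSize)
    stop("nGenes must be >= nModules * moduleSize")
  nS <- nrow(design)
  geneIds <- sprintf("gene%05d", seq_len(nGenes))
  if (is.null(degSamples))
    degSamples <- design$sample_id[design$treatment == "NaCl"]
  withSeed(seed, {
    base <- stats::rnorm(nGenes, mean = 3, sd = 1)
    logExpr <- matrix(base, nrow = nGenes, ncol = nS) +
      matrix(stats::rnorm(nGenes * nS, sd = noiseSd), nGenes, nS)
    groups <- design$group
    ug <- unique(groups)
    moduleOf <- setNames(rep(NA_character_, nGenes), geneIds)
    signOf <- setNames(rep(NA_character_, nGenes), geneIds)
    modules <- list()
    if (nModules > 0) {
      # Latent per-sample module activities, decorrelated across
      # modules (QR) when the design has enough samples: planted
      # modules are distinct latent factors by construction, so the
      # truth labels remain identifiable rather than accidentally
      # collinear.
      actRaw <- matrix(stats::rnorm(nS * nModules), nrow = nS)
      if (nS >= nModules && nModules > 1L) {
        actRaw <- qr.Q(qr(actRaw))
      }
      actSample <- apply(actRaw, 2L, function(a) as.numeric(scale(a)))
      for (m in seq_len(nModules)) {
        idx <- ((m - 1L) * moduleSize + 1L):(m * moduleSize)
        mid <- sprintf("mod%02d", m)
        members <- geneIds[idx]
        modules[[mid]] <- members
        moduleOf[idx] <- mid
        nNeg <- round(negFraction * moduleSize)
        sgn <- c(rep(-1, nNeg), rep(1, moduleSize - nNeg))
        signOf[idx] <- ifelse(sgn < 0, "-", "+")
        act <- actSample[, m]
        logExpr[idx, ] <- logExpr[idx, ] +
          outer(sgn, act, FUN = "*")
      }
    }
    background <- geneIds[is.na(moduleOf)]
    if (is.character(degGenes)) {
      degIds <- degGenes
      if (!all(degIds %in% geneIds)) stop("unknown DEG gene id(s)")
    } else if (degGenes > 0) {
      if (degGenes > length(background))
        stop("not enough background genes for planted DEGs")
      degIds <- sample(background, degGenes)
    } else degIds <- character()
    if (length(degIds)) {
      sCols <- match(degSamples, design$sample_id)
      if (any(is.na(sCols))) stop("unknown DEG sample id(s)")
      logExpr[match(degIds, geneIds), sCols] <-
        logExpr[match(degIds, geneIds), sCols] + degEffect
    }
    fpkmVals <- pmax(2^logExpr, 0)
    dimnames(fpkmVals) <- list(geneIds, design$sample_id)
    fs <- FPKMSet(fpkmVals, tissue = design$tissue,
                  treatment = design$treatment, group = design$group)
    truth <- list(modules = modules, module_of = moduleOf,
                  member_sign = signOf,
                  deg = list(genes = sort(degIds), effect = degEffect,
                             samples = degSamples),
                  seed = seed)
    list(fpkm = fs, truth = truth)
  })
}

# Resolve one IUPAC motif into a concrete instance by sampling each
# ambiguous position uniformly from its base set.
instantiateMotif <- function(motif) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[
    strsplit(toupper(motif), "")[[1]]], "")
  paste(vapply(sets, function(s)
    if (length(s) == 1L) s else sample(s, 1L), character(1)),
    collapse = "")
}

#' Generate synthetic promoter sequences with a planted motif
#'
#' I.i.d. uniform ACGT sequences; motif instances (IUPAC codes
#' resolved randomly per insertion) are inserted at non-overlapping
#' positions, with Poisson-distributed counts per promoter:
#' `plantedRate` for enriched genes, `backgroundRate` otherwise.
#'
#' @param genes gene ids.
#' @param length promoter length in bp (default 3000).
#' @param motif IUPAC motif to plant (NULL for none).
#' @param enrichedGenes gene ids receiving the planted rate.
#' @param plantedRate,backgroundRate mean motif insertions per
#'   promoter (planted > background >= 0).
#' @param seed RNG seed (default 1).
#' @return list with `promoters` (named `DNAStringSet`,
#'   `metadata()$provenance = "supplied"`) and `truth`.
#' @export
generatePromoters <- function(genes, length = 3000, motif = NULL,
                              enrichedGenes = character(),
                              plantedRate = 0, backgroundRate = 0,
                              seed = 1) {
  promLen <- as.integer(length)
  if (promLen < 1L) stop("length must be >= 1")
  if (!is.null(motif)) {
    motif <- checkIupac(motif)
    if (nchar(motif) > promLen) stop("motif longer than promoter")
    if (plantedRate < backgroundRate)
      stop("plantedRate must be >= backgroundRate")
  }
  if (base::length(enrichedGenes) && !all(enrichedGenes %in% genes))
    stop("enrichedGenes must be a subset of genes")
  n <- base::length(genes)
  withSeed(seed, {
    chars <- sample(c("A", "C", "G", "T"), n * promLen, replace = TRUE)
    m <- matrix(chars, nrow = n)
    seqs <- apply(m, 1L, paste, collapse = "")
    if (!is.null(motif) && (plantedRate > 0 || backgroundRate > 0)) {
      w <- nchar(motif)
      rates <- ifelse(genes %in% enrichedGenes, plantedRate,
                      backgroundRate)
      counts <- stats::rpois(n, rates)
      for (i in seq_len(n)) {
        if (counts[i] == 0L) next
        used <- integer()
        placed <- 0L
        tries <- 0L
        while (placed < counts[i] && tries < 200L) {
          tries <- tries + 1L
          pos <- sample.int(promLen - w + 1L, 1L)
          if (any(abs(used - pos) < w)) next
          inst <- instantiateMotif(motif)
          substr(seqs[i], pos, pos + w - 1L) <- inst
          used <- c(used, pos)
          placed <- placed + 1L
        }
      }
    } else counts <- integer(n)
    promoters <- Biostrings::DNAStringSet(setNames(seqs, genes))
    metadata(promoters)$provenance <- "supplied"
    truth <- list(motif = motif, enriched_genes = sort(enrichedGenes),
                  planted_rate = plantedRate,
                  background_rate = backgroundRate,
                  inserted_counts = setNames(counts, genes),
                  seed = seed)
    list(promoters = promoters, truth = truth)
  })
}

#' Generate synthetic bidirectional BLAST hit tables
#'
#' True orthologue pairs get reciprocal rank-1 hits with very low
#' e-values; decoy hits get higher (but sometimes sub-1e-55) e-values
#' so that secondary-tier calls also occur.
#'
#' @param nA,nB gene counts in species A and B.
#' @param truePairs fraction of `min(nA, nB)` genes given a true
#'   reciprocal partner (default 0.8).
#' @param seed RNG seed (default 1).
#' @return list with `hits_ab`, `hits_ba` (12-column outfmt-6
#'   data.frames) and `truth` (the planted pairs).
#' @export
generateBlastTables <- function(nA, nB, truePairs = 0.8, seed = 1) {
  if (nA < 1 || nB < 1) stop("gene counts must be >= 1")
  idsA <- sprintf("A%04d", seq_len(nA))
  idsB <- sprintf("B%04d", seq_len(nB))
  nTrue <- round(truePairs * min(nA, nB))
  withSeed(seed, {
    mkHit <- function(q, s, evalue, bitscore) {
      len <- sample(100:500, base::length(q), replace = TRUE)
      data.frame(qseqid = q, sseqid = s,
                 pident = round(stats::runif(base::length(q), 40, 100), 2),
                 length = len,
                 mismatch = sample(0:50, base::length(q), replace = TRUE),
                 gapopen = sample(0:5, base::length(q), replace = TRUE),
                 qstart = 1L, qend = len, sstart = 1L, send = len,
                 evalue = evalue, bitscore = bitscore,
                 stringsAsFactors = FALSE)
    }
    hits <- list(ab = list(), ba = list())
    if (nTrue > 0) {
      eAB <- 10^-stats::runif(nTrue, 80, 140)
      eBA <- 10^-stats::runif(nTrue, 80, 140)
      hits$ab[[1]] <- mkHit(idsA[seq_len(nTrue)], idsB[seq_len(nTrue)],
                            eAB, round(stats::runif(nTrue, 300, 800)))
      hits$ba[[1]] <- mkHit(idsB[seq_len(nTrue)], idsA[seq_len(nTrue)],
                            eBA, round(stats::runif(nTrue, 300, 800)))
    }
    decoys <- function(qIds, sIds) {
      out <- list()
      for (q in qIds) {
        nd <- sample(0:3, 1L)
        if (nd == 0L) next
        subj <- sample(sIds, nd)
        out[[q]] <- mkHit(rep(q, nd), subj, 10^-stats::runif(nd, 1, 70),
                          round(stats::runif(nd, 50, 280)))
      }
      out
    }
    hits$ab <- c(hits$ab, decoys(idsA, idsB))
    hits$ba <- c(hits$ba, decoys(idsB, idsA))
    ab <- do.call(rbind, hits$ab)
    ba <- do.call(rbind, hits$ba)
    if (is.null(ab)) ab <- mkHit(character(), character(),
                                 numeric(), numeric())
    if (is.null(ba)) ba <- mkHit(character(), character(),
                                 numeric(), numeric())
    rownames(ab) <- rownames(ba) <- NULL
    truth <- list(pairs = if (nTrue > 0)
      data.frame(gene_a = idsA[seq_len(nTrue)],
                 gene_b = idsB[seq_len(nTrue)],
                 stringsAsFactors = FALSE)
      else data.frame(gene_a = character(), gene_b = character()),
      seed = seed)
    list(hits_ab = ab, hits_ba = ba, truth = truth)
  })
}

#' Write a BLAST outfmt-6 table to file
#' @param hits 12-column hit data.frame (extra columns are dropped).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeBlastTabular <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
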