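#' Extract promoter sequences from a genome FASTA and GFF3 annotation
#'
#' For each `gene` feature, takes the `length` bases immediately
#' upstream of the transcription start on the coding strand (the bases
#' downstream of the gene end, reverse-complemented, for minus-strand
#' genes), truncated at sequence boundaries. Genes on sequences missing
#' from the FASTA are skipped with a warning; truncated promoters are
#' reported via a message.
#'
#' @param genomeFasta path to the genome FASTA (or a `DNAStringSet`).
#' @param gffPath path to the GFF3 annotation; `gene` features must
#'   carry an `ID` (or `Name`) attribute and a strand.
#' @param length promoter length in bp (default 3000).
#' @return A `DNAStringSet` named by gene id (uppercase), with
#'   `metadata()$provenance = "extracted"`.
#' @export
extractPromoters <- function(genomeFasta, gffPath, length = 3000) {
  promLen <- as.integer(length)
  if (promLen < 1L) stop("length must be >= 1")
  genome <- if (is(genomeFasta, "DNAStringSet")) genomeFasta
  else Biostrings::readDNAStringSet(genomeFasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- as.data.frame(rtracklayer::import(gffPath))
  gff <- gff[gff$type == "gene", , drop = FALSE]
  if (!nrow(gff)) stop("no gene features in ", gffPath)
  ids <- if ("ID" %in% colnames(gff) && !all(is.na(gff$ID))) gff$ID
  else gff$Name
  if (is.null(ids) || any(is.na(ids)))
    stop("gene features must carry an ID or Name attribute")
  seqLens <- setNames(Biostrings::width(genome), names(genome))
  out <- vector("list", nrow(gff))
  keep <- logical(nrow(gff))
  nTrunc <- 0L
  for (i in seq_len(nrow(gff))) {
    chr <- as.character(gff$seqnames[i])
    if (!chr %in% names(genome)) {
      warning("gene '", ids[i], "' on missing sequence '", chr,
              "'; skipped")
      next
    }
    L <- seqLens[[chr]]
    if (as.character(gff$strand[i]) == "-") {
      s <- gff$end[i] + 1L
      e <- min(L, gff$end[i] + promLen)
      if (s > e) { pr <- Biostrings::DNAString("") }
      else pr <- Biostrings::reverseComplement(
        Biostrings::subseq(genome[[chr]], s, e))
    } else {
      s <- max(1L, gff$start[i] - promLen)
      e <- gff$start[i] - 1L
      if (s > e) { pr <- Biostrings::DNAString("") }
      else pr <- Biostrings::subseq(genome[[chr]], s, e)
    }
    if (base::length(pr) < promLen) nTrunc <- nTrunc + 1L
    out[[i]] <- pr
    keep[i] <- TRUE
  }
  if (nTrunc > 0)
    message(nTrunc, " promoter(s) truncated at sequence boundaries")
  res <- Biostrings::DNAStringSet(out[keep])
  names(res) <- ids[keep]
  metadata(res)$provenance <- "extracted"
  res
}

#' Read a motif definition table
#'
#' Two-column TSV `motif_id<TAB>iupac` (PLACE-style), no header
#' required if the first line parses as a motif.
#'
#' @param path path to the motif TSV.
#' @return data.frame `motif_id`, `iupac`.
#' @export
readMotifTable <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("motif table needs motif_id and iupac columns")
  colnames(tab)[1:2] <- c("motif_id", "iupac")
  if (tolower(tab$motif_id[1]) %in% c("motif_id", "id"))
    tab <- tab[-1L, , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("motif_id", "iupac")]
}

checkIupac <- function(motif) {
  motif <- toupper(motif)
  letters <- strsplit(motif, "")[[1]]
  bad <- setdiff(letters, names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  if (nchar(motif) < 2L) stop("motif too short")
  motif
}

#' Count IUPAC motif matches in a DNA sequence
#'
#' Counts (possibly overlapping) match start positions of the motif;
#' with `bothStrands`, matches of the reverse complement are added,
#' de-duplicated by (start, matched-strand pattern) so a palindromic
#' motif counts once per position. IUPAC ambiguity codes in the motif
#' are expanded; the subject is matched literally (an `N` in the
#' sequence matches nothing).
#'
#' @param sequence a DNA sequence (character or `DNAString`).
#' @param motif IUPAC pattern string.
#' @param bothStrands scan both strands (default TRUE).
#' @return integer match count.
#' @examples
#' countMotif("AAAA", "AAA", bothStrands = FALSE)  # 2, overlaps allowed
#' countMotif("ACGTACGT", "ACGT")                  # 2, palindrome
#' @export
countMotif <- function(sequence, motif, bothStrands = TRUE) {
  motif <- checkIupac(motif)
  subj <- if (is(sequence, "DNAString")) sequence
  else Biostrings::DNAString(toupper(as.character(sequence)))
  n <- Biostrings::countPattern(motif, subj, fixed = "subject")
  if (bothStrands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    if (!identical(rc, motif))
      n <- n + Biostrings::countPattern(rc, subj, fixed = "subject")
  }
  as.integer(n)
}

# Vectorised motif counts over a DNAStringSet.
countMotifSet <- function(promoters, motif, bothStrands = TRUE) {
  motif <- checkIupac(motif)
  n <- Biostrings::vcountPattern(motif, promoters, fixed = "subject")
  if (bothStrands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    if (!identical(rc, motif))
      n <- n + Biostrings::vcountPattern(rc, promoters, fixed = "subject")
  }
  setNames(as.integer(n), names(promoters))
}

#' Permutation Z-score test for cis-element enrichment
#'
#' The observed statistic is the sum of motif counts over the gene
#' list's promoters. The null distribution is built from `nPerm`
#' random gene lists of the same size drawn uniformly without
#' replacement from the background; the Z score is
#' `(s - mu) / sigma` with `mu`/`sigma` the mean and sample SD of the
#' null sums, and p is the one-sided upper-tail normal probability.
#'
#' @param geneList gene ids (subset of `background`).
#' @param promoters a named `DNAStringSet` of promoter sequences
#'   covering the background genes.
#' @param motif IUPAC pattern string.
#' @param background background gene ids (default: all promoter
#'   genes); must be strictly larger than the list.
#' @param nPerm number of random lists (default 1000, minimum 100).
#' @param seed RNG seed for reproducible permutations.
#' @param alpha significance level (default 0.05); `significant` is
#'   `p_value < alpha`.
#' @param bothStrands scan both strands (default TRUE).
#' @return one-row data.frame: `motif`, `s_observed`, `mu_null`,
#'   `sigma_null`, `z_score`, `p_value`, `n_permutations`,
#'   `significant`.
#' @export
motifZTest <- function(geneList, promoters, motif,
                       background = names(promoters), nPerm = 1000,
                       seed = NULL, alpha = 0.05, bothStrands = TRUE) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  background <- unique(background)
  geneList <- unique(geneList)
  if (!all(geneList %in% background))
    stop("geneList must be a subset of background")
  if (!all(background %in% names(promoters)))
    stop("background gene(s) lack promoter sequences")
  if (length(background) <= length(geneList))
    stop("background must be larger than the gene list")
  counts <- countMotifSet(promoters[background], motif, bothStrands)
  s <- sum(counts[geneList])
  m <- length(geneList)
  nullSums <- withSeed(seed, {
    vapply(seq_len(nPerm),
           function(i) sum(counts[sample.int(length(counts), m)]),
           numeric(1))
  })
  mu <- mean(nullSums)
  sigma <- stats::sd(nullSums)
  if (sigma == 0) {
    warning("null SD is zero; degenerate p-value")
    z <- if (s > mu) Inf else if (s < mu) -Inf else 0
    p <- if (s <= mu) 1 else 0
  } else {
    z <- (s - mu) / sigma
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  data.frame(motif = motif, s_observed = s, mu_null = mu,
             sigma_null = sigma, z_score = z, p_value = p,
             n_permutations = as.integer(nPerm),
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Read a term-to-gene annotation map
#'
#' TSV with one `term_id<TAB>gene_id` pair per line (header optional).
#'
#' @param path path to the TSV.
#' @return named list: term id -> character vector of gene ids.
#' @export
readTermMap <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("term map needs term_id and gene_id columns")
  if (tolower(tab[[1]][1]) %in% c("term_id", "term"))
    tab <- tab[-1L, , drop = FALSE]
  split(tab[[2]], tab[[1]])
}

#' Fisher-exact term enrichment with FDR control
#'
#' One-sided (enrichment) Fisher exact test per term on the 2x2 table
#' of list/background membership, adjusted by Benjamini-Yekutieli
#' (default, matching a dependence-robust FDR) or Benjamini-Hochberg.
#' Terms with no gene in the background are skipped with a warning.
#'
#' @param geneList gene ids (subset of `background`).
#' @param background background gene ids.
#' @param termMap named list term id -> gene ids (see [readTermMap()]).
#' @param adjust `"BY"` (default) or `"BH"`.
#' @param alpha significance level on q (default 0.05).
#' @return data.frame `term_id`, `list_hits`, `list_size`,
#'   `background_hits`, `background_size`, `p_value`, `q_value`,
#'   `significant`, ordered by p.
#' @export
fisherTermEnrichment <- function(geneList, background, termMap,
                                 adjust = c("BY", "BH"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  background <- unique(background)
  geneList <- unique(geneList)
  if (!length(geneList)) stop("empty gene list")
  if (!all(geneList %in% background))
    stop("geneList must be a subset of background")
  N <- length(background)
  n <- length(geneList)
  rows <- lapply(names(termMap), function(term) {
    termGenes <- intersect(unique(termMap[[term]]), background)
    K <- length(termGenes)
    if (K == 0L) {
      warning("term '", term, "' has no background genes; skipped")
      return(NULL)
    }
    k <- length(intersect(termGenes, geneList))
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term_id = term, list_hits = k, list_size = n,
               background_hits = K, background_size = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term_id = character(), list_hits = integer(),
                      list_size = integer(), background_hits = integer(),
                      background_size = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q_value <- adjustPvalues(res$p_value, method = adjust)
  res$significant <- res$q_value <= alpha
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
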