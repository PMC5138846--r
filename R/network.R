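#' Pearson correlation between two expression vectors
#'
#' Plain product-moment correlation. When either vector has zero
#' variance the correlation is undefined and `NA` is returned; network
#' construction excludes such genes.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA_real_` for zero variance.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Directional PCC rank matrices
#'
#' For each gene A, its partners are ranked twice: by descending PCC
#' (positive direction: A's most positively co-expressed partner has
#' rank 1) and by ascending PCC (negative direction: the most negative
#' partner has rank 1). Ranks are 1-based ordinal ranks; ties are broken
#' lexicographically by gene id so ranking is a deterministic
#' permutation. The rank of the third-highest co-expressed partner is 3.
#'
#' @param pcc square symmetric PCC matrix with gene ids as dimnames;
#'   the diagonal is ignored.
#' @return list with elements `positive` and `negative`: matrices where
#'   entry `[A, B]` is the rank of B among A's partners (NA diagonal).
#' @export
rankMatrices <- function(pcc) {
  stopifnot(is.matrix(pcc), nrow(pcc) == ncol(pcc))
  ids <- rownames(pcc)
  if (is.null(ids) || !identical(ids, colnames(pcc)))
    stop("pcc must have matching row/column gene ids")
  n <- nrow(pcc)
  pos <- neg <- matrix(NA_real_, n, n, dimnames = dimnames(pcc))
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    if (!length(j)) next
    oPos <- j[order(-pcc[i, j], ids[j])]
    pos[i, oPos] <- seq_along(oPos)
    oNeg <- j[order(pcc[i, j], ids[j])]
    neg[i, oNeg] <- seq_along(oNeg)
  }
  list(positive = pos, negative = neg)
}

#' Mutual Rank of a gene pair
#'
#' Geometric mean of the two directional PCC ranks,
#' `sqrt(rank_ab * rank_ba)`. Vectorised.
#'
#' @param rankAB,rankBA numeric ranks >= 1.
#' @return `sqrt(rankAB * rankBA)`.
#' @examples
#' mutualRank(3, 12)  # 6
#' @export
mutualRank <- function(rankAB, rankBA) {
  if (any(rankAB < 1) || any(rankBA < 1))
    stop("ranks must be >= 1")
  sqrt(rankAB * rankBA)
}

# Infer network provenance from the sample subset's treatments.
inferProvenance <- function(x, sampleIds) {
  tr <- as.character(SummarizedExperiment::colData(x)$treatment)
  names(tr) <- colnames(x)
  if (length(sampleIds) == ncol(x)) return("global")
  if (any(tr[sampleIds] %in% c("PEG", "NaCl"))) "stress_treatment"
  else "tissue_specific"
}

#' Build a signed, tiered Mutual-Rank co-expression network
#'
#' Computes all-pairs PCC over the chosen samples, ranks partners in
#' both the positive and negative directions, and retains, separately
#' within the positive (`pcc > posCutoff`) and negative
#' (`pcc < negCutoff`) candidate sets, the union of pairs with a single
#' direction rank `min(rank_ab, rank_ba) <= rankCutoff` and pairs with
#' Mutual Rank `<= mrCutoff`. Retained edges are tiered `rank_top`
#' (min rank within the rank cutoff), else `mr_le_5` (MR <= 5), else
#' `mr_le_30`. Genes with zero variance across the chosen samples are
#' excluded before ranking (their PCC is undefined); the count is
#' reported via a message.
#'
#' With `cutoffMode = "percentile"` the PCC cutoffs are taken from the
#' all-pairs PCC distribution (by default its 95th and 5th percentiles)
#' instead of the fixed values.
#'
#' @param x an [FPKMSet-class].
#' @param samples sample ids to use (default: all). At least 3.
#' @param posCutoff,negCutoff fixed PCC cutoffs (defaults +0.65 / -0.45).
#' @param cutoffMode `"fixed"` (default) or `"percentile"`.
#' @param posPercentile,negPercentile percentiles used in percentile
#'   mode (defaults 0.95 and 0.05).
#' @param rankCutoff single-direction rank retention cutoff (default 3).
#' @param mrCutoff Mutual Rank retention cutoff (default 30).
#' @param provenance override the inferred provenance label.
#' @return A [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(x, samples = NULL,
                         posCutoff = 0.65, negCutoff = -0.45,
                         cutoffMode = c("fixed", "percentile"),
                         posPercentile = 0.95, negPercentile = 0.05,
                         rankCutoff = 3, mrCutoff = 30,
                         provenance = NULL) {
  stopifnot(is(x, "FPKMSet"))
  cutoffMode <- match.arg(cutoffMode)
  if (rankCutoff < 1 || mrCutoff <= 0)
    stop("rankCutoff must be >= 1 and mrCutoff > 0")
  if (is.null(samples)) samples <- colnames(x)
  bad <- setdiff(samples, colnames(x))
  if (length(bad))
    stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  if (length(samples) < 3L)
    stop("need at least 3 samples to build a network")
  if (is.null(provenance)) provenance <- inferProvenance(x, samples)

  v <- fpkm(x)[, samples, drop = FALSE]
  vars <- apply(v, 1L, stats::sd)
  nZero <- sum(vars == 0)
  if (nZero > 0) {
    message(nZero, " gene(s) with zero variance excluded")
    v <- v[vars > 0, , drop = FALSE]
  }
  params <- list(samples = samples, pos_cutoff = posCutoff,
                 neg_cutoff = negCutoff, cutoff_mode = cutoffMode,
                 rank_cutoff = rankCutoff, mr_cutoff = mrCutoff,
                 zero_variance_excluded = nZero)
  emptyEdges <- data.frame(gene_a = character(), gene_b = character(),
                           pcc = numeric(), rank_ab = numeric(),
                           rank_ba = numeric(), mr = numeric(),
                           sign = character(), tier = character(),
                           stringsAsFactors = FALSE)
  if (nrow(v) < 2L)
    return(new("CoexpressionNetwork", nodes = character(),
               edges = emptyEdges, provenance = provenance,
               parameters = params))

  pcc <- stats::cor(t(v))
  ids <- rownames(v)
  if (cutoffMode == "percentile") {
    allP <- pcc[upper.tri(pcc)]
    posCutoff <- stats::quantile(allP, posPercentile, names = FALSE)
    negCutoff <- stats::quantile(allP, negPercentile, names = FALSE)
    params$pos_cutoff <- posCutoff
    params$neg_cutoff <- negCutoff
  }
  rk <- rankMatrices(pcc)

  collect <- function(candidate, ranks, signLabel) {
    idx <- which(candidate & upper.tri(candidate), arr.ind = TRUE)
    if (!nrow(idx)) return(emptyEdges)
    i <- idx[, 1L]; j <- idx[, 2L]
    rab <- ranks[cbind(i, j)]  # rank of j among i's partners
    rba <- ranks[cbind(j, i)]
    # store with gene_a < gene_b lexicographically; rank_ab is the rank
    # of gene_b among gene_a's partners
    swap <- ids[i] > ids[j]
    ga <- ifelse(swap, ids[j], ids[i])
    gb <- ifelse(swap, ids[i], ids[j])
    r1 <- ifelse(swap, rba, rab)
    r2 <- ifelse(swap, rab, rba)
    mr <- sqrt(r1 * r2)
    keep <- (pmin(r1, r2) <= rankCutoff) | (mr <= mrCutoff)
    if (!any(keep)) return(emptyEdges)
    ga <- ga[keep]; gb <- gb[keep]; r1 <- r1[keep]; r2 <- r2[keep]
    mr <- mr[keep]
    tier <- ifelse(pmin(r1, r2) <= rankCutoff, "rank_top",
                   ifelse(mr <= 5, "mr_le_5", "mr_le_30"))
    data.frame(gene_a = ga, gene_b = gb,
               pcc = pcc[cbind(match(ga, ids), match(gb, ids))],
               rank_ab = r1, rank_ba = r2, mr = mr,
               sign = signLabel, tier = tier, stringsAsFactors = FALSE)
  }

  posEdges <- collect(pcc > posCutoff, rk$positive, "positive")
  negEdges <- collect(pcc < negCutoff & pcc < 0, rk$negative, "negative")
  edges <- rbind(posEdges, negEdges)
  edges <- edges[order(edges$gene_a, edges$gene_b, edges$sign), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  new("CoexpressionNetwork", nodes = nodes, edges = edges,
      provenance = provenance, parameters = params)
}

#' Extract the neighbourhood sub-network of seed genes
#'
#' Returns the sub-network of edges incident to at least one seed gene
#' (filtered by sign `mode`) together with the seeds and their direct
#' neighbours.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param seeds non-empty character vector of gene ids. Seeds absent
#'   from the network are skipped with a warning.
#' @param mode `"both"` (default), `"positive"` or `"negative"`.
#' @return A [CoexpressionNetwork-class] with provenance `"subnetwork"`.
#' @export
extractSubnetwork <- function(network, seeds,
                              mode = c("both", "positive", "negative")) {
  stopifnot(is(network, "CoexpressionNetwork"))
  mode <- match.arg(mode)
  if (!length(seeds)) stop("seeds must be non-empty")
  absent <- setdiff(seeds, network@nodes)
  if (length(absent))
    warning("seed(s) not in network, skipped: ",
            paste(absent, collapse = ", "))
  seeds <- intersect(seeds, network@nodes)
  ed <- network@edges
  keep <- (ed$gene_a %in% seeds) | (ed$gene_b %in% seeds)
  if (mode != "both") keep <- keep & (ed$sign == mode)
  ed <- ed[keep, , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- sort(unique(c(seeds, ed$gene_a, ed$gene_b)))
  new("CoexpressionNetwork", nodes = nodes, edges = ed,
      provenance = "subnetwork", parameters = network@parameters)
}

#' Compare two co-expression networks
#'
#' Edge identity is the unordered gene pair plus the sign. Overlap
#' ratios are reported against each network's own node/edge counts,
#' together with the edge Jaccard index.
#'
#' @param a,b [CoexpressionNetwork-class] objects.
#' @return list with `shared_nodes`, `shared_edges`,
#'   `node_overlap_ratio_a/_b`, `edge_overlap_ratio_a/_b`,
#'   `jaccard_edges`.
#' @export
compareNetworks <- function(a, b) {
  stopifnot(is(a, "CoexpressionNetwork"), is(b, "CoexpressionNetwork"))
  edgeKey <- function(n) {
    ed <- n@edges
    if (!nrow(ed)) return(character())
    paste(ed$gene_a, ed$gene_b, ed$sign, sep = "\r")
  }
  ratio <- function(num, den) if (den == 0) 0 else num / den
  ea <- edgeKey(a); eb <- edgeKey(b)
  sharedN <- length(intersect(a@nodes, b@nodes))
  sharedE <- length(intersect(ea, eb))
  unionE <- length(union(ea, eb))
  list(shared_nodes = sharedN, shared_edges = sharedE,
       node_overlap_ratio_a = ratio(sharedN, length(a@nodes)),
       node_overlap_ratio_b = ratio(sharedN, length(b@nodes)),
       edge_overlap_ratio_a = ratio(sharedE, length(ea)),
       edge_overlap_ratio_b = ratio(sharedE, length(eb)),
       jaccard_edges = if (unionE == 0) 0 else sharedE / unionE)
}

#' Write a network edge list to TSV
#'
#' Columns: `gene_a`, `gene_b`, `pcc`, `rank_ab`, `rank_ba`, `mr`,
#' `sign`, `tier`.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeEdgeList <- function(network, path) {
  stopifnot(is(network, "CoexpressionNetwork"))
  write.table(network@edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Convert a CoexpressionNetwork to an igraph graph
#'
#' Node attribute `gene_id`; edge attributes `pcc`, `rank_ab`,
#' `rank_ba`, `mr`, `sign`, `tier`.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param signMode keep `"both"` signs (default), or `"positive_only"`.
#' @return An undirected `igraph` graph.
#' @export
networkToIgraph <- function(network,
                            signMode = c("both", "positive_only")) {
  stopifnot(is(network, "CoexpressionNetwork"))
  signMode <- match.arg(signMode)
  ed <- network@edges
  if (signMode == "positive_only")
    ed <- ed[ed$sign == "positive", , drop = FALSE]
  verts <- data.frame(name = network@nodes, gene_id = network@nodes,
                      stringsAsFactors = FALSE)
  if (!nrow(verts))
    return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_data_frame(
    d = ed[, c("gene_a", "gene_b", "pcc", "rank_ab", "rank_ba",
               "mr", "sign", "tier")],
    directed = FALSE, vertices = verts)
}
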