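#' FPKMSet: an FPKM expression matrix with sample metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' single `fpkm` assay (genes x samples, non-negative finite values) and
#' mandatory per-sample metadata columns `tissue`, `treatment` and `group`
#' (the experimental/replicate grouping). The `treatment` vocabulary is
#' `CK` (control), `PEG`, `NaCl` and `none` (samples outside the stress
#' experiment).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("FPKMSet", contains = "SummarizedExperiment")

setValidity("FPKMSet", function(object) {
  msg <- character()
  if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fpkm' is required")
  else {
    v <- SummarizedExperiment::assay(object, "fpkm")
    if (any(!is.finite(v)))
      msg <- c(msg, "FPKM values must be finite (no NA/NaN/Inf)")
    else if (any(v < 0))
      msg <- c(msg, "FPKM values must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("tissue", "treatment", "group")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    for (f in need)
      if (any(is.na(cd[[f]])))
        msg <- c(msg, paste0("colData column '", f, "' has NA entries"))
    bad <- setdiff(unique(as.character(cd$treatment)),
                   c("CK", "PEG", "NaCl", "none"))
    if (length(bad))
      msg <- c(msg, paste0("unknown treatment label(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an FPKMSet
#'
#' @param values numeric matrix of FPKM values, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param tissue,treatment,group character vectors, one entry per sample.
#'   `treatment` must use the vocabulary `CK`, `PEG`, `NaCl`, `none`.
#' @return An [FPKMSet-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' fs <- FPKMSet(m, tissue = c("leaf", "root"),
#'               treatment = c("none", "none"), group = c("L", "R"))
#' @export
FPKMSet <- function(values, tissue, treatment, group) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- S4Vectors::DataFrame(tissue = as.character(tissue),
                             treatment = as.character(treatment),
                             group = as.character(group),
                             row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = values), colData = cd)
  new("FPKMSet", se)
}

#' Extract the FPKM matrix from an FPKMSet
#' @param x an `FPKMSet`.
#' @return numeric matrix, genes x samples.
#' @export
fpkm <- function(x) {
  stopifnot(is(x, "FPKMSet"))
  SummarizedExperiment::assay(x, "fpkm")
}

#' A signed, tiered co-expression network
#'
#' Nodes are genes incident to at least one retained edge. Each edge
#' records the Pearson correlation, the two directional PCC ranks, the
#' Mutual Rank (geometric mean of the ranks), a sign (`positive` iff
#' PCC > 0) and a retention tier (`rank_top`, `mr_le_5`, `mr_le_30`).
#'
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `pcc`,
#'   `rank_ab`, `rank_ba`, `mr`, `sign`, `tier`; `gene_a < gene_b`
#'   lexicographically and each unordered pair appears at most once.
#' @slot provenance one of `global`, `tissue_specific`,
#'   `stress_treatment`, `subnetwork`.
#' @slot parameters list echoing the construction parameters.
#' @export
setClass("CoexpressionNetwork",
         representation(nodes = "character", edges = "data.frame",
                        provenance = "character", parameters = "list"))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("gene_a", "gene_b", "pcc", "rank_ab", "rank_ba",
            "mr", "sign", "tier")
  if (!all(need %in% colnames(ed)))
    return(paste0("edges must have columns: ", paste(need, collapse = ", ")))
  if (nrow(ed)) {
    if (!all(ed$gene_a %in% object@nodes) ||
        !all(ed$gene_b %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a node")
    if (any(ed$gene_a >= ed$gene_b))
      msg <- c(msg, "edges must satisfy gene_a < gene_b (no self edges)")
    if (anyDuplicated(paste(ed$gene_a, ed$gene_b)))
      msg <- c(msg, "each unordered gene pair may appear at most once")
    if (!all(ed$sign %in% c("positive", "negative")) ||
        any((ed$pcc > 0) != (ed$sign == "positive")))
      msg <- c(msg, "sign must be 'positive' iff pcc > 0")
    if (any(abs(ed$mr - sqrt(ed$rank_ab * ed$rank_ba)) > 1e-8))
      msg <- c(msg, "mr must equal sqrt(rank_ab * rank_ba)")
  }
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node ids")
  if (length(object@provenance) != 1L)
    msg <- c(msg, "provenance must be a single string")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoexpressionNetwork-class node (gene id) accessor
#' @param x a `CoexpressionNetwork`.
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork")); x@nodes
}

#' @describeIn CoexpressionNetwork-class edge table accessor
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork")); x@edges
}

#' @describeIn CoexpressionNetwork-class provenance accessor
#' @export
networkProvenance <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork")); x@provenance
}

#' @describeIn CoexpressionNetwork-class construction-parameter accessor
#' @export
networkParameters <- function(x) {
  stopifnot(is(x, "CoexpressionNetwork")); x@parameters
}

setMethod("show", "CoexpressionNetwork", function(object) {
  ed <- object@edges
  cat("CoexpressionNetwork (", object@provenance, ")\n", sep = "")
  cat("  nodes: ", length(object@nodes), "\n", sep = "")
  cat("  edges: ", nrow(ed),
      " (positive ", sum(ed$sign == "positive"),
      ", negative ", sum(ed$sign == "negative"), ")\n", sep = "")
  invisible(object)
})

#' Overlapping gene communities from k-clique percolation
#'
#' @slot modules named list of sorted character vectors (gene ids); names
#'   are module ids assigned deterministically from the sorted member
#'   lists.
#' @slot k integer clique size used.
#' @slot signMode edge-sign filter used (`both` or `positive_only`).
#' @export
setClass("CommunityModules",
         representation(modules = "list", k = "integer",
                        signMode = "character"))

setValidity("CommunityModules", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 3L)
    msg <- c(msg, "k must be a single integer >= 3")
  sizes <- lengths(object@modules)
  if (length(sizes) && any(sizes < object@k))
    msg <- c(msg, "every module must have at least k members")
  if (length(msg)) msg else TRUE
})

#' @describeIn CommunityModules-class list of member vectors
#' @param x a `CommunityModules` object.
#' @export
moduleList <- function(x) {
  stopifnot(is(x, "CommunityModules")); x@modules
}

#' @describeIn CommunityModules-class clique size used
#' @export
moduleK <- function(x) {
  stopifnot(is(x, "CommunityModules")); x@k
}

#' @describeIn CommunityModules-class module sizes (named integer vector)
#' @export
moduleSizes <- function(x) {
  stopifnot(is(x, "CommunityModules")); lengths(x@modules)
}

setMethod("show", "CommunityModules", function(object) {
  sizes <- lengths(object@modules)
  cat("CommunityModules: ", length(sizes), " module(s), k = ",
      object@k, ", sign mode '", object@signMode, "'\n", sep = "")
  if (length(sizes))
    cat("  sizes: ", min(sizes), "-", max(sizes), " genes\n", sep = "")
  invisible(object)
})
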