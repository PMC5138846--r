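#' Read an FPKM expression matrix with sample metadata
#'
#' Reads a tab-separated expression table (header row of sample ids,
#' first column `gene_id`) and a metadata table (columns `sample_id`,
#' `tissue`, `treatment`, `group`) and joins them into an [FPKMSet-class].
#' Row and column order are preserved from the files.
#'
#' @param path path to the expression TSV.
#' @param metadataPath path to the sample metadata TSV.
#' @return An [FPKMSet-class].
#' @export
readExpressionMatrix <- function(path, metadataPath) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("expression table needs a gene_id column and >= 1 sample column")
  geneIds <- tab[[1L]]
  sampleIds <- colnames(tab)[-1L]
  dupG <- unique(geneIds[duplicated(geneIds)])
  if (length(dupG))
    stop("duplicated gene id(s): ", paste(dupG, collapse = ", "))
  dupS <- unique(sampleIds[duplicated(sampleIds)])
  if (length(dupS))
    stop("duplicated sample id(s): ", paste(dupS, collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = length(sampleIds),
                 dimnames = list(geneIds, sampleIds))
  for (j in seq_along(sampleIds)) {
    col <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(is.na(col) | col < 0)
    if (length(bad))
      stop("non-numeric or negative FPKM for gene '", geneIds[bad[1L]],
           "', sample '", sampleIds[j], "'")
    vals[, j] <- col
  }
  md <- read.delim(metadataPath, header = TRUE, sep = "\t",
                   check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "tissue", "treatment", "group")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample id(s) in metadata")
  absent <- setdiff(sampleIds, md$sample_id)
  if (length(absent))
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "))
  md <- md[match(sampleIds, md$sample_id), , drop = FALSE]
  FPKMSet(vals, tissue = md$tissue, treatment = md$treatment,
          group = md$group)
}

#' Write an FPKMSet to expression + metadata TSV files
#'
#' Inverse of [readExpressionMatrix()]: values round-trip exactly
#' (written with full precision).
#'
#' @param x an [FPKMSet-class].
#' @param path output path for the expression TSV.
#' @param metadataPath output path for the metadata TSV.
#' @return Invisibly, `c(path, metadataPath)`.
#' @export
writeExpressionMatrix <- function(x, path, metadataPath) {
  stopifnot(is(x, "FPKMSet"))
  v <- fpkm(x)
  out <- data.frame(gene_id = rownames(v),
                    format(v, digits = 17, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(x)
  md <- data.frame(sample_id = colnames(v),
                   tissue = cd$tissue, treatment = cd$treatment,
                   group = cd$group, stringsAsFactors = FALSE)
  write.table(md, metadataPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, metadataPath))
}

#' Minimum-expression threshold from the lower FPKM tail
#'
#' For each experimental group, pools every member sample's lower-tail
#' FPKM values (values at or below the per-sample `quantile` quantile,
#' linear-interpolation type 7) and computes
#' `mean(pool) + sdMultiplier * sd(pool)` (sample SD, n-1 denominator).
#' The global threshold aggregates the per-group thresholds with
#' `aggregate` (default `min`, the minimum expression threshold).
#'
#' @param x an [FPKMSet-class].
#' @param quantile tail quantile in (0, 0.5], default 0.05.
#' @param sdMultiplier SD multiplier, default 3.
#' @param aggregate how to combine per-group thresholds into the global
#'   one: `"min"` (default), `"max"` or `"mean"`.
#' @return A list with elements `global_threshold`, `per_group_thresholds`
#'   (named numeric), `quantile`, `sd_multiplier`, `aggregate`.
#' @examples
#' fs <- FPKMSet(matrix(c(0.1, 0.1, 0.1, 0.3), 2,
#'                      dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'               tissue = c("leaf", "leaf"), treatment = c("none", "none"),
#'               group = c("L", "L"))
#' computeExpressionThreshold(fs, quantile = 0.5)
#' @export
computeExpressionThreshold <- function(x, quantile = 0.05,
                                       sdMultiplier = 3,
                                       aggregate = c("min", "max", "mean")) {
  stopifnot(is(x, "FPKMSet"))
  aggregate <- match.arg(aggregate)
  if (!is.numeric(quantile) || quantile <= 0 || quantile > 0.5)
    stop("quantile must lie in (0, 0.5]")
  v <- fpkm(x)
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty expression matrix")
  groups <- as.character(SummarizedExperiment::colData(x)$group)
  perGroup <- vapply(unique(groups), function(g) {
    pool <- unlist(lapply(which(groups == g), function(j) {
      col <- v[, j]
      col[col <= stats::quantile(col, probs = quantile, type = 7)]
    }), use.names = FALSE)
    if (length(pool) < 2L) {
      warning("group '", g, "': pooled tail has fewer than 2 values; ",
              "SD treated as 0")
      s <- 0
    } else s <- stats::sd(pool)
    mean(pool) + sdMultiplier * s
  }, numeric(1))
  glob <- switch(aggregate, min = min(perGroup), max = max(perGroup),
                 mean = mean(perGroup))
  list(global_threshold = glob, per_group_thresholds = perGroup,
       quantile = quantile, sd_multiplier = sdMultiplier,
       aggregate = aggregate)
}
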