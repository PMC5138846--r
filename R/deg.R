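#' Floored log2 fold change of FPKM values
#'
#' `log2(max(treat, floor) / max(ctrl, floor))`. The floor (default the
#' minimum expression threshold, 0.24) prevents division by zero for
#' unexpressed genes.
#'
#' @param treat,ctrl non-negative FPKM values (vectorised).
#' @param floor positive FPKM floor.
#' @return log2 fold change(s).
#' @examples
#' log2FoldChange(4, 1, floor = 0.24)  # 2
#' @export
log2FoldChange <- function(treat, ctrl, floor = 0.24) {
  if (floor <= 0) stop("floor must be > 0")
  if (any(treat < 0) || any(ctrl < 0))
    stop("FPKM values must be non-negative")
  log2(pmax(treat, floor) / pmax(ctrl, floor))
}

#' Welch two-sample two-sided t-test p-value
#'
#' Unequal-variance (Welch) t-test. Degenerate inputs are handled
#' explicitly: if both groups are constant and equal the p-value is 1;
#' if both are constant but different it is 0 (with a warning).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return Two-sided p-value.
#' @export
welchTest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
    warning("both groups constant but different; p set to 0")
    return(0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Adjust p-values for multiple testing (BH or BY step-up)
#'
#' Benjamini-Hochberg or Benjamini-Yekutieli step-up adjustment, clipped
#' to <= 1 (BY multiplies by the harmonic-sum factor before the
#' step-up pass).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return Adjusted q-values in the input order.
#' @export
adjustPvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Call differentially expressed genes between two sample classes
#'
#' Per gene: log2 fold change of the class means (floored), Welch
#' two-sided p-value, BH (or BY) q-value. Genes with
#' `q <= fdrCutoff` and `|log2FC| >= lfcCutoff` are returned, with
#' direction `up` iff the fold change is positive (class A over
#' class B). By default the Welch test is applied to
#' `log2(max(FPKM, floor))` values, where expression noise is
#' approximately Gaussian with stable variance; set
#' `logTransform = FALSE` to test raw FPKM values.
#'
#' @param x an [FPKMSet-class].
#' @param classA,classB disjoint sample-id vectors, each >= 2 samples.
#'   `classA` is the numerator of the fold change.
#' @param fdrCutoff FDR cutoff on q (default 0.05).
#' @param lfcCutoff absolute log2-fold-change cutoff (default 1).
#' @param floor FPKM floor for the fold change (default 0.24).
#' @param adjust multiple-testing method, `"BH"` (default) or `"BY"`.
#' @param logTransform test on the log2 scale (default TRUE).
#' @return data.frame `gene_id`, `log2fc`, `p_value`, `q_value`,
#'   `direction`, ordered by q then gene id.
#' @export
callDEGs <- function(x, classA, classB, fdrCutoff = 0.05,
                     lfcCutoff = 1, floor = 0.24, adjust = "BH",
                     logTransform = TRUE) {
  stopifnot(is(x, "FPKMSet"))
  if (length(intersect(classA, classB)))
    stop("classA and classB overlap")
  bad <- setdiff(c(classA, classB), colnames(x))
  if (length(bad))
    stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  if (length(classA) < 2L || length(classB) < 2L)
    stop("each class needs at least 2 samples")
  v <- fpkm(x)
  va <- v[, classA, drop = FALSE]
  vb <- v[, classB, drop = FALSE]
  lfc <- log2FoldChange(rowMeans(va), rowMeans(vb), floor = floor)
  ta <- if (logTransform) log2(pmax(va, floor)) else va
  tb <- if (logTransform) log2(pmax(vb, floor)) else vb
  p <- vapply(seq_len(nrow(v)),
              function(i) welchTest(ta[i, ], tb[i, ]), numeric(1))
  q <- adjustPvalues(p, method = adjust)
  keep <- which(q <= fdrCutoff & abs(lfc) >= lfcCutoff)
  res <- data.frame(gene_id = rownames(v)[keep], log2fc = lfc[keep],
                    p_value = p[keep], q_value = q[keep],
                    direction = ifelse(lfc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  res <- res[order(res$q_value, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tissue-preferential expression states for a network overlay
#'
#' A gene is `expressed` in a tissue iff its mean FPKM over that
#' tissue's samples is strictly greater than the threshold.
#'
#' @param genes gene ids to annotate.
#' @param x an [FPKMSet-class].
#' @param tissue tissue label (must have >= 1 sample).
#' @param threshold expression threshold (FPKM), e.g. from
#'   [computeExpressionThreshold()].
#' @return data.frame `gene_id`, `context`, `state`
#'   (`expressed`/`not_expressed`).
#' @export
assignTissueStates <- function(genes, x, tissue, threshold) {
  stopifnot(is(x, "FPKMSet"))
  cd <- SummarizedExperiment::colData(x)
  cols <- which(cd$tissue == tissue)
  if (!length(cols)) stop("unknown tissue: ", tissue)
  badG <- setdiff(genes, rownames(x))
  if (length(badG))
    stop("unknown gene id(s): ", paste(badG, collapse = ", "))
  m <- rowMeans(fpkm(x)[genes, cols, drop = FALSE])
  data.frame(gene_id = genes, context = tissue,
             state = ifelse(m > threshold, "expressed", "not_expressed"),
             stringsAsFactors = FALSE)
}

#' Stress-differential expression states for a network overlay
#'
#' Compares a stress treatment against its control (CK) in one tissue.
#' A gene below the expression threshold in both samples is
#' `not_expressed`; otherwise it is `up` if the floored log2 fold
#' change (treatment over control) is >= 1, `down` if <= -1, else
#' `unchanged`. Boundaries are inclusive. When several samples exist
#' for a condition their mean FPKM is used.
#'
#' @param genes gene ids to annotate.
#' @param x an [FPKMSet-class].
#' @param tissue tissue label.
#' @param treatment stress treatment label (`PEG` or `NaCl`).
#' @param threshold expression threshold (FPKM).
#' @param floor FPKM floor for the fold change; defaults to
#'   `threshold`.
#' @param lfcCutoff highlight cutoff on |log2FC| (default 1).
#' @return data.frame `gene_id`, `context`, `state`
#'   (`up`/`down`/`unchanged`/`not_expressed`), `log2fc` (NA when
#'   `not_expressed`).
#' @export
assignStressStates <- function(genes, x, tissue, treatment, threshold,
                               floor = threshold, lfcCutoff = 1) {
  stopifnot(is(x, "FPKMSet"))
  cd <- SummarizedExperiment::colData(x)
  trtCols <- which(cd$tissue == tissue & cd$treatment == treatment)
  ctrlCols <- which(cd$tissue == tissue & cd$treatment == "CK")
  if (!length(trtCols))
    stop("no '", treatment, "' sample for tissue '", tissue, "'")
  if (!length(ctrlCols))
    stop("no control (CK) sample for tissue '", tissue, "'")
  badG <- setdiff(genes, rownames(x))
  if (length(badG))
    stop("unknown gene id(s): ", paste(badG, collapse = ", "))
  v <- fpkm(x)
  mt <- rowMeans(v[genes, trtCols, drop = FALSE])
  mc <- rowMeans(v[genes, ctrlCols, drop = FALSE])
  lfc <- log2FoldChange(mt, mc, floor = floor)
  notExpr <- mt <= threshold & mc <= threshold
  state <- ifelse(notExpr, "not_expressed",
                  ifelse(lfc >= lfcCutoff, "up",
                         ifelse(lfc <= -lfcCutoff, "down", "unchanged")))
  data.frame(gene_id = genes,
             context = paste(tissue, treatment, sep = ":"),
             state = state,
             log2fc = ifelse(notExpr, NA_real_, lfc),
             stringsAsFactors = FALSE)
}

#' Write node-state overlays to TSV
#'
#' @param overlay data.frame from [assignTissueStates()] or
#'   [assignStressStates()] (rows of several calls may be rbind-ed).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeOverlay <- function(overlay, path) {
  if (!"log2fc" %in% colnames(overlay)) overlay$log2fc <- NA_real_
  write.table(overlay, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
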