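#' Parse BLAST tabular (outfmt 6) output
#'
#' Reads a 12-column tabular hit file (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore) and
#' assigns per-query hit ranks by ascending e-value, ties broken by
#' descending bitscore then subject id.
#'
#' @param path path to the tabular file.
#' @return data.frame with the 12 standard columns plus
#'   `rank_within_query`.
#' @export
parseBlastTabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  empty <- as.data.frame(setNames(
    c(list(character(), character()), rep(list(numeric()), 10),
      list(integer())),
    c(cols, "rank_within_query")), stringsAsFactors = FALSE)
  fields <- utils::count.fields(path, sep = "\t", comment.char = "#",
                                blank.lines.skip = TRUE)
  if (!length(fields) || all(is.na(fields))) return(empty)
  bad <- which(fields != 12L)
  if (length(bad))
    stop("malformed BLAST tabular line ", bad[1L], " in ", path,
         " (", fields[bad[1L]], " fields, expected 12)")
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    comment.char = "#",
                    colClasses = c("character", "character",
                                   rep("numeric", 10)))
  colnames(tab) <- cols
  if (any(!is.finite(tab$evalue)) || any(tab$evalue < 0))
    stop("invalid e-value(s) in ", path)
  o <- order(tab$qseqid, tab$evalue, -tab$bitscore, tab$sseqid)
  tab <- tab[o, , drop = FALSE]
  tab$rank_within_query <- stats::ave(seq_len(nrow(tab)), tab$qseqid,
                                      FUN = seq_along)
  rownames(tab) <- NULL
  tab
}

#' Call orthologue pairs from bidirectional BLAST hits
#'
#' Best pairs: gene pairs where each gene lies within the other's top
#' `topN` hits (default 3). Secondary pairs: reciprocal hits (present
#' in both directions) whose e-values pass `secondaryEvalue` (default
#' 1e-55) but that are not best; with
#' `evalueBothDirections = FALSE` only the better of the two e-values
#' must pass. Each unordered pair is reported once with the better
#' tier.
#'
#' @param hitsAB,hitsBA data.frames from [parseBlastTabular()] for the
#'   A-to-B and B-to-A searches.
#' @param topN reciprocal-rank cutoff for best pairs (default 3).
#' @param secondaryEvalue e-value cutoff for secondary pairs (default
#'   1e-55), strict (`<`).
#' @param evalueBothDirections require both directions to pass the
#'   e-value cutoff (default TRUE).
#' @return data.frame `gene_a`, `gene_b`, `tier` (`best`/`secondary`),
#'   `evalue_ab`, `evalue_ba`.
#' @export
callOrthologs <- function(hitsAB, hitsBA, topN = 3,
                          secondaryEvalue = 1e-55,
                          evalueBothDirections = TRUE) {
  if (topN < 1) stop("topN must be >= 1")
  if (!nrow(hitsAB) || !nrow(hitsBA))
    return(data.frame(gene_a = character(), gene_b = character(),
                      tier = character(), evalue_ab = numeric(),
                      evalue_ba = numeric(), stringsAsFactors = FALSE))
  # collapse multiple HSPs per (query, subject) to the best one, then
  # rank each query's distinct subjects (top-N counts subjects, not
  # HSP lines)
  best <- function(h) {
    o <- order(h$qseqid, h$evalue, -h$bitscore, h$sseqid)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(paste(h$qseqid, h$sseqid, sep = "\r")), ,
           drop = FALSE]
    h$rank_within_query <- stats::ave(seq_len(nrow(h)), h$qseqid,
                                      FUN = seq_along)
    h[, c("qseqid", "sseqid", "evalue", "rank_within_query")]
  }
  ab <- best(hitsAB)
  ba <- best(hitsBA)
  keyAB <- paste(ab$qseqid, ab$sseqid, sep = "\r")
  keyBA <- paste(ba$sseqid, ba$qseqid, sep = "\r")  # as (a, b)
  common <- intersect(keyAB, keyBA)
  if (!length(common))
    return(data.frame(gene_a = character(), gene_b = character(),
                      tier = character(), evalue_ab = numeric(),
                      evalue_ba = numeric(), stringsAsFactors = FALSE))
  iAB <- match(common, keyAB)
  iBA <- match(common, keyBA)
  geneA <- ab$qseqid[iAB]
  geneB <- ab$sseqid[iAB]
  eAB <- ab$evalue[iAB]
  eBA <- ba$evalue[iBA]
  rAB <- ab$rank_within_query[iAB]
  rBA <- ba$rank_within_query[iBA]
  isBest <- rAB <= topN & rBA <= topN
  passE <- if (evalueBothDirections)
    eAB < secondaryEvalue & eBA < secondaryEvalue
  else pmin(eAB, eBA) < secondaryEvalue
  isSecondary <- !isBest & passE
  keep <- isBest | isSecondary
  res <- data.frame(gene_a = geneA[keep], gene_b = geneB[keep],
                    tier = ifelse(isBest[keep], "best", "secondary"),
                    evalue_ab = eAB[keep], evalue_ba = eBA[keep],
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an ortholog-pair table to TSV
#' @param pairs data.frame from [callOrthologs()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeOrthologs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
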