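# Independent brute-force oracles used across the test suite. These
# deliberately re-derive every rule with literal loops, separate from
# the package implementation.

# Literal evaluation of the network retention rules on a gene x sample
# FPKM matrix: per-pair PCC, directional ranks by explicit sorting,
# sign-appropriate candidate cutoffs, union retention, tier labels.
bruteNetworkEdges <- function(v, posCut = 0.65, negCut = -0.45,
                              rankCut = 3, mrCut = 30) {
  v <- v[apply(v, 1, stats::sd) > 0, , drop = FALSE]
  ids <- rownames(v)
  n <- nrow(v)
  if (n < 2) return(NULL)
  pcc <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    pcc[i, j] <- stats::cor(v[i, ], v[j, ])
  rankOf <- function(i, j, direction) {
    others <- setdiff(seq_len(n), i)
    key <- if (direction == "pos") -pcc[i, others] else pcc[i, others]
    ord <- others[order(key, ids[others])]
    which(ord == j)
  }
  rows <- list()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    p <- pcc[i, j]
    if (p > posCut) dirn <- "pos"
    else if (p < negCut && p < 0) dirn <- "neg"
    else next
    a <- i; b <- j
    if (ids[i] > ids[j]) { a <- j; b <- i }
    rab <- rankOf(a, b, dirn)
    rba <- rankOf(b, a, dirn)
    mr <- sqrt(rab * rba)
    if (!(min(rab, rba) <= rankCut || mr <= mrCut)) next
    tier <- if (min(rab, rba) <= rankCut) "rank_top"
    else if (mr <= 5) "mr_le_5" else "mr_le_30"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ids[a], gene_b = ids[b], pcc = p,
      rank_ab = rab, rank_ba = rba, mr = mr,
      sign = if (dirn == "pos") "positive" else "negative",
      tier = tier, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b, out$sign), , drop = FALSE]
}

# Brute-force k-clique percolation on an adjacency matrix: enumerate
# all k-subsets, keep complete ones, chain cliques sharing k-1 nodes,
# return sorted node-unions of the connected clique sets.
bruteCPM <- function(adj, k) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  if (n < k) return(list())
  cl <- list()
  idx <- utils::combn(n, k)
  for (c0 in seq_len(ncol(idx))) {
    s <- idx[, c0]
    if (sum(adj[s, s]) == k * (k - 1)) cl[[length(cl) + 1L]] <- s
  }
  if (!length(cl)) return(list())
  m <- length(cl)
  comp <- seq_len(m)
  for (a in seq_len(m - 1)) for (b in seq.int(a + 1, m)) {
    if (length(intersect(cl[[a]], cl[[b]])) == k - 1) {
      old <- comp[b]; new <- comp[a]
      if (old != new) comp[comp == old] <- new
    }
  }
  out <- lapply(unique(comp), function(cc)
    sort(nodes[unique(unlist(cl[comp == cc]))]))
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# Erdos-Renyi graph as an adjacency matrix with gene-like node names.
erdosRenyiAdj <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p]
  adj[on] <- 1L
  adj <- adj + t(adj)
  nm <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(nm, nm)
  adj
}

# Wrap an adjacency matrix as a CoexpressionNetwork with positive
# edges so the package's CPM can run on it.
adjToNetwork <- function(adj) {
  up <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  nm <- rownames(adj)
  ed <- if (nrow(up)) data.frame(
    gene_a = nm[up[, 1]], gene_b = nm[up[, 2]], pcc = 0.9,
    rank_ab = 1, rank_ba = 1, mr = 1, sign = "positive",
    tier = "rank_top", stringsAsFactors = FALSE)
  else data.frame(gene_a = character(), gene_b = character(),
                  pcc = numeric(), rank_ab = numeric(),
                  rank_ba = numeric(), mr = numeric(),
                  sign = character(), tier = character(),
                  stringsAsFactors = FALSE)
  new("CoexpressionNetwork", nodes = nm, edges = ed,
      provenance = "global", parameters = list())
}

# Step-up multiple-testing adjustment written as an explicit loop.
bruteStepUp <- function(p, method) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  cm <- if (method == "BY") sum(1 / seq_len(n)) else 1
  adj <- sorted * n * cm / seq_len(n)
  if (n > 1)
    for (i in seq.int(n - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper hypergeometric tail P(X >= k) for a 2x2 enrichment table.
hyperTail <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Literal evaluation of the reciprocal-top-N / secondary e-value
# orthologue rules from two ranked hit tables.
bruteOrthologs <- function(ab, ba, topN = 3, secondaryEvalue = 1e-55) {
  bestHits <- function(h) {
    out <- list()
    for (q in unique(h$qseqid)) {
      sub <- h[h$qseqid == q, , drop = FALSE]
      sub <- sub[order(sub$evalue, -sub$bitscore, sub$sseqid), ,
                 drop = FALSE]
      sub <- sub[!duplicated(sub$sseqid), , drop = FALSE]
      sub$rank <- seq_len(nrow(sub))
      out[[q]] <- sub
    }
    out
  }
  habs <- bestHits(ab)
  hbas <- bestHits(ba)
  rows <- list()
  for (q in names(habs)) {
    for (r in seq_len(nrow(habs[[q]]))) {
      s <- habs[[q]]$sseqid[r]
      rev <- hbas[[s]]
      if (is.null(rev) || !(q %in% rev$sseqid)) next
      rr <- which(rev$sseqid == q)
      eAB <- habs[[q]]$evalue[r]
      eBA <- rev$evalue[rr]
      isBest <- habs[[q]]$rank[r] <= topN && rev$rank[rr] <= topN
      isSec <- !isBest && eAB < secondaryEvalue && eBA < secondaryEvalue
      if (isBest || isSec)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = q, gene_b = s,
          tier = if (isBest) "best" else "secondary",
          evalue_ab = eAB, evalue_ba = eBA, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      tier = character(), evalue_ab = numeric(),
                      evalue_ba = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mean best-match Jaccard between planted modules and recovered
# communities.
meanBestJaccard <- function(planted, recovered) {
  if (!length(recovered)) return(0)
  mean(vapply(planted, function(tm)
    max(vapply(recovered, function(m)
      length(intersect(m, tm)) / length(union(m, tm)), numeric(1))),
    numeric(1)))
}

# Small FPKMSet fixture.
toyFPKMSet <- function(values, groups = NULL) {
  ns <- ncol(values)
  if (is.null(groups)) groups <- rep("G1", ns)
  FPKMSet(values, tissue = rep("leaf", ns),
          treatment = rep("none", ns), group = groups)
}

# Random FPKM-like matrix with an optional block of correlated genes.
randomFPKMMatrix <- function(nGenes, nSamples, nCorrelated = 0) {
  base <- stats::rnorm(nGenes, 3, 1)
  le <- matrix(base, nGenes, nSamples) +
    matrix(stats::rnorm(nGenes * nSamples, sd = 0.6), nGenes, nSamples)
  if (nCorrelated >= 2) {
    act <- stats::rnorm(nSamples, sd = 1.5)
    sgn <- rep(c(1, -1), length.out = nCorrelated)
    le[seq_len(nCorrelated), ] <- le[seq_len(nCorrelated), ] +
      outer(sgn, act)
  }
  v <- 2^le
  dimnames(v) <- list(sprintf("g%03d", seq_len(nGenes)),
                      sprintf("s%02d", seq_len(nSamples)))
  v
}

# Evaluate code under a temporary seed, restoring the RNG state.
withSeedForTest <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
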