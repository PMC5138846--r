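test_that("pearsonCorrelation matches hand-evaluated values", {
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
  # cov-sum 4, each centered sum of squares 5 -> r = 4/5
  expect_equal(pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearsonCorrelation(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pearsonCorrelation(c(1, 2), c(1, 2)), "3")
})

test_that("mutualRank is the geometric mean of the directional ranks", {
  expect_equal(mutualRank(3, 12), 6)
  expect_equal(mutualRank(1, 1), 1)
  expect_equal(mutualRank(2, 8), 4)
  expect_error(mutualRank(0, 5), ">= 1")
  set.seed(77)
  a <- sample(1:500, 2000, replace = TRUE)
  b <- sample(1:500, 2000, replace = TRUE)
  mr <- mutualRank(a, b)
  expect_true(all(mr >= pmin(a, b) - 1e-12))
  expect_true(all(mr <= pmax(a, b) + 1e-12))
})

test_that("directional ranks sort partners by PCC with lexicographic ties", {
  pcc <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  pcc["a", "b"] <- pcc["b", "a"] <- 0.9
  pcc["a", "c"] <- pcc["c", "a"] <- 0.5
  pcc["a", "d"] <- pcc["d", "a"] <- 0.1
  pcc["b", "c"] <- pcc["c", "b"] <- -0.2
  pcc["b", "d"] <- pcc["d", "b"] <- -0.8
  pcc["c", "d"] <- pcc["d", "c"] <- 0.5
  rk <- rankMatrices(pcc)
  expect_equal(rk$positive["a", "b"], 1)  # highest partner of a
  expect_equal(rk$positive["a", "c"], 2)
  expect_equal(rk$positive["a", "d"], 3)  # third highest -> rank 3
  expect_equal(rk$negative["b", "d"], 1)  # most negative first
  expect_equal(rk$negative["b", "c"], 2)
  # ties: c and d both at 0.5 for... (c: partners a 0.5, b -0.2, d 0.5)
  expect_equal(rk$positive["c", "a"], 1)  # tie with d, 'a' < 'd'
  expect_equal(rk$positive["c", "d"], 2)
})

test_that("buildNetwork reproduces a brute-force evaluation of the retention rules", {
  set.seed(2024)
  for (rep in 1:8) {
    nG <- sample(20:40, 1)
    v <- randomFPKMMatrix(nG, 10, nCorrelated = sample(c(0, 5, 8), 1))
    fs <- toyFPKMSet(v)
    net <- suppressMessages(buildNetwork(fs))
    got <- networkEdges(net)
    want <- bruteNetworkEdges(v)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(want) <- NULL
      expect_equal(got, want, tolerance = 1e-12)
    }
    # stored PCC must be reproducible from the matrix
    if (nrow(got)) {
      recomputed <- vapply(seq_len(nrow(got)), function(r)
        stats::cor(v[got$gene_a[r], ], v[got$gene_b[r], ]), numeric(1))
      expect_equal(got$pcc, recomputed, tolerance = 1e-9)
      expect_equal(got$mr, sqrt(got$rank_ab * got$rank_ba))
      expect_true(all((got$pcc > 0) == (got$sign == "positive")))
    }
  }
})

test_that("perfectly correlated triples form rank-top edges of both signs", {
  base <- c(1, 2, 3, 4, 5, 6)
  v <- rbind(A = 2 * base + 1, B = 2 * base + 1.0001,
             C = max(base) * 2 - 2 * base)
  colnames(v) <- paste0("s", 1:6)
  fs <- toyFPKMSet(v)
  net <- buildNetwork(fs)
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 3)
  ab <- ed[ed$gene_a == "A" & ed$gene_b == "B", ]
  expect_equal(ab$sign, "positive")
  expect_equal(ab$tier, "rank_top")
  for (pair in list(c("A", "C"), c("B", "C"))) {
    e <- ed[ed$gene_a == pair[1] & ed$gene_b == pair[2], ]
    expect_equal(e$sign, "negative")
    expect_equal(e$tier, "rank_top")
  }
})

test_that("single-gene and zero-variance inputs yield empty or reduced networks", {
  v <- matrix(2^rnorm(8), nrow = 1,
              dimnames = list("g1", paste0("s", 1:8)))
  net <- buildNetwork(toyFPKMSet(v))
  expect_length(networkNodes(net), 0)
  expect_equal(nrow(networkEdges(net)), 0)

  v2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),
              g3 = c(5, 5, 5, 5))
  colnames(v2) <- paste0("s", 1:4)
  expect_message(net2 <- buildNetwork(toyFPKMSet(v2)), "zero variance")
  expect_false("g3" %in% networkNodes(net2))
  expect_equal(networkParameters(net2)$zero_variance_excluded, 1)
})

test_that("network construction is deterministic", {
  set.seed(5)
  v <- randomFPKMMatrix(25, 10, nCorrelated = 6)
  fs <- toyFPKMSet(v)
  n1 <- buildNetwork(fs)
  n2 <- buildNetwork(fs)
  expect_identical(networkEdges(n1), networkEdges(n2))
})

test_that("extractSubnetwork returns the seed neighbourhood under a sign filter", {
  ed <- data.frame(
    gene_a = c("a", "a", "a", "a", "a", "x"),
    gene_b = c("b", "c", "d", "e", "f", "y"),
    pcc = c(0.9, 0.8, 0.7, -0.6, -0.7, 0.9),
    rank_ab = 1, rank_ba = 1, mr = 1,
    sign = c("positive", "positive", "positive", "negative",
             "negative", "positive"),
    tier = "rank_top", stringsAsFactors = FALSE)
  net <- new("CoexpressionNetwork",
             nodes = c("a", "b", "c", "d", "e", "f", "x", "y"),
             edges = ed, provenance = "global", parameters = list())
  sub <- extractSubnetwork(net, "a")
  expect_setequal(networkNodes(sub), c("a", "b", "c", "d", "e", "f"))
  expect_equal(nrow(networkEdges(sub)), 5)
  subNeg <- extractSubnetwork(net, "a", mode = "negative")
  expect_setequal(networkNodes(subNeg), c("a", "e", "f"))
  expect_equal(nrow(networkEdges(subNeg)), 2)
  # two seeds sharing a neighbour: the neighbour appears once
  sub2 <- extractSubnetwork(net, c("a", "x"))
  expect_equal(sum(networkNodes(sub2) == "y"), 1)
  expect_warning(sub3 <- extractSubnetwork(net, c("a", "zz")), "zz")
  expect_setequal(networkNodes(sub3), networkNodes(sub))
  expect_error(extractSubnetwork(net, character()), "non-empty")
})

test_that("compareNetworks computes overlap ratios and edge Jaccard", {
  mk <- function(pairs, signs) {
    ed <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                     pcc = ifelse(signs == "positive", 0.9, -0.9),
                     rank_ab = 1, rank_ba = 1, mr = 1, sign = signs,
                     tier = "rank_top", stringsAsFactors = FALSE)
    new("CoexpressionNetwork",
        nodes = sort(unique(c(pairs))), edges = ed,
        provenance = "global", parameters = list())
  }
  a <- mk(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "e")),
          rep("positive", 4))
  same <- compareNetworks(a, a)
  expect_equal(same$jaccard_edges, 1)
  expect_equal(same$edge_overlap_ratio_a, 1)
  b <- mk(cbind(c("a", "b", "p", "q"), c("b", "c", "q", "r")),
          rep("positive", 4))
  cmp <- compareNetworks(a, b)
  expect_equal(cmp$shared_edges, 2)
  expect_equal(cmp$jaccard_edges, 2 / 6)
  # same pair with opposite sign is a different edge
  c2 <- mk(cbind("a", "b"), "negative")
  expect_equal(compareNetworks(a, c2)$shared_edges, 0)
  disj <- mk(cbind("u", "v"), "positive")
  expect_equal(compareNetworks(a, disj)$jaccard_edges, 0)
})
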