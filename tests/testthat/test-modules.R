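completeAdj <- function(n) {
  adj <- matrix(1L, n, n) - diag(1L, n)
  nm <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(nm, nm)
  adj
}

test_that("k-clique enumeration counts cliques in canonical graphs", {
  expect_length(enumerateKCliques(adjToNetwork(completeAdj(6)), 6), 1)
  expect_length(enumerateKCliques(adjToNetwork(completeAdj(7)), 6), 7)
  # path graph has no k-cliques for k >= 3
  path <- matrix(0L, 8, 8,
                 dimnames = list(sprintf("n%02d", 1:8),
                                 sprintf("n%02d", 1:8)))
  for (i in 1:7) path[i, i + 1] <- path[i + 1, i] <- 1L
  expect_length(enumerateKCliques(adjToNetwork(path), 6), 0)
  expect_error(enumerateKCliques(adjToNetwork(path), 2), ">= 3")
})

test_that("clique overlap chaining matches the textbook CPM cases", {
  # two 6-cliques sharing 5 nodes percolate into one 7-node community
  adj <- completeAdj(7)
  adj["n01", "n07"] <- adj["n07", "n01"] <- 0L
  cm <- cpmCommunities(adjToNetwork(adj), 6)
  expect_length(moduleList(cm), 1)
  expect_length(moduleList(cm)[[1]], 7)

  # two 6-cliques sharing 4 nodes stay separate, overlapping in 4 nodes
  nm <- sprintf("n%02d", 1:8)
  adj2 <- matrix(0L, 8, 8, dimnames = list(nm, nm))
  c1 <- nm[1:6]; c2 <- nm[c(3:6, 7, 8)]
  for (cl in list(c1, c2))
    for (a in cl) for (b in cl) if (a != b) adj2[a, b] <- 1L
  cm2 <- cpmCommunities(adjToNetwork(adj2), 6)
  expect_length(moduleList(cm2), 2)
  expect_equal(lengths(moduleList(cm2)), c(M0001 = 6L, M0002 = 6L))
  expect_length(intersect(moduleList(cm2)[[1]], moduleList(cm2)[[2]]), 4)

  # a single 6-clique is one community of 6
  cm3 <- cpmCommunities(adjToNetwork(completeAdj(6)), 6)
  expect_equal(lengths(moduleList(cm3)), c(M0001 = 6L))
})

test_that("cpmCommunities equals the brute-force oracle on random graphs", {
  set.seed(314)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    p <- sample(c(0.2, 0.3, 0.4, 0.5, 0.6), 1)
    k <- sample(3:6, 1)
    adj <- erdosRenyiAdj(n, p)
    got <- unname(moduleList(cpmCommunities(adjToNetwork(adj), k)))
    want <- bruteCPM(adj, k)
    expect_equal(got, want)
  }
})

test_that("sign mode controls which edges support cliques", {
  nm <- sprintf("n%02d", 1:6)
  ed <- do.call(rbind, lapply(utils::combn(6, 2, simplify = FALSE),
    function(ij) data.frame(gene_a = nm[ij[1]], gene_b = nm[ij[2]],
                            pcc = 0.9, rank_ab = 1, rank_ba = 1,
                            mr = 1, sign = "positive",
                            tier = "rank_top",
                            stringsAsFactors = FALSE)))
  # flip one edge negative: positive_only loses the 6-clique
  ed$pcc[1] <- -0.9
  ed$sign[1] <- "negative"
  net <- new("CoexpressionNetwork", nodes = nm, edges = ed,
             provenance = "global", parameters = list())
  expect_length(moduleList(cpmCommunities(net, 6, "both")), 1)
  expect_length(moduleList(cpmCommunities(net, 6, "positive_only")), 0)
})

test_that("module connections require the minimum number of linking nodes", {
  nm <- c(sprintf("a%d", 1:6), sprintf("b%d", 1:6))
  mkMods <- function(shared) {
    m1 <- sprintf("a%d", 1:6)
    m2 <- c(sprintf("a%d", seq_len(shared)),
            sprintf("b%d", seq_len(6 - shared)))
    new("CommunityModules",
        modules = list(M0001 = sort(m1), M0002 = sort(m2)),
        k = 6L, signMode = "both")
  }
  emptyNet <- new("CoexpressionNetwork", nodes = nm,
                  edges = data.frame(gene_a = character(),
                                     gene_b = character(),
                                     pcc = numeric(), rank_ab = numeric(),
                                     rank_ba = numeric(), mr = numeric(),
                                     sign = character(),
                                     tier = character(),
                                     stringsAsFactors = FALSE),
                  provenance = "global", parameters = list())
  expect_equal(nrow(moduleConnections(mkMods(3), emptyNet)$links), 1)
  expect_equal(moduleConnections(mkMods(3), emptyNet)$links$linking_nodes, 3)
  expect_equal(nrow(moduleConnections(mkMods(2), emptyNet)$links), 0)
  expect_equal(nrow(moduleConnections(mkMods(0), emptyNet)$links), 0)
  # an edge from a module node into the other module also links
  ed <- data.frame(gene_a = c("a4", "a5", "a6"),
                   gene_b = c("b1", "b2", "b3"),
                   pcc = 0.9, rank_ab = 1, rank_ba = 1, mr = 1,
                   sign = "positive", tier = "rank_top",
                   stringsAsFactors = FALSE)
  net <- new("CoexpressionNetwork", nodes = nm, edges = ed,
             provenance = "global", parameters = list())
  mods <- new("CommunityModules",
              modules = list(M0001 = sprintf("a%d", 1:6),
                             M0002 = sprintf("b%d", 1:6)),
              k = 6L, signMode = "both")
  expect_equal(moduleConnections(mods, net)$links$linking_nodes, 3)
  expect_equal(nrow(moduleConnections(mods, net,
                                      minLinkingNodes = 4)$links), 0)
})

test_that("module ids are deterministic and sized at least k", {
  sim <- generateExpression(nGenes = 150, nModules = 3, moduleSize = 10,
                            seed = 4)
  net <- suppressMessages(buildNetwork(sim$fpkm))
  cm1 <- cpmCommunities(net, 6)
  cm2 <- cpmCommunities(net, 6)
  expect_identical(moduleList(cm1), moduleList(cm2))
  expect_true(all(moduleSizes(cm1) >= 6))
  expect_true(all(unlist(moduleList(cm1)) %in% networkNodes(net)))
})

test_that("the parameter report tracks module count and coverage by k", {
  sim <- generateExpression(nGenes = 100, nModules = 2, moduleSize = 10,
                            seed = 8)
  net <- suppressMessages(buildNetwork(sim$fpkm))
  rep6 <- cpmParameterReport(net, ks = c(4, 6, 10))
  expect_equal(rep6$k, c(4, 6, 10))
  expect_true(all(rep6$gene_coverage >= rep6$n_modules))
  # coverage can only shrink as k grows
  expect_true(all(diff(rep6$gene_coverage) <= 0))
})
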