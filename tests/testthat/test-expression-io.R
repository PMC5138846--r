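test_that("expression matrices round-trip through TSV exactly", {
  set.seed(101)
  sim <- generateExpression(nGenes = 50, nModules = 2, moduleSize = 8,
                            seed = 3)
  fs <- sim$fpkm
  ep <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(fs, ep, mp)
  back <- readExpressionMatrix(ep, mp)
  expect_identical(dim(back), dim(fs))
  expect_identical(rownames(back), rownames(fs))
  expect_identical(colnames(back), colnames(fs))
  expect_equal(fpkm(back), fpkm(fs), tolerance = 0)
  cd <- SummarizedExperiment::colData(back)
  cd0 <- SummarizedExperiment::colData(fs)
  expect_identical(as.character(cd$tissue), as.character(cd0$tissue))
  expect_identical(as.character(cd$group), as.character(cd0$group))
})

test_that("malformed expression inputs are rejected with informative errors", {
  ep <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), ep)
  writeLines(c("sample_id\ttissue\ttreatment\tgroup",
               "s1\tleaf\tnone\tA", "s2\troot\tnone\tB"), mp)
  expect_error(readExpressionMatrix(ep, mp), "g1")

  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t-4"), ep)
  expect_error(readExpressionMatrix(ep, mp), "g2")

  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\tx"), ep)
  expect_error(readExpressionMatrix(ep, mp), "s2")

  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), ep)
  writeLines(c("sample_id\ttissue\ttreatment\tgroup",
               "s1\tleaf\tnone\tA"), mp)
  expect_error(readExpressionMatrix(ep, mp), "s2")
})

test_that("FPKMSet validity enforces the matrix invariants", {
  m <- matrix(c(1, 2, 3, 4), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_s4_class(FPKMSet(m, c("leaf", "root"), c("none", "none"),
                          c("A", "B")), "FPKMSet")
  m2 <- m; m2[1, 1] <- -1
  expect_error(FPKMSet(m2, c("leaf", "root"), c("none", "none"),
                       c("A", "B")), "non-negative")
  m3 <- m; m3[2, 2] <- NA
  expect_error(FPKMSet(m3, c("leaf", "root"), c("none", "none"),
                       c("A", "B")), "finite")
  expect_error(FPKMSet(m, c("leaf", "root"), c("mock", "none"),
                       c("A", "B")), "treatment")
})

test_that("threshold formula matches hand-computed values", {
  # pooled tail {0.1, 0.1, 0.1, 0.3}: mean 0.15, sample SD 0.1 -> 0.45
  v <- matrix(c(0.1, 0.1, 0.1, 0.3, 10, 20, 30, 40), ncol = 1,
              dimnames = list(paste0("g", 1:8), "s1"))
  fs <- toyFPKMSet(v)
  thr <- computeExpressionThreshold(fs, quantile = 0.5)
  expect_equal(unname(thr$per_group_thresholds["G1"]), 0.45)

  # all values equal c in one group -> threshold c (SD = 0)
  vc <- matrix(2.5, nrow = 3, ncol = 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  thr2 <- computeExpressionThreshold(toyFPKMSet(vc), quantile = 0.5)
  expect_equal(unname(thr2$global_threshold), 2.5)

  # two groups 0.2 / 0.5: min aggregation takes 0.2
  v3 <- matrix(c(0.2, 0.2, 0.5, 0.5), nrow = 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fs3 <- toyFPKMSet(v3, groups = c("A", "B"))
  thr3 <- computeExpressionThreshold(fs3, quantile = 0.5)
  expect_equal(unname(thr3$global_threshold), 0.2)
  thr3max <- computeExpressionThreshold(fs3, quantile = 0.5,
                                        aggregate = "max")
  expect_equal(unname(thr3max$global_threshold), 0.5)
})

test_that("threshold is order-invariant and monotone in the SD multiplier", {
  set.seed(42)
  sim <- generateExpression(nGenes = 60, nModules = 0, seed = 9)
  fs <- sim$fpkm
  t1 <- computeExpressionThreshold(fs)
  perm <- sample(nrow(fs))
  permS <- sample(ncol(fs))
  fsP <- FPKMSet(fpkm(fs)[perm, permS],
                 tissue = SummarizedExperiment::colData(fs)$tissue[permS],
                 treatment = SummarizedExperiment::colData(fs)$treatment[permS],
                 group = SummarizedExperiment::colData(fs)$group[permS])
  t2 <- computeExpressionThreshold(fsP)
  expect_equal(t1$global_threshold, t2$global_threshold)
  multipliers <- c(0, 1, 2, 3, 5)
  thr <- vapply(multipliers, function(m)
    computeExpressionThreshold(fs, sdMultiplier = m)$global_threshold,
    numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("degenerate threshold inputs warn or error as specified", {
  v <- matrix(1, nrow = 1, dimnames = list("g1", "s1"))
  fs <- toyFPKMSet(v, groups = "A")
  # the group pools a single value -> SD treated as 0, with warning
  expect_warning(thr <- computeExpressionThreshold(fs, quantile = 0.5),
                 "fewer than 2")
  expect_equal(unname(thr$global_threshold), 1)
  expect_error(computeExpressionThreshold(fs, quantile = 0.7),
               "quantile")
})
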