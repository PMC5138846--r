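test_that("promoters are extracted upstream on the correct strand", {
  gdir <- tempfile(); dir.create(gdir)
  fa <- file.path(gdir, "genome.fa")
  gff <- file.path(gdir, "genes.gff3")
  set.seed(11)
  chrSeq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                  collapse = "")
  writeLines(c(">chr1 test", chrSeq), fa)
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t201\t260\t.\t+\t.\tID=gplus",
    "chr1\ttest\tgene\t30\t100\t.\t-\t.\tID=gminus",
    "chr1\ttest\tgene\t51\t80\t.\t+\t.\tID=gtrunc",
    "chr2\ttest\tgene\t10\t40\t.\t+\t.\tID=gmissing"), gff)
  expect_warning(
    expect_message(pr <- extractPromoters(fa, gff, length = 100),
                   "truncated"),
    "gmissing")
  expect_setequal(names(pr), c("gplus", "gminus", "gtrunc"))
  expect_equal(as.character(pr[["gplus"]]), substr(chrSeq, 101, 200))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrSeq, 101, 200))))
  expect_equal(as.character(pr[["gminus"]]), rc)
  expect_equal(nchar(as.character(pr[["gtrunc"]])), 50)
})

test_that("IUPAC motif counting allows overlaps and de-duplicates palindromes", {
  expect_equal(countMotif("AAAA", "AAA", bothStrands = FALSE), 2)
  expect_equal(countMotif("ACGTACGT", "ACGT"), 2)  # palindrome once/pos
  # forward scan misses the motif; its reverse complement TTTAATTT
  # is present, so the both-strand count is 1
  expect_equal(countMotif("TTTTAATTT", "AAATTAAA",
                          bothStrands = FALSE), 0)
  expect_equal(countMotif("TTTTAATTT", "AAATTAAA"), 1)
  expect_equal(countMotif(paste0("GGG", "AAATTAAA", "GGG"),
                          "AAATTAAA"), 1)  # embedded once
  expect_equal(countMotif("AAATTT", "AAA", bothStrands = TRUE), 2)
  # W = A or T
  expect_equal(countMotif("AAATA", "AWA", bothStrands = FALSE), 2)
  expect_error(countMotif("ACGT", "AXA"), "IUPAC")
})

test_that("both-strand counts are strand-symmetric", {
  set.seed(23)
  for (motif in c("CACGTG", "AAATTAAA", "TGACGT")) {
    seqs <- replicate(20, paste(
      sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
    rcs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
    fwd <- vapply(seqs, countMotif, integer(1), motif = motif)
    rev <- vapply(rcs, countMotif, integer(1), motif = motif)
    expect_equal(unname(fwd), unname(rev))
  }
})

test_that("motif Z statistics follow the permutation-null definition", {
  gen <- generatePromoters(sprintf("g%03d", 1:60), length = 200,
                           motif = "CACGTG",
                           enrichedGenes = sprintf("g%03d", 1:10),
                           plantedRate = 4, backgroundRate = 0.2,
                           seed = 6)
  res <- motifZTest(sprintf("g%03d", 1:10), gen$promoters, "CACGTG",
                    nPerm = 500, seed = 42)
  expect_equal(res$z_score,
               (res$s_observed - res$mu_null) / res$sigma_null)
  expect_equal(res$p_value, pnorm(res$z_score, lower.tail = FALSE))
  expect_true(res$significant)
  # bit-for-bit reproducible under the same seed
  res2 <- motifZTest(sprintf("g%03d", 1:10), gen$promoters, "CACGTG",
                     nPerm = 500, seed = 42)
  expect_identical(res, res2)
  expect_error(motifZTest(sprintf("g%03d", 1:10), gen$promoters,
                          "CACGTG", nPerm = 50), "100")
  expect_error(motifZTest(c("zz"), gen$promoters, "CACGTG"),
               "subset")
})

test_that("Z = 1.645 sits at the one-sided 5% point", {
  expect_equal(pnorm(1.645, lower.tail = FALSE), 0.05, tolerance = 1e-3)
})

test_that("Fisher term enrichment equals the hypergeometric upper tail", {
  bg <- sprintf("g%03d", 1:100)
  lst <- bg[1:10]
  termMap <- list(T1 = bg[c(1:6, 20:33)],   # 6/10 in list, 20 total
                  T2 = bg,                   # whole background
                  T3 = bg[50:54])            # overlap 0
  res <- fisherTermEnrichment(lst, bg, termMap, adjust = "BY")
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$p_value, hyperTail(6, 20, 10, 100), tolerance = 1e-12)
  expect_equal(r1$list_hits, 6)
  expect_equal(res[res$term_id == "T2", "p_value"], 1)
  expect_false(res[res$term_id == "T3", "significant"])
  expect_warning(
    fisherTermEnrichment(lst, bg, list(T0 = "absent_gene")),
    "skipped")
})

test_that("Fisher p equals the hypergeometric tail across table space", {
  set.seed(99)
  for (i in 1:150) {
    N <- sample(8:30, 1)
    n <- sample(1:(N - 1), 1)
    K <- sample(1:N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    bg <- sprintf("x%02d", seq_len(N))
    lst <- bg[seq_len(n)]
    term <- c(bg[seq_len(k)],
              if (K > k) bg[(n + 1):(n + K - k)])
    res <- fisherTermEnrichment(lst, bg, list(T = term), adjust = "BH")
    expect_equal(res$p_value, hyperTail(k, K, n, N), tolerance = 1e-12)
  }
})
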