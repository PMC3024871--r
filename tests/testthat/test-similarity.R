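test_that("locus states follow the match/mismatch/unknown definition", {
  expect_equal(locusState(0L, 0L), "match")
  expect_equal(locusState(1L, 1L), "match")
  expect_equal(locusState(0L, 1L), "mismatch")
  expect_equal(locusState(0L, NA), "unknown")
  expect_equal(locusState(NA, NA), "unknown")
  expect_equal(locusState(c(0L, 0L, NA), c(0L, 1L, 1L)),
               c("match", "mismatch", "unknown"))
})

test_that("maximum matching regions handle the canonical cases", {
  # identical haplotypes: the whole window, all loci matching
  r <- maxMatchRegions(rep(1L, 5), rep(1L, 5), tMis = 2L)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$p, r$q, r$matches), c(1L, 5L, 5L))
  # isolated single mismatches are tolerated
  r <- maxMatchRegions(c(1L, 0L, 1L, 0L, 1L), rep(1L, 5), tMis = 2L)
  expect_equal(c(r$p, r$q, r$matches), c(1L, 5L, 3L))
  # two matches bracketing a 5-long mismatch run: no admissible region
  r <- maxMatchRegions(c(1L, 0L, 0L, 0L, 0L, 0L, 1L), rep(1L, 7), tMis = 2L)
  expect_equal(nrow(r), 0L)
  # all returned regions share the same (maximal) match count
  set.seed(42)
  for (i in 1:25) {
    h1 <- randomHap(15, 0.1); h2 <- randomHap(15, 0.1)
    r <- maxMatchRegions(h1, h2, 2L)
    if (nrow(r) > 1L) expect_length(unique(r$matches), 1L)
  }
  expect_error(maxMatchRegions(rep(1L, 3), rep(1L, 4)), "equal length")
  expect_error(maxMatchRegions(rep(1L, 3), rep(1L, 3), tMis = 0L), "tMis")
})

test_that("similarity matches its definition on worked values", {
  h <- c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L)
  expect_identical(haplotypeSimilarity(h, h), 1)
  expect_equal(haplotypeSimilarity(h, rep(1L, 10)), 0.9)
  # fully mismatching pair: empty region set, similarity 0
  expect_equal(haplotypeSimilarity(rep(0L, 6), rep(1L, 6)), 0)
})

test_that("similarity is bounded, symmetric and monotone in tMis", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(5:20, 1L)
    h1 <- randomHap(n, 0.1); h2 <- randomHap(n, 0.1)
    s2 <- haplotypeSimilarity(h1, h2, 2L)
    expect_gte(s2, 0); expect_lte(s2, 1)
    expect_equal(haplotypeSimilarity(h2, h1, 2L), s2)
    s1 <- haplotypeSimilarity(h1, h2, 1L)
    s3 <- haplotypeSimilarity(h1, h2, 3L)
    expect_lte(s1, s2)
    expect_lte(s2, s3)
  }
  # self-similarity is 1 whenever the haplotype is fully observed
  set.seed(8)
  for (i in 1:10) {
    h <- randomHap(sample(2:30, 1L))
    expect_identical(haplotypeSimilarity(h, h), 1)
  }
})

test_that("similarity equals the exhaustive all-region oracle", {
  set.seed(11)
  for (i in 1:150) {
    n <- sample(4:20, 1L)
    tMis <- sample(1:3, 1L)
    h1 <- randomHap(n, 0.15); h2 <- randomHap(n, 0.15)
    expect_equal(haplotypeSimilarity(h1, h2, tMis, cache = FALSE),
                 oracleSimilarity(h1, h2, tMis),
                 info = sprintf("n=%d tMis=%d %s %s", n, tMis,
                                paste(h1, collapse = ""),
                                paste(h2, collapse = "")))
  }
})

test_that("similarity agrees with the region table it is defined from", {
  set.seed(12)
  for (i in 1:30) {
    h1 <- randomHap(12, 0.1); h2 <- randomHap(12, 0.1)
    r <- maxMatchRegions(h1, h2, 2L)
    v <- haplotypeSimilarity(h1, h2, 2L, cache = FALSE)
    expect_equal(v, if (nrow(r)) r$matches[1L] / 12 else 0)
  }
})
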