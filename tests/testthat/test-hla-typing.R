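test_that("maximum-weight labeled neighbors are found correctly", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.9
  W[1, 4] <- W[4, 1] <- 0.9
  g <- SimilarityGraph(W)
  lab <- c(NA, "0101", "0101", "0201")
  # one labeled neighbor at the maximum weight
  expect_equal(neighborLabels(g, c(NA, "0101", NA, NA), 1),
               list(wm = 0.8, L = "0101"))
  # two neighbors tie at the maximum: both labels are returned
  nl <- neighborLabels(g, lab, 1)
  expect_equal(nl$wm, 0.9)
  expect_equal(nl$L, c("0101", "0201"))
  # no labeled vertex anywhere
  expect_equal(neighborLabels(g, rep(NA_character_, 4), 1),
               list(wm = 0, L = character(0)))
})

test_that("neighbor scans agree with an exhaustive oracle", {
  set.seed(23)
  alleles <- c("0101", "0201", "0301")
  for (i in 1:20) {
    n <- sample(4:10, 1L)
    W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
    g <- SimilarityGraph(W)
    lab <- sample(c(alleles, NA), n, replace = TRUE)
    v <- sample.int(n, 1L)
    got <- neighborLabels(g, lab, v)
    # oracle: scan every other vertex
    wm <- 0; L <- character(0)
    for (u in seq_len(n)) {
      if (u == v || is.na(lab[u])) next
      if (W[v, u] > wm + 1e-12) { wm <- W[v, u]; L <- lab[u] }
      else if (abs(W[v, u] - wm) <= 1e-12) L <- union(L, lab[u])
    }
    expect_equal(got$wm, wm)
    expect_setequal(got$L, L)
  }
})

test_that("unambiguous neighbors yield direct calls and weak ones no-calls", {
  # vertices 1,2 = query; 3,4 labeled references
  W <- matrix(0, 4, 4)
  W[1, 3] <- W[3, 1] <- 1.0
  W[2, 4] <- W[4, 2] <- 1.0
  vt <- data.frame(vertex = 1:4, id = c("q", "q", "r", "r"),
                   hap = c(1L, 2L, 1L, 2L))
  g <- SimilarityGraph(W, vertices = vt)
  lab <- c(NA, NA, "0101", "2401")
  calls <- hlaType(g, lab, "q", tS = 0.65)
  expect_equal(calls$status, "called")
  expect_setequal(c(calls$allele1, calls$allele2), c("0101", "2401"))
  # drop one side's support below the threshold: the whole call is void
  W2 <- W; W2[2, 4] <- W2[4, 2] <- 0.5
  g2 <- SimilarityGraph(W2, vertices = vt)
  calls2 <- hlaType(g2, lab, "q", tS = 0.65)
  expect_equal(calls2$status, "nocall")
  expect_true(is.na(calls2$allele1))
})

test_that("ambiguous neighbor sets resolve by maximal supporting weight", {
  # V1 ties to labels {0101, 0201} at w = 0.9; V2 uniquely supports 0201;
  # the pair (0101, 0201) wins because 0101 keeps its own 0.9 support on
  # V1 while (0201, 0201) would reuse the weaker cross support
  W <- matrix(0, 6, 6)
  W[1, 3] <- W[3, 1] <- 0.9   # V1 ~ 0101 reference
  W[1, 4] <- W[4, 1] <- 0.9   # V1 ~ 0201 reference
  W[2, 4] <- W[4, 2] <- 0.95  # V2 ~ 0201 reference
  W[2, 3] <- W[3, 2] <- 0.7
  vt <- data.frame(vertex = 1:6, id = c("q", "q", "a", "b", "c", "c"),
                   hap = c(1L, 2L, 1L, 1L, 1L, 2L))
  g <- SimilarityGraph(W, vertices = vt)
  lab <- c(NA, NA, "0101", "0201", NA, NA)
  calls <- hlaType(g, lab, "q", tS = 0.65)
  expect_equal(calls$status, "called")
  expect_setequal(c(calls$allele1, calls$allele2), c("0101", "0201"))
})

test_that("coverage and accuracy follow the chromosome-count definitions", {
  truth <- data.frame(id = paste0("i", 1:5),
                      allele1 = c("0101", "0101", "0201", "0201", "0301"),
                      allele2 = c("0201", "0101", "0301", "0101", "0301"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(id = paste0("i", 1:5),
                      allele1 = c("0101", "0101", "0201", NA, "0301"),
                      allele2 = c("0201", "0201", "0301", NA, "0301"),
                      status = c("called", "called", "called", "nocall",
                                 "called"),
                      w1 = 1, w2 = 1, stringsAsFactors = FALSE)
  m <- computeMetrics(truth, calls, 4L)
  # 10 truth chromosomes, 8 called (i4 is a no-call), 7 correct
  # (i2's second allele is wrong)
  expect_equal(m@nAnalyzed, 10L)
  expect_equal(m@nCalled, 8L)
  expect_equal(m@nCorrect, 7L)
  expect_equal(coverage(m), 80)
  expect_equal(accuracy(m), 87.5)
})

test_that("perfect call sets give 100/100 and empty ones an undefined accuracy", {
  truth <- data.frame(id = c("a", "b"), allele1 = c("0101", "0201"),
                      allele2 = c("0201", "0201"), stringsAsFactors = FALSE)
  calls <- data.frame(id = c("a", "b"), allele1 = c("0201", "0201"),
                      allele2 = c("0101", "0201"),
                      status = "called", w1 = 1, w2 = 1,
                      stringsAsFactors = FALSE)
  m <- computeMetrics(truth, calls, 4L)
  expect_equal(coverage(m), 100)
  expect_equal(accuracy(m), 100)  # unordered comparison: {a,b} == {b,a}
  none <- calls; none$status <- "nocall"
  m0 <- computeMetrics(truth, none, 4L)
  expect_equal(coverage(m0), 0)
  expect_true(is.na(accuracy(m0)))
})

test_that("singleton alleles are excluded before any ratio is formed", {
  # 2401 occurs exactly once in the truth data at 4 digits
  truth <- data.frame(id = c("a", "b", "c"),
                      allele1 = c("0101", "0101", "0101"),
                      allele2 = c("0101", "2401", "0101"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(id = "b", allele1 = "0101", allele2 = "0101",
                      status = "called", w1 = 1, w2 = 1,
                      stringsAsFactors = FALSE)
  m <- computeMetrics(truth, calls, 4L)
  expect_equal(m@nAnalyzed, 1L)  # b's 2401 chromosome is excluded
  expect_equal(m@nCalled, 1L)
  expect_equal(m@nCorrect, 1L)
})

test_that("alleles unresolved at the requested resolution are excluded", {
  truth <- data.frame(id = c("a", "b"),
                      allele1 = c("01", "0101"),
                      allele2 = c("0101", "0101"),
                      stringsAsFactors = FALSE)
  calls <- data.frame(id = c("a", "b"),
                      allele1 = c("0101", "0101"),
                      allele2 = c("0101", "0101"),
                      status = "called", w1 = 1, w2 = 1,
                      stringsAsFactors = FALSE)
  m4 <- computeMetrics(truth, calls, 4L)
  expect_equal(m4@nAnalyzed, 3L)  # a's 2-digit allele is not resolvable
  m2 <- computeMetrics(truth, calls, 2L)
  expect_equal(m2@nAnalyzed, 4L)  # at 2 digits everything is analyzable
  expect_equal(accuracy(m2), 100)
})
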