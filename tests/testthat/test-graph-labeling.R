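test_that("two typed individuals yield the textbook graph shape", {
  fx <- makeWorkedFixture()
  configs <- fx$haplotypes[c("I1", "I2")]
  hla <- fx$truth[fx$truth$id %in% c("I1", "I2"), ]
  g <- buildSimilarityGraph(configs, hla, tMis = 2L)
  expect_equal(nrow(vertexTable(g)), 4L)
  cons <- constraintTable(g)
  expect_equal(nrow(cons), 2L)
  expect_false(any(cons$hom))
  expect_setequal(alleleUniverse(g), c("0101", "0201", "2401"))
  # complete similarity edge set: choose(4, 2) unordered pairs
  expect_equal(nrow(similarityEdges(g)), 6L)
  # weights match the pairwise similarity recomputed independently
  W <- edgeWeights(g)
  haps <- c(I1 = list(configs$I1), I2 = list(configs$I2))
  flat <- rbind(configs$I1, configs$I2)
  for (p in 1:3) for (q in (p + 1):4) {
    expect_equal(W[p, q],
                 oracleSimilarity(flat[p, ], flat[q, ], 2L))
  }
})

test_that("a homozygous-typed individual gets a homozygous edge", {
  fx <- makeWorkedFixture()
  g <- buildSimilarityGraph(fx$haplotypes["R1"],
                            fx$truth[fx$truth$id == "R1", ], 2L)
  cons <- constraintTable(g)
  expect_equal(nrow(cons), 1L)
  expect_true(cons$hom)
  expect_equal(cons$a1, "0201")
})

test_that("the within-label objective sums same-label pair weights", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.2
  W[2, 3] <- W[3, 2] <- 0.3
  g <- SimilarityGraph(W)
  expect_equal(conScore(g, rep("0101", 3)), 1.0)
  expect_equal(conScore(g, c("0101", "0201", "2401")), 0)
  expect_equal(conScore(g, c("0101", "0101", NA)), 0.5)
  # random graphs against the independent double-loop oracle
  set.seed(14)
  alleles <- c("0101", "0201", "0301")
  for (i in 1:20) {
    n <- sample(4:10, 1L)
    W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
    g <- SimilarityGraph(W)
    lab <- sample(c(alleles, NA), n, replace = TRUE)
    expect_equal(conScore(g, lab), oracleCon(W, lab))
  }
})

test_that("sparsification keeps exactly the edges at or above tS", {
  set.seed(15)
  n <- 8L
  W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 0
  g <- SimilarityGraph(W)
  expect_equal(nrow(similarityEdges(sparsifyGraph(g, 0))), choose(n, 2))
  expect_equal(nrow(similarityEdges(sparsifyGraph(g, max(W) + 0.01))), 0L)
  s <- sparsifyGraph(g, 0.65)
  kept <- similarityEdges(s)
  oracle <- which(upper.tri(W) & W >= 0.65, arr.ind = TRUE)
  expect_equal(nrow(kept), nrow(oracle))
  expect_true(all(kept$w >= 0.65))
  expect_equal(nrow(vertexTable(s)), n)  # vertices unchanged
})

test_that("the heuristic labeling is always feasible", {
  set.seed(16)
  for (i in 1:40) {
    g <- randomConstraintGraph(nInd = sample(3:8, 1L),
                               nAlleles = sample(2:4, 1L))
    for (tS in c(0.3, 0.65, 0.9)) {
      lab <- heuLabel(g, tS)
      expect_true(isFeasibleLabeling(g, lab))
    }
  }
})

test_that("homozygous seeds and empty-constraint graphs label correctly", {
  # single homozygous edge: both endpoints carry the allele
  W <- matrix(0.5, 2, 2); diag(W) <- 0
  cons <- data.frame(id = "i1", v1 = 1L, v2 = 2L,
                     a1 = "0101", a2 = "0101")
  g <- SimilarityGraph(W, cons)
  expect_equal(heuLabel(g), c("0101", "0101"))
  # no constraint edges at all: every vertex stays unlabeled
  W <- matrix(runif(16), 4, 4); W <- (W + t(W)) / 2; diag(W) <- 0
  expect_true(all(is.na(heuLabel(SimilarityGraph(W)))))
})

test_that("heterozygous edges orient toward their strong neighbors", {
  # vertices: 1-2 het-typed {0101, 0201}; 3 and 4 homozygous-typed
  # references for 0101 and 0201; strong edges force the orientation
  W <- matrix(0, 6, 6)
  W[1, 3] <- W[3, 1] <- 0.9   # v1 close to the 0101 reference
  W[2, 5] <- W[5, 2] <- 0.9   # v2 close to the 0201 reference
  cons <- data.frame(id = c("q", "r0101", "r0201"),
                     v1 = c(1L, 3L, 5L), v2 = c(2L, 4L, 6L),
                     a1 = c("0101", "0101", "0201"),
                     a2 = c("0201", "0101", "0201"))
  g <- SimilarityGraph(W, cons)
  lab <- heuLabel(g, 0.65)
  expect_equal(lab[1], "0101")
  expect_equal(lab[2], "0201")
  # flipping the anchors flips the orientation
  W2 <- matrix(0, 6, 6)
  W2[1, 5] <- W2[5, 1] <- 0.9
  W2[2, 3] <- W2[3, 2] <- 0.9
  g2 <- SimilarityGraph(W2, cons)
  lab2 <- heuLabel(g2, 0.65)
  expect_equal(lab2[1], "0201")
  expect_equal(lab2[2], "0101")
})

test_that("the brute-force labeler is exact and guarded", {
  set.seed(17)
  # exhaustive scan over a 3-individual instance is the definition
  g <- randomConstraintGraph(nInd = 3L, nAlleles = 3L, homProb = 0)
  best <- bruteForceLabel(g)
  expect_true(isFeasibleLabeling(g, best))
  # enumerate the 2^3 orientations independently and compare
  het <- constraintTable(g)
  W <- edgeWeights(g)
  top <- -Inf
  for (o in 0:7) {
    bits <- assignmentBits_test(o, 3L)
    lab <- rep(NA_character_, 6L)
    for (k in 1:3) {
      if (bits[k] == 0L) {
        lab[het$v1[k]] <- het$a1[k]; lab[het$v2[k]] <- het$a2[k]
      } else {
        lab[het$v1[k]] <- het$a2[k]; lab[het$v2[k]] <- het$a1[k]
      }
    }
    top <- max(top, oracleCon(W, lab))
  }
  expect_equal(attr(best, "con"), top)
  # symmetric-weight single het edge: both orientations tie
  W <- matrix(0.4, 2, 2); diag(W) <- 0
  cons <- data.frame(id = "i", v1 = 1L, v2 = 2L, a1 = "01", a2 = "02")
  tie <- bruteForceLabel(SimilarityGraph(W, cons))
  expect_true(isFeasibleLabeling(SimilarityGraph(W, cons), tie))
  # guard refuses oversized instances
  big <- randomConstraintGraph(nInd = 20L, nAlleles = 3L, homProb = 0)
  expect_error(bruteForceLabel(big, maxHet = 15L), "too many|too large")
})

test_that("the heuristic never beats the exact optimum", {
  set.seed(18)
  for (i in 1:25) {
    g <- randomConstraintGraph(nInd = sample(3:7, 1L), nAlleles = 3L)
    lab <- heuLabel(g, 0.5)
    best <- bruteForceLabel(g)
    expect_lte(conScore(g, lab), attr(best, "con") + 1e-9)
  }
})
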