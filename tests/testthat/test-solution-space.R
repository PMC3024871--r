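singletonPed <- function(id = "s1") {
  data.frame(family = "X", id = id, father = NA_character_,
             mother = NA_character_, sex = 1L)
}

trioPed <- function() {
  data.frame(family = "T", id = c("fa", "mo", "ch"),
             father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
             sex = c(1L, 2L, 1L))
}

test_that("phase-free pedigrees collapse to a unique configuration", {
  # both parents homozygous at all loci: no phase freedom anywhere
  g <- rbind(fa = c(0L, 2L, 0L), mo = c(2L, 2L, 0L), ch = c(1L, 2L, 0L))
  sp <- buildSolutionSpace(trioPed(), g, "T")
  expect_equal(nFreeVars(sp), 0L)
  sols <- enumerateSolutions(sp)
  expect_length(sols, 1L)
  expect_true(isTRUE(validateConfiguration(sols[[1]], trioPed(), g)))
  expect_equal(unname(sols[[1]]$haps["ch", 1L, ]), c(0, 1, 0))
  expect_equal(unname(sols[[1]]$haps["ch", 2L, ]), c(1, 1, 0))
})

test_that("a singleton with three het loci has four unordered phasings", {
  g <- matrix(c(1L, 1L, 1L, 0L, 2L), nrow = 1,
              dimnames = list("s1", NULL))
  sp <- buildSolutionSpace(singletonPed(), g, "X")
  expect_equal(nFreeVars(sp), 2L)
  sols <- enumerateSolutions(sp)
  expect_length(sols, 4L)
  keys <- vapply(sols, canonicalConfig, "", ped = singletonPed())
  expect_length(unique(keys), 4L)
  for (s in sols)
    expect_true(isTRUE(validateConfiguration(s, singletonPed(), g)))
})

test_that("a trio heterozygous at a single locus has two configurations", {
  g <- rbind(fa = 1L, mo = 1L, ch = 1L)
  colnames(g) <- NULL
  sp <- buildSolutionSpace(trioPed(), g, "T")
  expect_equal(nFreeVars(sp), 1L)
  sols <- enumerateSolutions(sp)
  keys <- vapply(sols, canonicalConfig, "", ped = trioPed())
  expect_length(unique(keys), 2L)
})

test_that("instantiation validates the assignment vector", {
  g <- matrix(c(1L, 1L), nrow = 1, dimnames = list("s1", NULL))
  sp <- buildSolutionSpace(singletonPed(), g, "X")
  expect_equal(nFreeVars(sp), 1L)
  expect_error(instantiateSolution(sp, integer(0)), "length")
  expect_error(instantiateSolution(sp, c(0L, 1L)), "length")
  expect_error(instantiateSolution(sp, 2L), "0/1")
})

test_that("enumeration is exhaustive, duplicate-free and Mendelian-sound", {
  set.seed(33)
  for (i in 1:25) {
    fam <- randomSmallFamily(m = sample(4:8, 1L))
    sp <- buildSolutionSpace(fam$ped, fam$geno, "X")
    sols <- enumerateSolutions(sp)
    expect_length(sols, 2^nFreeVars(sp))
    keys <- vapply(sols, canonicalConfig, "", ped = fam$ped)
    expect_length(unique(keys), length(keys))
    for (s in sols)
      expect_true(isTRUE(validateConfiguration(s, fam$ped, fam$geno)))
    # completeness and soundness against the brute-force phasing oracle
    oracle <- bruteForceConfigs(fam$ped, fam$geno)
    expect_setequal(keys, oracle)
  }
})

test_that("space construction and enumeration are deterministic", {
  set.seed(5)
  fam <- randomSmallFamily(m = 6L)
  sp1 <- buildSolutionSpace(fam$ped, fam$geno, "X")
  sp2 <- buildSolutionSpace(fam$ped, fam$geno, "X")
  expect_equal(nFreeVars(sp1), nFreeVars(sp2))
  k1 <- vapply(enumerateSolutions(sp1), canonicalConfig, "", ped = fam$ped)
  k2 <- vapply(enumerateSolutions(sp2), canonicalConfig, "", ped = fam$ped)
  expect_identical(k1, k2)
})

test_that("missing genotypes stay unknown unless forced by relatives", {
  # singleton, one missing locus: nothing can force it
  g <- matrix(c(0L, NA, 2L), nrow = 1, dimnames = list("s1", NULL))
  sp <- buildSolutionSpace(singletonPed(), g, "X")
  cfg <- instantiateSolution(sp, integer(0))
  expect_true(all(is.na(cfg$haps[1, , 2])))
  expect_equal(unname(cfg$haps[1, , c(1, 3)]), rbind(c(0, 1), c(0, 1)))
  # trio, child missing at a locus where both parents are homozygous:
  # the child's alleles are forced through transmission
  g2 <- rbind(fa = c(0L, 0L), mo = c(2L, 2L), ch = c(1L, NA))
  sp2 <- buildSolutionSpace(trioPed(), g2, "T")
  cfg2 <- instantiateSolution(sp2, integer(0))
  expect_equal(unname(cfg2$haps["ch", , 2]), c(0, 1))
})

test_that("an obligate crossover triggers the segmented fallback", {
  # father het at both loci; two children force opposite phase relations,
  # so no zero-recombinant configuration exists over the whole window
  ped <- data.frame(family = "R", id = c("fa", "mo", "k1", "k2"),
                    father = c(NA, NA, "fa", "fa"),
                    mother = c(NA, NA, "mo", "mo"),
                    sex = c(1L, 2L, 1L, 1L))
  g <- rbind(fa = c(1L, 1L), mo = c(0L, 0L),
             k1 = c(0L, 0L), k2 = c(0L, 1L))
  # k1 received (0,0) from fa; k2 received (0,1): phases conflict
  expect_error(buildSolutionSpace(ped, g, "R"), "zero-recombinant")
  sp <- segmentFallback(ped, g, "R")
  expect_true(sp@segmented)
  expect_length(sp@segments, 2L)
  for (k in seq_len(2^nFreeVars(sp)) - 1L) {
    cfg <- instantiateSolution(sp, assignmentBits_test(k, nFreeVars(sp)))
    expect_true(isTRUE(validateConfiguration(cfg, ped, g,
                                             maxSwitches = 1L)))
    # stitching introduces at most one transmission switch in total
    expect_lte(sum(attr(cfg, "switches")), 1L)
  }
})

test_that("the fallback reduces to the plain space without recombination", {
  set.seed(77)
  fam <- randomSmallFamily(m = 6L)
  sp1 <- buildSolutionSpace(fam$ped, fam$geno, "X")
  sp2 <- segmentFallback(fam$ped, fam$geno, "X")
  expect_false(sp2@segmented)
  expect_equal(nFreeVars(sp1), nFreeVars(sp2))
})
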