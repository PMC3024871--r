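test_that("noiseless haplotypes are exact copies of founder backgrounds", {
  sim <- simulatePopulation(SimConfig(nFamilies = 4, nChildren = 3,
                                      nMarkers = 20, seed = 3))
  ped <- pedigree(sim$pop)
  founders <- ped$id[is.na(ped$father)]
  bgPool <- unique(unlist(lapply(sim$haplotypes[founders], function(h)
    c(paste(h[1, ], collapse = ""), paste(h[2, ], collapse = "")))))
  for (id in ped$id) {
    h <- sim$haplotypes[[id]]
    expect_true(paste(h[1, ], collapse = "") %in% bgPool)
    expect_true(paste(h[2, ], collapse = "") %in% bgPool)
  }
  # each haplotype's background determines its HLA allele consistently
  # across the population (allele <-> background is a bijection here)
  seen <- list()
  for (id in ped$id) {
    h <- sim$haplotypes[[id]]
    al <- unlist(sim$truth[sim$truth$id == id, c("allele1", "allele2")])
    for (k in 1:2) {
      key <- paste(h[k, ], collapse = "")
      if (is.null(seen[[key]])) seen[[key]] <- al[k]
      else expect_equal(unname(seen[[key]]), unname(al[k]))
    }
  }
})

test_that("simulation is reproducible and seeds matter", {
  a <- simulatePopulation(SimConfig(nFamilies = 3, nMarkers = 15, seed = 4))
  b <- simulatePopulation(SimConfig(nFamilies = 3, nMarkers = 15, seed = 4))
  expect_identical(genotypes(a$pop), genotypes(b$pop))
  expect_identical(a$truth, b$truth)
  expect_identical(a$haplotypes, b$haplotypes)
  c_ <- simulatePopulation(SimConfig(nFamilies = 3, nMarkers = 15, seed = 5))
  expect_false(identical(genotypes(a$pop), genotypes(c_$pop)))
})

test_that("realized founder allele frequencies match the configuration", {
  # 100 couples = 200 founders = 400 founder chromosomes
  cfg <- SimConfig(nFamilies = 100L, nChildren = 0L, nMarkers = 10L,
                   seed = 6)
  sim <- simulatePopulation(cfg)
  ped <- pedigree(sim$pop)
  founders <- ped$id[is.na(ped$father)]
  expect_length(founders, 200L)
  draws <- unlist(sim$truth[sim$truth$id %in% founders,
                            c("allele1", "allele2")])
  p0 <- 1 / 6
  for (al in names(cfg@alleleFreqs)) {
    phat <- mean(draws == al)
    se <- sqrt(p0 * (1 - p0) / length(draws))
    expect_lt(abs(phat - p0), 3 * se + 1e-12)
  }
})

test_that("error-free pedigrees pass Mendelian checks and need no fallback", {
  sim <- simulatePopulation(SimConfig(nFamilies = 5, nChildren = 2,
                                      nMarkers = 15, seed = 7))
  clean <- cleanMendelianErrors(sim$pop)
  expect_equal(nrow(clean$flagged), 0L)
  ped <- pedigree(sim$pop)
  for (fam in unique(ped$family)) {
    rows <- ped[ped$family == fam, , drop = FALSE]
    sp <- segmentFallback(rows, genotypes(sim$pop)[rows$id, , drop = FALSE],
                          fam)
    expect_false(sp@segmented)
  }
})

test_that("noise knobs produce approximately the configured rates", {
  cfg <- SimConfig(nFamilies = 20, nChildren = 2, nMarkers = 40,
                   missingRate = 0.1, seed = 8)
  sim <- simulatePopulation(cfg)
  rate <- mean(is.na(genotypes(sim$pop)))
  expect_gt(rate, 0.06); expect_lt(rate, 0.14)
  # genotype errors break Mendelian consistency at some markers
  cfgE <- SimConfig(nFamilies = 20, nChildren = 3, nMarkers = 40,
                    errorRate = 0.05, seed = 9)
  simE <- simulatePopulation(cfgE)
  expect_gt(nrow(cleanMendelianErrors(simE$pop)$flagged), 0L)
})

test_that("background divergence is enforced between allele seeds", {
  cfg <- SimConfig(nFamilies = 2, nMarkers = 30, seed = 10)
  sim <- simulatePopulation(cfg)
  ped <- pedigree(sim$pop)
  founders <- ped$id[is.na(ped$father)]
  byAllele <- list()
  for (id in founders) {
    al <- unlist(sim$truth[sim$truth$id == id, c("allele1", "allele2")])
    h <- sim$haplotypes[[id]]
    for (k in 1:2) byAllele[[al[k]]] <- h[k, ]
  }
  als <- names(byAllele)
  if (length(als) >= 2) {
    for (i in seq_len(length(als) - 1)) for (j in (i + 1):length(als)) {
      expect_gte(sum(byAllele[[als[i]]] != byAllele[[als[j]]]),
                 cfg@minDivergence)
    }
  }
  expect_error(simulatePopulation(SimConfig(nMarkers = 4,
                                            minDivergence = 4)),
               "divergence")
})

test_that("an invalid configuration is rejected up front", {
  expect_error(SimConfig(alleleFreqs = c(a = 0.5, b = 0.3)), "sum to 1")
  expect_error(SimConfig(missingRate = 1.5), "rates")
})
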