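# Synthetic pedigree populations with allele-specific haplotype
# backgrounds.
#
# The generator emulates the regime the imputation method relies on: each
# HLA allele rides on one (or a few) distinctive SNP background
# haplotypes, founders draw (allele, background) pairs i.i.d. from the
# allele frequency distribution, and children inherit whole parental
# haplotypes (optionally with a single uniform crossover per meiosis).
# Genotyping noise -- allele flips and missingness -- is applied to the
# conflated genotypes. The truth (HLA table and haplotypes) is retained
# for evaluation.

# Internal: distinctive background haplotypes, one seed per allele with
# minimum pairwise Hamming distance enforced by rejection; additional
# backgrounds per allele are tMis-tolerable perturbations of the seed
# (isolated single-locus flips).
.makeBackgrounds <- function(nAlleles, nPer, m, minDiv) {
  seeds <- list()
  tries <- 0L
  while (length(seeds) < nAlleles) {
    cand <- sample(0:1, m, replace = TRUE)
    okDist <- all(vapply(seeds, function(s) sum(s != cand) >= minDiv,
                         logical(1)))
    if (okDist) seeds[[length(seeds) + 1L]] <- cand
    tries <- tries + 1L
    if (tries > 10000L)
      stop("cannot achieve the requested background divergence")
  }
  out <- list()
  for (a in seq_len(nAlleles)) {
    bgs <- list(seeds[[a]])
    while (length(bgs) < nPer) {
      b <- seeds[[a]]
      flip <- sample.int(m, 2L)
      if (min(abs(diff(sort(flip)))) <= 1L) next  # keep flips isolated
      b[flip] <- 1L - b[flip]
      bgs[[length(bgs) + 1L]] <- b
    }
    out[[a]] <- bgs
  }
  out
}

#' Simulate a pedigree population
#'
#' @param config a [SimConfig-class].
#' @return list with `pop` (an [HlaPopulation-class] whose HLA table holds
#'   the full truth), `truth` (the HLA truth table), and `haplotypes`
#'   (named list: individual -> 2 x m matrix of true haplotypes).
#' @export
simulatePopulation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  withLocalSeed(config@seed, {
    m <- config@nMarkers
    alleles <- names(config@alleleFreqs)
    bg <- .makeBackgrounds(length(alleles), config@backgroundsPerAllele,
                           m, config@minDivergence)
    drawFounder <- function() {
      a <- sample(alleles, 2L, replace = TRUE, prob = config@alleleFreqs)
      h <- lapply(a, function(al) {
        k <- sample.int(config@backgroundsPerAllele, 1L)
        bg[[match(al, alleles)]][[k]]
      })
      list(alleles = a, haps = do.call(rbind, h))
    }
    meiosis <- function(haps) {
      src <- sample(1:2, 1L)
      h <- haps[src, ]
      if (stats::runif(1) < config@recombRate && m >= 2L) {
        cut <- sample.int(m - 1L, 1L)
        h <- c(haps[src, seq_len(cut)], haps[3L - src, (cut + 1L):m])
        src <- c(src, 3L - src)
      }
      list(h = h, src = src)
    }
    nKids <- rep_len(config@nChildren, config@nFamilies)
    ped <- NULL; hlaTruth <- NULL
    haps <- list(); hlaOf <- list()
    for (famI in seq_len(config@nFamilies)) {
      fam <- sprintf("F%02d", famI)
      fid <- paste0(fam, "-1"); mid <- paste0(fam, "-2")
      fa <- drawFounder(); mo <- drawFounder()
      haps[[fid]] <- fa$haps; haps[[mid]] <- mo$haps
      hlaOf[[fid]] <- fa$alleles; hlaOf[[mid]] <- mo$alleles
      ped <- rbind(ped,
                   data.frame(family = fam, id = c(fid, mid),
                              father = NA_character_, mother = NA_character_,
                              sex = c(1L, 2L)))
      for (k in seq_len(nKids[famI])) {
        kid <- paste0(fam, "-", 2L + k)
        mp <- meiosis(fa$haps); mm <- meiosis(mo$haps)
        haps[[kid]] <- rbind(mp$h, mm$h)
        hlaOf[[kid]] <- c(fa$alleles[mp$src[1L]], mo$alleles[mm$src[1L]])
        ped <- rbind(ped,
                     data.frame(family = fam, id = kid, father = fid,
                                mother = mid, sex = sample(1:2, 1L)))
      }
    }
    ids <- ped$id
    g <- matrix(NA_integer_, nrow = length(ids), ncol = m,
                dimnames = list(ids, NULL))
    for (i in seq_along(ids)) {
      h <- haps[[ids[i]]]
      if (config@errorRate > 0) {
        flip <- matrix(stats::runif(2L * m) < config@errorRate, nrow = 2L)
        h[flip] <- 1L - h[flip]
      }
      g[i, ] <- h[1L, ] + h[2L, ]
    }
    if (config@missingRate > 0) {
      drop <- matrix(stats::runif(length(g)) < config@missingRate,
                     nrow = nrow(g))
      g[drop] <- NA_integer_
    }
    pos <- as.integer(round(config@geneCenterBp -
                              config@markerSpacingBp * (m - 1) / 2 +
                              config@markerSpacingBp * (seq_len(m) - 1)))
    map <- data.frame(marker = sprintf("rs%04d", seq_len(m)),
                      chrom = "6", pos = pos)
    truth <- data.frame(id = ids,
                        allele1 = unname(vapply(hlaOf[ids], `[`, "", 1L)),
                        allele2 = unname(vapply(hlaOf[ids], `[`, "", 2L)),
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    pop <- HlaPopulation(ped, g, map, truth)
    list(pop = pop, truth = truth, haplotypes = haps)
  })
}

#' Tiny worked example population
#'
#' Six singleton individuals over a 12-marker window. Three homozygous
#' references anchor the Hap-HLA relation (their phase is forced), two
#' heterozygous-typed individuals carry the allele pairs {0201, 0101} and
#' {0201, 2401} (two heterozygous constraint edges), and one untyped
#' individual whose true pair is {0101, 2401} is inferred. Each allele
#' rides a fixed, distinctive background haplotype (pairwise Hamming
#' distance 6, mismatch runs of at most 2). Deterministic.
#'
#' @return list with `pop` (untyped sixth individual), `truth`, and the
#'   true `haplotypes`.
#' @export
#' @examples
#' fx <- makeWorkedFixture()
#' fx$pop
makeWorkedFixture <- function() {
  b0101 <- rep(0L, 12L)
  b0201 <- as.integer(seq_len(12L) %in% c(1L, 2L, 4L, 7L, 10L, 11L))
  b2401 <- as.integer(seq_len(12L) %in% c(2L, 4L, 6L, 9L, 10L, 12L))
  haps <- list(R1 = rbind(b0201, b0201),
               R2 = rbind(b0101, b0101),
               R3 = rbind(b2401, b2401),
               I1 = rbind(b0201, b0101),
               I2 = rbind(b0201, b2401),
               I3 = rbind(b0101, b2401))
  ids <- names(haps)
  ped <- data.frame(family = paste0("P", seq_along(ids)), id = ids,
                    father = NA_character_, mother = NA_character_,
                    sex = 1L)
  g <- t(vapply(haps, function(h) h[1L, ] + h[2L, ], integer(12L)))
  map <- data.frame(marker = sprintf("rs%02d", 1:12), chrom = "6",
                    pos = as.integer(31500000 - 22000 + 4000 * (0:11)))
  truth <- data.frame(id = ids,
                      allele1 = c("0201", "0101", "2401", "0201", "0201", "0101"),
                      allele2 = c("0201", "0101", "2401", "0101", "2401", "2401"),
                      stringsAsFactors = FALSE)
  hla <- truth
  hla[hla$id == "I3", c("allele1", "allele2")] <- NA_character_
  pop <- HlaPopulation(ped, g, map, hla)
  list(pop = pop, truth = truth, haplotypes = haps)
}
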