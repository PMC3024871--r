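# Independent oracles and random-instance generators used across the
# suite. These deliberately use naive algorithms (exhaustive scans,
# explicit enumeration) so they stay independent of the implementation
# paths they check.

# Similarity by exhaustive enumeration of all regions [p, q]: endpoints
# must match, no run of more than tMis consecutive mismatches inside,
# value = max match count / n.
oracleSimilarity <- function(h1, h2, tMis) {
  n <- length(h1)
  st <- integer(n)
  known <- !is.na(h1) & !is.na(h2)
  st[known & h1 == h2] <- 1L
  st[known & h1 != h2] <- -1L
  best <- 0L
  if (n >= 2L) {
    for (p in 1:(n - 1L)) {
      if (st[p] != 1L) next
      for (q in (p + 1L):n) {
        if (st[q] != 1L) next
        run <- 0L; ok <- TRUE; nm <- 0L
        for (l in p:q) {
          if (st[l] == -1L) {
            run <- run + 1L
            if (run > tMis) { ok <- FALSE; break }
          } else run <- 0L
          if (st[l] == 1L) nm <- nm + 1L
        }
        if (ok && nm > best) best <- nm
      }
    }
  }
  best / n
}

randomHap <- function(n, naProb = 0) {
  h <- sample(0:1, n, replace = TRUE)
  if (naProb > 0) h[stats::runif(n) < naProb] <- NA_integer_
  as.integer(h)
}

# Canonical string form of a configuration: founders as sorted unordered
# hap pairs, non-founders as ordered (paternal, maternal) pairs.
canonicalConfig <- function(cfg, ped) {
  out <- character(length(cfg$ids))
  for (i in seq_along(cfg$ids)) {
    h1 <- paste(cfg$haps[i, 1L, ], collapse = "")
    h2 <- paste(cfg$haps[i, 2L, ], collapse = "")
    founder <- is.na(ped$father[match(cfg$ids[i], ped$id)])
    out[i] <- if (founder) paste(sort(c(h1, h2)), collapse = "/")
              else paste(h1, h2, sep = "/")
  }
  paste(out, collapse = ";")
}

# All Mendelian zero-recombinant configurations of one family by brute
# force: enumerate founder phasings of heterozygous loci and per-child
# transmission bits, keep assignments whose conflation reproduces every
# genotype. Genotypes must be fully observed. Returns the set of
# canonical configuration strings.
bruteForceConfigs <- function(ped, geno) {
  ids <- ped$id
  n <- length(ids)
  m <- ncol(geno)
  founders <- which(is.na(ped$father))
  children <- setdiff(seq_len(n), founders)
  # founder haplotype options
  founderHaps <- function(i) {
    g <- geno[ids[i], ]
    het <- which(g == 1L)
    base1 <- ifelse(g == 2L, 1L, 0L)
    if (!length(het)) return(list(rbind(base1, base1 + (g == 2L) * 0L)))
    out <- list()
    for (k in seq_len(2^length(het)) - 1L) {
      bits <- as.integer(intToBits(k))[seq_along(het)]
      h1 <- base1; h1[het] <- bits
      h2 <- base1; h2[het] <- 1L - bits
      out[[length(out) + 1L]] <- rbind(h1, h2)
    }
    out
  }
  opts <- lapply(founders, founderHaps)
  names(opts) <- as.character(founders)
  nT <- length(children)
  res <- character(0)
  gridF <- lapply(opts, seq_along)
  combosF <- do.call(expand.grid, c(gridF, list(KEEP.OUT.ATTRS = FALSE)))
  for (r in seq_len(nrow(combosF))) {
    haps <- array(NA_integer_, dim = c(n, 2L, m))
    for (fi in seq_along(founders))
      haps[founders[fi], , ] <- opts[[fi]][[combosF[r, fi]]]
    for (tmask in seq_len(4^nT) - 1L) {
      bits <- as.integer(intToBits(tmask))[seq_len(2L * max(nT, 1L))]
      ok <- TRUE
      # children in pedigree order; parents may themselves be children,
      # so resolve repeatedly (handles multi-generation families)
      resolved <- rep(FALSE, n)
      resolved[founders] <- TRUE
      todo <- children
      guard <- 0L
      while (length(todo) && guard < 10L) {
        guard <- guard + 1L
        for (ci in todo) {
          k <- match(ci, children)
          fa <- match(ped$father[ci], ids)
          mo <- match(ped$mother[ci], ids)
          if (!resolved[fa] || !resolved[mo]) next
          tp <- bits[2L * k - 1L] + 1L
          tm <- bits[2L * k] + 1L
          haps[ci, 1L, ] <- haps[fa, tp, ]
          haps[ci, 2L, ] <- haps[mo, tm, ]
          resolved[ci] <- TRUE
        }
        todo <- children[!resolved[children]]
      }
      if (length(todo)) next
      for (i in seq_len(n)) {
        if (any(haps[i, 1L, ] + haps[i, 2L, ] != geno[ids[i], ])) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        cfg <- list(ids = ids, haps = haps)
        res <- c(res, canonicalConfig(cfg, ped))
      }
    }
  }
  unique(res)
}

# A random small family (singleton, trio, or couple with 2-3 children)
# with fully observed, Mendelian-consistent, zero-recombinant genotypes.
# Enumeration effort is capped by resampling.
randomSmallFamily <- function(m = 6L, maxBits = 14L) {
  repeat {
    type <- sample(c("singleton", "trio", "quad", "quint"), 1L)
    nKids <- switch(type, singleton = 0L, trio = 1L, quad = 2L, quint = 3L)
    if (type == "singleton") {
      ped <- data.frame(family = "X", id = "s1",
                        father = NA_character_, mother = NA_character_,
                        sex = 1L)
      h <- rbind(randomHap(m), randomHap(m))
      geno <- matrix(h[1L, ] + h[2L, ], nrow = 1L,
                     dimnames = list("s1", NULL))
      haps <- list(s1 = h)
    } else {
      ids <- c("fa", "mo", paste0("k", seq_len(nKids)))
      ped <- data.frame(family = "X", id = ids,
                        father = c(NA, NA, rep("fa", nKids)),
                        mother = c(NA, NA, rep("mo", nKids)),
                        sex = c(1L, 2L, rep(1L, nKids)))
      fa <- rbind(randomHap(m), randomHap(m))
      mo <- rbind(randomHap(m), randomHap(m))
      haps <- list(fa = fa, mo = mo)
      geno <- rbind(fa[1L, ] + fa[2L, ], mo[1L, ] + mo[2L, ])
      for (k in seq_len(nKids)) {
        h <- rbind(fa[sample(1:2, 1L), ], mo[sample(1:2, 1L), ])
        haps[[paste0("k", k)]] <- h
        geno <- rbind(geno, h[1L, ] + h[2L, ])
      }
      rownames(geno) <- ids
    }
    hetBits <- sum(geno[ped$id[is.na(ped$father)], , drop = FALSE] == 1L)
    bits <- hetBits + 2L * nKids
    if (bits <= maxBits) {
      storage.mode(geno) <- "integer"
      return(list(ped = ped, geno = geno, haps = haps))
    }
  }
}

# A random all-typed constraint graph: k individuals with random allele
# pairs over a small universe, arbitrary symmetric weights.
randomConstraintGraph <- function(nInd = 6L, nAlleles = 3L, homProb = 0.2) {
  nV <- 2L * nInd
  W <- matrix(stats::runif(nV * nV), nV, nV)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  alleles <- sprintf("%02d01", seq_len(nAlleles))
  cons <- data.frame(id = paste0("i", seq_len(nInd)),
                     v1 = 2L * seq_len(nInd) - 1L,
                     v2 = 2L * seq_len(nInd),
                     a1 = character(nInd), a2 = character(nInd),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nInd)) {
    if (stats::runif(1) < homProb) {
      a <- sample(alleles, 1L)
      cons$a1[i] <- a; cons$a2[i] <- a
    } else {
      ab <- sample(alleles, 2L)
      cons$a1[i] <- ab[1L]; cons$a2[i] <- ab[2L]
    }
  }
  SimilarityGraph(W, cons)
}

# Con by an independent double loop over all unordered vertex pairs.
oracleCon <- function(W, labeling) {
  tot <- 0
  n <- nrow(W)
  for (p in seq_len(n - 1L)) for (q in (p + 1L):n) {
    if (!is.na(labeling[p]) && !is.na(labeling[q]) &&
        labeling[p] == labeling[q])
      tot <- tot + W[p, q]
  }
  tot
}

# Small deterministic search fixture: two homozygous reference singletons
# (f = 0) plus one ambiguous singleton whose genotype conflates two of
# the backgrounds; returns population pieces for search tests.
searchToyFixture <- function(mDiff = 4L, m = 10L, typed = TRUE) {
  bgA <- rep(0L, m)
  diffLoci <- seq(2L, by = 2L, length.out = mDiff)
  bgB <- bgA; bgB[diffLoci] <- 1L
  ids <- c("refA", "refB", "query")
  ped <- data.frame(family = c("RA", "RB", "Q"), id = ids,
                    father = NA_character_, mother = NA_character_,
                    sex = 1L)
  geno <- rbind(refA = 2L * bgA, refB = 2L * bgB, query = bgA + bgB)
  storage.mode(geno) <- "integer"
  hla <- data.frame(id = ids,
                    allele1 = c("0101", "0201",
                                if (typed) "0101" else NA_character_),
                    allele2 = c("0101", "0201",
                                if (typed) "0201" else NA_character_),
                    stringsAsFactors = FALSE)
  list(ped = ped, geno = geno, hla = hla, bgA = bgA, bgB = bgB)
}

# Exported-surface-free bit expansion (mirrors the package's enumeration
# order: variable 1 in the least significant position).
assignmentBits_test <- function(k, f) {
  if (f == 0L) return(integer(0))
  as.integer(intToBits(k))[seq_len(f)]
}
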