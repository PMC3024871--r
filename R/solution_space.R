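# Zero-recombinant pedigree haplotype solution spaces.
#
# Under the zero-recombinant model every child haplotype is an unmodified
# copy of one parental haplotype across the window. All Mendelian,
# zero-recombinant haplotype configurations of a pedigree then form an
# affine subspace over GF(2): the unknowns are per-(individual, het locus)
# phase bits, per-(child, parent) transmission bits and per-(individual,
# missing locus) allele bits, tied by XOR constraints. Gaussian
# elimination yields an affine parametrization; the free-variable count f
# is the rank of the map from free variables to the alleles at loci with
# observed genotypes, so the space holds exactly 2^f configurations that
# are pairwise distinct on observed loci.
#
# Founders' haplotype pairs are unordered; the representation is
# canonicalised by forcing the allele at each founder's first heterozygous
# locus to 0 on haplotype 1, which halves away the swap symmetry. For
# non-founders haplotype 1 is paternal and haplotype 2 maternal.

# Internal: build the family structures used by the solver.
.familyFrame <- function(ped, geno) {
  ids <- ped$id
  n <- length(ids)
  fa <- match(ped$father, ids)
  mo <- match(ped$mother, ids)
  list(ids = ids, n = n, fa = fa, mo = mo,
       founder = is.na(fa), geno = geno[ids, , drop = FALSE])
}

# Internal core: attempt to build the affine solution space for one family
# over markers `cols` of `geno`. Returns a SolutionSpace or NULL when the
# constraints are infeasible (i.e. an obligate recombination).
.solveFamily <- function(family, ped, geno, cols = seq_len(ncol(geno))) {
  fr <- .familyFrame(ped, geno)
  g <- fr$geno[, cols, drop = FALSE]
  n <- fr$n
  m <- length(cols)

  # --- variable table ----------------------------------------------------
  # kinds: P = phase bit at a het locus, T = transmission bit,
  #        A = allele bit at a missing locus (soft; two per locus).
  # Ordering: P by (individual, locus), then T by (individual, side),
  # then A by (individual, locus, hap). P/T first so pivots prefer them.
  vkind <- character(0); vind <- integer(0); vloc <- integer(0)
  vhap <- integer(0)
  for (i in seq_len(n)) {
    het <- which(!is.na(g[i, ]) & g[i, ] == 1L)
    if (length(het)) {
      vkind <- c(vkind, rep("P", length(het)))
      vind <- c(vind, rep(i, length(het)))
      vloc <- c(vloc, het)
      vhap <- c(vhap, rep(0L, length(het)))
    }
  }
  tChild <- integer(0); tSide <- integer(0)
  for (i in seq_len(n)) {
    if (!fr$founder[i]) {
      vkind <- c(vkind, "T", "T"); vind <- c(vind, i, i)
      vloc <- c(vloc, 0L, 0L); vhap <- c(vhap, 1L, 2L)
      tChild <- c(tChild, i, i); tSide <- c(tSide, 1L, 2L)
    }
  }
  for (i in seq_len(n)) {
    mis <- which(is.na(g[i, ]))
    for (l in mis) {
      vkind <- c(vkind, "A", "A"); vind <- c(vind, i, i)
      vloc <- c(vloc, l, l); vhap <- c(vhap, 1L, 2L)
    }
  }
  nv <- length(vkind)
  pIdx <- function(i, l) which(vkind == "P" & vind == i & vloc == l)
  tIdx <- function(i, s) which(vkind == "T" & vind == i & vhap == s)
  aIdx <- function(i, l, h) which(vkind == "A" & vind == i & vloc == l & vhap == h)

  # allele slot expression: list(const, var) with var = 0 for none
  slotExpr <- function(i, h, l) {
    gi <- g[i, l]
    if (is.na(gi)) return(c(0L, aIdx(i, l, h)))
    if (gi == 0L) return(c(0L, 0L))
    if (gi == 2L) return(c(1L, 0L))
    if (h == 1L) c(0L, pIdx(i, l)) else c(1L, pIdx(i, l))
  }

  # --- equations ---------------------------------------------------------
  rows <- list()
  addRow <- function(vars, rhs) {
    rows[[length(rows) + 1L]] <<- list(vars = vars, rhs = rhs %% 2L)
  }
  feasible <- TRUE
  for (i in seq_len(n)) {
    if (fr$founder[i]) next
    for (side in 1:2) {
      par <- if (side == 1L) fr$fa[i] else fr$mo[i]
      tv <- tIdx(i, side)
      for (l in seq_len(m)) {
        gp <- g[par, l]
        if (is.na(gp)) next  # unconstrained through this parent here
        ce <- slotExpr(i, side, l)
        if (gp == 1L) {
          # child allele = parent phase xor transmission
          vars <- c(ce[2L], pIdx(par, l), tv)
          vars <- vars[vars != 0L]
          addRow(vars, ce[1L])
        } else {
          pa <- gp %/% 2L
          if (ce[2L] == 0L) {
            if ((ce[1L] %% 2L) != pa) { feasible <- FALSE }
          } else {
            addRow(ce[2L], (pa + ce[1L]) %% 2L)
          }
        }
      }
      if (!feasible) break
    }
    if (!feasible) break
  }
  # founder canonicalisation: first het locus phased 0 on haplotype 1
  if (feasible) for (i in seq_len(n)) {
    if (!fr$founder[i]) next
    het <- which(!is.na(g[i, ]) & g[i, ] == 1L)
    if (length(het)) addRow(pIdx(i, het[1L]), 0L)
  }
  if (!feasible) return(NULL)

  A <- matrix(0L, nrow = length(rows), ncol = nv + 1L)
  for (r in seq_along(rows)) {
    A[r, rows[[r]]$vars] <- (A[r, rows[[r]]$vars] + 1L) %% 2L
    A[r, nv + 1L] <- rows[[r]]$rhs
  }
  sol <- gf2Rref(A, nv)
  if (!sol$consistent) return(NULL)

  # per-variable affine expressions over the free variables
  freeVars <- setdiff(seq_len(nv), sol$pivots)
  nf <- length(freeVars)
  vConst <- integer(nv)
  vCoef <- matrix(0L, nrow = nv, ncol = nf)
  if (nf) vCoef[cbind(freeVars, seq_len(nf))] <- 1L
  if (length(sol$pivots)) {
    R <- sol$mat
    for (k in seq_along(sol$pivots)) {
      pv <- sol$pivots[k]; rw <- sol$rows[k]
      vConst[pv] <- R[rw, nv + 1L]
      if (nf) vCoef[pv, ] <- R[rw, freeVars]
    }
  }

  # --- allele slot parametrization --------------------------------------
  aConst <- array(NA_real_, dim = c(n, 2L, m))
  aCoefFull <- array(0L, dim = c(n, 2L, m, max(nf, 1L)))
  hardMask <- array(FALSE, dim = c(n, 2L, m))
  for (i in seq_len(n)) for (h in 1:2) for (l in seq_len(m)) {
    e <- slotExpr(i, h, l)
    hard <- !is.na(g[i, l])
    cst <- e[1L]; coef <- if (nf) rep(0L, nf) else integer(0)
    if (e[2L] != 0L) {
      cst <- (cst + vConst[e[2L]]) %% 2L
      if (nf) coef <- vCoef[e[2L], ]
    }
    hardMask[i, h, l] <- hard
    aConst[i, h, l] <- cst
    if (nf) aCoefFull[i, h, l, ] <- coef
  }

  # free variables that actually distinguish configurations on observed loci
  hardSlots <- which(hardMask)
  if (nf && length(hardSlots)) {
    B <- matrix(aCoefFull, ncol = nf)[hardSlots, , drop = FALSE]
    J <- gf2IndependentCols(B)
  } else J <- integer(0)
  f <- length(J)

  # soft slots: resolvable only if their expression stays inside span(J)
  # coordinates; otherwise the allele is genuinely unknowable -> NA.
  for (i in seq_len(n)) for (h in 1:2) for (l in seq_len(m)) {
    if (hardMask[i, h, l]) next
    coef <- if (nf) aCoefFull[i, h, l, ] else integer(0)
    dropc <- if (nf) coef[setdiff(seq_len(nf), J)] else integer(0)
    if (length(dropc) && any(dropc == 1L)) {
      aConst[i, h, l] <- NA_real_
    }
    # expression over dropped free vars only through J is kept as-is
  }

  aCoef <- array(0L, dim = c(n, 2L, m, max(f, 0L)))
  if (f) {
    tmp <- matrix(aCoefFull, ncol = nf)[, J, drop = FALSE]
    aCoef <- array(tmp, dim = c(n, 2L, m, f))
  } else {
    aCoef <- array(0L, dim = c(n, 2L, m, 0L))
  }

  # transmission-bit expressions (for diagnostics and the missing-locus fill)
  nT <- length(tChild)
  tTab <- data.frame(child = tChild, side = tSide,
                     parent = ifelse(tSide == 1L, fr$fa[tChild], fr$mo[tChild]),
                     const = integer(max(nT, 0L)),
                     known = logical(max(nT, 0L)))
  tC <- matrix(0L, nrow = nT, ncol = max(f, 0L))
  if (nT) for (k in seq_len(nT)) {
    tv <- tIdx(tChild[k], tSide[k])
    cst <- vConst[tv]
    coef <- if (nf) vCoef[tv, ] else integer(0)
    dropc <- if (nf) coef[setdiff(seq_len(nf), J)] else integer(0)
    tTab$const[k] <- cst
    tTab$known[k] <- !(length(dropc) && any(dropc == 1L))
    if (f) tC[k, ] <- coef[J]
  }

  new("SolutionSpace", family = family, individuals = fr$ids,
      m = as.integer(m), f = as.integer(f),
      alleleConst = aConst, alleleCoef = aCoef,
      tTable = tTab, tCoef = tC, geno = g,
      segmented = FALSE, segments = list(), segStarts = 1L)
}

#' Build the zero-recombinant solution space of one pedigree
#'
#' @param ped pedigree roster for one family (data.frame with `id`,
#'   `father`, `mother`; parents `NA` for founders).
#' @param geno dosage matrix (individuals x markers) restricted to the
#'   marker window; rownames must cover `ped$id`.
#' @param family family label for bookkeeping.
#' @return A [SolutionSpace-class]. Signals an error of class
#'   `pedhla_recombinant` when no zero-recombinant configuration exists
#'   (use [segmentFallback] then).
#' @export
buildSolutionSpace <- function(ped, geno, family = "fam") {
  sp <- .solveFamily(family, ped, geno)
  if (is.null(sp)) {
    stop(structure(class = c("pedhla_recombinant", "error", "condition"),
                   list(message = sprintf(
                     "pedigree %s admits no zero-recombinant configuration over the window",
                     family), call = sys.call())))
  }
  sp
}

#' Segmented fallback for recombinant pedigrees
#'
#' When a pedigree admits no zero-recombinant configuration over the whole
#' window, the window is split greedily into maximal zero-recombinant
#' prefix segments; the per-segment spaces are combined and, at
#' instantiation time, stitched left to right while flipping founder
#' haplotype pairs so that transmissions switch as rarely as possible.
#' The result is a valid (possibly non-minimum-recombinant) space.
#'
#' @inheritParams buildSolutionSpace
#' @return A [SolutionSpace-class], segmented unless the whole window is
#'   already zero-recombinant.
#' @export
segmentFallback <- function(ped, geno, family = "fam") {
  whole <- .solveFamily(family, ped, geno)
  if (!is.null(whole)) return(whole)
  m <- ncol(geno)
  segs <- list(); starts <- integer(0)
  s <- 1L
  while (s <= m) {
    e <- s
    best <- .solveFamily(family, ped, geno, cols = s:e)
    if (is.null(best))
      stop(sprintf("pedigree %s is Mendelian-inconsistent at marker %d (clean genotypes first)",
                   family, s))
    while (e < m) {
      cand <- .solveFamily(family, ped, geno, cols = s:(e + 1L))
      if (is.null(cand)) break
      e <- e + 1L; best <- cand
    }
    segs[[length(segs) + 1L]] <- best
    starts <- c(starts, s)
    s <- e + 1L
  }
  f <- sum(vapply(segs, function(x) x@f, integer(1)))
  new("SolutionSpace", family = family,
      individuals = segs[[1L]]@individuals, m = as.integer(m),
      f = as.integer(f),
      alleleConst = array(NA_real_, dim = c(1, 2, 1)),
      alleleCoef = array(0L, dim = c(1, 2, 1, 0)),
      tTable = data.frame(), tCoef = matrix(0L, 0, 0),
      geno = geno[segs[[1L]]@individuals, , drop = FALSE],
      segmented = TRUE, segments = segs, segStarts = starts)
}

# Internal: realized transmission bit per (child, side) for a concrete
# configuration of one segment: 0 when the child's side haplotype equals
# the parent's hap 1, 1 when hap 2, NA when indistinguishable.
.realizedT <- function(space, haps) {
  tt <- space@tTable
  if (!nrow(tt)) return(integer(0))
  out <- rep(NA_integer_, nrow(tt))
  for (k in seq_len(nrow(tt))) {
    ch <- haps[tt$child[k], tt$side[k], ]
    p1 <- haps[tt$parent[k], 1L, ]
    p2 <- haps[tt$parent[k], 2L, ]
    eq1 <- all(ch == p1 | is.na(ch) | is.na(p1))
    eq2 <- all(ch == p2 | is.na(ch) | is.na(p2))
    if (eq1 && !eq2) out[k] <- 0L
    else if (eq2 && !eq1) out[k] <- 1L
    else if (eq1 && eq2) out[k] <- NA_integer_
    else out[k] <- NA_integer_
  }
  out
}

#' Instantiate one configuration from a solution space
#'
#' @param space a [SolutionSpace-class].
#' @param assignment 0/1 vector of length `nFreeVars(space)`.
#' @return A haplotype configuration: list with `ids` and `haps`, an
#'   `(n, 2, m)` array over `{0, 1, NA}` (hap 1 = paternal for
#'   non-founders). For segmented spaces the attribute `"switches"` counts
#'   the stitched transmission switches per child/side.
#' @export
instantiateSolution <- function(space, assignment = integer(0)) {
  assignment <- as.integer(assignment)
  if (length(assignment) != space@f)
    stop(sprintf("assignment must have length f = %d", space@f))
  if (space@f && !all(assignment %in% 0:1))
    stop("assignment must be a 0/1 vector")
  if (!space@segmented) {
    n <- length(space@individuals); m <- space@m
    vals <- space@alleleConst
    if (space@f) {
      contrib <- matrix(space@alleleCoef, ncol = space@f) %*% assignment
      vals <- (vals + array(contrib, dim = dim(vals))) %% 2
    }
    # missing-locus fill: copy alleles through determined transmissions at
    # loci where the linear system had no equation (parent genotype missing)
    tt <- space@tTable
    if (nrow(tt) && anyNA(vals)) {
      tv <- (tt$const + if (space@f) as.vector(space@tCoef %*% assignment) else 0L) %% 2L
      tv[!tt$known] <- NA_integer_
      for (rep in 1:3) {
        changed <- FALSE
        for (k in seq_len(nrow(tt))) {
          if (is.na(tv[k])) next
          ch <- tt$child[k]; sd <- tt$side[k]; par <- tt$parent[k]
          ph <- tv[k] + 1L
          cv <- vals[ch, sd, ]; pv <- vals[par, ph, ]
          up <- which(is.na(pv) & !is.na(cv))
          dn <- which(is.na(cv) & !is.na(pv))
          if (length(up)) { vals[par, ph, up] <- cv[up]; changed <- TRUE }
          if (length(dn)) { vals[ch, sd, dn] <- pv[dn]; changed <- TRUE }
        }
        if (!changed) break
      }
    }
    dimnames(vals) <- list(space@individuals, NULL, NULL)
    return(list(ids = space@individuals, haps = vals))
  }
  # segmented: instantiate each segment, flip founders greedily, concatenate
  segs <- space@segments
  fs <- vapply(segs, function(x) x@f, integer(1))
  offs <- cumsum(c(0L, fs))
  n <- length(space@individuals); m <- space@m
  ped <- segs[[1L]]@tTable
  founder <- !(seq_len(n) %in% unique(ped$child))
  haps <- array(NA_real_, dim = c(n, 2L, m),
                dimnames = list(space@individuals, NULL, NULL))
  prevT <- NULL
  switches <- if (nrow(segs[[1L]]@tTable))
    rep(0L, nrow(segs[[1L]]@tTable)) else integer(0)
  for (si in seq_along(segs)) {
    seg <- segs[[si]]
    a <- if (fs[si]) assignment[(offs[si] + 1L):(offs[si] + fs[si])] else integer(0)
    cfg <- instantiateSolution(seg, a)
    hv <- cfg$haps
    tv <- .realizedT(seg, hv)
    if (!is.null(prevT) && nrow(seg@tTable)) {
      tt <- seg@tTable
      for (i in which(founder)) {
        kids <- which(tt$parent == i)
        if (!length(kids)) next
        now <- tv[kids]; was <- prevT[kids]
        keep <- sum(now != was, na.rm = TRUE)
        flip <- sum((1L - now) != was, na.rm = TRUE)
        if (flip < keep) {
          hv[i, , ] <- hv[i, 2:1, ]
          tv[kids] <- 1L - tv[kids]
        }
      }
      chg <- !is.na(tv) & !is.na(prevT) & tv != prevT
      switches <- switches + as.integer(chg)
    }
    cols <- space@segStarts[si]:(space@segStarts[si] + seg@m - 1L)
    haps[, , cols] <- hv
    if (length(tv)) {
      if (is.null(prevT)) prevT <- tv
      else prevT <- ifelse(is.na(tv), prevT, tv)
    }
  }
  out <- list(ids = space@individuals, haps = haps)
  attr(out, "switches") <- switches
  out
}

#' Enumerate all configurations of a solution space
#'
#' Yields exactly `2^f` pairwise-distinct configurations in a fixed order
#' (assignments are the binary expansions of `0 .. 2^f - 1`, variable 1 in
#' the least significant position).
#'
#' @param space a [SolutionSpace-class].
#' @param maxF refuse to enumerate spaces with more free variables than
#'   this (default 20).
#' @return list of configurations (see [instantiateSolution]).
#' @export
enumerateSolutions <- function(space, maxF = 20L) {
  if (space@f > maxF)
    stop(sprintf("space has f = %d free variables; enumeration capped at %d",
                 space@f, maxF))
  lapply(seq_len(2^space@f) - 1L, function(k)
    instantiateSolution(space, assignmentBits(k, space@f)))
}

#' Validate a haplotype configuration against genotypes and pedigree
#'
#' Checks that conflated haplotype pairs reproduce every observed
#' genotype, and that each child haplotype equals one parental haplotype
#' (zero-recombinant) wherever both are observed.
#'
#' @param config a configuration from [instantiateSolution].
#' @param ped family roster (`id`, `father`, `mother`).
#' @param geno dosage matrix for the same window.
#' @param maxSwitches allowed transmission switches per child haplotype
#'   (0 for strict zero-recombinance).
#' @return TRUE or a character description of the first violation.
#' @export
validateConfiguration <- function(config, ped, geno, maxSwitches = 0L) {
  ids <- config$ids
  haps <- config$haps
  g <- geno[ids, , drop = FALSE]
  for (i in seq_along(ids)) {
    confl <- haps[i, 1L, ] + haps[i, 2L, ]
    obs <- !is.na(g[i, ])
    bad <- obs & !is.na(confl) & confl != g[i, ]
    if (any(bad))
      return(sprintf("genotype mismatch: %s locus %d", ids[i], which(bad)[1L]))
    if (any(obs & is.na(confl)))
      return(sprintf("observed genotype left unresolved: %s locus %d",
                     ids[i], which(obs & is.na(confl))[1L]))
  }
  for (i in seq_along(ids)) {
    fid <- ped$father[match(ids[i], ped$id)]
    if (is.na(fid)) next
    mid <- ped$mother[match(ids[i], ped$id)]
    for (sd in 1:2) {
      par <- match(if (sd == 1L) fid else mid, ids)
      ch <- haps[i, sd, ]
      ok <- FALSE
      for (ph in 1:2) {
        pv <- haps[par, ph, ]
        cmp <- !is.na(ch) & !is.na(pv)
        if (all(ch[cmp] == pv[cmp])) { ok <- TRUE; break }
      }
      if (!ok && maxSwitches > 0L) {
        # allow up to maxSwitches changes of source haplotype, provided every
        # observed child allele is carried by at least one parental haplotype
        p1 <- haps[par, 1L, ]; p2 <- haps[par, 2L, ]
        carried <- vapply(seq_along(ch), function(l) {
          if (is.na(ch[l])) return(TRUE)
          if (is.na(p1[l]) && is.na(p2[l])) return(TRUE)
          isTRUE(ch[l] == p1[l]) || isTRUE(ch[l] == p2[l])
        }, logical(1))
        only1 <- !is.na(ch) & !is.na(p1) & !is.na(p2) & ch == p1 & ch != p2
        only2 <- !is.na(ch) & !is.na(p1) & !is.na(p2) & ch == p2 & ch != p1
        src <- ifelse(only1, 1L, ifelse(only2, 2L, NA))
        src <- src[!is.na(src)]
        nsw <- if (length(src) > 1L) sum(diff(src) != 0L) else 0L
        ok <- all(carried) && nsw <= maxSwitches
      }
      if (!ok)
        return(sprintf("haplotype of %s (side %d) is not a parental copy",
                       ids[i], sd))
    }
  }
  TRUE
}
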