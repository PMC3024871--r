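# Incremental selection of one haplotype configuration per pedigree.
#
# Pedigrees are processed in ascending order of their free-variable count
# f. Pedigrees with a unique configuration (f = 0) seed the graph; each
# further pedigree is committed to the configuration that maximizes the
# within-label similarity objective of the grown, labeled graph --
# exhaustively when 2^f is small, by a genetic algorithm otherwise.
#
# Candidate scoring is incremental by default: the committed base
# labeling is frozen, the candidate pedigree's vertices are labeled by
# the same seeding / orientation / voting rules against it, and the
# objective is the base value plus the candidate's delta. The committed
# configuration is then relabeled globally (full Heu-Label), so the
# Hap-HLA relation passed on is always the exact heuristic labeling.
# Scoring with a full relabel per candidate is available via
# `relabel = "full"`.

#' Order pedigrees for the incremental search
#'
#' Ascending by free-variable count, stable in the input order.
#'
#' @param spaces list of [SolutionSpace-class] objects.
#' @return integer permutation of `seq_along(spaces)`.
#' @export
orderPedigrees <- function(spaces) {
  f <- vapply(spaces, nFreeVars, integer(1))
  order(f)
}

# Internal: fresh empty search state. `simEnv` is a mutable registry of
# unique haplotype strings with lazily cached per-string similarity rows,
# shared across candidate evaluations.
newSearchState <- function(tMis = 2L, tS = 0.65) {
  e <- .getSimRegistry(tMis)
  list(graph = NULL, labeling = character(0), con = 0,
       configs = list(), tMis = as.integer(tMis), tS = tS,
       simEnv = e, baseUIdx = integer(0),
       log = data.frame(family = character(0), f = integer(0),
                        method = character(0), con = numeric(0)))
}

# Internal: ids of haplotype strings in the registry, extending it for
# unseen strings. Similarities are filled lazily by .simBlock.
.registerHaps <- function(e, haps, tMis) {
  pos <- vapply(haps, function(h) {
    id <- e$map[[h]]
    if (is.null(id)) NA_integer_ else id
  }, integer(1), USE.NAMES = FALSE)
  if (!anyNA(pos)) return(pos)
  for (h in unique(haps[is.na(pos)])) {
    if (is.null(e$map[[h]])) {
      id <- length(e$uh) + 1L
      e$uh <- c(e$uh, h)
      e$hv[[id]] <- stringToHap(h)
      e$map[[h]] <- id
    }
  }
  vapply(haps, function(h) e$map[[h]], integer(1), USE.NAMES = FALSE)
}

# Internal: similarity block sim(uh[rows], uh[cols]), computing and
# caching missing values on the row-strings' cached rows.
.simBlock <- function(e, rows, cols, tMis) {
  k <- length(e$uh)
  out <- matrix(0, length(rows), length(cols))
  urows <- unique(rows)
  for (i in urows) {
    ri <- if (i <= length(e$P)) e$P[[i]] else NULL
    vals <- if (is.null(ri)) rep(NA_real_, length(cols)) else ri[cols]
    if (anyNA(vals)) {
      # grow with headroom so cached rows are rarely reallocated
      if (is.null(ri) || length(ri) < max(cols)) {
        old <- ri
        ri <- rep(NA_real_, max(64L, 2L * k))
        if (!is.null(old)) ri[seq_along(old)] <- old
      }
      hi <- e$hv[[i]]
      for (j in unique(cols[is.na(vals)]))
        ri[j] <- .simValue(hi, e$hv[[j]], tMis)
      e$P[[i]] <- ri
    }
  }
  for (r in seq_along(rows)) out[r, ] <- e$P[[rows[r]]][cols]
  out
}

# Internal: refresh the registry and base-vertex index map after the
# committed graph changed.
.syncSimEnv <- function(state) {
  if (is.null(state$graph)) return(state)
  state$baseUIdx <- .registerHaps(state$simEnv, state$graph@haps,
                                  state$tMis)
  state
}

# Internal: constraint rows (allele pairs) for the typed members of one
# configuration, in local vertex indices (2 per individual).
.localConstraints <- function(ids, hla) {
  if (is.null(hla) || !nrow(hla))
    return(data.frame(i = integer(0), a1 = character(0), a2 = character(0),
                      hom = logical(0)))
  typed <- hla[!is.na(hla$allele1) & hla$id %in% ids, , drop = FALSE]
  if (!nrow(typed))
    return(data.frame(i = integer(0), a1 = character(0), a2 = character(0),
                      hom = logical(0)))
  data.frame(i = match(typed$id, ids),
             a1 = pmin(typed$allele1, typed$allele2),
             a2 = pmax(typed$allele1, typed$allele2),
             hom = typed$allele1 == typed$allele2)
}

#' Score a candidate configuration against the current search state
#'
#' Computes the within-label objective of the graph grown with the
#' candidate configuration. With `relabel = "local"` (default) the base
#' labeling is frozen and only the candidate's vertices are labeled (by
#' the heuristic's own seeding, orientation and voting rules); with
#' `relabel = "full"` the grown graph is fully relabeled with [heuLabel].
#'
#' @param state a search state (see [seedUnique]).
#' @param config a configuration (see [instantiateSolution]).
#' @param hla HLA table used for constraint edges.
#' @param relabel `"local"` or `"full"`.
#' @return the objective value (numeric scalar).
#' @export
scoreCandidate <- function(state, config, hla,
                           relabel = c("local", "full")) {
  relabel <- match.arg(relabel)
  if (relabel == "full") {
    g <- if (is.null(state$graph))
      buildSimilarityGraph(config, hla, state$tMis)
    else extendGraph(state$graph, config, hla)
    lab <- heuLabel(g, state$tS)
    return(conScore(g, lab))
  }
  add <- normalizeConfigs(config)
  ctx <- .familyContext(state, names(add), hla)
  .scoreLocal(state, ctx, add)
}

# Internal: per-family invariants for local candidate scoring.
.familyContext <- function(state, ids, hla) {
  cons <- .localConstraints(ids, hla)
  alleles <- sort(unique(c(
    if (!is.null(state$graph)) state$graph@alleles else character(0),
    cons$a1, cons$a2)))
  baseLab <- state$labeling
  labIdx <- lapply(alleles, function(a)
    which(!is.na(baseLab) & baseLab == a))
  hom <- cons[cons$hom, , drop = FALSE]
  het <- cons[!cons$hom, , drop = FALSE]
  consV <- c(2L * cons$i - 1L, 2L * cons$i)
  list(ids = ids, kN = 2L * length(ids), cons = cons, hom = hom,
       het = het, consV = consV, alleles = alleles,
       nA = length(alleles), labIdx = labIdx,
       hetI1 = match(het$a1, alleles), hetI2 = match(het$a2, alleles),
       gainCache = new.env(parent = emptyenv()))
}

# Internal: per-allele sparse gains and full-weight sums of one haplotype
# string against the frozen base labeling, cached per family context.
.baseGains <- function(state, ctx, id) {
  key <- as.character(id)
  hit <- ctx$gainCache[[key]]
  if (!is.null(hit)) return(hit)
  nA <- ctx$nA
  gs <- numeric(max(nA, 1L))
  gf <- numeric(max(nA, 1L))
  if (nA && length(state$labeling)) {
    row <- .simBlock(state$simEnv, id, state$baseUIdx, state$tMis)[1L, ]
    sp <- row
    sp[sp < state$tS] <- 0
    for (a in seq_len(nA)) {
      idx <- ctx$labIdx[[a]]
      if (length(idx)) {
        gs[a] <- sum(sp[idx])
        gf[a] <- sum(row[idx])
      }
    }
  }
  out <- list(gs = gs, gf = gf)
  ctx$gainCache[[key]] <- out
  out
}

# Internal: local candidate scorer (see scoreCandidate). Mirrors the
# heuristic labeler's structure: T[v, a] = sparse gain of giving vertex v
# allele a (base part cached per string, within-family part maintained
# incrementally); for a heterozygous pair the two labels always differ,
# so the only stale term in a flip evaluation is the pair's own weight.
.scoreLocal <- function(state, ctx, add) {
  kN <- ctx$kN
  newHaps <- character(kN)
  for (i in seq_along(add)) {
    newHaps[2L * i - 1L] <- hapToString(add[[i]][1L, ])
    newHaps[2L * i] <- hapToString(add[[i]][2L, ])
  }
  tS <- state$tS
  e <- state$simEnv
  newIdx <- .registerHaps(e, newHaps, state$tMis)
  Wnn <- .simBlock(e, newIdx, newIdx, state$tMis)
  diag(Wnn) <- 0
  alleles <- ctx$alleles
  nA <- ctx$nA
  labN <- rep(NA_character_, kN)
  labI <- rep(NA_integer_, kN)
  Sn <- Wnn
  Sn[Sn < tS] <- 0
  TT <- matrix(0, kN, max(nA, 1L))   # sparse gains, base + within-new
  GF <- matrix(0, kN, max(nA, 1L))   # full-weight sums vs base
  for (v in seq_len(kN)) {
    bg <- .baseGains(state, ctx, newIdx[v])
    TT[v, ] <- bg$gs
    GF[v, ] <- bg$gf
  }
  setLabN <- function(v, ai) {
    old <- labI[v]
    if (!is.na(old)) TT[, old] <<- TT[, old] - Sn[, v]
    labI[v] <<- ai
    labN[v] <<- if (is.na(ai)) NA_character_ else alleles[ai]
    if (!is.na(ai)) TT[, ai] <<- TT[, ai] + Sn[, v]
  }
  hom <- ctx$hom
  for (k in seq_len(nrow(hom))) {
    ai <- match(hom$a1[k], alleles)
    setLabN(2L * hom$i[k] - 1L, ai)
    setLabN(2L * hom$i[k], ai)
  }
  het <- ctx$het
  nH <- nrow(het)
  if (nH) {
    vmax <- vapply(seq_len(nH), function(k) {
      v1 <- 2L * het$i[k] - 1L; v2 <- 2L * het$i[k]
      max(c(0, TT[c(v1, v2), ], Sn[c(v1, v2), ]))
    }, numeric(1))
    ord <- order(-vmax, seq_len(nH))
    for (k in ord) {
      v1 <- 2L * het$i[k] - 1L; v2 <- 2L * het$i[k]
      i1 <- ctx$hetI1[k]; i2 <- ctx$hetI2[k]
      g1 <- TT[v1, i1] + TT[v2, i2]
      g2 <- TT[v1, i2] + TT[v2, i1]
      if (g2 > g1) { setLabN(v1, i2); setLabN(v2, i1) }
      else { setLabN(v1, i1); setLabN(v2, i2) }
    }
    for (sweep in 1:10) {
      changed <- FALSE
      for (k in seq_len(nH)) {
        v1 <- 2L * het$i[k] - 1L; v2 <- 2L * het$i[k]
        c1 <- labI[v1]; c2 <- labI[v2]
        gKeep <- TT[v1, c1] + TT[v2, c2]
        gFlip <- TT[v1, c2] + TT[v2, c1] - 2 * Sn[v1, v2]
        if (gFlip > gKeep) {
          setLabN(v1, c2); setLabN(v2, c1)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  freeV <- setdiff(seq_len(kN), ctx$consV)
  if (length(freeV) && nA) {
    for (sweep in 1:10) {
      changed <- FALSE
      for (v in freeV) {
        wts <- TT[v, ]
        if (all(wts <= 0)) next
        pick <- which(wts == max(wts))
        pick <- pick[order(alleles[pick])][1L]
        if (is.na(labI[v]) || labI[v] != pick) {
          setLabN(v, pick)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  # exact objective delta with full weights
  delta <- 0
  for (v in seq_len(kN)) {
    if (is.na(labI[v])) next
    delta <- delta + GF[v, labI[v]]
    if (v < kN) {
      idx2 <- which(!is.na(labI) & labI == labI[v])
      idx2 <- idx2[idx2 > v]
      if (length(idx2)) delta <- delta + sum(Wnn[v, idx2])
    }
  }
  state$con + delta
}

# Internal: commit a configuration: extend the graph, relabel globally,
# rescore exactly.
commitConfig <- function(state, config, hla, family, f, method) {
  cfg <- normalizeConfigs(config)
  g <- if (is.null(state$graph))
    buildSimilarityGraph(cfg, hla, state$tMis)
  else extendGraph(state$graph, cfg, hla)
  lab <- heuLabel(g, state$tS)
  state$graph <- g
  state$labeling <- lab
  state$con <- conScore(g, lab)
  state$configs <- c(state$configs, cfg)
  state <- .syncSimEnv(state)
  state$log <- rbind(state$log,
                     data.frame(family = family, f = f, method = method,
                                con = state$con))
  state
}

#' Seed the search state with all unique-solution pedigrees
#'
#' Builds one graph from every pedigree with `f = 0` (their configurations
#' are forced), then labels it once. With no such pedigree the state
#' starts from an empty graph and the first ambiguous pedigree is scored
#' against its own constraints only.
#'
#' @param spaces list of [SolutionSpace-class], ascending in `f`.
#' @param hla HLA table used for constraint edges.
#' @param tMis,tS similarity and labeling parameters.
#' @return list: the search state (`state`) and the index of the first
#'   unprocessed pedigree (`next_`).
#' @export
seedUnique <- function(spaces, hla, tMis = 2L, tS = 0.65) {
  state <- newSearchState(tMis, tS)
  i <- 1L
  while (i <= length(spaces) && nFreeVars(spaces[[i]]) == 0L) {
    cfg <- instantiateSolution(spaces[[i]], integer(0))
    state$configs <- c(state$configs, normalizeConfigs(cfg))
    state$log <- rbind(state$log,
                       data.frame(family = spaces[[i]]@family, f = 0L,
                                  method = "unique", con = NA_real_))
    i <- i + 1L
  }
  if (length(state$configs)) {
    state$graph <- buildSimilarityGraph(state$configs, hla, tMis)
    state$labeling <- heuLabel(state$graph, tS)
    state$con <- conScore(state$graph, state$labeling)
    state <- .syncSimEnv(state)
    state$log$con[state$log$method == "unique"] <- state$con
  }
  list(state = state, next_ = i)
}

#' Commit one pedigree by exhaustive enumeration (Enum-Alg)
#'
#' Scores every one of the `2^f` configurations of the pedigree's
#' solution space against the current state and commits the first
#' configuration attaining the maximal objective (ties broken by
#' enumeration order, so the result is deterministic).
#'
#' @param state a search state (see [seedUnique]).
#' @param space the pedigree's [SolutionSpace-class].
#' @param hla HLA table.
#' @param relabel candidate scoring mode (see [scoreCandidate]).
#' @return the updated state.
#' @export
enumAlg <- function(state, space, hla, relabel = c("local", "full")) {
  relabel <- match.arg(relabel)
  f <- nFreeVars(space)
  ctx <- if (relabel == "local")
    .familyContext(state, space@individuals, hla) else NULL
  bestK <- 0L; bestScore <- -Inf
  for (k in seq_len(2^f) - 1L) {
    cfg <- instantiateSolution(space, assignmentBits(k, f))
    sc <- if (is.null(ctx)) scoreCandidate(state, cfg, hla, relabel)
          else .scoreLocal(state, ctx, normalizeConfigs(cfg))
    if (sc > bestScore) { bestScore <- sc; bestK <- k }
  }
  commitConfig(state, instantiateSolution(space, assignmentBits(bestK, f)),
               hla, space@family, f, "enum")
}

#' Commit one pedigree by genetic search (Genetic-Alg)
#'
#' Chromosomes are the free-variable assignment vectors of the solution
#' space; the fitness of a chromosome is the within-label objective of the
#' graph grown with its instantiated configuration. Parents are drawn
#' half by size-2 tournament and half by roulette-wheel selection on
#' positively shifted fitness; offspring undergo single-point crossover
#' with probability `rc` and single-point mutation with probability `rm`;
#' replacement is generational with one elite carried over, for at most
#' `gm` generations (stopping early once the best fitness has stalled for
#' `stall` consecutive generations). The best chromosome ever seen is
#' committed, so the
#' best-so-far fitness is non-decreasing, and the run is reproducible
#' given the seed.
#'
#' @param state a search state.
#' @param space the pedigree's [SolutionSpace-class].
#' @param hla HLA table.
#' @param params a [GAParams-class].
#' @param relabel candidate scoring mode (see [scoreCandidate]).
#' @return the updated state; the per-generation best-so-far trajectory is
#'   attached as attribute `"trajectory"` on the state's log.
#' @export
geneticAlg <- function(state, space, hla, params = GAParams(),
                       relabel = c("local", "full")) {
  relabel <- match.arg(relabel)
  f <- nFreeVars(space)
  if (f == 0L) return(enumAlg(state, space, hla, relabel))
  ctx <- if (relabel == "local")
    .familyContext(state, space@individuals, hla) else NULL
  scoreOne <- function(bits) {
    cfg <- instantiateSolution(space, bits)
    if (is.null(ctx)) scoreCandidate(state, cfg, hla, relabel)
    else .scoreLocal(state, ctx, normalizeConfigs(cfg))
  }
  fitEnv <- new.env(parent = emptyenv())
  pow <- 2^(seq_len(f) - 1L)
  evalPop <- function(pop) {
    keys <- as.character(pop %*% pow)
    out <- numeric(nrow(pop))
    for (i in seq_len(nrow(pop))) {
      v <- fitEnv[[keys[i]]]
      if (is.null(v)) {
        v <- scoreOne(pop[i, ])
        fitEnv[[keys[i]]] <- v
      }
      out[i] <- v
    }
    out
  }
  res <- withLocalSeed(params@seed, {
    ps <- params@ps
    pop <- matrix(sample(0:1, ps * f, replace = TRUE), nrow = ps)
    fit <- evalPop(pop)
    bestIdx <- which.max(fit)
    bestBits <- pop[bestIdx, ]
    bestFit <- fit[bestIdx]
    traj <- bestFit
    sinceImprove <- 0L
    for (g in seq_len(params@gm)) {
      shifted <- fit - min(fit) + 1e-9
      nT <- ps %/% 2L
      # half the parents by size-2 tournament, half by roulette wheel
      a <- sample.int(ps, nT, replace = TRUE)
      b <- sample.int(ps, nT, replace = TRUE)
      win <- ifelse(fit[a] >= fit[b], a, b)
      wheel <- sample.int(ps, ps - nT, replace = TRUE, prob = shifted)
      child <- pop[c(win, wheel), , drop = FALSE]
      for (k in seq(1L, ps - 1L, by = 2L)) {  # single-point crossover
        if (f >= 2L && stats::runif(1) < params@rc) {
          cut <- sample.int(f - 1L, 1L)
          tailIdx <- (cut + 1L):f
          tmp <- child[k, tailIdx]
          child[k, tailIdx] <- child[k + 1L, tailIdx]
          child[k + 1L, tailIdx] <- tmp
        }
      }
      mrows <- which(stats::runif(ps) < params@rm)  # single-point mutation
      if (length(mrows)) {
        pos <- sample.int(f, length(mrows), replace = TRUE)
        idx <- cbind(mrows, pos)
        child[idx] <- 1L - child[idx]
      }
      child[1L, ] <- bestBits  # elitism
      pop <- child
      fit <- evalPop(pop)
      gi <- which.max(fit)
      if (fit[gi] > bestFit) {
        bestFit <- fit[gi]
        bestBits <- pop[gi, ]
        sinceImprove <- 0L
      } else sinceImprove <- sinceImprove + 1L
      traj <- c(traj, bestFit)
      if (params@stall > 0L && sinceImprove >= params@stall) break
    }
    list(bits = bestBits, fit = bestFit, traj = traj)
  })
  state <- commitConfig(state, instantiateSolution(space, res$bits),
                        hla, space@family, f, "ga")
  attr(state$log, "trajectory") <- res$traj
  state
}
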