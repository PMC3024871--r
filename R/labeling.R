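# Feasible labeling of the similarity graph.
#
# The heuristic labeler proceeds in the order: (i) seed from homozygous
# constraint edges, whose endpoints are labeled unambiguously; (ii) drop
# similarity edges below tS; (iii) walk connected components of the sparse
# graph in decreasing order of internal weight, orienting each
# heterozygous constraint edge so that the incremental within-label weight
# against already-labeled vertices is maximal; (iv) revisit orientations
# with deterministic hill-climbing sweeps until no flip improves the
# sparse-graph objective; (v) let unconstrained vertices adopt the
# weighted-majority label among labeled vertices adjacent in their
# component, iterated to a fixed point. Every step preserves feasibility:
# constrained vertices always carry exactly their constraint pair.

# Internal: connected components of the thresholded weight matrix
# (igraph does the traversal).
.components <- function(Ws) {
  if (!nrow(Ws)) return(integer(0))
  g <- igraph::graph_from_adjacency_matrix(Ws > 0, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Heuristic feasible labeling (Heu-Label)
#'
#' Produces a feasible labeling of the graph: every homozygous-typed
#' individual's vertices carry its allele, every heterozygous-typed
#' individual's vertices carry its two alleles in the orientation that
#' maximizes the within-label weight on the `tS`-sparsified graph, and
#' unlabeled vertices adopt the weighted-majority label of their
#' component's labeled vertices (or stay unlabeled when no labeled vertex
#' is reachable). Orientations are revisited with deterministic
#' hill-climbing sweeps until no flip improves the sparse within-label
#' weight. Ties go to the lexicographically smaller allele on the
#' lower-index vertex.
#'
#' @param graph a [SimilarityGraph-class].
#' @param tS sparsification threshold (default 0.65).
#' @param maxSweeps cap on re-orientation / vote sweeps.
#' @return character vector of labels per vertex (`NA` = unlabeled).
#' @export
heuLabel <- function(graph, tS = 0.65, maxSweeps = 10L) {
  W <- graph@weights
  nV <- nrow(W)
  cons <- graph@constraints
  lab <- rep(NA_character_, nV)
  if (!nV) return(lab)
  alleles <- graph@alleles
  nA <- length(alleles)
  Ws <- W
  Ws[Ws < tS] <- 0
  diag(Ws) <- 0
  # G[v, a] = total sparse weight from v to vertices currently labeled a;
  # maintained incrementally so gain queries are O(1). For a heterozygous
  # edge the two labels always differ, so the only stale term when a flip
  # is evaluated is the edge's own weight (subtracted in closed form).
  G <- matrix(0, nrow = nV, ncol = max(nA, 1L))
  # Step 2: homozygous constraints are unambiguous
  if (nrow(cons)) {
    hom <- cons[cons$hom, , drop = FALSE]
    for (k in seq_len(nrow(hom))) {
      a <- match(hom$a1[k], alleles)
      lab[hom$v1[k]] <- hom$a1[k]
      lab[hom$v2[k]] <- hom$a1[k]
      G[, a] <- G[, a] + Ws[, hom$v1[k]] + Ws[, hom$v2[k]]
    }
  }
  comp <- .components(Ws)
  het <- if (nrow(cons)) cons[!cons$hom, , drop = FALSE] else cons
  nH <- nrow(het)
  if (nH) {
    i1 <- match(het$a1, alleles)
    i2 <- match(het$a2, alleles)
    # Step 4: orient het edges, component by component (decreasing
    # internal weight), edges by decreasing strongest incident sparse edge
    nC <- max(comp)
    compW <- vapply(seq_len(nC), function(cid) {
      idx <- which(comp == cid)
      sum(Ws[idx, idx]) / 2
    }, numeric(1))
    compFirst <- vapply(seq_len(nC), function(cid)
      min(which(comp == cid)), integer(1))
    compOrder <- order(-compW, compFirst)
    rowMax <- apply(Ws, 1L, max)
    edgeMax <- pmax(rowMax[het$v1], rowMax[het$v2])
    oriented <- rep(FALSE, nH)
    flipped <- rep(FALSE, nH)  # TRUE: a2 on v1
    for (cid in compOrder) {
      inComp <- which(!oriented &
                        (comp[het$v1] == cid | comp[het$v2] == cid))
      for (k in inComp[order(-edgeMax[inComp], inComp)]) {
        v1 <- het$v1[k]; v2 <- het$v2[k]
        g1 <- G[v1, i1[k]] + G[v2, i2[k]]
        g2 <- G[v1, i2[k]] + G[v2, i1[k]]
        if (g2 > g1) {  # tie keeps a1 (<= a2) on the lower-index vertex
          flipped[k] <- TRUE
          lab[v1] <- het$a2[k]; lab[v2] <- het$a1[k]
          G[, i2[k]] <- G[, i2[k]] + Ws[, v1]
          G[, i1[k]] <- G[, i1[k]] + Ws[, v2]
        } else {
          lab[v1] <- het$a1[k]; lab[v2] <- het$a2[k]
          G[, i1[k]] <- G[, i1[k]] + Ws[, v1]
          G[, i2[k]] <- G[, i2[k]] + Ws[, v2]
        }
        oriented[k] <- TRUE
      }
    }
    # deterministic hill-climbing: flip orientations while that improves
    # the sparse within-label weight
    for (sweep in seq_len(maxSweeps)) {
      changed <- FALSE
      for (k in seq_len(nH)) {
        v1 <- het$v1[k]; v2 <- het$v2[k]
        c1 <- if (flipped[k]) i2[k] else i1[k]
        c2 <- if (flipped[k]) i1[k] else i2[k]
        gKeep <- G[v1, c1] + G[v2, c2]
        gFlip <- G[v1, c2] + G[v2, c1] - 2 * Ws[v1, v2]
        if (gFlip > gKeep) {
          flipped[k] <- !flipped[k]
          lab[v1] <- alleles[c2]; lab[v2] <- alleles[c1]
          d <- Ws[, v1] - Ws[, v2]
          G[, c1] <- G[, c1] - d
          G[, c2] <- G[, c2] + d
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  # Step 5: unconstrained vertices vote; sparse edges never cross
  # components, so G already restricts votes to each vertex's component
  constrained <- if (nrow(cons)) c(cons$v1, cons$v2) else integer(0)
  freeV <- setdiff(seq_len(nV), constrained)
  if (length(freeV) && nA) {
    for (sweep in seq_len(maxSweeps)) {
      changed <- FALSE
      for (v in freeV) {
        wts <- G[v, ]  # self never contributes (zero diagonal)
        if (all(wts <= 0)) next
        top <- alleles[wts == max(wts)]
        pick <- sort(top)[1L]
        if (is.na(lab[v]) || lab[v] != pick) {
          old <- lab[v]
          if (!is.na(old)) {
            oi <- match(old, alleles)
            G[, oi] <- G[, oi] - Ws[, v]
          }
          lab[v] <- pick
          pi_ <- match(pick, alleles)
          G[, pi_] <- G[, pi_] + Ws[, v]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  lab
}

#' Exact maximum-Con labeling by exhaustive search (test oracle)
#'
#' Enumerates every orientation of the heterozygous constraint edges and,
#' jointly, every assignment of the unconstrained vertices over the allele
#' universe plus "unlabeled", and returns a feasible labeling with
#' globally maximal [conScore]. Exponential; refuses instances beyond the
#' guards.
#'
#' @param graph a [SimilarityGraph-class].
#' @param maxHet refuse more heterozygous constraint edges than this.
#' @param maxCombo refuse more than this many total labelings.
#' @return the optimal labeling, with the optimum as attribute `"con"`.
#' @export
bruteForceLabel <- function(graph, maxHet = 15L, maxCombo = 2^18) {
  cons <- graph@constraints
  W <- graph@weights
  nV <- nrow(W)
  het <- if (nrow(cons)) cons[!cons$hom, , drop = FALSE] else cons
  nh <- nrow(het)
  constrained <- if (nrow(cons)) c(cons$v1, cons$v2) else integer(0)
  freeV <- setdiff(seq_len(nV), constrained)
  u <- length(freeV)
  opts <- c(graph@alleles, NA_character_)
  if (nh > maxHet) stop("too many heterozygous constraint edges for brute force")
  total <- 2^nh * length(opts)^u
  if (total > maxCombo) stop("instance too large for brute force")
  base <- rep(NA_character_, nV)
  if (nrow(cons)) {
    hom <- cons[cons$hom, , drop = FALSE]
    base[hom$v1] <- hom$a1
    base[hom$v2] <- hom$a1
  }
  best <- NULL; bestCon <- -Inf
  freeGrid <- if (u) do.call(expand.grid,
                             c(rep(list(seq_along(opts)), u),
                               list(KEEP.OUT.ATTRS = FALSE))) else NULL
  for (o in seq_len(2^nh) - 1L) {
    labO <- base
    if (nh) {
      bits <- assignmentBits(o, nh)
      for (k in seq_len(nh)) {
        if (bits[k] == 0L) {
          labO[het$v1[k]] <- het$a1[k]; labO[het$v2[k]] <- het$a2[k]
        } else {
          labO[het$v1[k]] <- het$a2[k]; labO[het$v2[k]] <- het$a1[k]
        }
      }
    }
    if (u) {
      for (r in seq_len(nrow(freeGrid))) {
        lab <- labO
        lab[freeV] <- opts[as.integer(freeGrid[r, ])]
        con <- conScore(graph, lab)
        if (con > bestCon) { bestCon <- con; best <- lab }
      }
    } else {
      con <- conScore(graph, lab <- labO)
      if (con > bestCon) { bestCon <- con; best <- lab }
    }
  }
  attr(best, "con") <- bestCon
  best
}
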