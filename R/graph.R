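# Weighted similarity graph with HLA constraint edges.

#' Construct a SimilarityGraph from raw parts
#'
#' Mostly useful for tests and small examples; analysis code should build
#' graphs from haplotype configurations with [buildSimilarityGraph].
#'
#' @param weights symmetric matrix of similarity weights in `[0, 1]`
#'   (diagonal is zeroed).
#' @param constraints data.frame `id`, `v1`, `v2`, `a1`, `a2` (one row per
#'   typed individual; `hom` is derived).
#' @param vertices optional vertex table; derived from `constraints` and
#'   the matrix size when omitted.
#' @param haps optional haplotype strings backing the vertices.
#' @param tMis mismatch tolerance recorded on the graph.
#' @return A [SimilarityGraph-class].
#' @export
SimilarityGraph <- function(weights, constraints = NULL, vertices = NULL,
                            haps = NULL, tMis = 2L) {
  nV <- nrow(weights)
  diag(weights) <- 0
  if (is.null(constraints))
    constraints <- data.frame(id = character(0), v1 = integer(0),
                              v2 = integer(0), a1 = character(0),
                              a2 = character(0))
  if (nrow(constraints)) {
    sw <- constraints$a1 > constraints$a2
    tmp <- constraints$a1[sw]
    constraints$a1[sw] <- constraints$a2[sw]
    constraints$a2[sw] <- tmp
    constraints$hom <- constraints$a1 == constraints$a2
  } else constraints$hom <- logical(0)
  if (is.null(vertices)) {
    vertices <- data.frame(vertex = seq_len(nV),
                           id = paste0("v", seq_len(nV)),
                           hap = 1L)
    if (nrow(constraints)) {
      vertices$id[constraints$v1] <- constraints$id
      vertices$id[constraints$v2] <- constraints$id
      vertices$hap[constraints$v2] <- 2L
    }
  }
  if (is.null(haps)) haps <- rep(NA_character_, nV)
  new("SimilarityGraph", vertices = vertices, weights = weights,
      constraints = constraints,
      alleles = sort(unique(c(constraints$a1, constraints$a2))),
      haps = haps, tMis = as.integer(tMis), minWeight = 0)
}

#' Build the weighted similarity graph of a set of haplotype configurations
#'
#' Creates two vertices per individual (one per chromosome copy), a
#' complete similarity edge set weighted by [haplotypeSimilarity], and one
#' constraint edge per HLA-typed individual carrying its unordered allele
#' pair ({a, a} homozygous, {a, b} heterozygous).
#'
#' @param configs named list: individual id -> 2 x m matrix of haplotype
#'   alleles (rows = the two chromosome copies), or a configuration list
#'   from [instantiateSolution] (its `haps` array is unpacked).
#' @param hla HLA table (`id`, `allele1`, `allele2`); individuals absent
#'   from it, or with `NA` alleles, get no constraint edge.
#' @param tMis similarity mismatch tolerance.
#' @return A [SimilarityGraph-class].
#' @export
buildSimilarityGraph <- function(configs, hla, tMis = 2L) {
  configs <- normalizeConfigs(configs)
  ids <- names(configs)
  nV <- 2L * length(ids)
  haps <- character(nV)
  for (i in seq_along(ids)) {
    haps[2L * i - 1L] <- hapToString(configs[[i]][1L, ])
    haps[2L * i] <- hapToString(configs[[i]][2L, ])
  }
  uc <- .uniqueSimCache(haps, tMis)
  W <- uc$uSim[uc$uIdx, uc$uIdx, drop = FALSE]
  diag(W) <- 0
  vertices <- data.frame(vertex = seq_len(nV),
                         id = rep(ids, each = 2L),
                         hap = rep(1:2, length(ids)))
  cons <- data.frame(id = character(0), v1 = integer(0), v2 = integer(0),
                     a1 = character(0), a2 = character(0))
  if (!is.null(hla) && nrow(hla)) {
    typed <- hla[!is.na(hla$allele1) & hla$id %in% ids, , drop = FALSE]
    if (nrow(typed)) {
      i <- match(typed$id, ids)
      cons <- data.frame(id = typed$id, v1 = 2L * i - 1L, v2 = 2L * i,
                         a1 = pmin(typed$allele1, typed$allele2),
                         a2 = pmax(typed$allele1, typed$allele2))
    }
  }
  cons$hom <- if (nrow(cons)) cons$a1 == cons$a2 else logical(0)
  g <- new("SimilarityGraph", vertices = vertices, weights = W,
           constraints = cons,
           alleles = sort(unique(c(cons$a1, cons$a2))),
           haps = haps, tMis = as.integer(tMis), minWeight = 0)
  attr(g, "ucache") <- uc
  g
}

# Internal: accept either a named list of 2 x m matrices or a single
# configuration (list(ids, haps)) or a list of configurations; return the
# named-list-of-matrices form.
normalizeConfigs <- function(configs) {
  if (is.list(configs) && !is.null(configs$haps)) configs <- list(configs)
  if (is.list(configs) && length(configs) &&
      is.list(configs[[1L]]) && !is.null(configs[[1L]]$haps)) {
    out <- list()
    for (cfg in configs) {
      m <- dim(cfg$haps)[3L]
      for (i in seq_along(cfg$ids))
        out[[cfg$ids[i]]] <- matrix(cfg$haps[i, , ], nrow = 2L, ncol = m)
    }
    return(out)
  }
  configs
}

# Internal: similarity cache over unique haplotype strings. `prev` is a
# cache to extend with additional strings.
.uniqueSimCache <- function(haps, tMis, prev = NULL) {
  if (is.null(prev)) {
    uh <- character(0)
    uSim <- matrix(0, 0, 0)
  } else {
    uh <- prev$uh
    uSim <- prev$uSim
  }
  newU <- setdiff(unique(haps), uh)
  if (length(newU)) {
    k0 <- length(uh)
    uh <- c(uh, newU)
    k <- length(uh)
    S <- matrix(0, k, k)
    if (k0) S[seq_len(k0), seq_len(k0)] <- uSim
    hv <- lapply(uh, stringToHap)
    for (i in (k0 + 1L):k) {
      for (j in seq_len(i)) {
        S[i, j] <- S[j, i] <- haplotypeSimilarity(hv[[i]], hv[[j]], tMis)
      }
    }
    uSim <- S
  }
  list(uh = uh, uSim = uSim, uIdx = match(haps, uh))
}

# Internal: append one configuration's individuals to an existing graph,
# computing only the similarities involving genuinely new unique
# haplotypes (everything else is matrix indexing).
extendGraph <- function(graph, config, hla) {
  add <- normalizeConfigs(config)
  ids <- names(add)
  oldV <- nrow(graph@vertices)
  newHaps <- character(2L * length(ids))
  for (i in seq_along(ids)) {
    newHaps[2L * i - 1L] <- hapToString(add[[i]][1L, ])
    newHaps[2L * i] <- hapToString(add[[i]][2L, ])
  }
  allHaps <- c(graph@haps, newHaps)
  nV <- length(allHaps)
  tMis <- graph@tMis
  uc <- attr(graph, "ucache")
  if (is.null(uc) || !identical(uc$uIdx, match(graph@haps, uc$uh)))
    uc <- .uniqueSimCache(graph@haps, tMis)
  uc <- .uniqueSimCache(allHaps, tMis, prev = uc)
  W <- uc$uSim[uc$uIdx, uc$uIdx, drop = FALSE]
  diag(W) <- 0
  newIdx <- (oldV + 1L):nV
  vertices <- rbind(graph@vertices,
                    data.frame(vertex = newIdx, id = rep(ids, each = 2L),
                               hap = rep(1:2, length(ids))))
  cons <- graph@constraints
  if (!is.null(hla) && nrow(hla)) {
    typed <- hla[!is.na(hla$allele1) & hla$id %in% ids, , drop = FALSE]
    if (nrow(typed)) {
      i <- match(typed$id, ids)
      extra <- data.frame(id = typed$id,
                          v1 = oldV + 2L * i - 1L, v2 = oldV + 2L * i,
                          a1 = pmin(typed$allele1, typed$allele2),
                          a2 = pmax(typed$allele1, typed$allele2))
      extra$hom <- extra$a1 == extra$a2
      cons <- rbind(cons, extra)
    }
  }
  g <- new("SimilarityGraph", vertices = vertices, weights = W,
           constraints = cons,
           alleles = sort(unique(c(cons$a1, cons$a2))),
           haps = allHaps, tMis = tMis, minWeight = graph@minWeight)
  attr(g, "ucache") <- uc
  g
}

#' Remove weak similarity edges
#'
#' Retains similarity edges with weight at or above `tS`; vertices and
#' constraint edges are unchanged.
#'
#' @param graph a [SimilarityGraph-class].
#' @param tS threshold in `[0, 1]`.
#' @return The sparsified graph (removed edges carry weight 0 and the
#'   graph records `tS` as its `minWeight`).
#' @export
sparsifyGraph <- function(graph, tS) {
  stopifnot(tS >= 0, tS <= 1)
  W <- graph@weights
  W[W < tS] <- 0
  graph@weights <- W
  graph@minWeight <- tS
  graph
}

#' Within-label similarity objective (Con)
#'
#' The total similarity weight over unordered vertex pairs that carry the
#' same (non-missing) label. This is the objective the labeling heuristic
#' and the configuration search maximize: haplotypes assigned the same
#' HLA allele should be similar.
#'
#' @param graph a [SimilarityGraph-class].
#' @param labeling character vector of allele labels per vertex
#'   (`NA` = unlabeled).
#' @return non-negative numeric.
#' @export
conScore <- function(graph, labeling) {
  W <- graph@weights
  if (length(labeling) != nrow(W))
    stop("labeling must cover every vertex")
  tot <- 0
  for (a in unique(labeling[!is.na(labeling)])) {
    idx <- which(!is.na(labeling) & labeling == a)
    if (length(idx) > 1L) tot <- tot + sum(W[idx, idx]) / 2
  }
  tot
}

#' Is a labeling feasible?
#'
#' A labeling is feasible when, for every constraint edge with allele pair
#' `{a, b}`, the labels of its two endpoints are exactly `{a, b}`.
#'
#' @inheritParams conScore
#' @return TRUE/FALSE.
#' @export
isFeasibleLabeling <- function(graph, labeling) {
  cons <- graph@constraints
  if (!nrow(cons)) return(TRUE)
  for (k in seq_len(nrow(cons))) {
    l1 <- labeling[cons$v1[k]]; l2 <- labeling[cons$v2[k]]
    if (is.na(l1) || is.na(l2)) return(FALSE)
    got <- sort(c(l1, l2))
    if (!identical(got, sort(c(cons$a1[k], cons$a2[k])))) return(FALSE)
  }
  TRUE
}
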