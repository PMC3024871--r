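# Calling HLA types for untyped individuals from the labeled graph.

#' Maximum-weight labeled neighbors of a vertex
#'
#' Over all labeled vertices (label != NA, excluding `v` itself), finds
#' the maximum similarity-edge weight `wm` from `v` and the set `L` of
#' labels attained at that weight.
#'
#' @param graph a [SimilarityGraph-class].
#' @param labeling labels per vertex.
#' @param v vertex index.
#' @return list with `wm` (0 when no labeled vertex exists) and `L`
#'   (sorted character vector, possibly empty).
#' @export
neighborLabels <- function(graph, labeling, v) {
  W <- graph@weights
  idx <- which(!is.na(labeling))
  idx <- setdiff(idx, v)
  if (!length(idx)) return(list(wm = 0, L = character(0)))
  w <- W[v, idx]
  wm <- max(w)
  list(wm = wm, L = sort(unique(labeling[idx[w == wm]])))
}

# Internal: best edge weight from vertex v to a vertex labeled `a`
# (-Inf when none).
.bestTo <- function(W, labeling, v, a) {
  idx <- which(!is.na(labeling) & labeling == a)
  idx <- setdiff(idx, v)
  if (!length(idx)) return(-Inf)
  max(W[v, idx])
}

#' Call HLA types for untyped individuals (HLA-type)
#'
#' For each untyped individual the two vertices' maximum-weight labeled
#' neighbor sets `L1`, `L2` are computed. If either maximum weight falls
#' below `tS` the individual is a no-call. Singleton label sets are called
#' directly; ambiguous sets are resolved by the allele pair `(g1, g2)`,
#' `g1 in L1`, `g2 in L2`, maximizing the total supporting weight over the
#' two ways of pairing the alleles onto the two chromosomes (ties to the
#' lexicographically smallest pair).
#'
#' @param graph a [SimilarityGraph-class].
#' @param labeling a feasible labeling (see [heuLabel]).
#' @param U character vector of untyped individual ids.
#' @param tS no-call threshold on the maximum neighbor weight.
#' @return data.frame `id`, `allele1`, `allele2`, `status`, `w1`, `w2`.
#' @export
hlaType <- function(graph, labeling, U, tS = 0.65) {
  W <- graph@weights
  vt <- graph@vertices
  if (!length(U))
    return(data.frame(id = character(0), allele1 = character(0),
                      allele2 = character(0), status = character(0),
                      w1 = numeric(0), w2 = numeric(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(id = U, allele1 = NA_character_,
                    allele2 = NA_character_, status = "nocall",
                    w1 = NA_real_, w2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_along(U)) {
    vs <- vt$vertex[vt$id == U[r]]
    if (length(vs) != 2L) next
    n1 <- neighborLabels(graph, labeling, vs[1L])
    n2 <- neighborLabels(graph, labeling, vs[2L])
    out$w1[r] <- n1$wm; out$w2[r] <- n2$wm
    if (n1$wm < tS || n2$wm < tS) next
    if (!length(n1$L) || !length(n2$L)) next
    if (length(n1$L) == 1L && length(n2$L) == 1L) {
      out$allele1[r] <- n1$L; out$allele2[r] <- n2$L
      out$status[r] <- "called"
      next
    }
    pairs <- expand.grid(g1 = n1$L, g2 = n2$L, stringsAsFactors = FALSE)
    score <- vapply(seq_len(nrow(pairs)), function(k) {
      g1 <- pairs$g1[k]; g2 <- pairs$g2[k]
      s1 <- .bestTo(W, labeling, vs[1L], g1) + .bestTo(W, labeling, vs[2L], g2)
      s2 <- .bestTo(W, labeling, vs[1L], g2) + .bestTo(W, labeling, vs[2L], g1)
      max(s1, s2)
    }, numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1L) {
      key <- paste(pmin(pairs$g1[best], pairs$g2[best]),
                   pmax(pairs$g1[best], pairs$g2[best]))
      best <- best[order(key)][1L]
    }
    out$allele1[r] <- pairs$g1[best]
    out$allele2[r] <- pairs$g2[best]
    out$status[r] <- "called"
  }
  out
}

#' Coverage and accuracy of a call set against known truth
#'
#' Counts chromosomes, not individuals. Truth chromosomes whose allele is
#' not resolved to the requested resolution, or whose allele (at that
#' resolution) occurs exactly once in the truth data, are excluded before
#' any ratio is formed. Called/truth pairs are compared unordered: the
#' pairing of called onto truth alleles that maximizes agreement is used.
#'
#' @param truth HLA truth table (`id`, `allele1`, `allele2`) for the whole
#'   dataset (used both for scoring and for the singleton-allele filter).
#' @param calls data.frame as returned by [hlaType] (or the `calls` slot
#'   of an [HLACallSet-class]); only rows with status `"called"` or
#'   `"nocall"` are evaluated.
#' @param resolution 2 or 4 digits.
#' @return An [EvalMetrics-class].
#' @export
computeMetrics <- function(truth, calls, resolution = 4L) {
  resolution <- as.integer(resolution)
  tr1 <- truncateAllele(truth$allele1, resolution)
  tr2 <- truncateAllele(truth$allele2, resolution)
  counts <- table(c(tr1, tr2))
  singles <- names(counts)[counts == 1L]
  eval_ <- calls[calls$status %in% c("called", "nocall"), , drop = FALSE]
  nAnalyzed <- 0L; nCalled <- 0L; nCorrect <- 0L
  for (r in seq_len(nrow(eval_))) {
    i <- match(eval_$id[r], truth$id)
    if (is.na(i)) next
    tt <- c(tr1[i], tr2[i])
    if (all(is.na(c(truth$allele1[i], truth$allele2[i])))) next
    keep <- !is.na(tt) & !(tt %in% singles)
    nAnalyzed <- nAnalyzed + sum(keep)
    if (eval_$status[r] != "called" || !any(keep)) next
    cc <- c(truncateAllele(eval_$allele1[r], resolution),
            truncateAllele(eval_$allele2[r], resolution))
    sc <- function(perm) sum(keep & !is.na(cc[perm]) & cc[perm] == tt)
    nCalled <- nCalled + sum(keep)
    nCorrect <- nCorrect + max(sc(1:2), sc(2:1))
  }
  new("EvalMetrics", nAnalyzed = nAnalyzed, nCalled = nCalled,
      nCorrect = nCorrect,
      coverage = if (nAnalyzed) 100 * nCalled / nAnalyzed else NA_real_,
      accuracy = if (nCalled) 100 * nCorrect / nCalled else NA_real_,
      resolution = resolution)
}
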