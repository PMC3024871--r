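# Haplotype similarity via maximum regions of nearly identical matching.
#
# Two haplotypes over {0, 1, NA} are compared locus by locus. A region
# [p, q] is admissible when p < q, both endpoints are matching loci, and
# no run of more than tMis consecutive mismatches occurs inside it.
# Unknown loci neither match nor mismatch; they interrupt (reset) a
# mismatch run, because only literally adjacent mismatches count as
# continuous. The similarity is the largest number of matching loci over
# all admissible regions, divided by the window length n (unknown loci
# included in the denominator so weights stay comparable across pairs);
# it is 0 when no admissible region exists, and 1 for two identical,
# fully observed haplotypes.

#' Locus comparison state
#'
#' @param a,b alleles (0, 1 or `NA`).
#' @return `"match"`, `"mismatch"` or `"unknown"` (vectorised).
#' @export
#' @examples
#' locusState(0, 0)   # match
#' locusState(0, 1)   # mismatch
#' locusState(0, NA)  # unknown
locusState <- function(a, b) {
  out <- rep("unknown", length(a))
  known <- !is.na(a) & !is.na(b)
  out[known & a == b] <- "match"
  out[known & a != b] <- "mismatch"
  out
}

# Internal: per-locus states as integers (1 match, -1 mismatch, 0 unknown).
.locusStates <- function(h1, h2) {
  st <- integer(length(h1))
  known <- !is.na(h1) & !is.na(h2)
  st[known & h1 == h2] <- 1L
  st[known & h1 != h2] <- -1L
  st
}

#' Maximum regions of nearly identical matching
#'
#' Returns every region `[p, q]` that (i) has matching loci at both
#' endpoints with `p < q`, (ii) contains no run of more than `tMis`
#' consecutive mismatches, and (iii) attains the global maximum number of
#' matching loci over all regions satisfying (i)-(ii).
#'
#' @param h1,h2 integer haplotypes over `{0, 1, NA}`, equal length.
#' @param tMis maximum tolerated run of consecutive mismatches
#'   (integer >= 1; default 2).
#' @return data.frame with columns `p`, `q`, `matches` (possibly 0 rows).
#' @export
#' @examples
#' maxMatchRegions(rep(1L, 5), rep(1L, 5))          # the whole window
#' maxMatchRegions(c(1L,0L,1L,0L,1L), rep(1L, 5))   # isolated mismatches
maxMatchRegions <- function(h1, h2, tMis = 2L) {
  tMis <- as.integer(tMis)
  if (length(h1) != length(h2)) stop("haplotypes must have equal length")
  if (is.na(tMis) || tMis < 1L) stop("tMis must be an integer >= 1")
  st <- .locusStates(h1, h2)
  n <- length(st)
  empty <- data.frame(p = integer(0), q = integer(0), matches = integer(0))
  if (n < 2L) return(empty)
  # split the window at runs of more than tMis consecutive mismatches
  r <- rle(st == -1L)
  barrier <- r$values & r$lengths > tMis
  chunk <- rep.int(cumsum(barrier) - ifelse(barrier, 1L, 0L), r$lengths)
  chunk[rep.int(barrier, r$lengths)] <- NA_integer_
  regions <- empty
  for (cid in unique(chunk[!is.na(chunk)])) {
    pos <- which(!is.na(chunk) & chunk == cid & st == 1L)
    if (length(pos) >= 2L) {
      regions <- rbind(regions,
                       data.frame(p = pos[1L], q = pos[length(pos)],
                                  matches = length(pos)))
    }
  }
  if (!nrow(regions)) return(empty)
  best <- max(regions$matches)
  out <- regions[regions$matches == best, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Haplotype similarity
#'
#' The number of matching loci in a maximum region of nearly identical
#' matching, divided by the window length. 0 when no admissible region
#' exists; 1 for identical fully observed haplotypes; symmetric in its
#' arguments and non-decreasing in `tMis`.
#'
#' @inheritParams maxMatchRegions
#' @param cache memoise the result in the package-level cache keyed by the
#'   two haplotype strings and `tMis` (default TRUE).
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' h <- c(1L, 1L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 1L)
#' haplotypeSimilarity(h, h)                  # 1
#' haplotypeSimilarity(h, rep(1L, 10))        # 0.9
haplotypeSimilarity <- function(h1, h2, tMis = 2L, cache = TRUE) {
  if (length(h1) != length(h2)) stop("haplotypes must have equal length")
  tMis <- as.integer(tMis)
  if (is.na(tMis) || tMis < 1L) stop("tMis must be an integer >= 1")
  if (cache) {
    s1 <- hapToString(h1); s2 <- hapToString(h2)
    key <- if (s1 <= s2) paste(s1, s2, tMis, sep = "|")
           else paste(s2, s1, tMis, sep = "|")
    hit <- .pedhla$simcache[[key]]
    if (!is.null(hit)) return(hit)
  }
  val <- .simValue(h1, h2, tMis)
  if (cache) .pedhla$simcache[[key]] <- val
  val
}

# Internal fast path: the similarity value without building the region
# table. Same semantics as maxMatchRegions (asserted by tests).
.simValue <- function(h1, h2, tMis) {
  known <- !is.na(h1) & !is.na(h2)
  eq <- known & h1 == h2
  if (!any(eq)) return(0)
  mis <- known & !eq
  n <- length(h1)
  r <- rle(mis)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  barrier <- r$values & r$lengths > tMis
  cm <- cumsum(eq)
  bs <- c(1L, ends[barrier] + 1L)   # chunk starts
  be <- c(starts[barrier] - 1L, n)  # chunk ends
  best <- 0L
  for (k in seq_along(bs)) {
    s <- bs[k]; e <- be[k]
    if (s > e) next
    cnt <- cm[e] - if (s > 1L) cm[s - 1L] else 0L
    if (cnt >= 2L && cnt > best) best <- cnt
  }
  best / n
}

# Internal: similarity matrix for a character vector of haplotype strings.
# Deduplicates identical strings and goes through the cache.
similarityMatrixFromStrings <- function(haps, tMis) {
  n <- length(haps)
  W <- matrix(0, n, n)
  if (n < 2L) return(W)
  uh <- unique(haps)
  idx <- match(haps, uh)
  k <- length(uh)
  U <- matrix(0, k, k)
  hv <- lapply(uh, stringToHap)
  for (i in seq_len(k)) {
    U[i, i] <- haplotypeSimilarity(hv[[i]], hv[[i]], tMis)
    if (i < k) for (j in (i + 1L):k) {
      U[i, j] <- U[j, i] <- haplotypeSimilarity(hv[[i]], hv[[j]], tMis)
    }
  }
  W <- U[idx, idx, drop = FALSE]
  diag(W) <- 0
  W
}
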