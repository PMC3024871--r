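# Internal utilities: GF(2) linear algebra, the similarity cache and a
# local-RNG helper. None of these are exported.

.pedhla <- new.env(parent = emptyenv())
.pedhla$simcache <- new.env(parent = emptyenv())
.pedhla$registry <- new.env(parent = emptyenv())

# Session-global registry of unique haplotype strings and lazily cached
# per-string similarity rows, one per tMis value. Similarities depend
# only on the two strings and tMis, so sharing across runs is safe.
.getSimRegistry <- function(tMis) {
  key <- as.character(as.integer(tMis))
  e <- .pedhla$registry[[key]]
  if (is.null(e)) {
    e <- new.env(parent = emptyenv())
    e$uh <- character(0)
    e$hv <- list()
    e$P <- list()
    e$map <- new.env(parent = emptyenv())
    .pedhla$registry[[key]] <- e
  }
  e
}

#' Clear the pairwise similarity cache
#'
#' Pairwise haplotype similarities depend only on the two allele strings and
#' on `tMis`, so they are memoised in a package-level cache that persists for
#' the session. The cache is transparent to results; this resets it.
#'
#' @return Invisibly, the number of entries removed.
#' @export
clearSimilarityCache <- function() {
  n <- length(ls(.pedhla$simcache, all.names = TRUE))
  .pedhla$simcache <- new.env(parent = emptyenv())
  .pedhla$registry <- new.env(parent = emptyenv())
  invisible(n)
}

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched. seed must be a single finite integer-like value.
withLocalSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# --- GF(2) linear algebra -------------------------------------------------
# Equation systems are integer matrices with one column per variable plus a
# final right-hand-side column; all arithmetic is mod 2.

# Row-reduce A (rows = equations). Returns the reduced matrix, the pivot
# column index per pivot row, and a consistency flag (FALSE when a row
# reduces to 0 = 1).
gf2Rref <- function(A, nVars) {
  if (nrow(A) == 0L) {
    return(list(mat = A, pivots = integer(0), rows = integer(0),
                consistent = TRUE))
  }
  A <- A %% 2L
  r <- 1L
  pivots <- integer(0)
  pivotRows <- integer(0)
  for (col in seq_len(nVars)) {
    hot <- which(A[, col] == 1L)
    hot <- hot[hot >= r]
    if (!length(hot)) next
    if (hot[1L] != r) A[c(r, hot[1L]), ] <- A[c(hot[1L], r), ]
    others <- which(A[, col] == 1L)
    others <- others[others != r]
    if (length(others)) {
      A[others, ] <- (A[others, , drop = FALSE] +
                        matrix(A[r, ], nrow = length(others),
                               ncol = ncol(A), byrow = TRUE)) %% 2L
    }
    pivots <- c(pivots, col)
    pivotRows <- c(pivotRows, r)
    r <- r + 1L
    if (r > nrow(A)) break
  }
  bad <- which(rowSums(A[, seq_len(nVars), drop = FALSE]) == 0L &
                 A[, nVars + 1L] == 1L)
  list(mat = A, pivots = pivots, rows = pivotRows,
       consistent = length(bad) == 0L)
}

# Indices of a maximal linearly independent subset of the columns of M
# (0/1 matrix), in left-to-right greedy order.
gf2IndependentCols <- function(M) {
  if (is.null(dim(M)) || ncol(M) == 0L || nrow(M) == 0L) return(integer(0))
  M <- M %% 2L
  keep <- integer(0)
  r <- 1L
  work <- M
  for (col in seq_len(ncol(work))) {
    hot <- which(work[, col] == 1L)
    hot <- hot[hot >= r]
    if (!length(hot)) next
    if (hot[1L] != r) work[c(r, hot[1L]), ] <- work[c(hot[1L], r), ]
    others <- which(work[, col] == 1L)
    others <- others[others != r]
    if (length(others)) {
      work[others, ] <- (work[others, , drop = FALSE] +
                           matrix(work[r, ], nrow = length(others),
                                  ncol = ncol(work), byrow = TRUE)) %% 2L
    }
    keep <- c(keep, col)
    r <- r + 1L
    if (r > nrow(work)) break
  }
  keep
}

# --- haplotype string helpers --------------------------------------------

hapToString <- function(h) {
  u <- h + 48L           # '0'/'1'
  u[is.na(u)] <- 45L     # '-'
  intToUtf8(u)
}

stringToHap <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- suppressWarnings(as.integer(v))
  out
}

# Bit vector (little-endian, v1 = least significant) for k in 0..2^f-1.
assignmentBits <- function(k, f) {
  if (f == 0L) return(integer(0))
  as.integer(intToBits(k))[seq_len(f)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
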