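# End-to-end orchestration: window selection, per-pedigree solution
# spaces, incremental configuration search, labeling, and type calls.

#' Run the full HLA imputation pipeline
#'
#' Executes, in order: marker window selection; Mendelian cleaning;
#' per-pedigree zero-recombinant solution spaces (with the segmented
#' fallback for recombinant pedigrees); a stable sort of pedigrees by
#' free-variable count; seeding of the similarity graph with all
#' unique-solution pedigrees; exhaustive configuration selection while
#' `f <= tc`; genetic-algorithm selection for the rest; and finally type
#' calls for every individual whose HLA type is unknown. Individuals with
#' known types are passed through unchanged.
#'
#' @param pop an [HlaPopulation-class]. Its HLA table defines the typed
#'   reference set R; individuals absent from the table or with unknown
#'   alleles form the query set U.
#' @param config a [RunConfig-class].
#' @param spaces optional precomputed solution spaces (as returned with
#'   the result in `$spaces`); they depend only on genotypes, so
#'   evaluation harnesses that re-run the pipeline under different HLA
#'   masks can reuse them.
#' @return An [HLACallSet-class]; attribute-free access via [callTable]
#'   and [runLog]. The per-pedigree spaces are attached as attribute
#'   `"spaces"` for reuse.
#' @export
runHlaInference <- function(pop, config = RunConfig(), spaces = NULL) {
  idx <- windowMarkers(pop@map, config@centerBp, config@windowKb)
  if (!length(idx)) stop("marker window is empty")
  ped <- pop@pedigree
  hla <- pop@hla
  # truncate the reference table to the working resolution
  if (nrow(hla)) {
    hla$allele1 <- truncateAllele(hla$allele1, config@resolution)
    hla$allele2 <- truncateAllele(hla$allele2, config@resolution)
    drop <- is.na(hla$allele1) | is.na(hla$allele2)
    hla$allele1[drop] <- NA_character_
    hla$allele2[drop] <- NA_character_
  }
  typedIds <- hla$id[!is.na(hla$allele1)]
  if (!length(typedIds))
    warning("no typed individuals: every call will be a no-call")
  if (is.null(spaces)) {
    sub <- pop
    sub@genotypes <- pop@genotypes[, idx, drop = FALSE]
    sub@map <- pop@map[idx, , drop = FALSE]
    sub <- cleanMendelianErrors(sub)$pop
    fams <- unique(ped$family)
    spaces <- lapply(fams, function(fam) {
      rows <- ped[ped$family == fam, , drop = FALSE]
      gsub_ <- sub@genotypes[rows$id, , drop = FALSE]
      tryCatch(buildSolutionSpace(rows, gsub_, family = fam),
               pedhla_recombinant = function(e)
                 segmentFallback(rows, gsub_, family = fam))
    })
  }
  ord <- orderPedigrees(spaces)
  spaces <- spaces[ord]
  seeded <- seedUnique(spaces, hla, tMis = config@tMis, tS = config@tS)
  state <- seeded$state
  i <- seeded$next_
  tc <- config@ga@tc
  while (i <= length(spaces)) {
    f <- nFreeVars(spaces[[i]])
    if (f <= tc) {
      state <- enumAlg(state, spaces[[i]], hla)
    } else {
      state <- geneticAlg(state, spaces[[i]], hla, config@ga)
    }
    i <- i + 1L
  }
  if (is.null(state$graph)) {
    # degenerate: no pedigree at all
    calls <- data.frame(id = character(0), allele1 = character(0),
                        allele2 = character(0), status = character(0),
                        w1 = numeric(0), w2 = numeric(0))
    return(new("HLACallSet", calls = calls, log = state$log,
               labeling = character(0), params = list(config = config)))
  }
  U <- setdiff(ped$id, typedIds)
  typed <- hla[!is.na(hla$allele1), , drop = FALSE]
  callsU <- hlaType(state$graph, state$labeling, U, tS = config@tS)
  callsR <- data.frame(id = typed$id, allele1 = typed$allele1,
                       allele2 = typed$allele2,
                       status = rep("known", nrow(typed)),
                       w1 = rep(NA_real_, nrow(typed)),
                       w2 = rep(NA_real_, nrow(typed)),
                       stringsAsFactors = FALSE)
  calls <- rbind(callsR, callsU)
  calls <- calls[match(ped$id, calls$id), , drop = FALSE]
  rownames(calls) <- NULL
  out <- new("HLACallSet", calls = calls, log = state$log,
             labeling = state$labeling,
             params = list(config = config))
  attr(out, "spaces") <- spaces
  out
}

#' Leave-one-out evaluation
#'
#' For each individual with a known HLA type, the type is removed, the
#' full pipeline is re-run, and the re-inferred pair is scored against
#' the removed truth. Solution spaces depend only on genotypes and are
#' computed once and reused across the masked runs.
#'
#' @param pop fully typed [HlaPopulation-class] (the HLA table is the
#'   truth).
#' @param config a [RunConfig-class].
#' @return list: `metrics` (an [EvalMetrics-class]) and `calls` (one row
#'   per held-out individual).
#' @export
leaveOneOut <- function(pop, config = RunConfig()) {
  truth <- pop@hla
  targets <- truth$id[!is.na(truth$allele1)]
  spaces <- NULL
  rows <- NULL
  for (id in targets) {
    masked <- pop
    r <- masked@hla$id == id
    masked@hla$allele1[r] <- NA_character_
    masked@hla$allele2[r] <- NA_character_
    res <- runHlaInference(masked, config, spaces = spaces)
    if (is.null(spaces)) spaces <- attr(res, "spaces")
    rows <- rbind(rows, res@calls[res@calls$id == id, , drop = FALSE])
  }
  list(metrics = computeMetrics(truth, rows, config@resolution),
       calls = rows)
}

#' Leave-one-pedigree-out evaluation
#'
#' As [leaveOneOut], but the HLA types of every member of a pedigree are
#' removed together before re-inference, so no within-family reference
#' information remains.
#'
#' @inheritParams leaveOneOut
#' @return list: `metrics` and `calls`.
#' @export
leaveOnePedigreeOut <- function(pop, config = RunConfig()) {
  truth <- pop@hla
  ped <- pop@pedigree
  spaces <- NULL
  rows <- NULL
  for (fam in unique(ped$family)) {
    ids <- ped$id[ped$family == fam]
    ids <- ids[ids %in% truth$id[!is.na(truth$allele1)]]
    if (!length(ids)) next
    masked <- pop
    r <- masked@hla$id %in% ids
    masked@hla$allele1[r] <- NA_character_
    masked@hla$allele2[r] <- NA_character_
    res <- runHlaInference(masked, config, spaces = spaces)
    if (is.null(spaces)) spaces <- attr(res, "spaces")
    rows <- rbind(rows, res@calls[res@calls$id %in% ids, , drop = FALSE])
  }
  list(metrics = computeMetrics(truth, rows, config@resolution),
       calls = rows)
}
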