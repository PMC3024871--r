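#' @import methods
NULL

# Unknown HLA allele token used in on-disk tables.
UNKNOWN_ALLELE <- "-"

#' Pedigree population container
#'
#' Holds the four linked inputs of an HLA-imputation run: the pedigree
#' roster, the bi-allelic SNP genotype matrix, the marker map and the HLA
#' type table. Genotypes are stored as minor-allele dosages (0, 1, 2, `NA`
#' for missing), one row per individual and one column per marker.
#'
#' @slot pedigree data.frame with columns `family`, `id`, `father`,
#'   `mother`, `sex`; `father`/`mother` are `NA` for founders.
#' @slot genotypes integer matrix of allele dosages, rownames = individual
#'   ids, colnames = marker ids.
#' @slot map data.frame with columns `marker`, `chrom`, `pos` (1-based
#'   base-pair positions, strictly increasing within a chromosome).
#' @slot hla data.frame with columns `id`, `allele1`, `allele2`; both
#'   alleles `NA` when the individual is untyped.
#'
#' @export
setClass("HlaPopulation",
  representation(pedigree = "data.frame", genotypes = "matrix",
                 map = "data.frame", hla = "data.frame"))

setValidity("HlaPopulation", function(object) {
  ped <- object@pedigree
  msgs <- character(0)
  need <- c("family", "id", "father", "mother", "sex")
  if (!all(need %in% names(ped)))
    return(paste("pedigree must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(ped$id)) msgs <- c(msgs, "duplicated individual ids")
  if (!identical(rownames(object@genotypes), as.character(ped$id)))
    msgs <- c(msgs, "genotype rows must match the pedigree roster (same ids, same order)")
  if (nrow(object@map) != ncol(object@genotypes))
    msgs <- c(msgs, "marker map rows must match genotype columns")
  if (anyDuplicated(object@map$marker)) msgs <- c(msgs, "duplicated marker ids")
  oneSided <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(oneSided))
    msgs <- c(msgs, "individuals must have both parents or neither")
  parents <- c(ped$father, ped$mother)
  parents <- parents[!is.na(parents)]
  if (!all(parents %in% ped$id)) {
    msgs <- c(msgs, "parent id absent from roster")
  } else {
    # parents must belong to the same family as the child
    fam <- stats::setNames(ped$family, ped$id)
    kid <- !is.na(ped$father)
    if (any(kid) && (any(fam[ped$father[kid]] != ped$family[kid]) ||
                     any(fam[ped$mother[kid]] != ped$family[kid])))
      msgs <- c(msgs, "parents must belong to the child's family")
  }
  # acyclic parent links (only checkable when every parent is on the roster)
  if (!all(is.na(ped$father)) && all(parents %in% ped$id)) {
    depth <- stats::setNames(rep(NA_integer_, nrow(ped)), ped$id)
    resolve <- function(id, seen) {
      if (id %in% seen) return(NA_integer_)  # cycle
      if (!is.na(depth[[id]])) return(depth[[id]])
      i <- match(id, ped$id)
      if (is.na(ped$father[i])) { depth[[id]] <<- 0L; return(0L) }
      df <- resolve(ped$father[i], c(seen, id))
      dm <- resolve(ped$mother[i], c(seen, id))
      if (is.na(df) || is.na(dm)) return(NA_integer_)
      depth[[id]] <<- max(df, dm) + 1L
      depth[[id]]
    }
    for (id in ped$id) {
      if (is.na(resolve(id, character(0)))) {
        msgs <- c(msgs, "pedigree contains a parent-link cycle")
        break
      }
    }
  }
  for (ch in unique(object@map$chrom)) {
    p <- object@map$pos[object@map$chrom == ch]
    if (any(diff(p) <= 0))
      msgs <- c(msgs, sprintf("marker positions not strictly increasing on chromosome %s", ch))
  }
  if (nrow(object@hla)) {
    if (!all(object@hla$id %in% ped$id))
      msgs <- c(msgs, "HLA table contains unknown individual id")
    if (any(xor(is.na(object@hla$allele1), is.na(object@hla$allele2))))
      msgs <- c(msgs, "HLA allele pair must be fully known or fully unknown")
  }
  g <- object@genotypes
  if (!all(g[!is.na(g)] %in% 0:2))
    msgs <- c(msgs, "genotype dosages must be 0, 1, 2 or NA")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an HlaPopulation
#'
#' @param pedigree,genotypes,map,hla see the class slots.
#' @return A validated [HlaPopulation-class] object.
#' @export
HlaPopulation <- function(pedigree, genotypes, map, hla) {
  pedigree$family <- as.character(pedigree$family)
  pedigree$id <- as.character(pedigree$id)
  pedigree$father <- as.character(pedigree$father)
  pedigree$mother <- as.character(pedigree$mother)
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- pedigree$id
  colnames(genotypes) <- as.character(map$marker)
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (missing(hla) || is.null(hla))
    hla <- data.frame(id = character(0), allele1 = character(0),
                      allele2 = character(0), stringsAsFactors = FALSE)
  hla$id <- as.character(hla$id)
  hla$allele1 <- as.character(hla$allele1)
  hla$allele2 <- as.character(hla$allele2)
  rownames(pedigree) <- NULL
  rownames(map) <- NULL
  rownames(hla) <- NULL
  new("HlaPopulation", pedigree = pedigree, genotypes = genotypes,
      map = map, hla = hla)
}

#' Zero-recombinant pedigree haplotype solution space
#'
#' Compact representation of every haplotype configuration of one pedigree
#' that satisfies the Mendelian and zero-recombinant constraints over a
#' marker window. The space is an affine subspace over GF(2): each allele
#' slot is a constant plus a linear combination of `f` free binary
#' variables, so the space holds exactly `2^f` distinct configurations.
#'
#' @slot family family id.
#' @slot individuals individual ids (roster order).
#' @slot m number of markers in the window.
#' @slot f number of free binary variables.
#' @slot alleleConst numeric array `(n, 2, m)`; the constant term of each
#'   allele slot, `NA` where the allele is unresolvable (missing genotype
#'   with no constraint through relatives).
#' @slot alleleCoef integer array `(n, 2, m, f)` of GF(2) coefficients.
#' @slot tTable data.frame describing the transmission bits (one per
#'   child/parent link) with their affine expressions.
#' @slot tCoef integer matrix `(nrow(tTable), f)`.
#' @slot geno the (cleaned) dosage submatrix used to build the space.
#' @slot segmented TRUE when the space was built by the recombination
#'   fallback as a stitched product of per-segment spaces.
#' @slot segments list of per-segment `SolutionSpace` objects.
#' @slot segStarts integer start column of each segment.
#'
#' @export
setClass("SolutionSpace",
  representation(family = "character", individuals = "character",
                 m = "integer", f = "integer",
                 alleleConst = "array", alleleCoef = "array",
                 tTable = "data.frame", tCoef = "matrix",
                 geno = "matrix",
                 segmented = "logical", segments = "list",
                 segStarts = "integer"))

setValidity("SolutionSpace", function(object) {
  if (object@f < 0L) return("f must be >= 0")
  if (!object@segmented) {
    d <- dim(object@alleleCoef)
    if (length(d) != 4L || d[4L] != object@f)
      return("alleleCoef must have f coefficient slices")
  }
  TRUE
})

#' Weighted haplotype similarity graph
#'
#' Two vertices per individual (one per chromosome copy), a complete
#' similarity edge set weighted by the pairwise haplotype similarity, and
#' one constraint edge per HLA-typed individual carrying its unordered
#' allele pair.
#'
#' @slot vertices data.frame `vertex`, `id`, `hap` (1 or 2).
#' @slot weights symmetric numeric matrix of similarity weights in [0, 1],
#'   zero diagonal.
#' @slot constraints data.frame `id`, `v1`, `v2`, `a1`, `a2`, `hom`.
#' @slot alleles allele universe (sorted labels appearing in constraints).
#' @slot haps haplotype strings backing each vertex.
#' @slot tMis mismatch-run tolerance used for the weights.
#' @slot minWeight similarity edges below this weight are treated as
#'   removed (see [sparsifyGraph]).
#'
#' @export
setClass("SimilarityGraph",
  representation(vertices = "data.frame", weights = "matrix",
                 constraints = "data.frame", alleles = "character",
                 haps = "character", tMis = "integer",
                 minWeight = "numeric"))

setValidity("SimilarityGraph", function(object) {
  W <- object@weights
  if (nrow(W) != nrow(object@vertices)) return("weight matrix size mismatch")
  if (nrow(W) && max(abs(W - t(W))) > 1e-12) return("weights must be symmetric")
  if (nrow(W) && (min(W) < -1e-12 || max(W) > 1 + 1e-12))
    return("weights must lie in [0, 1]")
  if (nrow(object@constraints) && anyDuplicated(object@constraints$id))
    return("at most one constraint edge per individual")
  TRUE
})

#' HLA call set
#'
#' Per-individual inferred unordered allele pairs with call status and the
#' supporting maximum neighbor weights, plus the run log.
#'
#' @slot calls data.frame `id`, `allele1`, `allele2`, `status`
#'   (`"called"`, `"nocall"` or `"known"`), `w1`, `w2`.
#' @slot log data.frame with one row per pedigree: `family`, `f`, `method`,
#'   `con` (committed objective value).
#' @slot labeling the final vertex labeling.
#' @slot params list of run parameters.
#'
#' @export
setClass("HLACallSet",
  representation(calls = "data.frame", log = "data.frame",
                 labeling = "character", params = "list"))

#' Coverage / accuracy metrics
#'
#' Chromosome-level evaluation counts: `coverage = nCalled / nAnalyzed` and
#' `accuracy = nCorrect / nCalled`, both reported as percentages.
#'
#' @slot nAnalyzed,nCalled,nCorrect chromosome counts.
#' @slot coverage,accuracy percentages on the 0-100 scale; `accuracy` is
#'   `NA` when no chromosome was called.
#' @slot resolution allele-name resolution (2 or 4 digits) used.
#'
#' @export
setClass("EvalMetrics",
  representation(nAnalyzed = "integer", nCalled = "integer",
                 nCorrect = "integer", coverage = "numeric",
                 accuracy = "numeric", resolution = "integer"))

setValidity("EvalMetrics", function(object) {
  if (object@nCorrect > object@nCalled || object@nCalled > object@nAnalyzed)
    return("need nCorrect <= nCalled <= nAnalyzed")
  TRUE
})

#' Genetic-algorithm parameters
#'
#' Defaults follow the standard settings for this search: population size
#' 400, at most 50 generations, crossover rate 0.8, mutation rate 0.2, and
#' an enumeration threshold of 10 free variables below which exhaustive
#' enumeration is used instead of the GA.
#'
#' @slot ps population size.
#' @slot gm maximum number of generations.
#' @slot rc crossover rate.
#' @slot rm mutation rate.
#' @slot tc enumeration threshold on the free-variable count.
#' @slot stall stop early once the best fitness has not improved for this
#'   many consecutive generations (`gm` remains the hard maximum).
#' @slot seed RNG seed for the GA.
#'
#' @export
setClass("GAParams",
  representation(ps = "integer", gm = "integer", rc = "numeric",
                 rm = "numeric", tc = "integer", stall = "integer",
                 seed = "integer"),
  prototype(ps = 400L, gm = 50L, rc = 0.8, rm = 0.2, tc = 10L,
            stall = 10L, seed = 1L))

setValidity("GAParams", function(object) {
  if (object@ps <= 0L) return("ps must be positive")
  if (object@rc < 0 || object@rc > 1 || object@rm < 0 || object@rm > 1)
    return("rates must lie in [0, 1]")
  TRUE
})

#' @param ps,gm,rc,rm,tc,stall,seed see the class slots.
#' @return A `GAParams` object.
#' @rdname GAParams-class
#' @export
GAParams <- function(ps = 400L, gm = 50L, rc = 0.8, rm = 0.2, tc = 10L,
                     stall = 10L, seed = 1L) {
  new("GAParams", ps = as.integer(ps), gm = as.integer(gm), rc = rc,
      rm = rm, tc = as.integer(tc), stall = as.integer(stall),
      seed = as.integer(seed))
}

#' End-to-end run configuration
#'
#' @slot gene gene name (bookkeeping only).
#' @slot centerBp center position of the gene in base pairs.
#' @slot windowKb total window size in kb (default 200, i.e. 100kb up- and
#'   downstream of the center).
#' @slot tMis similarity mismatch-run tolerance (default 2).
#' @slot tS labeling / no-call similarity threshold (default 0.65).
#' @slot resolution allele resolution in digits, 2 or 4.
#' @slot ga [GAParams-class] for large solution spaces.
#'
#' @export
setClass("RunConfig",
  representation(gene = "character", centerBp = "numeric",
                 windowKb = "numeric", tMis = "integer", tS = "numeric",
                 resolution = "integer", ga = "GAParams"),
  prototype(gene = "HLA", centerBp = 31500000, windowKb = 200,
            tMis = 2L, tS = 0.65, resolution = 4L))

setValidity("RunConfig", function(object) {
  if (object@windowKb <= 0) return("windowKb must be positive")
  if (object@tMis < 1L) return("tMis must be a positive integer")
  if (object@tS < 0 || object@tS > 1) return("tS must lie in [0, 1]")
  if (!object@resolution %in% c(2L, 4L)) return("resolution must be 2 or 4")
  TRUE
})

#' @param gene,centerBp,windowKb,tMis,tS,resolution,ga see the class slots.
#' @return A `RunConfig` object.
#' @rdname RunConfig-class
#' @export
RunConfig <- function(gene = "HLA", centerBp = 31500000, windowKb = 200,
                      tMis = 2L, tS = 0.65, resolution = 4L,
                      ga = GAParams()) {
  new("RunConfig", gene = gene, centerBp = centerBp, windowKb = windowKb,
      tMis = as.integer(tMis), tS = tS, resolution = as.integer(resolution),
      ga = ga)
}

#' Simulation configuration
#'
#' Describes a synthetic pedigree population with the statistical structure
#' the imputation method assumes: each HLA allele is carried on one or more
#' distinctive SNP background haplotypes, founders draw allele/background
#' pairs i.i.d. from the allele frequency distribution, and children
#' inherit whole parental haplotypes with an optional single crossover per
#' meiosis. Genotyping noise is modelled as i.i.d. allele flips and
#' missingness on the conflated genotypes.
#'
#' @slot nFamilies number of pedigrees (each: two founders + children).
#' @slot nChildren children per family (recycled over families).
#' @slot nMarkers markers in the window.
#' @slot alleleFreqs named numeric vector of allele frequencies (names are
#'   4-digit allele strings); must sum to 1.
#' @slot backgroundsPerAllele distinct background haplotypes per allele.
#' @slot minDivergence minimum pairwise Hamming distance between
#'   backgrounds of different alleles.
#' @slot recombRate per-meiosis probability of a single crossover.
#' @slot missingRate per-genotype missingness probability.
#' @slot errorRate per-haplotype-allele flip probability.
#' @slot geneCenterBp,markerSpacingBp map geometry.
#' @slot seed RNG seed.
#'
#' @export
setClass("SimConfig",
  representation(nFamilies = "integer", nChildren = "integer",
                 nMarkers = "integer", alleleFreqs = "numeric",
                 backgroundsPerAllele = "integer", minDivergence = "integer",
                 recombRate = "numeric", missingRate = "numeric",
                 errorRate = "numeric", geneCenterBp = "numeric",
                 markerSpacingBp = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (abs(sum(object@alleleFreqs) - 1) > 1e-8)
    return("allele frequencies must sum to 1")
  if (is.null(names(object@alleleFreqs)))
    return("allele frequencies must be named by allele")
  if (object@minDivergence > object@nMarkers)
    return("minDivergence not achievable with this marker count")
  if (any(c(object@recombRate, object@missingRate, object@errorRate) < 0) ||
      any(c(object@recombRate, object@missingRate, object@errorRate) > 1))
    return("rates must lie in [0, 1]")
  TRUE
})

#' @param nFamilies,nChildren,nMarkers,alleleFreqs,backgroundsPerAllele
#'   see the class slots.
#' @param minDivergence,recombRate,missingRate,errorRate,geneCenterBp
#'   see the class slots.
#' @param markerSpacingBp,seed see the class slots.
#' @return A `SimConfig` object.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nFamilies = 20L, nChildren = 3L, nMarkers = 50L,
                      alleleFreqs = NULL, backgroundsPerAllele = 1L,
                      minDivergence = NULL, recombRate = 0,
                      missingRate = 0, errorRate = 0,
                      geneCenterBp = 31500000, markerSpacingBp = 4000,
                      seed = 1L) {
  if (is.null(alleleFreqs)) {
    alleles <- c("0101", "0201", "0301", "2401", "2601", "3201")
    alleleFreqs <- stats::setNames(rep(1 / 6, 6), alleles)
  }
  if (is.null(minDivergence))
    minDivergence <- max(1L, as.integer(round(0.3 * nMarkers)))
  new("SimConfig", nFamilies = as.integer(nFamilies),
      nChildren = as.integer(nChildren), nMarkers = as.integer(nMarkers),
      alleleFreqs = alleleFreqs,
      backgroundsPerAllele = as.integer(backgroundsPerAllele),
      minDivergence = as.integer(minDivergence), recombRate = recombRate,
      missingRate = missingRate, errorRate = errorRate,
      geneCenterBp = geneCenterBp, markerSpacingBp = markerSpacingBp,
      seed = as.integer(seed))
}
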