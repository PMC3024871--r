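# Accessor generics, methods and show methods.

#' @rdname HlaPopulation-class
#' @param object an object.
#' @export
setGeneric("pedigree", function(object) standardGeneric("pedigree"))
#' @rdname HlaPopulation-class
#' @export
setMethod("pedigree", "HlaPopulation", function(object) object@pedigree)

#' @rdname HlaPopulation-class
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname HlaPopulation-class
#' @export
setMethod("genotypes", "HlaPopulation", function(object) object@genotypes)

#' @rdname HlaPopulation-class
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))
#' @rdname HlaPopulation-class
#' @export
setMethod("markerMap", "HlaPopulation", function(object) object@map)

#' @rdname HlaPopulation-class
#' @export
setGeneric("hlaTable", function(object) standardGeneric("hlaTable"))
#' @rdname HlaPopulation-class
#' @export
setMethod("hlaTable", "HlaPopulation", function(object) object@hla)

setMethod("show", "HlaPopulation", function(object) {
  ped <- object@pedigree
  typed <- sum(!is.na(object@hla$allele1))
  cat(sprintf("HlaPopulation: %d individuals in %d pedigrees, %d markers, %d HLA-typed\n",
              nrow(ped), length(unique(ped$family)),
              ncol(object@genotypes), typed))
})

#' @rdname SolutionSpace-class
#' @param object an object.
#' @export
setGeneric("nFreeVars", function(object) standardGeneric("nFreeVars"))
#' @rdname SolutionSpace-class
#' @export
setMethod("nFreeVars", "SolutionSpace", function(object) object@f)

#' @rdname SolutionSpace-class
#' @export
setGeneric("nSolutions", function(object) standardGeneric("nSolutions"))
#' @rdname SolutionSpace-class
#' @export
setMethod("nSolutions", "SolutionSpace", function(object) 2 ^ object@f)

setMethod("show", "SolutionSpace", function(object) {
  cat(sprintf("SolutionSpace: family %s, %d individuals, %d markers, f = %d (%s solutions)%s\n",
              object@family, length(object@individuals), object@m, object@f,
              format(2 ^ object@f, big.mark = ","),
              if (object@segmented)
                sprintf(", stitched from %d segments", length(object@segments))
              else ""))
})

#' @rdname SimilarityGraph-class
#' @param object an object.
#' @export
setGeneric("vertexTable", function(object) standardGeneric("vertexTable"))
#' @rdname SimilarityGraph-class
#' @export
setMethod("vertexTable", "SimilarityGraph", function(object) object@vertices)

#' @rdname SimilarityGraph-class
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))
#' @rdname SimilarityGraph-class
#' @export
setMethod("edgeWeights", "SimilarityGraph", function(object) object@weights)

#' @rdname SimilarityGraph-class
#' @export
setGeneric("constraintTable",
           function(object) standardGeneric("constraintTable"))
#' @rdname SimilarityGraph-class
#' @export
setMethod("constraintTable", "SimilarityGraph",
          function(object) object@constraints)

#' @rdname SimilarityGraph-class
#' @export
setGeneric("alleleUniverse", function(object) standardGeneric("alleleUniverse"))
#' @rdname SimilarityGraph-class
#' @export
setMethod("alleleUniverse", "SimilarityGraph", function(object) object@alleles)

#' Similarity edges retained after sparsification
#'
#' @param object a [SimilarityGraph-class].
#' @return data.frame with columns `p`, `q`, `w` (one row per unordered
#'   vertex pair with weight at or above the graph's `minWeight`).
#' @export
setGeneric("similarityEdges", function(object) standardGeneric("similarityEdges"))
#' @rdname similarityEdges
#' @export
setMethod("similarityEdges", "SimilarityGraph", function(object) {
  W <- object@weights
  n <- nrow(W)
  if (n < 2L) return(data.frame(p = integer(0), q = integer(0), w = numeric(0)))
  idx <- which(upper.tri(W) & W >= object@minWeight, arr.ind = TRUE)
  out <- data.frame(p = idx[, 1L], q = idx[, 2L], w = W[idx])
  out[order(out$p, out$q), , drop = FALSE]
})

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf("SimilarityGraph: %d vertices (%d individuals), %d constraint edges (%d het), %d alleles\n",
              nrow(object@vertices), length(unique(object@vertices$id)),
              nrow(object@constraints), sum(!object@constraints$hom),
              length(object@alleles)))
  if (object@minWeight > 0)
    cat(sprintf("  sparsified at w >= %.2f\n", object@minWeight))
})

#' @rdname HLACallSet-class
#' @param object an object.
#' @export
setGeneric("callTable", function(object) standardGeneric("callTable"))
#' @rdname HLACallSet-class
#' @export
setMethod("callTable", "HLACallSet", function(object) object@calls)

#' @rdname HLACallSet-class
#' @export
setGeneric("runLog", function(object) standardGeneric("runLog"))
#' @rdname HLACallSet-class
#' @export
setMethod("runLog", "HLACallSet", function(object) object@log)

setMethod("show", "HLACallSet", function(object) {
  st <- table(factor(object@calls$status,
                     levels = c("known", "called", "nocall")))
  cat(sprintf("HLACallSet: %d individuals (%d known, %d called, %d no-call)\n",
              nrow(object@calls), st[["known"]], st[["called"]],
              st[["nocall"]]))
})

#' @rdname EvalMetrics-class
#' @param object an object.
#' @export
setGeneric("coverage", function(object) standardGeneric("coverage"))
#' @rdname EvalMetrics-class
#' @export
setMethod("coverage", "EvalMetrics", function(object) object@coverage)

#' @rdname EvalMetrics-class
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname EvalMetrics-class
#' @export
setMethod("accuracy", "EvalMetrics", function(object) object@accuracy)

setMethod("show", "EvalMetrics", function(object) {
  cat(sprintf("EvalMetrics (%d-digit): analyzed %d, called %d, correct %d\n",
              object@resolution, object@nAnalyzed, object@nCalled,
              object@nCorrect))
  cat(sprintf("  coverage %.1f%%, accuracy %s\n", object@coverage,
              if (is.na(object@accuracy)) "n/a"
              else sprintf("%.1f%%", object@accuracy)))
})
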