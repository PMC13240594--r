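#' Accessors for core classes
#'
#' \code{pixels} returns the intensity matrix of a micrograph;
#' \code{maskValues} the matrix of a segmentation mask; \code{particles} the
#' coordinate data.frame of a \linkS4class{ParticleSet}; \code{nParticles}
#' its row count; \code{referenceShape} and \code{provenance} the
#' corresponding slots; \code{regionStats} the per-region statistics of a
#' \linkS4class{LabeledRegions}; \code{regionLabels} its label matrix.
#'
#' @param x object.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Micrograph", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))
#' @rdname accessors
#' @export
setMethod("maskValues", "SegmentationMask", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("maskKind", function(x) standardGeneric("maskKind"))
#' @rdname accessors
#' @export
setMethod("maskKind", "SegmentationMask", function(x) x@kind)

#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' @rdname accessors
#' @export
setMethod("particles", "ParticleSet", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setMethod("nParticles", "ParticleSet", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setGeneric("referenceShape", function(x) standardGeneric("referenceShape"))
#' @rdname accessors
#' @export
setMethod("referenceShape", "ParticleSet", function(x) x@referenceShape)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ParticleSet", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("regionStats", function(x) standardGeneric("regionStats"))
#' @rdname accessors
#' @export
setMethod("regionStats", "LabeledRegions", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setMethod("regionLabels", "LabeledRegions", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("matchCounts", function(x) standardGeneric("matchCounts"))
#' @rdname accessors
#' @export
setMethod("matchCounts", "MatchResult",
          function(x) c(tp = x@tp, fp = x@fp, fn = x@fn))

#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))
#' @rdname accessors
#' @export
setMethod("matchedPairs", "MatchResult", function(x) x@pairs)

setMethod("show", "Micrograph", function(object) {
  cat(sprintf("Micrograph %d x %d px", nrow(object@pixels),
              ncol(object@pixels)))
  if (!is.na(object@pixelSize))
    cat(sprintf(", %.3f A/px", object@pixelSize))
  cat(sprintf(", intensity [%.3g, %.3g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "SegmentationMask", function(object) {
  cat(sprintf("SegmentationMask (%s) %d x %d px, foreground %.1f%%\n",
              object@kind, nrow(object@values), ncol(object@values),
              100 * mean(object@values > 0.5)))
})

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf("ParticleSet (%s): %d particle(s)", object@provenance,
              nrow(object@coords)))
  if (!any(is.na(object@referenceShape)))
    cat(sprintf(" on a %d x %d image", object@referenceShape[1],
                object@referenceShape[2]))
  cat("\n")
  if (nrow(object@coords)) print(utils::head(object@coords, 5))
})

setMethod("show", "FewShotDataset", function(object) {
  cat(sprintf("FewShotDataset: K = %d annotated micrograph(s)\n", object@K))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: TP %d, FP %d, FN %d (radius %.2f px)\n",
              object@tp, object@fp, object@fn, object@matchRadius))
})

setMethod("show", "LabeledRegions", function(object) {
  cat(sprintf("LabeledRegions: %d region(s) on %d x %d px\n",
              nrow(object@stats), nrow(object@labels), ncol(object@labels)))
})
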