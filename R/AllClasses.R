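#' @import methods
#' @importFrom stats median rnorm runif sd pnorm dnorm fft shapiro.test
#' @importFrom utils modifyList
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Micrograph: a single 2D cryo-EM image
#'
#' A real-valued 2D image with an optional pixel size in Angstrom per pixel.
#' Pixels are stored as a numeric matrix indexed \code{[row, column]}; the
#' package-wide coordinate convention is 0-based pixel centers with
#' \code{x = column - 1}, \code{y = row - 1} and the origin at the top-left
#' pixel.
#'
#' @slot pixels numeric matrix of intensities (arbitrary units), all finite.
#' @slot pixelSize numeric(1) Angstrom/pixel, or \code{NA_real_} when unknown.
#' @slot sourcePath character(1) path the image was read from, or \code{NA}.
#'
#' @exportClass Micrograph
setClass("Micrograph",
  representation(pixels = "matrix", pixelSize = "numeric",
                 sourcePath = "character"),
  prototype(pixelSize = NA_real_, sourcePath = NA_character_))

setValidity("Micrograph", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 16L || ncol(p) < 16L)
    return("micrograph must be at least 16 x 16 pixels")
  if (any(!is.finite(p))) return("pixels contain non-finite values")
  if (length(object@pixelSize) != 1L) return("pixelSize must be length 1")
  TRUE
})

#' Construct a Micrograph
#'
#' Non-finite pixels (NaN/Inf, e.g. from detector defects) are replaced by
#' the image median with a warning, so that downstream FFT filtering and
#' normalization always see finite values.
#'
#' @param pixels numeric matrix.
#' @param pixelSize optional Angstrom/pixel.
#' @param sourcePath optional origin path.
#' @return A \linkS4class{Micrograph}.
#' @examples
#' m <- Micrograph(matrix(rnorm(32 * 32), 32))
#' dim(pixels(m))
#' @export
Micrograph <- function(pixels, pixelSize = NA_real_,
                       sourcePath = NA_character_) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  bad <- !is.finite(pixels)
  if (any(bad)) {
    warning(sum(bad), " non-finite pixel(s) replaced by the image median")
    pixels[bad] <- stats::median(pixels[!bad])
  }
  new("Micrograph", pixels = pixels, pixelSize = as.numeric(pixelSize)[1],
      sourcePath = as.character(sourcePath)[1])
}

#' SegmentationMask: probability or binary map aligned to a micrograph
#'
#' @slot values numeric matrix; in [0,1] for kind "probability", in {0,1}
#'   for kind "binary".
#' @slot kind character(1), "probability" or "binary".
#' @exportClass SegmentationMask
setClass("SegmentationMask",
  representation(values = "matrix", kind = "character"))

setValidity("SegmentationMask", function(object) {
  v <- object@values
  if (!object@kind %in% c("probability", "binary"))
    return("kind must be 'probability' or 'binary'")
  if (any(!is.finite(v))) return("mask values must be finite")
  if (object@kind == "probability" && (min(v) < 0 || max(v) > 1))
    return("probability mask values must lie in [0, 1]")
  if (object@kind == "binary" && !all(v %in% c(0, 1)))
    return("binary mask values must lie in {0, 1}")
  TRUE
})

#' Construct a SegmentationMask
#' @param values numeric matrix.
#' @param kind "probability" or "binary".
#' @return A \linkS4class{SegmentationMask}.
#' @export
SegmentationMask <- function(values, kind = c("probability", "binary")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("SegmentationMask", values = values, kind = kind)
}

#' ParticleSet: picked or ground-truth particle coordinates
#'
#' Coordinates follow the package convention: 0-based pixel centers,
#' \code{x} = column, \code{y} = row, origin at top-left. \code{diameter}
#' is in pixels and may be \code{NA} when unknown (e.g. read from a STAR
#' file that carries no size information); \code{score} in [0,1] may be
#' \code{NA}.
#'
#' @slot coords data.frame with columns x, y, diameter, score.
#' @slot referenceShape integer(2) (height, width) of the reference image;
#'   may be \code{NA} when the set is free-standing.
#' @slot provenance character(1), "ground_truth" or "predicted".
#' @exportClass ParticleSet
setClass("ParticleSet",
  representation(coords = "data.frame", referenceShape = "integer",
                 provenance = "character"))

setValidity("ParticleSet", function(object) {
  cc <- object@coords
  need <- c("x", "y", "diameter", "score")
  if (!all(need %in% names(cc)))
    return("coords must have columns x, y, diameter, score")
  if (!object@provenance %in% c("ground_truth", "predicted"))
    return("provenance must be 'ground_truth' or 'predicted'")
  if (length(object@referenceShape) != 2L)
    return("referenceShape must be length 2")
  if (nrow(cc)) {
    if (any(!is.finite(cc$x)) || any(!is.finite(cc$y)))
      return("particle coordinates must be finite")
    d <- cc$diameter
    if (any(!is.na(d) & d <= 0)) return("diameters must be > 0")
    s <- cc$score
    if (any(!is.na(s) & (s < 0 | s > 1))) return("scores must lie in [0, 1]")
    rs <- object@referenceShape
    if (!any(is.na(rs))) {
      if (any(cc$x < 0 | cc$x >= rs[2]) || any(cc$y < 0 | cc$y >= rs[1]))
        return("particle centers must lie inside the reference shape")
    }
  }
  TRUE
})

#' Construct a ParticleSet
#'
#' @param x,y numeric particle centers (0-based pixels; x = column, y = row).
#' @param diameter numeric particle diameters in pixels (recycled; NA allowed).
#' @param score numeric confidence in [0,1] (recycled; NA allowed).
#' @param referenceShape integer(2) (height, width) or NA.
#' @param provenance "predicted" or "ground_truth".
#' @return A \linkS4class{ParticleSet}.
#' @examples
#' ps <- ParticleSet(x = c(10, 20), y = c(12, 30), diameter = 16,
#'                   referenceShape = c(64, 64))
#' nParticles(ps)
#' @export
ParticleSet <- function(x = numeric(), y = numeric(), diameter = NA_real_,
                        score = NA_real_,
                        referenceShape = c(NA_integer_, NA_integer_),
                        provenance = c("predicted", "ground_truth")) {
  provenance <- match.arg(provenance)
  n <- length(x)
  stopifnot(length(y) == n)
  coords <- data.frame(x = as.numeric(x), y = as.numeric(y),
                       diameter = rep_len(as.numeric(diameter), n),
                       score = rep_len(as.numeric(score), n))
  new("ParticleSet", coords = coords,
      referenceShape = as.integer(referenceShape),
      provenance = provenance)
}

#' FewShotDataset: K annotated micrographs
#'
#' @slot items list of K lists, each with elements \code{micrograph}
#'   (\linkS4class{Micrograph}), \code{mask} (binary
#'   \linkS4class{SegmentationMask}) and \code{particles}
#'   (ground-truth \linkS4class{ParticleSet}).
#' @slot K integer shot count, \code{K == length(items)}.
#' @exportClass FewShotDataset
setClass("FewShotDataset", representation(items = "list", K = "integer"))

setValidity("FewShotDataset", function(object) {
  if (object@K != length(object@items)) return("K must equal length(items)")
  if (object@K < 1L) return("dataset must contain at least one item")
  for (it in object@items) {
    if (!all(c("micrograph", "mask", "particles") %in% names(it)))
      return("each item needs micrograph, mask, particles")
    if (!is(it$micrograph, "Micrograph") ||
        !is(it$mask, "SegmentationMask") ||
        !is(it$particles, "ParticleSet"))
      return("item elements have wrong classes")
    if (it$mask@kind != "binary") return("masks must be binary")
    if (!identical(dim(it$mask@values), dim(it$micrograph@pixels)))
      return("mask shape must equal micrograph shape")
  }
  TRUE
})

#' Construct a FewShotDataset
#' @param items list of triples (see \linkS4class{FewShotDataset}).
#' @return A \linkS4class{FewShotDataset}.
#' @export
FewShotDataset <- function(items) {
  new("FewShotDataset", items = items, K = length(items))
}

#' MatchResult: one-to-one pairing of predicted and ground-truth particles
#'
#' @slot tp,fp,fn non-negative integer counts.
#' @slot pairs data.frame with columns predIndex, gtIndex, distance.
#' @slot matchRadius numeric(1) pairing radius in pixels.
#' @exportClass MatchResult
setClass("MatchResult",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 pairs = "data.frame", matchRadius = "numeric"))

setValidity("MatchResult", function(object) {
  if (object@tp != nrow(object@pairs)) return("tp must equal nrow(pairs)")
  if (object@tp < 0 || object@fp < 0 || object@fn < 0)
    return("counts must be non-negative")
  if (nrow(object@pairs)) {
    if (anyDuplicated(object@pairs$predIndex) ||
        anyDuplicated(object@pairs$gtIndex))
      return("matching must be one-to-one")
    if (any(object@pairs$distance > object@matchRadius + 1e-12))
      return("pair distances must not exceed matchRadius")
  }
  TRUE
})

#' LabeledRegions: labelled instance map with per-region shape statistics
#'
#' @slot labels integer matrix, 0 = background, regions labelled 1..n
#'   contiguously.
#' @slot stats data.frame with one row per region: label, area, perimeter,
#'   x, y (centroid, 0-based), equivDiameter, circularity.
#' @exportClass LabeledRegions
setClass("LabeledRegions",
  representation(labels = "matrix", stats = "data.frame"))

setValidity("LabeledRegions", function(object) {
  n <- nrow(object@stats)
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  if (n && !identical(labs, seq_len(n)))
    return("labels must be contiguous from 1")
  if (!n && length(labs)) return("stats missing for labelled regions")
  if (n && any(object@stats$area <= 0)) return("region areas must be > 0")
  TRUE
})
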