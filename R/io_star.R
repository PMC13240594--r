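# RELION-dialect STAR coordinate files: one `data_` block with a `loop_`
# over _rlnCoordinateX/_rlnCoordinateY (+ _rlnAutopickFigureOfMerit when
# scores are present). Coordinates are written in the package convention:
# 0-based pixel centers, x = column, y = row, origin top-left; the
# convention is recorded in a comment line of every file written.

#' Write particle coordinates to a STAR file
#'
#' @param particleSet a \linkS4class{ParticleSet}; may be empty.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @examples
#' f <- tempfile(fileext = ".star")
#' writeStar(ParticleSet(x = 10, y = 20, diameter = 16), f)
#' readStar(f)
#' @export
writeStar <- function(particleSet, path) {
  stopifnot(is(particleSet, "ParticleSet"))
  cc <- particleSet@coords
  withScores <- nrow(cc) > 0 && all(!is.na(cc$score))
  lines <- c(
    "# Coordinates are 0-based pixel centers: x = column, y = row, origin at the top-left pixel.",
    "",
    "data_particles",
    "",
    "loop_",
    "_rlnCoordinateX #1",
    "_rlnCoordinateY #2")
  if (withScores) lines <- c(lines, "_rlnAutopickFigureOfMerit #3")
  if (nrow(cc)) {
    rows <- if (withScores) {
      sprintf("%.6f %.6f %.6f", cc$x, cc$y, cc$score)
    } else {
      sprintf("%.6f %.6f", cc$x, cc$y)
    }
    lines <- c(lines, rows)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("cannot write STAR file: ", path, call. = FALSE)
  invisible(path)
}

#' Read particle coordinates from a STAR file
#'
#' Parses the first \code{loop_} containing \code{_rlnCoordinateX} and
#' \code{_rlnCoordinateY}; unknown columns are ignored, and
#' \code{_rlnAutopickFigureOfMerit} is mapped to the particle score when in
#' [0,1].
#'
#' @param path file path.
#' @param provenance provenance of the returned set ("predicted" by
#'   default).
#' @param diameter optional diameter (pixels) to assign to all particles;
#'   STAR coordinate files carry no size information.
#' @param referenceShape optional integer(2) (height, width).
#' @return A \linkS4class{ParticleSet}.
#' @export
readStar <- function(path, provenance = c("predicted", "ground_truth"),
                     diameter = NA_real_,
                     referenceShape = c(NA_integer_, NA_integer_)) {
  provenance <- match.arg(provenance)
  if (!file.exists(path))
    stop("cannot read STAR file, no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  iLoop <- which(raw == "loop_")
  if (!length(iLoop))
    stop("format error: no loop_ block in STAR file ", path, call. = FALSE)
  i <- iLoop[1] + 1L
  labels <- character()
  while (i <= length(raw) && startsWith(raw[i], "_")) {
    labels <- c(labels, sub("\\s+#\\d+$", "", raw[i]))
    i <- i + 1L
  }
  xi <- match("_rlnCoordinateX", labels)
  yi <- match("_rlnCoordinateY", labels)
  if (is.na(xi) || is.na(yi))
    stop("format error: STAR file lacks coordinate columns; available: ",
         paste(labels, collapse = ", "), call. = FALSE)
  rows <- character()
  while (i <= length(raw) && !startsWith(raw[i], "data_") &&
         raw[i] != "loop_") {
    rows <- c(rows, raw[i])
    i <- i + 1L
  }
  if (!length(rows))
    return(ParticleSet(referenceShape = referenceShape,
                       provenance = provenance))
  fields <- strsplit(rows, "\\s+")
  getCol <- function(k) vapply(fields, function(f) as.numeric(f[k]), 0)
  x <- getCol(xi)
  y <- getCol(yi)
  si <- match("_rlnAutopickFigureOfMerit", labels)
  score <- if (!is.na(si)) getCol(si) else NA_real_
  if (!all(is.na(score)) && (min(score) < 0 || max(score) > 1))
    score <- NA_real_   # figure of merit on a non-probability scale
  ParticleSet(x = x, y = y, diameter = diameter, score = score,
              referenceShape = referenceShape, provenance = provenance)
}
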