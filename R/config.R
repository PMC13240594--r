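# Run configuration: a nested list mirroring the module-level defaults,
# merged as defaults < YAML file < command-line overrides. Unknown keys
# and type mismatches are rejected by name.

#' Default run configuration
#'
#' Nested sections mirror the module configurations (\code{adapter} follows
#' \code{\link{adapterStackConfig}}, \code{train} follows
#' \code{\link{trainConfig}}, \code{postprocess} follows
#' \code{\link{postprocessConfig}}, \code{synth} follows
#' \code{\link{syntheticSpec}}); \code{encoder} selects and sizes the
#' encoder plug-in (\code{surrogate} is built in; an external checkpoint
#' path may be supplied for a full-scale encoder, never downloaded).
#'
#' @return nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    log_level = "info",
    adapter = list(stage_dims = c(144L, 288L, 576L, 1152L),
                   stage_depths = c(2L, 6L, 36L, 4L),
                   reduction = 32L, fft_cutoff_fraction = 0.25, seed = 1L),
    encoder = list(name = "surrogate",
                   stage_dims = c(16L, 32L, 64L, 128L),
                   stage_depths = c(2L, 2L, 2L, 2L),
                   patch_stride = 2L, seed = 1L, checkpoint = ""),
    train = list(input_size = 1024L, batch_size = 2L,
                 learning_rate = 1e-4, max_epochs = 4000L, seed = 1L,
                 pos_weight_mode = "auto", pos_weight = 1,
                 threshold = 0.5, head_channels = 16L,
                 adapter_reduction = 4L),
    postprocess = list(expected_diameter_px = 16, threshold = 0.5,
                       area_range = c(0.3, 3.0), min_circularity = 0.6,
                       peak_scales = c(1, 2, 4),
                       min_peak_distance_frac = 0.5,
                       min_separation_frac = 0.6, dual_pass = TRUE,
                       drop_border = FALSE),
    evaluate = list(match_radius_frac = 0.5),
    synth = list(image_shape = c(128L, 128L), n_particles = 12L,
                 diameter_px = 16, diameter_jitter = 0, snr = 4,
                 min_separation = 24, allow_overlap = FALSE,
                 n_items = 5L))
}

mergeConfig <- function(base, upd, path = "") {
  for (key in names(upd)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(base[[key]])) {
      if (!is.list(upd[[key]]))
        stop("configuration key ", full, " expects a section",
             call. = FALSE)
      base[[key]] <- mergeConfig(base[[key]], upd[[key]], full)
    } else {
      val <- upd[[key]]
      if (is.numeric(base[[key]])) {
        if (!is.numeric(val))
          stop("configuration key ", full, " expects a numeric value",
               call. = FALSE)
        val <- if (is.integer(base[[key]]) &&
                   all(val == round(val))) as.integer(val)
               else as.numeric(val)
      } else if (is.logical(base[[key]])) {
        if (!is.logical(val))
          stop("configuration key ", full, " expects a logical value",
               call. = FALSE)
      } else {
        val <- as.character(val)
      }
      base[[key]] <- val
    }
  }
  base
}

parseOverride <- function(s) {
  eq <- regexpr("=", s, fixed = TRUE)
  if (eq < 0) stop("override must look like key=value: ", s, call. = FALSE)
  key <- substr(s, 1, eq - 1)
  val <- substr(s, eq + 1, nchar(s))
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  vals <- strsplit(val, ",", fixed = TRUE)[[1]]
  num <- suppressWarnings(as.numeric(vals))
  out <- if (!any(is.na(num))) num
         else if (all(tolower(vals) %in% c("true", "false")))
           tolower(vals) == "true"
         else vals
  node <- out
  for (p in rev(parts)) node <- stats::setNames(list(node), p)
  node
}

#' Load and resolve a run configuration
#'
#' Precedence: package defaults, then the YAML file (when given), then
#' \code{key=value} overrides (dots address nested keys, commas separate
#' vector elements). Unknown keys are rejected with an error naming the
#' key; values must match the type of the default.
#'
#' @param path optional YAML file.
#' @param overrides character vector of \code{section.key=value} strings.
#' @return resolved configuration list (class \code{"RunConfig"}).
#' @examples
#' cfg <- loadConfig(overrides = "train.learning_rate=2e-4")
#' cfg$train$learning_rate
#' @export
loadConfig <- function(path = NULL, overrides = character()) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("configuration file not found: ", path, call. = FALSE)
    fromFile <- yaml::read_yaml(path)
    if (!is.null(fromFile)) cfg <- mergeConfig(cfg, fromFile)
  }
  for (s in overrides) cfg <- mergeConfig(cfg, parseOverride(s))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

logMsg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible(NULL))
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [cryofsl] ", ...)
}
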