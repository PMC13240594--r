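# Hierarchical residual adapter stack: per-block bottleneck adapters with a
# block-specific (unshared) linear layer and a per-stage shared
# up-projection, fed by a projected copy of the block input features plus a
# projected high-pass FFT stream of the micrograph. The adapter output is
# added to the block input (residual injection) so that zero-initialized
# up-projections leave the frozen encoder's behavior untouched.

#' Adapter stack configuration
#'
#' Defaults mirror the four-stage hierarchical encoder this design targets:
#' stage embedding widths 144/288/576/1152 with 2/6/36/4 blocks (hence
#' adapters) per stage and a 1/32 bottleneck. The stage-1 bottleneck
#' 144/32 = 4.5 is floored to 4; a floor of 1 is enforced only when
#' \code{clampBottleneck} is set at build time.
#'
#' @param stageDims integer vector of per-stage embedding widths D_i.
#' @param stageDepths integer vector of blocks per stage.
#' @param reduction bottleneck divisor; bottleneck width d_i =
#'   floor(D_i / reduction).
#' @param fftCutoffFraction high-pass cutoff for the FFT stream, fraction
#'   of Nyquist.
#' @param seed integer seed for the small-random initialization.
#' @return A validated list of class \code{"AdapterStackConfig"}.
#' @examples
#' cfg <- adapterStackConfig()
#' bottleneckDims(cfg)
#' @export
adapterStackConfig <- function(stageDims = c(144L, 288L, 576L, 1152L),
                               stageDepths = c(2L, 6L, 36L, 4L),
                               reduction = 32L,
                               fftCutoffFraction = 0.25,
                               seed = 1L) {
  cfg <- list(stageDims = as.integer(stageDims),
              stageDepths = as.integer(stageDepths),
              reduction = as.integer(reduction),
              fftCutoffFraction = as.numeric(fftCutoffFraction),
              seed = as.integer(seed))
  if (length(cfg$stageDims) != length(cfg$stageDepths))
    stop("stageDims and stageDepths must have equal length", call. = FALSE)
  if (any(cfg$stageDims <= 0L) || any(cfg$stageDepths <= 0L))
    stop("stage dims and depths must be positive", call. = FALSE)
  if (cfg$reduction < 1L) stop("reduction must be >= 1", call. = FALSE)
  if (cfg$fftCutoffFraction <= 0 || cfg$fftCutoffFraction >= 1)
    stop("fftCutoffFraction must lie in (0, 1)", call. = FALSE)
  class(cfg) <- "AdapterStackConfig"
  cfg
}

#' Bottleneck widths of an adapter configuration
#' @param config an \code{\link{adapterStackConfig}}.
#' @param clampBottleneck clamp widths below 1 up to 1 instead of erroring.
#' @return integer vector d_i = floor(D_i / reduction).
#' @export
bottleneckDims <- function(config, clampBottleneck = FALSE) {
  d <- config$stageDims %/% config$reduction
  if (any(d < 1L)) {
    if (!clampBottleneck)
      stop("reduction ", config$reduction, " exceeds stage dim(s) ",
           paste(config$stageDims[d < 1L], collapse = ", "),
           "; bottleneck would be 0 (set clampBottleneck to force 1)",
           call. = FALSE)
    d <- pmax(d, 1L)
  }
  d
}

#' Allocate an adapter stack
#'
#' Per stage i: one embedding down-projection (D_i x d_i), one FFT-stream
#' projection (1 x d_i), one shared up-projection (d_i x D_i,
#' zero-initialized including its bias, so the stack is an exact identity
#' at initialization) — plus, per block j, one unshared d_i x d_i linear
#' layer. All layers carry biases. With the default configuration this
#' allocates 2 + 6 + 36 + 4 = 48 unshared layers and 4 shared
#' up-projections.
#'
#' @param config an \code{\link{adapterStackConfig}}.
#' @param clampBottleneck see \code{\link{bottleneckDims}}.
#' @return An object of class \code{"AdapterParams"}: a per-stage nested
#'   list of weight matrices.
#' @export
buildAdapterStack <- function(config, clampBottleneck = FALSE) {
  stopifnot(inherits(config, "AdapterStackConfig"))
  d <- bottleneckDims(config, clampBottleneck)
  D <- config$stageDims
  stages <- withSeed(config$seed, {
    lapply(seq_along(D), function(i) {
      list(
        E = matrix(rnorm(D[i] * d[i], sd = 0.02), D[i], d[i]),
        bE = numeric(d[i]),
        wF = rnorm(d[i], sd = 0.02),
        bF = numeric(d[i]),
        S = matrix(0, d[i], D[i]),
        bS = numeric(D[i]),
        blocks = lapply(seq_len(config$stageDepths[i]), function(j) {
          list(U = matrix(rnorm(d[i] * d[i], sd = 0.02), d[i], d[i]),
               bU = numeric(d[i]))
        }))
    })
  })
  structure(list(stages = stages, config = config, bottleneck = d),
            class = "AdapterParams")
}

#' @export
print.AdapterParams <- function(x, ...) {
  cat(sprintf(
    "AdapterParams: %d stage(s), %d unshared layer(s), %d trainable values\n",
    length(x$stages), sum(x$config$stageDepths), countNested(x$stages)))
  invisible(x)
}

#' One adapter application (residual feature modulation)
#'
#' Computes \code{feat + upShared(GELU(unshared(projEmb(feat) +
#' projFFT(stream))))} for block \code{block} of stage \code{stage}. The
#' feature map is given in token form, an \code{N x D_i} matrix whose rows
#' are spatial positions in column-major order; the FFT stream is the
#' matching length-\code{N} vector. A pure function of its inputs: the
#' output has the shape of \code{feat}.
#'
#' @param feat numeric \code{N x D_i} matrix of block-input features.
#' @param fftStream numeric vector of length \code{N} (per-stage high-pass
#'   stream values).
#' @param adapters an \code{"AdapterParams"} object.
#' @param stage,block 1-based stage and block indices.
#' @return The modulated \code{N x D_i} feature matrix.
#' @export
adapterForward <- function(feat, fftStream, adapters, stage, block) {
  stopifnot(inherits(adapters, "AdapterParams"))
  if (stage < 1L || stage > length(adapters$stages))
    contractError("stage index ", stage, " out of range")
  st <- adapters$stages[[stage]]
  if (block < 1L || block > length(st$blocks))
    contractError("block index ", block, " out of range in stage ", stage)
  if (ncol(feat) != nrow(st$E))
    contractError("feature width ", ncol(feat), " does not match stage ",
                  stage, " embedding dim ", nrow(st$E))
  if (length(fftStream) != nrow(feat))
    contractError("fft stream length ", length(fftStream),
                  " does not match token count ", nrow(feat))
  bl <- st$blocks[[block]]
  u <- feat %*% st$E + outer(as.numeric(fftStream), st$wF)
  u <- sweep(u, 2, st$bE + st$bF, "+")
  v <- sweep(u %*% bl$U, 2, bl$bU, "+")
  feat + sweep(gelu(v) %*% st$S, 2, st$bS, "+")
}

#' Count trainable parameters
#'
#' Counts the numeric values in trainable components (adapter stack and/or
#' decoder head). Frozen encoder parameters are excluded by construction:
#' an encoder is never part of the trainable set.
#'
#' @param x an \code{"AdapterParams"}, a decoder head, a trained model, or
#'   a plain nested list of numeric arrays.
#' @return integer count.
#' @export
countTrainableParams <- function(x) {
  if (inherits(x, "cryofslModel"))
    return(countNested(x$adapters$stages) + countNested(x$head$params))
  if (inherits(x, "AdapterParams")) return(countNested(x$stages))
  if (inherits(x, "DecoderHead")) return(countNested(x$params))
  if (inherits(x, "SurrogateEncoder")) return(0L)  # frozen
  if (is.list(x)) return(countNested(x))
  length(x)
}
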