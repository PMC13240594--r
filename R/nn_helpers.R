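# Nested-list parameter utilities and the Adam optimizer used to train
# adapter stacks and decoder heads. Parameters are nested lists whose
# leaves are numeric vectors/matrices; gradients mirror the structure.

mapNested <- function(f, ...) {
  xs <- list(...)
  a <- xs[[1]]
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a))
      out[[k]] <- do.call(mapNested, c(list(f), lapply(xs, `[[`, k)))
    out
  } else {
    do.call(f, xs)
  }
}

zeroLike <- function(params) mapNested(function(x) x * 0, params)

addNested <- function(a, b) mapNested(`+`, a, b)

scaleNested <- function(a, s) mapNested(function(x) x * s, a)

countNested <- function(params) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(params)
  n
}

adamInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapNested(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- mapNested(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- mapNested(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
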