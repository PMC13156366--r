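# Internal numeric and validation helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_binary <- function(x, what = "input") {
  if (!all(x %in% c(0, 1))) stopf("%s must contain only 0/1 values", what)
  invisible(TRUE)
}

# Deterministic sub-stream seed: every source of randomness (latents, noise,
# censoring, missingness, splits, minibatches, parameter init) draws from its
# own named stream derived from one master seed, so components can be re-run
# in isolation without perturbing each other.
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2039
  as.integer((as.numeric(seed) * 2063 + h * 97 + 17) %% 2147483629)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigen method.
gauss_legendre <- function(order) {
  stopifnot(order >= 1)
  if (order == 1) return(list(nodes = 0, weights = 2))
  k <- seq_len(order - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, order, order)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1, idx]^2)
}

# Trapezoid rule on an increasing grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Evaluate a right-continuous step function (times must be sorted unique jump
# points, values the post-jump levels, start the level before the first jump).
# left = TRUE gives the left limit G(t-).
step_eval <- function(times, values, t, start = 1, left = FALSE) {
  idx <- if (left) {
    findInterval(t, times, left.open = TRUE)
  } else {
    findInterval(t, times)
  }
  c(start, values)[idx + 1]
}
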