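# Minimal dense-network machinery: explicit forward/backward passes over
# matrices plus Adam. Kept deliberately small — everything the model needs and
# nothing more — so gradients can be verified against finite differences.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable log(1 + exp(x)).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' @noRd
mlp_init <- function(sizes, seed = 1, stream = "mlp", zero_last = FALSE) {
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  with_stream(seed, stream, {
    for (l in seq_len(L)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1]))   # Glorot uniform
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
  })
  if (zero_last) W[[L]][] <- 0
  structure(list(W = W, b = b, sizes = sizes), class = "mlp")
}

# Hidden layers use tanh; the output layer is linear (heads apply their own
# link). Returns the output and the activation cache needed for backward.
mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
    A[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  list(out = A[[L + 1]], A = A)
}

# dOut: gradient of the scalar loss wrt the network output.
# Returns parameter gradients (same shapes as net$W/net$b) and dX.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  for (l in L:1) {
    dW[[l]] <- crossprod(cache$A[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - cache$A[[l]]^2)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(W = dW, b = db, dX = delta)
}

# ---- flat parameter plumbing -------------------------------------------------
# Models are named lists of mlp objects; parameters travel as one flat list of
# arrays so the optimiser is agnostic to architecture.

collect_params <- function(nets) {
  out <- list()
  for (nm in names(nets)) {
    net <- nets[[nm]]
    for (l in seq_along(net$W)) {
      out[[paste0(nm, ".W", l)]] <- net$W[[l]]
      out[[paste0(nm, ".b", l)]] <- net$b[[l]]
    }
  }
  out
}

set_params <- function(nets, params) {
  for (nm in names(nets)) {
    for (l in seq_along(nets[[nm]]$W)) {
      nets[[nm]]$W[[l]] <- params[[paste0(nm, ".W", l)]]
      nets[[nm]]$b[[l]] <- params[[paste0(nm, ".b", l)]]
    }
  }
  nets
}

grads_to_flat <- function(grad_list) {
  out <- list()
  for (nm in names(grad_list)) {
    g <- grad_list[[nm]]
    for (l in seq_along(g$W)) {
      out[[paste0(nm, ".W", l)]] <- g$W[[l]]
      out[[paste0(nm, ".b", l)]] <- g$b[[l]]
    }
  }
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
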