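# Monotone neural survival head.
#
# The conditional CDF is parameterised as F(t | z) = tanh( int_0^t g(u, z) du )
# with g = softplus(MLP(u, z)) >= 0, so F is non-decreasing, F(0) = 0 and
# S = 1 - F is a valid survival curve for every input. The integral is
# evaluated by fixed-order Gauss-Legendre quadrature on [0, t]; the density is
# f(t | z) = g(t, z) * (1 - tanh^2(int)). Times are rescaled by the 99th
# training percentile and clipped, so the network always works on [0, ~1.2].
# The same head serves both the latent embeddings of the joint model and the
# completed/encoded feature matrices of the baseline strategies.

survhead_init <- function(input_dim, hidden = c(64, 64), quad_order = 15,
                          seed = 1, stream = "survhead") {
  gl <- gauss_legendre(quad_order)
  structure(
    list(net = mlp_init(c(1 + input_dim, hidden, 1), seed, stream),
         gl = gl, input_dim = input_dim, time_scale = NA_real_,
         time_cap = 1.2),
    class = "survhead"
  )
}

# Rescale raw times by the stored training scale, clipping at the cap.
survhead_rescale <- function(head, t_raw) {
  if (!is.finite(head$time_scale)) stopf("survival head has no time scale; fit first")
  pmin(t_raw / head$time_scale, head$time_cap)
}

# Forward pass: cumulative intensity Lambda_i = int_0^{t_i} g and, optionally,
# g at t_i itself. Keeps every cache needed for the backward pass.
survhead_cumint <- function(head, Z, t_resc) {
  n <- nrow(Z); Q <- length(head$gl$nodes)
  # node s_ik = t_i/2 * (x_k + 1), coefficient c_ik = t_i/2 * w_k
  half_t <- t_resc / 2
  S <- outer(half_t, head$gl$nodes + 1)          # n x Q
  C <- outer(half_t, head$gl$weights)            # n x Q
  In <- cbind(as.vector(S), Z[rep(seq_len(n), Q), , drop = FALSE])
  fw <- mlp_forward(head$net, In)
  pre <- fw$out                                   # (nQ) x 1
  g <- matrix(softplus(pre), n, Q)
  list(Lambda = rowSums(g * C), C = C, fw = fw, pre = pre, n = n, Q = Q)
}

survhead_g_at <- function(head, Z, t_resc) {
  In <- cbind(t_resc, Z)
  fw <- mlp_forward(head$net, In)
  list(g = softplus(fw$out)[, 1], fw = fw, pre = fw$out)
}

# Right-censored negative log-likelihood and its gradients.
#   event:    -log f(t) = -log g(t) - log(1 - u^2),   u = tanh(Lambda)
#   censored: -log S(t) = -log(1 - u)
# d(-log f)/dLambda = 2u ; d(-log S)/dLambda = 1 + u ; d(-log f)/dg(t) = -1/g(t)
survhead_loss_grad <- function(head, Z, t_resc, delta, want_grads = TRUE) {
  n <- nrow(Z)
  ci <- survhead_cumint(head, Z, t_resc)
  u <- tanh(ci$Lambda)
  ga <- survhead_g_at(head, Z, t_resc)
  g_t <- pmax(ga$g, 1e-12)
  loss_i <- delta * (-log(g_t) - log1p(-u^2)) + (1 - delta) * (-log1p(-u))
  loss <- mean(loss_i)
  if (!want_grads) return(list(loss = loss, u = u, g_t = g_t))

  dLambda <- (delta * 2 * u + (1 - delta) * (1 + u)) / n
  dg_mat <- dLambda * ci$C                       # n x Q (recycles by column)
  dpre_q <- as.vector(dg_mat) * sigmoid(ci$pre[, 1])
  bq <- mlp_backward(head$net, ci$fw, matrix(dpre_q, ncol = 1))

  dg_t <- -delta / (g_t * n)
  dpre_t <- dg_t * sigmoid(ga$pre[, 1])
  bt <- mlp_backward(head$net, ga$fw, matrix(dpre_t, ncol = 1))

  gw <- Map(`+`, bq$W, bt$W)
  gb <- Map(`+`, bq$b, bt$b)
  # gradient wrt the head inputs (used when Z are latent embeddings):
  # sum quadrature-node contributions per subject, drop the time column.
  dZ_q <- rowsum(bq$dX[, -1, drop = FALSE], rep(seq_len(n), ci$Q), reorder = TRUE)
  dZ <- dZ_q + bt$dX[, -1, drop = FALSE]
  list(loss = loss, grads = list(W = gw, b = gb), dZ = dZ, u = u, g_t = g_t)
}

# Train the head alone on a fixed feature matrix (the baseline-strategy path).
survhead_fit <- function(Z, time, event, Z_val, time_val, event_val,
                         hidden = c(64, 64), quad_order = 15, lr = 1e-3,
                         batch_size = 256, epochs = 50, patience = 10,
                         seed = 1, verbose = FALSE) {
  head <- survhead_init(ncol(Z), hidden, quad_order, seed)
  head$time_scale <- as.numeric(stats::quantile(time, 0.99))
  t_tr <- survhead_rescale(head, time)
  t_va <- survhead_rescale(head, time_val)
  nets <- list(head = head$net)
  params <- collect_params(nets)
  st <- adam_init(params)
  n <- nrow(Z)
  best <- list(loss = Inf, params = params, epoch = 0)
  history <- data.frame()
  wait <- 0
  for (ep in seq_len(epochs)) {
    ord <- with_stream(seed, paste0("shuffle", ep), sample.int(n))
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      head$net <- set_params(nets, params)$head
      res <- survhead_loss_grad(head, Z[idx, , drop = FALSE], t_tr[idx], event[idx])
      if (!is.finite(res$loss)) stopf("survival head diverged (non-finite loss)")
      up <- adam_step(params, grads_to_flat(list(head = res$grads)), st, lr)
      params <- up$params; st <- up$state
    }
    head$net <- set_params(nets, params)$head
    vl <- survhead_loss_grad(head, Z_val, t_va, event_val, want_grads = FALSE)$loss
    history <- rbind(history, data.frame(epoch = ep, val_loss = vl))
    if (verbose) message(sprintf("epoch %d val %.4f", ep, vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, params = params, epoch = ep); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  head$net <- set_params(nets, best$params)$head
  head$history <- history
  head$best_epoch <- best$epoch
  head
}

# Survival curves (and densities, raw-time scale) on a time grid.
survhead_predict <- function(head, Z, t_grid) {
  if (any(t_grid < 0)) stopf("negative time in grid")
  n <- nrow(Z); G <- length(t_grid)
  t_resc <- survhead_rescale(head, t_grid)
  surv <- matrix(NA_real_, n, G)
  dens <- matrix(NA_real_, n, G)
  for (jj in seq_len(G)) {
    tv <- rep(t_resc[jj], n)
    if (t_resc[jj] == 0) { surv[, jj] <- 1; dens[, jj] <- 0; next }
    u <- tanh(survhead_cumint(head, Z, tv)$Lambda)
    g <- survhead_g_at(head, Z, tv)$g
    surv[, jj] <- 1 - u
    # density wrt raw time; zero beyond the clipped range where F is flat
    live <- t_grid[jj] / head$time_scale < head$time_cap
    dens[, jj] <- if (live) g * (1 - u^2) / head$time_scale else 0
  }
  structure(list(time_grid = t_grid, surv = surv, dens = dens),
            class = "survival_curves")
}

#' @export
print.survival_curves <- function(x, ...) {
  cat(sprintf("survival_curves: %d subjects on %d grid points [%g, %g]\n",
              nrow(x$surv), length(x$time_grid), min(x$time_grid),
              max(x$time_grid)))
  invisible(x)
}
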