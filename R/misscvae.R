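#' MissCVAE model configuration
#'
#' Hyperparameters of the two-tiered VAE-cVAE survival model. The generative
#' story: a mask embedding h_m ~ N(0, I) decodes to Bernoulli missingness
#' indicators; a data embedding h_x ~ N(0, I) decodes, together with h_m, to
#' Gaussian covariates; the survival outcome is generated from the embeddings
#' through a monotone neural head. Training maximises a weighted evidence
#' lower bound: alpha * survival likelihood + beta * reconstruction +
#' gamma * KL regularisation, with the survival term upweighted
#' (`alpha = 10`) and reconstruction/KL downweighted (0.1) to favour
#' prediction and avoid KL vanishing.
#'
#' @param latent_x,latent_m Dimensions of the data and mask embeddings.
#' @param hidden Hidden widths of every encoder/decoder MLP.
#' @param head_hidden Hidden widths of the survival head.
#' @param alpha,beta_x,beta_m,gamma_x,gamma_m ELBO weights (all > 0).
#' @param quad_order Gauss-Legendre order of the survival head integral.
#' @param lr,batch_size,epochs,patience Optimiser settings (Adam, early
#'   stopping on validation total loss, best epoch restored).
#' @param mc_samples Monte-Carlo samples per datum during training.
#' @param include_hm_in_head If `FALSE`, the survival head sees h_x only (the
#'   ablation variant); h_m still conditions the data encoder/decoder.
#' @param var_floor Floor on decoder variances.
#' @return A `misscvae_config` list.
#' @export
misscvae_config <- function(latent_x = 16, latent_m = 8, hidden = c(64, 64),
                            head_hidden = c(64, 64), alpha = 10, beta_x = 0.1,
                            beta_m = 0.1, gamma_x = 0.1, gamma_m = 0.1,
                            quad_order = 15, lr = 1e-3, batch_size = 256,
                            epochs = 100, patience = 10, mc_samples = 1,
                            include_hm_in_head = TRUE, var_floor = 1e-4) {
  w <- c(alpha, beta_x, beta_m, gamma_x, gamma_m)
  if (any(w <= 0)) stopf("ELBO weights must be positive")
  if (latent_x < 1 || latent_m < 1) stopf("latent dimensions must be >= 1")
  structure(as.list(environment()), class = "misscvae_config")
}

misscvae_init <- function(p, config, seed = 1) {
  dx <- config$latent_x; dm <- config$latent_m; h <- config$hidden
  head_in <- if (config$include_hm_in_head) dx + dm else dx
  nets <- list(
    enc_m = mlp_init(c(p, h, 2 * dm), seed, "enc_m"),
    enc_x = mlp_init(c(p + dm, h, 2 * dx), seed, "enc_x"),
    dec_m = mlp_init(c(dm, h, p), seed, "dec_m"),
    dec_x = mlp_init(c(dx + dm, h, 2 * p), seed, "dec_x"),
    head = mlp_init(c(1 + head_in, config$head_hidden, 1), seed, "head")
  )
  structure(list(nets = nets, p = p, config = config,
                 gl = gauss_legendre(config$quad_order),
                 time_scale = NA_real_, standardiser = NULL),
            class = "misscvae")
}

#' @export
print.misscvae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("misscvae: p = %d, h_x dim %d, h_m dim %d%s\n", x$p,
              cfg$latent_x, cfg$latent_m,
              if (cfg$include_hm_in_head) "" else " (h_x-only head)"))
  cat(sprintf("  ELBO weights: alpha %g, beta (%g, %g), gamma (%g, %g)\n",
              cfg$alpha, cfg$beta_m, cfg$beta_x, cfg$gamma_m, cfg$gamma_x))
  invisible(x)
}

head_view <- function(model) {
  structure(list(net = model$nets$head, gl = model$gl,
                 time_scale = model$time_scale, time_cap = 1.2),
            class = "survhead")
}

#' Encode a missingness pattern
#'
#' Deterministic encoder pass m -> q(h_m | m), a diagonal Gaussian.
#'
#' @param model A fitted or initialised `misscvae`.
#' @param mask n x p binary matrix (or p-vector), 1 = observed.
#' @return List `mean`, `logvar` (n x latent_m matrices).
#' @export
encode_mask <- function(model, mask) {
  if (is.vector(mask)) mask <- matrix(mask, nrow = 1)
  check_binary(mask, "mask")
  if (ncol(mask) != model$p) stopf("mask has %d columns, expected %d",
                                   ncol(mask), model$p)
  out <- mlp_forward(model$nets$enc_m, mask)$out
  dm <- model$config$latent_m
  list(mean = out[, 1:dm, drop = FALSE],
       logvar = out[, dm + 1:dm, drop = FALSE])
}

#' Encode filled covariates conditional on a mask embedding
#'
#' @param model A `misscvae`.
#' @param x_filled Standardised covariates with missing entries zero-filled
#'   (the zero fill equals the observed-training mean); must contain no NA.
#' @param h_m Mask-embedding sample or posterior mean, n x latent_m.
#' @return List `mean`, `logvar` (n x latent_x).
#' @export
encode_data <- function(model, x_filled, h_m) {
  if (is.vector(x_filled)) x_filled <- matrix(x_filled, nrow = 1)
  if (is.vector(h_m)) h_m <- matrix(h_m, nrow = 1)
  if (anyNA(x_filled)) stopf("x_filled must not contain NA; apply the fill convention")
  out <- mlp_forward(model$nets$enc_x, cbind(x_filled, h_m))$out
  dx <- model$config$latent_x
  list(mean = out[, 1:dx, drop = FALSE],
       logvar = out[, dx + 1:dx, drop = FALSE])
}

#' Decode latent embeddings
#'
#' The mask decoder consumes h_m only; the data decoder consumes both
#' embeddings and returns per-column Gaussian parameters with a floored
#' variance.
#'
#' @param model A `misscvae`.
#' @param h_x,h_m Latent matrices.
#' @return List `mask_prob` (Bernoulli probabilities in (0,1)), `x_mean`,
#'   `x_var` (>= configured floor).
#' @export
decode <- function(model, h_x, h_m) {
  if (is.vector(h_x)) h_x <- matrix(h_x, nrow = 1)
  if (is.vector(h_m)) h_m <- matrix(h_m, nrow = 1)
  p <- model$p
  logits <- mlp_forward(model$nets$dec_m, h_m)$out
  dec <- mlp_forward(model$nets$dec_x, cbind(h_x, h_m))$out
  list(mask_prob = sigmoid(logits),
       x_mean = dec[, 1:p, drop = FALSE],
       x_var = pmax(exp(dec[, p + 1:p, drop = FALSE]), model$config$var_floor))
}

#' Survival curve from latent embeddings
#'
#' S(t) = 1 - tanh(int_0^t g(u, h) du) with g a non-negative network output;
#' the ablation configuration drops h_m from the head input.
#'
#' @param model A fitted `misscvae` (needs a time scale).
#' @param h_x,h_m Latent matrices.
#' @param t_grid Non-negative increasing raw-time grid.
#' @return A `survival_curves` object (survival and density matrices).
#' @export
survival_curve <- function(model, h_x, h_m, t_grid) {
  if (is.vector(h_x)) h_x <- matrix(h_x, nrow = 1)
  if (is.vector(h_m)) h_m <- matrix(h_m, nrow = 1)
  Hin <- if (model$config$include_hm_in_head) cbind(h_x, h_m) else h_x
  survhead_predict(head_view(model), Hin, t_grid)
}

# Fill convention: zeros at missing entries of the standardised matrix.
zero_fill <- function(ds_std) {
  x <- ds_std$x_tilde
  x[is.na(x)] <- 0
  x
}

#' Weighted ELBO of a batch
#'
#' One reparameterised sample of h_m, then of h_x conditioned on it. The
#' survival term is the right-censored negative log-likelihood (density at
#' event times, survival at censoring times); data reconstruction is Gaussian
#' negative log-likelihood over observed entries only; mask reconstruction is
#' Bernoulli over all p indicators; KL terms are the analytic diagonal
#' Gaussian vs standard normal, 0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2).
#' All components are batch means.
#'
#' @param model A `misscvae` with a time scale set.
#' @param x_filled,mask Standardised zero-filled covariates and mask.
#' @param time,event Raw times and event indicators.
#' @param eps_m,eps_x Optional fixed standard-normal draws (for gradient
#'   checking); drawn internally when `NULL`.
#' @param want_grads Compute parameter gradients.
#' @param seed Seed for the internal eps draws.
#' @return List with the `loss_breakdown` (survival, recon_x, recon_m, kl_x,
#'   kl_m, total) and, if requested, `grads`.
#' @export
misscvae_elbo <- function(model, x_filled, mask, time, event, eps_m = NULL,
                          eps_x = NULL, want_grads = FALSE, seed = 1) {
  cfg <- model$config
  n <- nrow(x_filled); p <- model$p
  dm <- cfg$latent_m; dx <- cfg$latent_x
  if (anyNA(x_filled)) stopf("x_filled contains NA")
  if (is.null(eps_m)) eps_m <- with_stream(seed, "eps_m", matrix(stats::rnorm(n * dm), n, dm))
  if (is.null(eps_x)) eps_x <- with_stream(seed, "eps_x", matrix(stats::rnorm(n * dx), n, dx))

  fw_em <- mlp_forward(model$nets$enc_m, mask)
  mu_m <- fw_em$out[, 1:dm, drop = FALSE]
  lv_m <- fw_em$out[, dm + 1:dm, drop = FALSE]
  sd_m <- exp(0.5 * lv_m)
  h_m <- mu_m + sd_m * eps_m

  fw_ex <- mlp_forward(model$nets$enc_x, cbind(x_filled, h_m))
  mu_x <- fw_ex$out[, 1:dx, drop = FALSE]
  lv_x <- fw_ex$out[, dx + 1:dx, drop = FALSE]
  sd_x <- exp(0.5 * lv_x)
  h_x <- mu_x + sd_x * eps_x

  fw_dm <- mlp_forward(model$nets$dec_m, h_m)
  logits <- fw_dm$out
  recon_m <- sum(softplus(logits) - mask * logits) / n

  fw_dx <- mlp_forward(model$nets$dec_x, cbind(h_x, h_m))
  mu_d <- fw_dx$out[, 1:p, drop = FALSE]
  lv_d_raw <- fw_dx$out[, p + 1:p, drop = FALSE]
  lv_floor <- log(cfg$var_floor)
  lv_d <- pmax(lv_d_raw, lv_floor)
  resid <- x_filled - mu_d
  recon_x <- sum(mask * 0.5 * (log(2 * pi) + lv_d + resid^2 / exp(lv_d))) / n

  kl_x <- 0.5 * sum(mu_x^2 + exp(lv_x) - 1 - lv_x) / n
  kl_m <- 0.5 * sum(mu_m^2 + exp(lv_m) - 1 - lv_m) / n

  Hin <- if (cfg$include_hm_in_head) cbind(h_x, h_m) else h_x
  hv <- head_view(model)
  t_resc <- survhead_rescale(hv, time)
  sh <- survhead_loss_grad(hv, Hin, t_resc, event, want_grads = want_grads)

  breakdown <- list(survival = sh$loss, recon_x = recon_x, recon_m = recon_m,
                    kl_x = kl_x, kl_m = kl_m)
  breakdown$total <- cfg$alpha * sh$loss + cfg$beta_x * recon_x +
    cfg$beta_m * recon_m + cfg$gamma_x * kl_x + cfg$gamma_m * kl_m
  if (!all(is.finite(unlist(breakdown)))) {
    bad <- names(breakdown)[!vapply(breakdown, is.finite, TRUE)]
    stopf("non-finite loss component(s): %s", paste(bad, collapse = ", "))
  }
  if (!want_grads) return(list(loss_breakdown = breakdown))

  # ---- backward ----
  dHin <- cfg$alpha * sh$dZ
  dh_x <- dHin[, 1:dx, drop = FALSE]
  dh_m <- if (cfg$include_hm_in_head) dHin[, dx + 1:dm, drop = FALSE] else
    matrix(0, n, dm)

  # data decoder
  dmu_d <- -cfg$beta_x * mask * resid / exp(lv_d) / n
  dlv_d <- cfg$beta_x * mask * 0.5 * (1 - resid^2 / exp(lv_d)) / n
  dlv_d <- dlv_d * (lv_d_raw > lv_floor)
  b_dx <- mlp_backward(model$nets$dec_x, fw_dx, cbind(dmu_d, dlv_d))
  dh_x <- dh_x + b_dx$dX[, 1:dx, drop = FALSE]
  dh_m <- dh_m + b_dx$dX[, dx + 1:dm, drop = FALSE]

  # mask decoder
  dlogits <- cfg$beta_m * (sigmoid(logits) - mask) / n
  b_dm <- mlp_backward(model$nets$dec_m, fw_dm, dlogits)
  dh_m <- dh_m + b_dm$dX

  # reparameterisation of h_x plus analytic KL gradients
  dmu_x <- dh_x + cfg$gamma_x * mu_x / n
  dlv_x <- dh_x * eps_x * sd_x * 0.5 + cfg$gamma_x * 0.5 * (exp(lv_x) - 1) / n
  b_ex <- mlp_backward(model$nets$enc_x, fw_ex, cbind(dmu_x, dlv_x))
  dh_m <- dh_m + b_ex$dX[, p + 1:dm, drop = FALSE]

  dmu_m <- dh_m + cfg$gamma_m * mu_m / n
  dlv_m <- dh_m * eps_m * sd_m * 0.5 + cfg$gamma_m * 0.5 * (exp(lv_m) - 1) / n
  b_em <- mlp_backward(model$nets$enc_m, fw_em, cbind(dmu_m, dlv_m))

  grads <- list(enc_m = b_em[c("W", "b")], enc_x = b_ex[c("W", "b")],
                dec_m = b_dm[c("W", "b")], dec_x = b_dx[c("W", "b")],
                head = list(W = lapply(sh$grads$W, `*`, cfg$alpha),
                            b = lapply(sh$grads$b, `*`, cfg$alpha)))
  list(loss_breakdown = breakdown, grads = grads)
}

#' Fit MissCVAE
#'
#' Standardises covariates on observed training entries, zero-fills, trains
#' the weighted ELBO by minibatch Adam with early stopping on the validation
#' total loss, and restores the best-epoch parameters. The fitted object
#' carries its standardiser and time scale, so prediction needs nothing else.
#'
#' @param train,validation `incomplete_dataset`s (raw scale).
#' @param config A [misscvae_config()].
#' @param seed Integer seed controlling initialisation, minibatches and
#'   Monte-Carlo draws.
#' @param verbose Print per-epoch validation loss.
#' @return A fitted `misscvae` with a `history` data frame of all loss
#'   components per epoch.
#' @export
misscvae_fit <- function(train, validation, config = misscvae_config(),
                         seed = 1, verbose = FALSE) {
  std <- fit_standardiser(train)
  tr <- standardise(std, train); va <- standardise(std, validation)
  x_tr <- zero_fill(tr); m_tr <- tr$mask
  x_va <- zero_fill(va); m_va <- va$mask

  model <- misscvae_init(ncol(x_tr), config, seed)
  model$standardiser <- std
  model$time_scale <- as.numeric(stats::quantile(train$time, 0.99))

  params <- collect_params(model$nets)
  st <- adam_init(params)
  n <- nrow(x_tr)
  best <- list(loss = Inf, params = params, epoch = 0)
  history <- data.frame()
  wait <- 0
  # fixed validation eps: comparable across epochs
  cfg <- config
  eps_vm <- with_stream(seed, "val_eps_m",
                        matrix(stats::rnorm(nrow(x_va) * cfg$latent_m),
                               nrow(x_va), cfg$latent_m))
  eps_vx <- with_stream(seed, "val_eps_x",
                        matrix(stats::rnorm(nrow(x_va) * cfg$latent_x),
                               nrow(x_va), cfg$latent_x))
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_stream(seed, paste0("mb", ep), sample.int(n))
    bi <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      bi <- bi + 1
      model$nets <- set_params(model$nets, params)
      acc <- NULL
      for (s in seq_len(cfg$mc_samples)) {
        res <- misscvae_elbo(model, x_tr[idx, , drop = FALSE],
                             m_tr[idx, , drop = FALSE], train$time[idx],
                             train$event[idx], want_grads = TRUE,
                             seed = substream_seed(seed, sprintf("mc%d_%d_%d", ep, bi, s)))
        flat <- grads_to_flat(res$grads)
        acc <- if (is.null(acc)) flat else Map(`+`, acc, flat)
      }
      if (cfg$mc_samples > 1) acc <- lapply(acc, `/`, cfg$mc_samples)
      up <- adam_step(params, acc, st, cfg$lr)
      params <- up$params; st <- up$state
    }
    model$nets <- set_params(model$nets, params)
    vres <- misscvae_elbo(model, x_va, m_va, validation$time, validation$event,
                          eps_m = eps_vm, eps_x = eps_vx)
    lb <- vres$loss_breakdown
    history <- rbind(history, data.frame(epoch = ep, total = lb$total,
                                         survival = lb$survival,
                                         recon_x = lb$recon_x,
                                         recon_m = lb$recon_m,
                                         kl_x = lb$kl_x, kl_m = lb$kl_m))
    if (verbose) message(sprintf("epoch %d total %.4f surv %.4f", ep, lb$total,
                                 lb$survival))
    if (lb$total < best$loss - 1e-6) {
      best <- list(loss = lb$total, params = params, epoch = ep); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }
  model$nets <- set_params(model$nets, best$params)
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' Predict survival curves for (possibly unseen) incomplete rows
#'
#' Deterministic deployment path: posterior means of h_m and h_x (no
#' sampling), then the monotone head. Works for any missingness pattern,
#' including all-missing rows and patterns never seen in training; needs only
#' the fitted object.
#'
#' @param object A fitted `misscvae`.
#' @param dataset An `incomplete_dataset` with the training feature schema.
#' @param t_grid Non-negative increasing raw-time grid.
#' @param ... Unused.
#' @return A `survival_curves` object.
#' @export
predict.misscvae <- function(object, dataset, t_grid, ...) {
  if (ncol(dataset$x_tilde) != object$p) {
    stopf("dataset has %d features, model expects %d", ncol(dataset$x_tilde),
          object$p)
  }
  ds <- standardise(object$standardiser, dataset)
  x_f <- zero_fill(ds)
  post_m <- encode_mask(object, ds$mask)
  post_x <- encode_data(object, x_f, post_m$mean)
  survival_curve(object, post_x$mean, post_m$mean, t_grid)
}
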