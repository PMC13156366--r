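small_config <- function(...) {
  args <- list(latent_x = 3, latent_m = 2, hidden = c(6), head_hidden = c(5),
               quad_order = 6, epochs = 5, batch_size = 32, patience = 3)
  override <- list(...)
  do.call(misscvae_config, utils::modifyList(args, override))
}

test_that("encoders and decoders satisfy their shape and codomain contracts", {
  cfg <- small_config()
  model <- misscvae:::misscvae_init(4, cfg, seed = 3)
  mask <- matrix(c(1, 0, 1, 1, 0, 0, 1, 1), 2, byrow = TRUE)
  post_m <- encode_mask(model, mask)
  expect_equal(dim(post_m$mean), c(2, 2))
  expect_equal(dim(post_m$logvar), c(2, 2))
  expect_identical(post_m, encode_mask(model, mask))   # deterministic
  expect_error(encode_mask(model, mask * 2), "0/1")
  expect_error(encode_mask(model, mask[, 1:3]), "columns")

  x <- matrix(rnorm(8), 2)
  post_x <- encode_data(model, x, post_m$mean)
  expect_equal(dim(post_x$mean), c(2, 3))
  xna <- x; xna[1, 2] <- NA
  expect_error(encode_data(model, xna, post_m$mean), "NA")

  # distinct mask embeddings condition the data posterior
  post_x2 <- encode_data(model, x, post_m$mean + 1)
  expect_false(isTRUE(all.equal(post_x$mean, post_x2$mean)))

  dec <- decode(model, post_x$mean, post_m$mean)
  expect_true(all(dec$mask_prob > 0 & dec$mask_prob < 1))
  expect_true(all(dec$x_var >= cfg$var_floor))
  # the mask decoder consumes h_m only
  dec2 <- decode(model, post_x$mean + 5, post_m$mean)
  expect_identical(dec$mask_prob, dec2$mask_prob)
})

test_that("zero-initialised encoder head gives standard-normal posteriors and zero KL", {
  cfg <- small_config()
  model <- misscvae:::misscvae_init(3, cfg, seed = 1)
  L <- length(model$nets$enc_m$W)
  model$nets$enc_m$W[[L]][] <- 0
  model$nets$enc_m$b[[L]][] <- 0
  post <- encode_mask(model, matrix(c(1, 0, 1), 1))
  expect_equal(post$mean, matrix(0, 1, 2))
  expect_equal(post$logvar, matrix(0, 1, 2))
})

test_that("KL terms match the closed form 0.5 (mu^2 + sigma^2 - 1 - log sigma^2)", {
  cfg <- small_config(alpha = 1, beta_x = 1, beta_m = 1, gamma_x = 1, gamma_m = 1)
  model <- misscvae:::misscvae_init(3, cfg, seed = 1)
  model$time_scale <- 1
  dm <- cfg$latent_m
  # force q(h_m) = N(1, 1) exactly: zero last layer, bias = (mean 1, logvar 0)
  L <- length(model$nets$enc_m$W)
  model$nets$enc_m$W[[L]][] <- 0
  model$nets$enc_m$b[[L]] <- c(rep(1, dm), rep(0, dm))
  x <- matrix(rnorm(6), 2); m <- matrix(1, 2, 3)
  res <- misscvae_elbo(model, x, m, time = c(0.5, 0.7), event = c(1, 0))
  expect_equal(res$loss_breakdown$kl_m, 0.5 * dm, tolerance = 1e-12)

  # N(0,1) posterior has zero KL
  model$nets$enc_m$b[[L]][] <- 0
  res0 <- misscvae_elbo(model, x, m, time = c(0.5, 0.7), event = c(1, 0))
  expect_equal(res0$loss_breakdown$kl_m, 0, tolerance = 1e-12)
})

test_that("weighted total composes the components with the configured weights", {
  cfg <- small_config(alpha = 10, beta_x = 0.1, beta_m = 0.1,
                      gamma_x = 0.1, gamma_m = 0.1)
  model <- misscvae:::misscvae_init(4, cfg, seed = 2)
  model$time_scale <- 1
  set.seed(5)
  x <- matrix(rnorm(12), 3); m <- matrix(rbinom(12, 1, 0.7), 3); x[m == 0] <- 0
  lb <- misscvae_elbo(model, x, m, time = runif(3), event = c(1, 0, 1),
                      seed = 9)$loss_breakdown
  expect_equal(lb$total,
               10 * lb$survival + 0.1 * lb$recon_x + 0.1 * lb$recon_m +
                 0.1 * lb$kl_x + 0.1 * lb$kl_m)
  expect_gte(lb$kl_x, 0)
  expect_gte(lb$kl_m, 0)
})

test_that("reconstruction is masked: values at missing entries never enter", {
  cfg <- small_config()
  model <- misscvae:::misscvae_init(4, cfg, seed = 2)
  model$time_scale <- 1
  set.seed(6)
  m <- matrix(rbinom(20, 1, 0.6), 5)
  x_a <- matrix(rnorm(20), 5); x_a[m == 0] <- 0
  tt <- runif(5); dd <- rbinom(5, 1, 0.5)
  em <- matrix(rnorm(10), 5); ex <- matrix(rnorm(15), 5)
  la <- misscvae_elbo(model, x_a, m, tt, dd, eps_m = em, eps_x = ex)
  # raw data differing arbitrarily at masked entries, same fill convention
  x_raw <- x_a; x_raw[m == 0] <- rnorm(sum(m == 0)) * 50
  x_b <- x_raw; x_b[m == 0] <- 0
  lb <- misscvae_elbo(model, x_b, m, tt, dd, eps_m = em, eps_x = ex)
  expect_identical(la$loss_breakdown, lb$loss_breakdown)
})

test_that("full ELBO gradients match finite differences", {
  cfg <- small_config()
  model <- misscvae:::misscvae_init(4, cfg, seed = 3)
  model$time_scale <- 1
  set.seed(42)
  n <- 5
  x <- matrix(rnorm(n * 4), n)
  m <- matrix(rbinom(n * 4, 1, 0.7), n)
  x[m == 0] <- 0
  tt <- runif(n, 0.1, 1); dd <- rbinom(n, 1, 0.5)
  em <- matrix(rnorm(n * 2), n); ex <- matrix(rnorm(n * 3), n)
  res <- misscvae_elbo(model, x, m, tt, dd, eps_m = em, eps_x = ex,
                       want_grads = TRUE)
  params <- misscvae:::collect_params(model$nets)
  flat <- misscvae:::grads_to_flat(res$grads)
  err <- max_grad_error(params, flat, function(p) {
    model$nets <- misscvae:::set_params(model$nets, p)
    misscvae_elbo(model, x, m, tt, dd, eps_m = em,
                  eps_x = ex)$loss_breakdown$total
  }, sample_frac = 0.4)
  expect_lt(err, 1e-5)
})

test_that("negated weighted loss at unit weights lower-bounds the log evidence", {
  # single datum; 1-D latents; evidence by dense 2-D grid quadrature
  cfg <- misscvae_config(latent_x = 1, latent_m = 1, hidden = c(4),
                         head_hidden = c(4), quad_order = 10,
                         alpha = 1, beta_x = 1, beta_m = 1,
                         gamma_x = 1, gamma_m = 1)
  model <- misscvae:::misscvae_init(1, cfg, seed = 11)
  model$time_scale <- 1
  x <- matrix(0.4, 1, 1); m <- matrix(1, 1, 1); tt <- 0.6; dd <- 1

  gr <- seq(-6, 6, length.out = 101)
  hstep <- gr[2] - gr[1]
  HH <- as.matrix(expand.grid(h_x = gr, h_m = gr))
  # log p(m | h_m), log p(x | h_x, h_m) from the decoders
  dec <- decode(model, HH[, 1, drop = FALSE], HH[, 2, drop = FALSE])
  lp_m <- log(dec$mask_prob[, 1])          # m = 1
  lp_x <- stats::dnorm(x[1, 1], dec$x_mean[, 1], sqrt(dec$x_var[, 1]),
                       log = TRUE)
  # log p(t | h): density at the event time from the survival head
  hv <- misscvae:::head_view(model)
  Hin <- HH
  ci <- misscvae:::survhead_cumint(hv, Hin, rep(tt, nrow(HH)))
  u <- tanh(ci$Lambda)
  g_t <- misscvae:::survhead_g_at(hv, Hin, rep(tt, nrow(HH)))$g
  lp_t <- log(g_t) + log1p(-u^2)
  lprior <- stats::dnorm(HH[, 1], log = TRUE) + stats::dnorm(HH[, 2], log = TRUE)
  log_evidence <- log(sum(exp(lp_m + lp_x + lp_t + lprior)) * hstep^2)

  # Monte-Carlo ELBO: replicate the datum, average the per-batch loss
  reps <- 400
  xs <- matrix(x, reps, 1); ms <- matrix(1, reps, 1)
  losses <- vapply(1:8, function(s) {
    misscvae_elbo(model, xs, ms, rep(tt, reps), rep(dd, reps),
                  seed = s)$loss_breakdown$total
  }, numeric(1))
  elbo <- -mean(losses)
  mc_se <- sd(losses) / sqrt(length(losses))
  expect_lte(elbo, log_evidence + 3 * mc_se + 1e-8)
  # and the bound is tight-ish for this near-linear toy
  expect_gt(elbo, log_evidence - 2)
})

test_that("training improves the validation objective and is reproducible", {
  spec <- tiny_spec(n = 600)
  sim <- simulate_dataset(spec, seed = 4)
  sp <- split_dataset(sim$dataset, seed = 4)
  cfg <- small_config(epochs = 8)
  fit1 <- misscvae_fit(sp$train, sp$validation, cfg, seed = 2)
  expect_lt(min(fit1$history$total), fit1$history$total[1])
  expect_equal(nrow(fit1$history), length(unique(fit1$history$epoch)))
  fit2 <- misscvae_fit(sp$train, sp$validation, cfg, seed = 2)
  expect_identical(fit1$history, fit2$history)   # bit-reproducible
})

test_that("very large KL weights collapse the posterior toward the prior", {
  spec <- tiny_spec(n = 400)
  sim <- simulate_dataset(spec, seed = 6)
  sp <- split_dataset(sim$dataset, seed = 6)
  fit_big <- misscvae_fit(sp$train, sp$validation,
                          small_config(epochs = 30, patience = 30, lr = 5e-3,
                                       gamma_x = 500, gamma_m = 500,
                                       alpha = 0.01, beta_x = 0.01,
                                       beta_m = 0.01),
                          seed = 3)
  last <- tail(fit_big$history, 1)
  expect_lt(last$kl_x + last$kl_m, 0.05)
})

test_that("prediction is deterministic, total, and pattern-robust", {
  spec <- tiny_spec(n = 600)
  sim <- simulate_dataset(spec, seed = 8)
  sp <- split_dataset(sim$dataset, seed = 8)
  fit <- misscvae_fit(sp$train, sp$validation, small_config(epochs = 4), seed = 5)
  grid <- make_eval_grid(sp$test$time, n_points = 20)

  # an all-missing row (every partially observed column NA) still predicts
  x_new <- sp$test$x_tilde[1:3, , drop = FALSE]
  x_new[2, 2:4] <- NA
  ds_new <- incomplete_dataset(x_new, sp$test$time[1:3], sp$test$event[1:3],
                               sp$test$feature_names)
  pr <- predict(fit, ds_new, grid)
  expect_true(all(is.finite(pr$surv)))
  expect_true(all(pr$surv >= 0 & pr$surv <= 1))

  # identical (x, m) rows get identical curves; repeated calls agree
  x_dup <- x_new[c(1, 1), , drop = FALSE]
  ds_dup <- incomplete_dataset(x_dup, rep(1, 2), c(1, 1),
                               sp$test$feature_names)
  pd <- predict(fit, ds_dup, grid)
  expect_identical(pd$surv[1, ], pd$surv[2, ])
  expect_identical(pr$surv, predict(fit, ds_new, grid)$surv)

  expect_error(predict(fit, toy_dataset(n = 4, p = 2), grid), "features")
})

test_that("the h_x-only ablation drops h_m from the head but keeps conditioning", {
  cfg <- small_config(include_hm_in_head = FALSE)
  model <- misscvae:::misscvae_init(4, cfg, seed = 2)
  model$time_scale <- 1
  # head input width is 1 + latent_x only
  expect_equal(model$nets$head$sizes[1], 1 + cfg$latent_x)
  # changing h_m leaves the survival curve unchanged ...
  hx <- matrix(rnorm(3), 1); hm1 <- matrix(0, 1, 2); hm2 <- matrix(3, 1, 2)
  g <- seq(0, 1, length.out = 5)
  expect_identical(survival_curve(model, hx, hm1, g)$surv,
                   survival_curve(model, hx, hm2, g)$surv)
  # ... but h_m still conditions the data encoder/decoder
  post1 <- encode_data(model, matrix(0, 1, 4), hm1)
  post2 <- encode_data(model, matrix(0, 1, 4), hm2)
  expect_false(isTRUE(all.equal(post1$mean, post2$mean)))
})
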