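test_that("latent draws follow the specified Gaussian, deterministically", {
  spec <- tiny_spec()
  spec$Sigma_H <- matrix(c(1, 0.5, 0.5, 1), 2)
  H <- simulate_latent(spec, seed = 3, n = 10000)
  expect_equal(dim(H), c(10000, 2))
  expect_true(all(abs(colMeans(H)) < 4 / sqrt(10000)))
  expect_equal(cor(H[, 1], H[, 2]), 0.5, tolerance = 0.05)
  expect_identical(H, simulate_latent(spec, seed = 3, n = 10000))

  spec$Sigma_H <- matrix(c(1, 2, 2, 1), 2)   # not positive definite
  expect_error(simulate_latent(spec, seed = 1), "positive definite")
})

test_that("risk factors follow their conditional laws given the latents", {
  # systolic-blood-pressure style law: N(130 - 20 * H1, sd 5)
  spec <- tiny_spec()
  spec$factor_intercepts <- c(130, 0, 0, 0)
  spec$factor_loadings <- rbind(c(-20, 0), c(0, 0), c(1, 0), c(2, 0))
  spec$factor_noise_sd <- c(5, 0.7, 0, 0)
  H <- matrix(0, 5000, 2)   # condition on H = 0
  X <- simulate_risk_factors(H, spec, seed = 4)
  expect_equal(mean(X[, 1]), 130, tolerance = 5 * 4 / sqrt(5000))
  expect_equal(sd(X[, 1]), 5, tolerance = 0.15)

  # zero loadings: independent of H; zero noise: deterministic in H
  H <- simulate_latent(spec, seed = 5, n = 5000)
  X <- simulate_risk_factors(H, spec, seed = 5)
  expect_lt(abs(cor(X[, 2], H[, 1])), 0.05)
  expect_equal(cor(X[, 3], X[, 4]), 1)   # both exact functions of H1

  spec$factor_noise_sd[1] <- -1
  expect_error(simulate_risk_factors(H, spec, seed = 1), "non-negative")
})

test_that("event times follow the PH inverse-sampling construction", {
  spec <- tiny_spec(n = 2000)
  spec$censoring_rate <- 0   # isolate event times
  H <- simulate_latent(spec, seed = 8)
  X <- simulate_risk_factors(H, spec, seed = 8)
  s0 <- spec; s0$beta_H <- c(0, 0); s0$beta_X <- rep(0, 4)
  s1 <- s0; s1$factor_intercepts <- s0$factor_intercepts
  out0 <- simulate_survival(H, X, s0, seed = 8)
  expect_true(all(out0$event == 1))
  # same uniform stream, eta shifted by log 2 halves every event time
  s2 <- s0; s2$beta_H <- c(0, 0); s2$beta_X <- rep(0, 4)
  eta_shift <- log(2)
  s2$factor_intercepts <- s0$factor_intercepts
  X1 <- cbind(X[, 1] * 0 + 1, X[, -1])   # constant first factor
  s2$beta_X <- c(eta_shift, 0, 0, 0)
  out2 <- simulate_survival(H, X1, s2, seed = 8)
  expect_equal(out2$time, out0$time / 2, tolerance = 1e-12)

  # empirical survival at eta = 0 matches exp(-rate * t)
  expect_equal(mean(out0$time > 10), exp(-spec$baseline$rate * 10),
               tolerance = 3 * sqrt(0.25 / 2000))

  bad <- spec; bad$baseline$rate <- -1
  expect_error(simulation_spec(
    n = 10, mu_H = spec$mu_H, Sigma_H = spec$Sigma_H,
    factor_intercepts = spec$factor_intercepts,
    factor_loadings = spec$factor_loadings,
    factor_noise_sd = spec$factor_noise_sd, beta_H = spec$beta_H,
    beta_X = spec$beta_X, baseline = list(family = "exponential", rate = -1),
    censoring_rate = 0.1, miss_mu0 = spec$miss_mu0,
    miss_coef = spec$miss_coef, Sigma_z = spec$Sigma_z,
    observed_cols = 1), "positive")
})

test_that("censoring vanishes as the censoring rate goes to zero", {
  spec <- tiny_spec(n = 800)
  spec$censoring_rate <- 1e-9
  sim <- simulate_dataset(spec, seed = 2)
  expect_gt(mean(sim$dataset$event), 0.999)
})

test_that("ground-truth oracle is a valid survival function matching KM", {
  spec <- tiny_spec(n = 20000)
  spec$censoring_rate <- 0
  sim <- simulate_dataset(spec, seed = 13)
  grid <- seq(0, 20, length.out = 50)
  S <- true_survival(sim$ground_truth, t_grid = grid)
  expect_equal(S[, 1], rep(1, nrow(S)))
  expect_true(all(diff(t(S)) <= 1e-14))
  # closed form at eta = 0
  gt0 <- structure(list(eta = 0, baseline = list(family = "exponential", rate = 1)),
                   class = "survival_ground_truth")
  expect_equal(drop(true_survival(gt0, 1, c(0, 1))), c(1, exp(-1)))
  expect_error(true_survival(gt0, 1, c(-1, 0)), "non-negative")

  # population-average oracle vs Kaplan-Meier of the simulated cohort
  km <- survival::survfit(survival::Surv(sim$dataset$time, sim$dataset$event) ~ 1)
  for (tq in c(2, 5, 10)) {
    km_at <- min(km$surv[km$time <= tq], 1)
    expect_equal(km_at, mean(true_survival(sim$ground_truth, t_grid = tq)),
                 tolerance = 3 / sqrt(20000) * 3)
  }
})

test_that("latent-threshold missingness has the stated marginal and joint laws", {
  spec <- tiny_spec(n = 50000, miss_mu0 = rep(0, 4))
  spec$miss_coef <- matrix(0, 4, 2)
  H <- simulate_latent(spec, seed = 21)
  mask <- induce_missingness(H, spec, seed = 21)
  expect_true(all(mask[, 1] == 1))   # always-observed column forced
  expect_equal(unname(colMeans(mask)[2:4]), rep(0.5, 3), tolerance = 0.01)

  # strong positive latent mean: essentially always observed
  spec5 <- spec; spec5$miss_mu0 <- rep(5, 4)
  mask5 <- induce_missingness(H, spec5, seed = 21)
  expect_true(all(colMeans(mask5) > 0.999))

  # block covariance induces within-block mask correlation, none across
  specB <- tiny_spec(n = 50000, miss_mu0 = rep(0, 4))
  specB$miss_coef <- matrix(0, 4, 2)
  specB$Sigma_z <- diag(4)
  specB$Sigma_z[2, 3] <- specB$Sigma_z[3, 2] <- 0.6
  maskB <- induce_missingness(H, specB, seed = 22)
  r_within <- cor(maskB[, 2], maskB[, 3])
  r_across <- cor(maskB[, 2], maskB[, 4])
  # tetrachoric relation at threshold 0: P(both) = 1/4 + asin(rho)/(2*pi)
  rho_expect <- (0.25 + asin(0.6) / (2 * pi) - 0.25) / 0.25
  expect_equal(r_within, rho_expect, tolerance = 0.03)
  expect_lt(abs(r_across), 0.02)
})

test_that("missingness is informative through the shared latents only", {
  spec <- tiny_spec(n = 20000)
  sim <- simulate_dataset(spec, seed = 31)
  # f_mu depends on H1: event incidence differs between missing and observed
  m2 <- sim$mask[, 2]
  diff_inf <- abs(mean(sim$dataset$event[m2 == 0]) -
                    mean(sim$dataset$event[m2 == 1]))
  expect_gt(diff_inf, 0.05)

  # MCAR control: constant f_mu makes the mask carry no outcome signal
  spec0 <- spec; spec0$miss_coef <- matrix(0, 4, 2)
  sim0 <- simulate_dataset(spec0, seed = 31)
  m2 <- sim0$mask[, 2]
  diff_mcar <- abs(mean(sim0$dataset$event[m2 == 0]) -
                     mean(sim0$dataset$event[m2 == 1]))
  expect_lt(diff_mcar, 0.02)
})

test_that("default design has the stated shape", {
  spec <- default_simulation_spec()
  expect_equal(spec$n, 50000)
  expect_equal(spec$d, 2)
  expect_equal(spec$p, 20)
  expect_equal(spec$observed_cols, 1:5)
  expect_equal(sum(!seq_len(spec$p) %in% spec$observed_cols), 15)
  expect_equal(pattern_code(rep(1, 15)), 2^15)
})

test_that("scenarios implement their withholding/shift contracts", {
  spec <- tiny_spec(n = 3000)
  # unseen patterns: a withheld observed-count stratum vanishes from train/val
  sc <- build_scenario("unseen_patterns", spec, seed = 2,
                       params = list(group = 2:4, withheld_counts = 2))
  cnt <- function(ds) rowSums(ds$mask[, 2:4])
  expect_false(any(cnt(sc$split$train) == 2))
  expect_false(any(cnt(sc$split$validation) == 2))
  expect_true(any(cnt(sc$split$test) == 2))

  expect_error(build_scenario("unseen_patterns", spec, seed = 2,
                              params = list(group = 2:4,
                                            withheld_counts = 0:3)),
               "all rows")

  # missingness shift: train/val masks shift, test masks stay baseline
  sc_b <- build_scenario("baseline", spec, seed = 2)
  sc_s <- build_scenario("missingness_shift", spec, seed = 2,
                         params = list(mu_shift = 1.5))
  expect_identical(sc_s$split$test$mask, sc_b$split$test$mask)
  expect_gt(mean(sc_s$split$train$mask[, 2:4]),
            mean(sc_b$split$train$mask[, 2:4]) + 0.05)

  # zero shift: same distribution of masks (rates agree within MC error)
  sc_0 <- build_scenario("missingness_shift", spec, seed = 2,
                         params = list(mu_shift = 0))
  expect_equal(colMeans(sc_0$split$train$mask), colMeans(sc_b$split$train$mask),
               tolerance = 0.06)

  # baseline: train and test pattern frequencies are homogeneous
  spec_big <- tiny_spec(n = 50000)
  sc_big <- build_scenario("baseline", spec_big, seed = 9)
  codes_tr <- pattern_code(sc_big$split$train$mask)
  codes_te <- pattern_code(sc_big$split$test$mask)
  lev <- sort(unique(c(codes_tr, codes_te)))
  tab <- rbind(tabulate(match(codes_tr, lev), length(lev)),
               tabulate(match(codes_te, lev), length(lev)))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("simulation specs round-trip through YAML presets", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preset: default", "n_subjects: 1234", "censoring_rate: 0.5"), path)
  spec <- read_simulation_spec(path)
  expect_equal(spec$n, 1234)
  expect_equal(spec$censoring_rate, 0.5)
  expect_equal(spec$p, 20)
  writeLines(c("preset: default", "banana: 1"), path)
  expect_error(read_simulation_spec(path), "unknown spec field")
  expect_error(read_simulation_spec("no-such-file.yaml"), "not found")

  packaged <- system.file("extdata", "default_study.yaml",
                          package = "misscvae")
  spec2 <- read_simulation_spec(packaged)
  expect_equal(spec2$n, 50000)
})
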