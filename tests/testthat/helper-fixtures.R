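# Shared fixture builders. Everything is generated in code; no stored data.

# Small incomplete dataset with a known missingness layout.
toy_dataset <- function(n = 8, p = 3, seed = 99, miss_frac = 0.25) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  x[matrix(runif(n * p) < miss_frac & col(x) > 1, n, p)] <- NA
  incomplete_dataset(x, time = rexp(n) + 0.1, event = rbinom(n, 1, 0.6),
                     feature_names = paste0("f", seq_len(p)))
}

# A tiny simulation design that runs in milliseconds.
tiny_spec <- function(n = 500, miss_mu0 = c(0, 0.4, 0.2, -0.2),
                      miss_coef_scale = -0.8) {
  simulation_spec(
    n = n, mu_H = c(0, 0), Sigma_H = diag(2),
    factor_intercepts = rep(0, 4),
    factor_loadings = rbind(c(-0.6, 0.1), c(-0.5, 0.2), c(0.2, -0.5),
                            c(-0.4, -0.3)),
    factor_noise_sd = rep(0.7, 4),
    beta_H = c(-0.5, -0.1), beta_X = c(0.2, 0.15, -0.1, 0.1),
    baseline = list(family = "exponential", rate = 0.1),
    censoring_rate = 0.05,
    miss_mu0 = miss_mu0,
    miss_coef = matrix(c(0, miss_coef_scale, miss_coef_scale / 2,
                         miss_coef_scale, 0, 0, 0.2, 0), 4, 2),
    Sigma_z = diag(4), observed_cols = 1
  )
}

# Analytic survival curves S(t) = exp(-rate_i * t) on a grid, as the
# structure the metrics consume.
analytic_curves <- function(rates, t_grid) {
  surv <- exp(-outer(rates, t_grid))
  structure(list(time_grid = t_grid, surv = surv,
                 dens = surv * rates),
            class = "survival_curves")
}

# Gradient comparison helper: central finite differences of `loss_fun(params)`
# against the supplied analytic flat gradients, returning the max abs error.
max_grad_error <- function(params, flat_grads, loss_fun, h = 1e-6,
                           sample_frac = 1) {
  maxerr <- 0
  for (nm in names(params)) {
    idx <- seq_along(params[[nm]])
    if (sample_frac < 1) {
      idx <- idx[seq(1, length(idx), length.out = ceiling(length(idx) * sample_frac))]
    }
    for (i in idx) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + h
      lp <- loss_fun(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h
      lm <- loss_fun(p2)
      maxerr <- max(maxerr, abs((lp - lm) / (2 * h) - flat_grads[[nm]][i]))
    }
  }
  maxerr
}

# Exhaustive-pair oracle for the time-dependent concordance.
brute_force_ctd <- function(curves, time, event) {
  n <- length(time)
  s_at <- function(j, t) approx(curves$time_grid, curves$surv[j, ], t,
                                rule = 2)$y
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- event[i] == 1 &&
      (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
    if (!comparable) next
    si <- s_at(i, time[i]); sj <- s_at(j, time[i])
    num <- num + if (si < sj) 1 else if (si == sj) 0.5 else 0
    den <- den + 1
  }
  num / den
}
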