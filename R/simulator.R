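#' Simulation specification for MNAR survival data
#'
#' Bundles the four generative steps: (1) latent health/lifestyle variables
#' H ~ N(mu_H, Sigma_H); (2) risk factors X_j = a_j + b_j' H + noise; (3)
#' proportional-hazards event times with baseline hazard lambda0 (exponential
#' or Weibull) and independent exponential censoring; (4) a latent missingness
#' variable Z ~ N(mu0 + C H, Sigma_z) thresholded at zero, so which covariates
#' get recorded depends on the same latent health state that drives the
#' outcome (missing not at random).
#'
#' @param n Number of subjects.
#' @param mu_H,Sigma_H Latent mean vector and covariance (d-dim).
#' @param factor_intercepts Length-p intercepts a_j.
#' @param factor_loadings p x d matrix of latent loadings b_j.
#' @param factor_noise_sd Length-p residual standard deviations (sd, not
#'   variance).
#' @param beta_H,beta_X Log-hazard coefficients on H and X.
#' @param baseline List: `family` ("exponential" or "weibull"), `rate`
#'   (lambda0 > 0), and `shape` for Weibull.
#' @param censoring_rate Rate of the exponential censoring distribution.
#' @param miss_mu0 Length-p intercepts of the latent missingness mean.
#' @param miss_coef p x d matrix C: mu_z = mu0 + H C'. Rows for
#'   always-observed columns are ignored.
#' @param Sigma_z p x p correlation matrix of Z (unit diagonal, block
#'   structure encodes jointly observed measurement clusters).
#' @param observed_cols Indices of always-observed columns.
#' @param feature_names Optional column names.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n, mu_H, Sigma_H, factor_intercepts, factor_loadings,
                            factor_noise_sd, beta_H, beta_X, baseline,
                            censoring_rate, miss_mu0, miss_coef, Sigma_z,
                            observed_cols, feature_names = NULL) {
  factor_loadings <- as.matrix(factor_loadings)
  p <- nrow(factor_loadings); d <- ncol(factor_loadings)
  stopifnot(length(mu_H) == d, nrow(Sigma_H) == d,
            length(factor_intercepts) == p, length(factor_noise_sd) == p,
            length(beta_H) == d, length(beta_X) == p,
            length(miss_mu0) == p, nrow(miss_coef) == p, ncol(miss_coef) == d,
            nrow(Sigma_z) == p)
  if (any(factor_noise_sd < 0)) stopf("factor noise sd must be non-negative")
  if (!isTRUE(all.equal(unname(diag(Sigma_z)[setdiff(seq_len(p), observed_cols)]),
                        rep(1, p - length(observed_cols))))) {
    stopf("Sigma_z must have unit diagonal on partially observed columns")
  }
  if (is.null(baseline$family)) baseline$family <- "exponential"
  if (!baseline$family %in% c("exponential", "weibull")) {
    stopf("unknown baseline hazard family '%s'", baseline$family)
  }
  if (baseline$rate <= 0) stopf("baseline rate must be positive")
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(p))
  structure(
    list(n = n, d = d, p = p, mu_H = mu_H, Sigma_H = Sigma_H,
         factor_intercepts = factor_intercepts, factor_loadings = factor_loadings,
         factor_noise_sd = factor_noise_sd, beta_H = beta_H, beta_X = beta_X,
         baseline = baseline, censoring_rate = censoring_rate,
         miss_mu0 = miss_mu0, miss_coef = miss_coef, Sigma_z = Sigma_z,
         observed_cols = sort(observed_cols), feature_names = feature_names),
    class = "simulation_spec"
  )
}

#' Default study design
#'
#' The packaged study conditions: 2 latent variables (health state, higher is
#' healthier, and lifestyle), 20 risk factors of which 5 are always observed
#' and 15 partially observed in three measurement clusters of 5 (pattern space
#' 2^15 = 32,768), a protective health effect on the hazard (beta_H1 < 0),
#' exponential baseline hazard, exponential censoring calibrated to roughly
#' 30% censoring, and missingness whose latent mean decreases with health, so
#' sicker subjects are measured more completely.
#'
#' @param n Number of subjects (the full design uses 50,000).
#' @return A [simulation_spec()].
#' @export
default_simulation_spec <- function(n = 50000) {
  B <- rbind(
    # always observed (demographic-style)
    c(-0.60, 0.10), c(-0.50, -0.20), c(-0.40, 0.30), c(0.30, 0.50), c(-0.20, -0.40),
    # cluster A: health-state laboratory panel
    c(-0.70, 0.00), c(-0.60, -0.10), c(-0.65, 0.10), c(-0.55, 0.00), c(-0.60, 0.20),
    # cluster B: mixed panel
    c(-0.40, 0.40), c(-0.35, 0.45), c(-0.45, 0.35), c(-0.30, 0.50), c(-0.40, 0.30),
    # cluster C: lifestyle panel
    c(-0.10, 0.60), c(0.00, 0.65), c(-0.15, 0.55), c(0.10, 0.60), c(-0.05, 0.50))
  p <- nrow(B)
  partial <- 6:20
  Sigma_z <- diag(p)
  block_cor <- c(0.5, 0.4, 0.6)
  for (b in 1:3) {
    cols <- partial[(b - 1) * 5 + 1:5]
    Sigma_z[cols, cols] <- block_cor[b]
    diag(Sigma_z)[cols] <- 1
  }
  miss_coef <- matrix(0, p, 2)
  miss_coef[6:10, 1] <- -0.6
  miss_coef[11:15, 1] <- -0.45
  miss_coef[16:20, 1] <- -0.35
  miss_coef[16:20, 2] <- -0.2   # lifestyle panel also tracks the second latent
  simulation_spec(
    n = n, mu_H = c(0, 0), Sigma_H = matrix(c(1, 0.3, 0.3, 1), 2),
    factor_intercepts = rep(0, p), factor_loadings = B,
    factor_noise_sd = rep(0.7, p),
    beta_H = c(-0.5, -0.15),
    beta_X = -0.3 * B[, 1] - 0.1 * B[, 2],
    baseline = list(family = "exponential", rate = 0.05),
    censoring_rate = 0.02,
    miss_mu0 = c(rep(0, 5), rep(c(0.3, 0.5, 0.7), each = 5)),
    miss_coef = miss_coef, Sigma_z = Sigma_z, observed_cols = 1:5,
    feature_names = c(paste0("base", 1:5), paste0("labA", 1:5),
                      paste0("labB", 1:5), paste0("labC", 1:5))
  )
}

#' Draw latent variables (Step 1)
#'
#' @param spec A `simulation_spec`.
#' @param seed Master seed; the latent draw uses its own named stream.
#' @param n Optional override of `spec$n`.
#' @return n x d matrix of multivariate-normal latents.
#' @export
simulate_latent <- function(spec, seed = 1, n = spec$n) {
  ev <- eigen(spec$Sigma_H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("Sigma_H is not positive definite")
  with_stream(seed, "latent",
              MASS::mvrnorm(n, mu = spec$mu_H, Sigma = spec$Sigma_H))
}

#' Draw risk factors given latents (Step 2)
#'
#' Each X_j is drawn independently given H from a Gaussian conditional law
#' a_j + b_j' H + N(0, sd_j^2); correlation between factors arises only
#' through shared latent dependence.
#'
#' @param H n x d latent matrix.
#' @param spec A `simulation_spec`.
#' @param seed Master seed (own stream).
#' @return n x p complete covariate matrix.
#' @export
simulate_risk_factors <- function(H, spec, seed = 1) {
  if (ncol(H) != spec$d) stopf("H has %d columns, expected %d", ncol(H), spec$d)
  if (any(spec$factor_noise_sd < 0)) stopf("factor noise sd must be non-negative")
  n <- nrow(H)
  mean_part <- sweep(H %*% t(spec$factor_loadings), 2, spec$factor_intercepts, `+`)
  noise <- with_stream(seed, "factor_noise",
                       matrix(stats::rnorm(n * spec$p), n, spec$p))
  X <- mean_part + sweep(noise, 2, spec$factor_noise_sd, `*`)
  colnames(X) <- spec$feature_names
  X
}

cum_hazard <- function(baseline, t) {
  switch(baseline$family,
         exponential = baseline$rate * t,
         weibull = (baseline$rate * t)^baseline$shape)
}

inv_cum_hazard <- function(baseline, v) {
  switch(baseline$family,
         exponential = v / baseline$rate,
         weibull = v^(1 / baseline$shape) / baseline$rate)
}

#' Draw survival outcomes (Step 3)
#'
#' Event times follow the proportional-hazards model
#' lambda(t | H, X) = lambda0(t) exp(beta_H' H + beta_X' X), drawn by inverse
#' sampling of the cumulative hazard: T_E = Lambda0^{-1}(-log U * exp(-eta)).
#' Censoring times are independent exponentials; T = min(T_E, T_C) and
#' delta = 1(T_E <= T_C).
#'
#' @param H,X Matrices from Steps 1-2.
#' @param spec A `simulation_spec`.
#' @param seed Master seed (event and censoring draws get separate streams).
#' @return List with `time`, `event`, and `ground_truth` (class
#'   `survival_ground_truth`: linear predictor eta and baseline hazard, giving
#'   a closed-form oracle for every subject's true survival curve).
#' @export
simulate_survival <- function(H, X, spec, seed = 1) {
  eta <- drop(H %*% spec$beta_H + X %*% spec$beta_X)
  n <- length(eta)
  u <- with_stream(seed, "event_u", stats::runif(n))
  t_event <- inv_cum_hazard(spec$baseline, -log(u) * exp(-eta))
  t_cens <- if (spec$censoring_rate > 0) {
    with_stream(seed, "censoring", stats::rexp(n, rate = spec$censoring_rate))
  } else rep(Inf, n)
  gt <- structure(list(eta = eta, baseline = spec$baseline),
                  class = "survival_ground_truth")
  list(time = pmin(t_event, t_cens),
       event = as.numeric(t_event <= t_cens),
       ground_truth = gt)
}

#' Ground-truth survival curves
#'
#' Evaluates the closed-form oracle S(t | i) = exp(-Lambda0(t) exp(eta_i)) on
#' a time grid; only available in simulation, where it feeds the integrated
#' squared error metric.
#'
#' @param gt A `survival_ground_truth`.
#' @param subjects Subject indices (default all).
#' @param t_grid Non-negative increasing time grid.
#' @return length(subjects) x length(t_grid) matrix of survival probabilities.
#' @export
true_survival <- function(gt, subjects = seq_along(gt$eta), t_grid) {
  if (any(t_grid < 0)) stopf("t_grid must be non-negative")
  if (is.unsorted(t_grid)) stopf("t_grid must be increasing")
  Lam <- cum_hazard(gt$baseline, t_grid)
  exp(-outer(exp(gt$eta[subjects]), Lam))
}

#' Draw the missingness mask (Step 4)
#'
#' Z ~ N(mu0 + H C', Sigma_z) row-wise; feature j is observed when Z_j > 0.
#' Always-observed columns are forced to 1. Because mu_z depends on the same
#' latents as the outcome, missingness is informative (MNAR); setting C = 0
#' recovers an MCAR control.
#'
#' @param H n x d latent matrix.
#' @param spec A `simulation_spec`.
#' @param seed Master seed (own stream; pass a distinct `stream` label to
#'   draw an independent shifted mask for the missingness-shift scenario).
#' @param mu_shift Optional length-p shift added to mu0.
#' @param stream Stream label, default "missingness".
#' @return n x p binary matrix, 1 = observed.
#' @export
induce_missingness <- function(H, spec, seed = 1, mu_shift = NULL,
                               stream = "missingness") {
  if (ncol(H) != spec$d) stopf("H has %d columns, expected %d", ncol(H), spec$d)
  n <- nrow(H)
  mu0 <- spec$miss_mu0
  if (!is.null(mu_shift)) {
    if (length(mu_shift) == 1) mu_shift <- rep(mu_shift, spec$p)
    mu0 <- mu0 + mu_shift
  }
  mu_z <- sweep(H %*% t(spec$miss_coef), 2, mu0, `+`)
  ev <- eigen(spec$Sigma_z, symmetric = TRUE)
  if (min(ev$values) <= 0) stopf("Sigma_z is not positive definite")
  root <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
  eps <- with_stream(seed, stream, matrix(stats::rnorm(n * spec$p), n, spec$p))
  Z <- mu_z + eps %*% root
  mask <- (Z > 0) * 1
  mask[, spec$observed_cols] <- 1
  colnames(mask) <- spec$feature_names
  mask
}

apply_mask <- function(X, mask) {
  x <- X
  x[mask == 0] <- NA
  x
}

#' Simulate a complete study dataset
#'
#' Runs Steps 1-4 and assembles an [incomplete_dataset()] plus the ground
#' truth oracle and the underlying complete matrices.
#'
#' @param spec A `simulation_spec`.
#' @param seed Master seed.
#' @return List: `dataset`, `ground_truth`, `H`, `X`, `mask`.
#' @export
simulate_dataset <- function(spec, seed = 1) {
  H <- simulate_latent(spec, seed)
  X <- simulate_risk_factors(H, spec, seed)
  surv <- simulate_survival(H, X, spec, seed)
  mask <- induce_missingness(H, spec, seed)
  ds <- incomplete_dataset(apply_mask(X, mask), surv$time, surv$event,
                           spec$feature_names,
                           seq_len(spec$p) %in% spec$observed_cols)
  list(dataset = ds, ground_truth = surv$ground_truth, H = H, X = X, mask = mask)
}

count_in_group <- function(mask, group) rowSums(mask[, group, drop = FALSE])

#' Build an evaluation scenario
#'
#' Three designs: `baseline` (train and test share one missingness spec);
#' `unseen_patterns` (rows whose mask shows a withheld number of observed
#' values within a designated column group are removed from train/validation
#' only, so the test set contains patterns never seen in training);
#' `missingness_shift` (Steps 1-3 shared, Step 4 re-run with a shifted latent
#' missingness mean for train/validation while the test set keeps the
#' unshifted masks).
#'
#' @param name One of `"baseline"`, `"unseen_patterns"`, `"missingness_shift"`.
#' @param spec A `simulation_spec`.
#' @param seed Master seed.
#' @param params Scenario parameters: for unseen_patterns `group` (column
#'   indices, default the first partially observed cluster) and
#'   `withheld_counts` (default `c(3, 4)` observed of 5); for
#'   missingness_shift `mu_shift` (default `0.75`).
#' @param fractions Train/validation/test fractions.
#' @return A `scenario_bundle`: `name`, `split` (a `split_bundle`),
#'   `ground_truth_test`, `metadata`.
#' @export
build_scenario <- function(name = c("baseline", "unseen_patterns", "missingness_shift"),
                           spec, seed = 1, params = list(),
                           fractions = c(0.64, 0.16, 0.20)) {
  name <- match.arg(name)
  H <- simulate_latent(spec, seed)
  X <- simulate_risk_factors(H, spec, seed)
  surv <- simulate_survival(H, X, spec, seed)
  mask <- induce_missingness(H, spec, seed)
  obs_flags <- seq_len(spec$p) %in% spec$observed_cols
  make_ds <- function(m) incomplete_dataset(apply_mask(X, m), surv$time,
                                            surv$event, spec$feature_names, obs_flags)
  full <- make_ds(mask)
  bundle <- split_dataset(full, fractions, seed)
  metadata <- list()

  if (name == "unseen_patterns") {
    group <- params$group %||% setdiff(seq_len(spec$p), spec$observed_cols)[1:5]
    withheld <- params$withheld_counts %||% c(3, 4)
    drop_row <- count_in_group(mask, group) %in% withheld
    if (!any(drop_row) || all(drop_row)) {
      stopf("withheld configuration matches %s rows",
            if (any(drop_row)) "all" else "zero")
    }
    keep <- function(idx) idx[!drop_row[idx]]
    tr <- keep(bundle$indices$train); va <- keep(bundle$indices$validation)
    bundle$train <- full[tr]; bundle$validation <- full[va]
    bundle$indices$train <- tr; bundle$indices$validation <- va
    metadata <- list(group = group, withheld_counts = withheld,
                     dropped = sum(drop_row[c(bundle$indices$train,
                                              bundle$indices$validation)]) == 0)
  } else if (name == "missingness_shift") {
    mu_shift <- params$mu_shift %||% 0.75
    shift_vec <- rep(0, spec$p)
    partial <- setdiff(seq_len(spec$p), spec$observed_cols)
    if (length(mu_shift) == 1) shift_vec[partial] <- mu_shift else shift_vec <- mu_shift
    mask_shift <- induce_missingness(H, spec, seed, mu_shift = shift_vec,
                                     stream = "missingness_shift")
    shifted <- make_ds(mask_shift)
    bundle$train <- shifted[bundle$indices$train]
    bundle$validation <- shifted[bundle$indices$validation]
    metadata <- list(mu_shift = shift_vec)
  }

  gt_test <- structure(list(eta = surv$ground_truth$eta[bundle$indices$test],
                            baseline = spec$baseline),
                       class = "survival_ground_truth")
  structure(list(name = name, split = bundle, ground_truth_test = gt_test,
                 metadata = metadata),
            class = "scenario_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation specification from a YAML file
#'
#' Two forms are accepted: `preset: default` (optionally with `n_subjects`
#' and any scalar overrides such as `censoring_rate`), or a fully explicit
#' specification whose keys mirror the [simulation_spec()] arguments, with
#' matrices written as lists of rows. The sample size travels as
#' `n_subjects` because a bare `n` is a YAML boolean literal.
#'
#' @param path YAML file path.
#' @return A [simulation_spec()].
#' @export
read_simulation_spec <- function(path) {
  if (!file.exists(path)) stopf("spec file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (identical(y$preset, "default")) {
    spec <- default_simulation_spec(n = y$n_subjects %||% 50000)
    for (nm in setdiff(names(y), c("preset", "n_subjects"))) {
      if (!nm %in% names(spec)) stopf("unknown spec field '%s'", nm)
      spec[[nm]] <- y[[nm]]
    }
    return(spec)
  }
  as_mat <- function(v) if (is.list(v)) do.call(rbind, v) else as.matrix(v)
  simulation_spec(
    n = y$n_subjects, mu_H = unlist(y$mu_H), Sigma_H = as_mat(y$Sigma_H),
    factor_intercepts = unlist(y$factor_intercepts),
    factor_loadings = as_mat(y$factor_loadings),
    factor_noise_sd = unlist(y$factor_noise_sd),
    beta_H = unlist(y$beta_H), beta_X = unlist(y$beta_X),
    baseline = y$baseline, censoring_rate = y$censoring_rate,
    miss_mu0 = unlist(y$miss_mu0), miss_coef = as_mat(y$miss_coef),
    Sigma_z = as_mat(y$Sigma_z), observed_cols = unlist(y$observed_cols),
    feature_names = if (!is.null(y$feature_names)) unlist(y$feature_names)
  )
}
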