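# Censoring-adjusted survival evaluation metrics. All operate on a
# survival_curves object (common time grid, one curve per subject) plus the
# observed (time, event) pairs; the integrated squared error additionally
# needs the simulation oracle and is unavailable on real data.

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Fits the Kaplan-Meier estimator treating censorings (1 - delta) as the
#' events; the result supplies the inverse-probability-of-censoring weights.
#'
#' @param time,event Observed times and event indicators.
#' @return A `censoring_estimate`: step function with jump `times`, post-jump
#'   `surv` values, and `eval(t, left)` semantics via [eval_censoring()].
#' @export
km_censoring <- function(time, event) {
  stopifnot(length(time) >= 1)
  cens <- 1 - event
  ut <- sort(unique(time[cens == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & cens == 1), numeric(1))
  structure(list(times = ut, surv = cumprod(1 - d / n_risk)),
            class = "censoring_estimate")
}

#' Evaluate the censoring survival function
#'
#' @param G A `censoring_estimate`.
#' @param t Evaluation times.
#' @param left If `TRUE`, return the left limit G(t-) (the Graf convention at
#'   event times).
#' @return Vector of censoring survival probabilities.
#' @export
eval_censoring <- function(G, t, left = FALSE) {
  step_eval(G$times, G$surv, t, start = 1, left = left)
}

# Linearly interpolate every subject's curve at time t (constant beyond ends).
interp_weights <- function(grid, t) {
  G <- length(grid)
  k <- findInterval(t, grid, all.inside = TRUE)
  w2 <- (t - grid[k]) / (grid[k + 1] - grid[k])
  w2 <- pmin(pmax(w2, 0), 1)
  list(k = k, w1 = 1 - w2, w2 = w2)
}

interp_curves <- function(curves, t) {
  w <- interp_weights(curves$time_grid, t)
  if (length(t) == 1) {
    curves$surv[, w$k] * w$w1 + curves$surv[, w$k + 1] * w$w2
  } else {
    curves$surv[, w$k, drop = FALSE] * rep(w$w1, each = nrow(curves$surv)) +
      curves$surv[, w$k + 1, drop = FALSE] * rep(w$w2, each = nrow(curves$surv))
  }
}

#' Time-dependent concordance index
#'
#' Antolini's estimator: over comparable pairs (i, j) - subject i with an
#' event at t_i and subject j still at risk at t_i (t_i < t_j, or t_i = t_j
#' with j censored) - the proportion where the predicted survival at t_i
#' ranks i below j. Tied predictions score 1/2. Not a proper scoring rule;
#' reported for comparability.
#'
#' @param curves A `survival_curves` for the evaluated subjects.
#' @param time,event Observed outcomes.
#' @return Concordance in \[0, 1\].
#' @export
concordance_td <- function(curves, time, event) {
  n <- length(time)
  w <- interp_weights(curves$time_grid, time)
  # S_at[j, i] = predicted survival of subject j at subject i's time
  S_at <- curves$surv[, w$k, drop = FALSE] * rep(w$w1, each = n) +
    curves$surv[, w$k + 1, drop = FALSE] * rep(w$w2, each = n)
  comparable <- outer(event == 1, rep(TRUE, n)) &
    (outer(time, time, `<`) |
       (outer(time, time, `==`) & outer(event == 1, event == 0, `&`)))
  diag(comparable) <- FALSE
  if (!any(comparable)) stopf("no comparable pairs; concordance undefined")
  Si <- matrix(diag(S_at), n, n)          # S_i(t_i), by row
  Sj <- t(S_at)                            # S_j(t_i), row i col j
  score <- (Si < Sj) + 0.5 * (Si == Sj)
  sum(score[comparable]) / sum(comparable)
}

#' IPCW Brier score at a fixed horizon
#'
#' BS(t) = mean_i \[ S_hat(t|i)^2 1(t_i <= t, d_i = 1) / G(t_i-) +
#' (1 - S_hat(t|i))^2 1(t_i > t) / G(t) \]. With no censoring (G = 1) this is
#' the plain squared error against 1(T > t).
#'
#' @param curves A `survival_curves`.
#' @param time,event Observed outcomes.
#' @param t Horizon.
#' @param G A `censoring_estimate`; default fits on (time, event).
#' @return The Brier score at t.
#' @export
brier_ipcw <- function(curves, time, event, t, G = km_censoring(time, event)) {
  s_t <- interp_curves(curves, t)
  w_event <- as.numeric(time <= t & event == 1)
  w_alive <- as.numeric(time > t)
  G_ti <- eval_censoring(G, time, left = TRUE)
  G_t <- eval_censoring(G, t)
  if (any(w_event > 0 & G_ti <= 0) || (any(w_alive > 0) && G_t <= 0)) {
    stopf("censoring estimate is zero at a required time; truncate the grid")
  }
  mean(s_t^2 * w_event / pmax(G_ti, 1e-300) +
         (1 - s_t)^2 * w_alive / max(G_t, 1e-300))
}

#' Integrated Brier score
#'
#' Trapezoid average of [brier_ipcw()] over the curve grid (normalised by the
#' grid span).
#'
#' @inheritParams brier_ipcw
#' @param t_grid Integration grid; defaults to the curves' own grid.
#' @return The IBS.
#' @export
integrated_brier <- function(curves, time, event,
                             G = km_censoring(time, event),
                             t_grid = curves$time_grid) {
  bs <- vapply(t_grid, function(t) brier_ipcw(curves, time, event, t, G),
               numeric(1))
  trapz(t_grid, bs) / (max(t_grid) - min(t_grid))
}

#' Integrated negative binomial log-likelihood
#'
#' The binomial log-loss analogue of the IPCW Brier score, integrated over
#' the grid; predicted survival clipped to \[1e-7, 1 - 1e-7\].
#'
#' @inheritParams integrated_brier
#' @return The INBLL.
#' @export
inbll <- function(curves, time, event, G = km_censoring(time, event),
                  t_grid = curves$time_grid) {
  eps <- 1e-7
  nbll_at <- function(t) {
    s_t <- pmin(pmax(interp_curves(curves, t), eps), 1 - eps)
    w_event <- as.numeric(time <= t & event == 1)
    w_alive <- as.numeric(time > t)
    G_ti <- eval_censoring(G, time, left = TRUE)
    G_t <- eval_censoring(G, t)
    if (any(w_event > 0 & G_ti <= 0) || (any(w_alive > 0) && G_t <= 0)) {
      stopf("censoring estimate is zero at a required time; truncate the grid")
    }
    mean(-log(1 - s_t) * w_event / pmax(G_ti, 1e-300) -
           log(s_t) * w_alive / max(G_t, 1e-300))
  }
  vals <- vapply(t_grid, nbll_at, numeric(1))
  trapz(t_grid, vals) / (max(t_grid) - min(t_grid))
}

#' Negative right-censored log-likelihood
#'
#' The proper scoring rule: mean of -\[d log f(t) + (1 - d) log S(t)\]
#' evaluated at each subject's observed time. Uses the analytic density when
#' the curves carry one, otherwise central finite differences of the survival
#' curve; both floored at 1e-12.
#'
#' @param curves A `survival_curves` (with or without a `dens` component).
#' @param time,event Observed outcomes.
#' @return Mean negative log-likelihood.
#' @export
rcll <- function(curves, time, event) {
  n <- length(time)
  w <- interp_weights(curves$time_grid, time)
  at_own <- function(M) {
    M[cbind(seq_len(n), w$k)] * w$w1 + M[cbind(seq_len(n), w$k + 1)] * w$w2
  }
  s_obs <- pmax(at_own(curves$surv), 1e-12)
  f_obs <- if (!is.null(curves$dens)) {
    at_own(curves$dens)
  } else {
    grid <- curves$time_grid
    h <- diff(range(grid)) / (length(grid) - 1)
    lo <- pmax(time - h, grid[1]); hi <- pmin(time + h, grid[length(grid)])
    wl <- interp_weights(grid, lo); wh <- interp_weights(grid, hi)
    s_lo <- curves$surv[cbind(seq_len(n), wl$k)] * wl$w1 +
      curves$surv[cbind(seq_len(n), wl$k + 1)] * wl$w2
    s_hi <- curves$surv[cbind(seq_len(n), wh$k)] * wh$w1 +
      curves$surv[cbind(seq_len(n), wh$k + 1)] * wh$w2
    (s_lo - s_hi) / (hi - lo)
  }
  f_obs <- pmax(f_obs, 1e-12)
  mean(-(event * log(f_obs) + (1 - event) * log(s_obs)))
}

#' Integrated squared error against the simulation oracle
#'
#' Mean over subjects of the time-averaged squared discrepancy between the
#' true and predicted survival curves,
#' (1/(t_max - t_min)) int (S_true - S_hat)^2 dt, by trapezoid on the grid.
#' Only available when the ground truth is known (simulation).
#'
#' @param curves A `survival_curves` for the test subjects (in oracle order).
#' @param ground_truth A `survival_ground_truth`.
#' @param t_grid Integration grid; defaults to the curves' grid.
#' @return The ISE.
#' @export
ise <- function(curves, ground_truth, t_grid = curves$time_grid) {
  if (is.null(ground_truth)) {
    stopf("ISE needs the simulation oracle; unavailable on real data")
  }
  w <- interp_weights(curves$time_grid, t_grid)
  n <- nrow(curves$surv)
  S_hat <- curves$surv[, w$k, drop = FALSE] * rep(w$w1, each = n) +
    curves$surv[, w$k + 1, drop = FALSE] * rep(w$w2, each = n)
  S_true <- true_survival(ground_truth, seq_len(n), t_grid)
  sq <- (S_true - S_hat)^2
  span <- max(t_grid) - min(t_grid)
  mean(apply(sq, 1, function(row) trapz(t_grid, row))) / span
}

#' Evaluation grid from observed times
#'
#' 100 equally spaced points from 0 to the 90th percentile of the observed
#' times (the span where the censoring estimate stays well-behaved).
#'
#' @param time Observed times.
#' @param n_points Number of grid points.
#' @param upper_quantile Upper end of the grid.
#' @return Numeric grid.
#' @export
make_eval_grid <- function(time, n_points = 100, upper_quantile = 0.9) {
  seq(0, as.numeric(stats::quantile(time, upper_quantile)),
      length.out = n_points)
}

#' All five metrics for one prediction set
#'
#' @param curves Test-set `survival_curves`.
#' @param time,event Test outcomes.
#' @param ground_truth Optional simulation oracle (enables ISE).
#' @return Named numeric vector: `ctd`, `ibs`, `inbll`, `nll`, and `ise` when
#'   the oracle is present.
#' @export
evaluate_all <- function(curves, time, event, ground_truth = NULL) {
  G <- km_censoring(time, event)
  out <- c(ctd = concordance_td(curves, time, event),
           ibs = integrated_brier(curves, time, event, G),
           inbll = inbll(curves, time, event, G),
           nll = rcll(curves, time, event))
  if (!is.null(ground_truth)) {
    out <- c(out, ise = ise(curves, ground_truth))
  }
  out
}
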