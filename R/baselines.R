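#' Baseline missingness-handling strategy
#'
#' The nine comparison strategies benchmarked against the joint model. Each
#' turns an incomplete covariate matrix into one (or, for multiple
#' imputation, several) complete feature matrices that are fed to the
#' identical monotone survival head, so differences in downstream performance
#' are attributable to the missingness handling alone.
#'
#' * `CW` - column-wise deletion: keep only columns fully observed in training.
#' * `CW+M` - the CW columns plus the full p-length missingness mask.
#' * `Mean` - observed-training-mean fill (zero on the standardised scale).
#' * `RI` - per-column regression imputation on the other (mean-filled) columns.
#' * `ICE` - chained per-column regressions cycled to convergence.
#' * `MICE` - ICE with stochastic residual draws, `m` independent chains.
#' * `MICE_O` - MICE with outcome proxies (Nelson-Aalen cumulative hazard and
#'   event indicator) as extra predictors during fitting.
#' * `-1 Enc.` (`NegOneEnc`) - min-max rescale to \[0, 1\] from training,
#'   missing entries filled with the out-of-range constant -1.
#' * `MIM` - missing-indicator method: zero fill plus the mask appended,
#'   doubling the width to 2p.
#'
#' @param name Strategy name (see above; `"CW+M"` and `"CWM"` are accepted).
#' @param n_imputations Number of chains for the MICE variants.
#' @param max_sweeps,tol Chained-equation stopping rule: fixed sweep cap or
#'   relative change below `tol`, whichever first.
#' @return A `strategy_spec`.
#' @export
strategy_spec <- function(name, n_imputations = 5, max_sweeps = 10, tol = 1e-3) {
  canonical <- c(CW = "CW", `CW+M` = "CWM", CWM = "CWM", Mean = "Mean",
                 RI = "RI", ICE = "ICE", MICE = "MICE", MICE_O = "MICE_O",
                 `-1 Enc.` = "NegOneEnc", NegOneEnc = "NegOneEnc", MIM = "MIM")
  if (!name %in% names(canonical)) {
    stopf("unknown strategy '%s'; choose from %s", name,
          paste(unique(canonical), collapse = ", "))
  }
  structure(list(name = unname(canonical[name]), n_imputations = n_imputations,
                 max_sweeps = max_sweeps, tol = tol),
            class = "strategy_spec")
}

# Linear least squares with a tiny ridge for numerical safety.
ridge_coef <- function(X, y, lambda = 1e-8) {
  Xd <- cbind(1, X)
  A <- crossprod(Xd) + diag(lambda, ncol(Xd))
  drop(solve(A, crossprod(Xd, y)))
}

fit_column_regressions <- function(x_filled, x_tilde, extra = NULL) {
  p <- ncol(x_tilde)
  lapply(seq_len(p), function(j) {
    obs <- !is.na(x_tilde[, j])
    if (all(obs)) return(NULL)
    pred <- x_filled[obs, -j, drop = FALSE]
    if (!is.null(extra)) pred <- cbind(pred, extra[obs, , drop = FALSE])
    coef <- ridge_coef(pred, x_tilde[obs, j])
    fitted_vals <- drop(cbind(1, pred) %*% coef)
    list(coef = coef, resid_sd = stats::sd(x_tilde[obs, j] - fitted_vals))
  })
}

apply_column_regression <- function(reg, x_filled, j, extra = NULL) {
  pred <- x_filled[, -j, drop = FALSE]
  if (!is.null(extra)) pred <- cbind(pred, extra)
  drop(cbind(1, pred) %*% reg$coef)
}

# One chained-equations pass to convergence. `noise_fun(n, sd, j, sweep)`
# returns stochastic draws (zero for deterministic ICE).
chained_fill <- function(regs, x_tilde, max_sweeps, tol, extra = NULL,
                         noise_fun = NULL, refit = FALSE) {
  x <- x_tilde
  x[is.na(x)] <- 0
  for (sweep in seq_len(max_sweeps)) {
    prev <- x
    for (j in seq_len(ncol(x))) {
      mis <- is.na(x_tilde[, j])
      if (!any(mis)) next
      if (refit) {
        obs <- !mis
        pred <- x[obs, -j, drop = FALSE]
        if (!is.null(extra)) pred <- cbind(pred, extra[obs, , drop = FALSE])
        coef <- ridge_coef(pred, x_tilde[obs, j])
        rs <- stats::sd(x_tilde[obs, j] - drop(cbind(1, pred) %*% coef))
        regs[[j]] <- list(coef = coef, resid_sd = rs)
      }
      fill <- apply_column_regression(regs[[j]], x, j, extra)[mis]
      if (!is.null(noise_fun)) {
        fill <- fill + noise_fun(sum(mis), regs[[j]]$resid_sd, j, sweep)
      }
      x[mis, j] <- fill
    }
    delta <- sqrt(mean((x - prev)^2)) / max(stats::sd(x), 1e-12)
    if (delta < tol) break
  }
  list(x = x, regs = regs)
}

nelson_aalen_at <- function(time, event, eval_times) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, ctype = 1)
  step_eval(fit$time, fit$cumhaz, eval_times, start = 0)
}

#' Fit a missingness-handling strategy on training data
#'
#' Every parameter used at transform time (standardisation statistics,
#' regression coefficients, residual scales, retained columns, outcome-proxy
#' plug-in means) is learned here; [transform_strategy()] is a pure function
#' of these parameters and the new covariates. Only the `MICE_O` strategy may
#' see the outcome, and it must; all other strategies reject one.
#'
#' @param spec A [strategy_spec()].
#' @param train An `incomplete_dataset` (raw scale). Per the benchmarking
#'   protocol the MICE variants should be handed the concatenated
#'   training + validation data.
#' @param outcome For `MICE_O` only: list with `time` and `event` for the
#'   rows of `train`.
#' @param seed Seed for the stochastic chains.
#' @return A `fitted_strategy`.
#' @export
fit_strategy <- function(spec, train, outcome = NULL, seed = 1) {
  if (spec$name != "MICE_O" && !is.null(outcome)) {
    stopf("strategy %s must not receive the outcome (outcome firewall)", spec$name)
  }
  if (spec$name == "MICE_O" && is.null(outcome)) {
    stopf("MICE_O requires the outcome during fitting")
  }
  std <- fit_standardiser(train)
  xs <- standardise(std, train)$x_tilde
  x0 <- xs; x0[is.na(x0)] <- 0
  fitted <- list(spec = spec, standardiser = std,
                 feature_names = train$feature_names, uses_outcome = FALSE)

  fitted$extra <- switch(
    spec$name,
    CW = , CWM = {
      keep <- colSums(is.na(xs)) == 0
      if (!any(keep)) stopf("CW deletion leaves zero columns")
      list(keep = keep)
    },
    Mean = list(),
    MIM = list(),
    NegOneEnc = {
      rng <- std$max - std$min
      if (any(rng <= 0)) stopf("degenerate min-max range")
      list()
    },
    RI = list(regs = fit_column_regressions(x0, xs)),
    ICE = {
      cf <- chained_fill(vector("list", ncol(xs)), xs, spec$max_sweeps,
                         spec$tol, refit = TRUE)
      list(regs = cf$regs)
    },
    MICE = {
      chains <- lapply(seq_len(spec$n_imputations), function(cc) {
        noise <- function(nn, sd, j, sweep) {
          with_stream(seed, sprintf("mice_fit_c%d_s%d_j%d", cc, sweep, j),
                      stats::rnorm(nn, 0, sd))
        }
        chained_fill(vector("list", ncol(xs)), xs, spec$max_sweeps, spec$tol,
                     noise_fun = noise, refit = TRUE)$regs
      })
      list(chains = chains)
    },
    MICE_O = {
      na_hat <- nelson_aalen_at(outcome$time, outcome$event, outcome$time)
      extra <- cbind(cumhaz = na_hat, event = outcome$event)
      chains <- lapply(seq_len(spec$n_imputations), function(cc) {
        noise <- function(nn, sd, j, sweep) {
          with_stream(seed, sprintf("miceo_fit_c%d_s%d_j%d", cc, sweep, j),
                      stats::rnorm(nn, 0, sd))
        }
        chained_fill(vector("list", ncol(xs)), xs, spec$max_sweeps, spec$tol,
                     extra = extra, noise_fun = noise, refit = TRUE)$regs
      })
      # outcome proxies are unknown at deployment; plug in their training means
      list(chains = chains, extra_means = colMeans(extra))
    },
    stopf("unhandled strategy %s", spec$name)
  )
  if (spec$name == "MICE_O") fitted$uses_outcome <- TRUE
  fitted$seed <- seed
  structure(fitted, class = "fitted_strategy")
}

#' Apply a fitted strategy to new data
#'
#' @param fitted A `fitted_strategy`.
#' @param dataset An `incomplete_dataset` with the fitting schema.
#' @return A complete numeric feature matrix, or a list of
#'   `n_imputations` matrices for the MICE variants.
#' @export
transform_strategy <- function(fitted, dataset) {
  if (!identical(fitted$feature_names, dataset$feature_names)) {
    stopf("feature schema mismatch between fitted strategy and dataset")
  }
  spec <- fitted$spec
  xs <- standardise(fitted$standardiser, dataset)$x_tilde
  x0 <- xs; x0[is.na(x0)] <- 0
  switch(
    spec$name,
    CW = x0[, fitted$extra$keep, drop = FALSE],
    CWM = cbind(x0[, fitted$extra$keep, drop = FALSE], dataset$mask),
    Mean = x0,
    MIM = cbind(x0, dataset$mask),
    NegOneEnc = {
      std <- fitted$standardiser
      u <- sweep(sweep(dataset$x_tilde, 2, std$min, `-`), 2,
                 std$max - std$min, `/`)
      u[is.na(u)] <- -1
      u
    },
    RI = {
      x <- x0
      for (j in seq_len(ncol(x))) {
        mis <- is.na(xs[, j])
        if (!any(mis) || is.null(fitted$extra$regs[[j]])) next
        x[mis, j] <- apply_column_regression(fitted$extra$regs[[j]], x0, j)[mis]
      }
      x
    },
    ICE = chained_fill(fitted$extra$regs, xs, spec$max_sweeps, spec$tol)$x,
    MICE = lapply(seq_along(fitted$extra$chains), function(cc) {
      noise <- function(nn, sd, j, sweep) {
        with_stream(fitted$seed, sprintf("mice_tr_c%d_s%d_j%d", cc, sweep, j),
                    stats::rnorm(nn, 0, sd))
      }
      chained_fill(fitted$extra$chains[[cc]], xs, spec$max_sweeps, spec$tol,
                   noise_fun = noise)$x
    }),
    MICE_O = lapply(seq_along(fitted$extra$chains), function(cc) {
      extra <- matrix(fitted$extra$extra_means, nrow(xs), 2, byrow = TRUE)
      noise <- function(nn, sd, j, sweep) {
        with_stream(fitted$seed, sprintf("miceo_tr_c%d_s%d_j%d", cc, sweep, j),
                    stats::rnorm(nn, 0, sd))
      }
      chained_fill(fitted$extra$chains[[cc]], xs, spec$max_sweeps, spec$tol,
                   extra = extra, noise_fun = noise)$x
    })
  )
}

average_curves <- function(curve_list) {
  out <- curve_list[[1]]
  if (length(curve_list) > 1) {
    out$surv <- Reduce(`+`, lapply(curve_list, `[[`, "surv")) / length(curve_list)
    out$dens <- Reduce(`+`, lapply(curve_list, `[[`, "dens")) / length(curve_list)
  }
  out
}

#' Run one baseline strategy end to end on a scenario
#'
#' Fits the strategy on the training split (training + validation jointly for
#' the MICE variants, which also receive the outcome when `MICE_O`), trains
#' the shared survival head on the transformed features with early stopping
#' on the validation split, and predicts test-set survival curves. MICE
#' variants train one head per imputation and average the predicted curves
#' pointwise.
#'
#' @param spec A [strategy_spec()].
#' @param scenario A `scenario_bundle` from [build_scenario()].
#' @param t_grid Evaluation time grid.
#' @param config A [misscvae_config()]; the head settings (hidden widths,
#'   quadrature order, optimiser) are shared with the joint model.
#' @param seed Seed.
#' @return List: `curves` (test-set `survival_curves`), `fitted`, `heads`.
#' @export
run_strategy <- function(spec, scenario, t_grid, config = misscvae_config(),
                         seed = 1) {
  sp <- scenario$split
  mice_like <- spec$name %in% c("MICE", "MICE_O")
  fit_data <- if (mice_like) {
    idx_x <- rbind(sp$train$x_tilde, sp$validation$x_tilde)
    incomplete_dataset(idx_x, c(sp$train$time, sp$validation$time),
                       c(sp$train$event, sp$validation$event),
                       sp$train$feature_names)
  } else sp$train
  outcome <- if (spec$name == "MICE_O") {
    list(time = fit_data$time, event = fit_data$event)
  } else NULL
  fitted <- fit_strategy(spec, fit_data, outcome = outcome, seed = seed)

  ztr <- transform_strategy(fitted, sp$train)
  zva <- transform_strategy(fitted, sp$validation)
  zte <- transform_strategy(fitted, sp$test)
  if (!is.list(ztr)) { ztr <- list(ztr); zva <- list(zva); zte <- list(zte) }

  heads <- vector("list", length(ztr))
  curves <- vector("list", length(ztr))
  for (k in seq_along(ztr)) {
    heads[[k]] <- survhead_fit(ztr[[k]], sp$train$time, sp$train$event,
                               zva[[k]], sp$validation$time, sp$validation$event,
                               hidden = config$head_hidden,
                               quad_order = config$quad_order, lr = config$lr,
                               batch_size = config$batch_size,
                               epochs = config$epochs,
                               patience = config$patience,
                               seed = substream_seed(seed, paste0("imp", k)))
    curves[[k]] <- survhead_predict(heads[[k]], zte[[k]], t_grid)
  }
  list(curves = average_curves(curves), fitted = fitted, heads = heads)
}
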