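#' Calibration settings
#'
#' Settings shared by the per-animal fits. Positivity of `mu0`, `D` and `C`
#' is enforced by optimising on the log scale; the recovery switch `ts` is
#' optimised through a logistic transform onto `(0, horizon_days)`, so the
#' Nelder-Mead search is unconstrained.
#'
#' @param horizon_days fit window: only weighings at `t <= horizon_days` are
#'   used (default 75 d post-weaning).
#' @param multistart_ts_grid starting values for the recovery switch, days;
#'   the perturbed fit is started once from each and the best (weighted-J)
#'   solution wins, ties going to the smaller fitted `ts`.
#' @param n_restarts jittered restarts added around the best deterministic
#'   start, guarding against local minima of the piecewise-smooth objective.
#' @param max_iterations Nelder-Mead iteration cap per start.
#' @param convergence_tolerance relative convergence tolerance on the
#'   objective.
#' @param random_seed seed for the restart jitter; fixing it makes fits
#'   bit-reproducible.
#'
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(horizon_days = 75,
                               multistart_ts_grid = c(5, 10, 15, 20),
                               n_restarts = 2L,
                               max_iterations = 2000L,
                               convergence_tolerance = 1e-12,
                               random_seed = 20190516L) {
  stopifnot(horizon_days > 0,
            all(multistart_ts_grid > 0 & multistart_ts_grid < horizon_days),
            n_restarts >= 0, max_iterations > 0, convergence_tolerance > 0)
  structure(list(horizon_days = horizon_days,
                 multistart_ts_grid = multistart_ts_grid,
                 n_restarts = as.integer(n_restarts),
                 max_iterations = as.integer(max_iterations),
                 convergence_tolerance = convergence_tolerance,
                 random_seed = as.integer(random_seed)),
            class = "calibration_config")
}

#' Least-squares calibration objective
#'
#' Residual sum of squares between observed and predicted weights,
#' `J = sum((W_d - W)^2)` (kg^2), optionally weighted by the number of
#' measurements `n_t` (i.e. divided by `n_t`) so that animals weighed a
#' different number of times can be compared on a common scale.
#'
#' @param observed,predicted weight vectors of equal length, kg.
#' @param weighted if `TRUE`, divide the sum of squares by `n_t`.
#' @return The objective value, kg^2.
#' @export
#' @examples
#' objective_J(c(9, 10, 11), c(8, 11, 9))                  # 6
#' objective_J(c(9, 10, 11), c(8, 11, 9), weighted = TRUE) # 2
objective_J <- function(observed, predicted, weighted = FALSE) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have the same length", call. = FALSE)
  }
  J <- sum((observed - predicted)^2)
  if (weighted) J / length(observed) else J
}

#' Goodness of fit: r-squared and Lin's concordance correlation coefficient
#'
#' `r2 = 1 - SSE / SStot` with `SStot` about the observed mean, and Lin's
#' `CCC = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` using
#' population (1/n) moments. CCC penalises both dispersion and location
#' disagreement, so `CCC <= |Pearson r|` always.
#'
#' @param observed,predicted weight vectors of equal length (>= 3).
#' @return A list with `r2`, `ccc` and `pearson_r`. With zero variance in
#'   `observed`, `r2` and the correlations are `NA` (undefined).
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have the same length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 3L) stop("need at least 3 paired values", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    return(list(r2 = NA_real_, ccc = NA_real_, pearson_r = NA_real_))
  }
  mx <- mean(observed); my <- mean(predicted)
  vx <- mean((observed - mx)^2)
  vy <- mean((predicted - my)^2)
  sxy <- mean((observed - mx) * (predicted - my))
  ccc <- 2 * sxy / (vx + vy + (mx - my)^2)
  r <- if (vy == 0) NA_real_ else sxy / sqrt(vx * vy)
  list(r2 = 1 - sse / sstot, ccc = ccc, pearson_r = r)
}

#' AIC for least-squares calibration
#'
#' Akaike information criterion in the least-squares form
#' `AIC = n_t * log(J) + 2 * (n_p + 1)`, where `J` is the weighted
#' calibration objective (the residual sum of squares divided by `n_t`),
#' `n_t` the number of observations and `n_p` the number of estimated model
#' parameters (+1 for the error variance). With around 14 weighings per
#' animal the sample is far below the `n / k >= 40` rule of thumb, so by
#' default the small-sample corrected form is returned,
#' `AICc = AIC + 2 * (n_p + 1) * (n_p + 2) / (n_t - n_p)`; without the
#' correction the two extra parameters of the perturbed model are routinely
#' preferred on unperturbed animals. Smaller is better.
#'
#' @param J_weighted weighted objective value, kg^2; must be non-negative.
#' @param n_t number of observations.
#' @param n_p number of estimated parameters (2 for Gompertz, 4 for the
#'   perturbed model).
#' @param corrected apply the small-sample (AICc) correction (default
#'   `TRUE`).
#' @return The AIC; `-Inf` (with attribute `perfect_fit = TRUE`) when
#'   `J_weighted == 0`.
#' @export
compute_aic <- function(J_weighted, n_t, n_p, corrected = TRUE) {
  stopifnot(J_weighted >= 0, n_t > n_p)
  if (J_weighted == 0) {
    return(structure(-Inf, perfect_fit = TRUE))
  }
  aic <- n_t * log(J_weighted) + 2 * (n_p + 1)
  if (corrected) {
    aic <- aic + 2 * (n_p + 1) * (n_p + 2) / (n_t - n_p)
  }
  aic
}

# classed condition used when an animal has too few usable records;
# run_pipeline() catches these and flags the animal instead of aborting
skip_animal <- function(msg) {
  stop(structure(class = c("weanres_skip", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# restore the global RNG state on exit so fits do not perturb user RNG flow
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# shared Nelder-Mead driver: multiple starts, best-J wins (ties -> smaller
# fitted ts when a ts component is present), then the winner is polished by
# restarting Nelder-Mead from it until no further improvement.
# `tie_eps` is an absolute objective tolerance below which candidates are
# considered equivalent (kg^2 scale): fits agreeing with the data to far
# better than measurement precision are ties, whatever their sub-machine J.
run_nelder_mead <- function(objective, starts, cfg, ts_index = NA_integer_,
                            tie_eps = 0) {
  fit_one <- function(par) {
    stats::optim(par, objective, method = "Nelder-Mead",
                 control = list(maxit = cfg$max_iterations,
                                reltol = cfg$convergence_tolerance))
  }
  fits <- lapply(starts, fit_one)
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- which.min(vals)
  if (!is.na(ts_index)) {
    # near-ties: prefer the most parsimonious perturbation (smallest C),
    # then the smallest ts. C comes first because when the data carry no
    # perturbation the objective has a flat ridge (ts -> 0 with arbitrary C)
    # on which smaller ts alone would select an unbounded C.
    near <- which(vals <= max(vals[best] * (1 + 1e-9), vals[best] + tie_eps))
    if (length(near) > 1L) {
      c_vals <- vapply(fits[near], function(f) f$par[ts_index - 1L], numeric(1))
      ts_vals <- vapply(fits[near], function(f) f$par[ts_index], numeric(1))
      best <- near[order(c_vals, ts_vals)[1L]]
    }
  }
  fit <- fits[[best]]
  for (i in 1:3) {   # polish: NM restarts sharpen the collapsed simplex
    refit <- fit_one(fit$par)
    if (refit$value >= fit$value * (1 - 1e-14)) {
      if (refit$value < fit$value) fit <- refit
      break
    }
    fit <- refit
  }
  fit$n_starts <- length(starts)
  fit
}

# build the FitResult structure shared by all three fit entry points
make_fit_result <- function(model_name, params, traj_win, predicted,
                            n_p, converged, n_restarts_used) {
  n_t <- length(traj_win$times)
  J_raw <- objective_J(traj_win$weights, predicted, weighted = FALSE)
  J <- J_raw / n_t
  gof <- goodness_of_fit(traj_win$weights, predicted)
  structure(list(animal_id = traj_win$animal_id,
                 model_name = model_name,
                 params = params,
                 J = J, J_raw = J_raw,
                 r2 = gof$r2, ccc = gof$ccc,
                 aic = compute_aic(J, n_t, n_p),
                 n_t = n_t, n_p = n_p,
                 converged = converged,
                 n_restarts_used = n_restarts_used),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit for animal %s (n_t = %d): J = %.4g kg^2, r2 = %.4f, CCC = %.4f, AIC = %.2f%s\n",
              x$model_name, x$animal_id, x$n_t, x$J, x$r2, x$ccc, x$aic,
              if (!x$converged) " [not converged]" else ""))
  p <- x$params
  if (inherits(p, "perturbed_params")) {
    cat(sprintf("  mu0 = %.4g /d, D = %.4g /d, C = %.4g /d, ts = %.3f d\n",
                p$mu0, p$D, p$C, p$ts))
  } else {
    cat(sprintf("  mu0 = %.4g /d, D = %.4g /d\n", p$mu0, p$D))
  }
  invisible(x)
}

# restrict a trajectory to the fit window and check the weaning record
window_trajectory <- function(traj, horizon) {
  keep <- traj$times <= horizon
  times <- traj$times[keep]
  weights <- traj$weights[keep]
  if (length(times) == 0L || times[1L] != 0) {
    skip_animal(sprintf("animal %s has no weighing at t = 0", traj$animal_id))
  }
  list(animal_id = traj$animal_id, times = times, weights = weights)
}

#' Fit the classic Gompertz model to one animal
#'
#' `W0` is fixed at the observed weaning weight; `mu0` and `D` are estimated
#' by Nelder-Mead minimisation of the weighted least-squares objective on
#' weighings within the fit window.
#'
#' @param traj a [weight_trajectory()].
#' @param cfg a [calibration_config()].
#' @return A `fit_result` (model name `"gompertz"`, `n_p = 2`).
#' @export
fit_gompertz <- function(traj, cfg = calibration_config()) {
  stopifnot(inherits(traj, "weight_trajectory"))
  win <- window_trajectory(traj, cfg$horizon_days)
  if (length(win$times) < 4L) {
    skip_animal(sprintf("animal %s: %d weighings in window, need >= 4 for the Gompertz fit",
                        traj$animal_id, length(win$times)))
  }
  W0 <- win$weights[1L]
  obj <- function(theta) {
    p <- list(W0 = W0, mu0 = exp(theta[1L]), D = exp(theta[2L]))
    pred <- W0 * exp(p$mu0 / p$D * (1 - exp(-p$D * win$times)))
    objective_J(win$weights, pred, weighted = TRUE)
  }
  # data-driven start: average specific growth rate over the window
  t_end <- win$times[length(win$times)]
  mu_bar <- log(win$weights[length(win$weights)] / W0) / t_end
  mu0_init <- max(mu_bar * 1.3, 1e-5)
  starts <- list(c(log(0.05), log(0.02)),
                 c(log(mu0_init), log(0.02)))
  starts <- c(starts, with_preserved_seed(cfg$random_seed, {
    lapply(seq_len(cfg$n_restarts), function(i) {
      starts[[2L]] + stats::rnorm(2L, sd = 0.3)
    })
  }))
  fit <- run_nelder_mead(obj, starts, cfg)
  params <- gompertz_params(W0, exp(fit$par[1L]), exp(fit$par[2L]))
  make_fit_result("gompertz", params, win,
                  gompertz_weight(params, win$times),
                  n_p = 2L, converged = fit$convergence == 0L,
                  n_restarts_used = fit$n_starts)
}

#' Fit the perturbed (Gompertz-Makeham) model to one animal
#'
#' `W0` is fixed at the observed weaning weight; `mu0`, `D`, `C` and the
#' recovery switch `ts` are estimated by multi-start Nelder-Mead on the
#' weighted least-squares objective. `mu0`, `D`, `C` are log-transformed;
#' `ts` is mapped into `(0, horizon)` by a logistic transform. Starts combine
#' the animal's own Gompertz estimates (`C` initialised at 0.02 /d) with each
#' value of the `ts` grid, plus jittered restarts; the best objective wins,
#' ties broken towards the smaller `ts`.
#'
#' @inheritParams fit_gompertz
#' @return A `fit_result` (model name `"perturbed"`, `n_p = 4`).
#' @export
fit_perturbed <- function(traj, cfg = calibration_config()) {
  stopifnot(inherits(traj, "weight_trajectory"))
  win <- window_trajectory(traj, cfg$horizon_days)
  if (length(win$times) < 6L) {
    skip_animal(sprintf("animal %s: %d weighings in window, need >= 6 for the perturbed fit",
                        traj$animal_id, length(win$times)))
  }
  W0 <- win$weights[1L]
  H <- cfg$horizon_days
  obj <- function(theta) {
    mu0 <- exp(theta[1L]); D <- exp(theta[2L]); C <- exp(theta[3L])
    ts <- H * stats::plogis(theta[4L])
    pred <- W0 * exp(mu0 / D * (1 - exp(-D * win$times)) - C * pmin(win$times, ts))
    objective_J(win$weights, pred, weighted = TRUE)
  }
  # two (mu0, D) bases per ts start: the animal's own Gompertz estimates
  # (clamped away from the degenerate D -> 0 exponential limit that the
  # Gompertz fit reaches on strongly perturbed data) and canonical
  # piglet-scale values
  base_fit <- fit_gompertz(traj, cfg)
  th_own <- c(log(min(max(base_fit$params$mu0, 1e-4), 0.5)),
              log(min(max(base_fit$params$D, 0.004), 0.1)))
  bases <- list(th_own, c(log(0.05), log(0.02)))
  starts <- unlist(lapply(cfg$multistart_ts_grid, function(ts0) {
    lapply(bases, function(b) c(b, log(0.02), stats::qlogis(ts0 / H)))
  }), recursive = FALSE)
  starts <- c(starts, with_preserved_seed(cfg$random_seed, {
    lapply(seq_len(cfg$n_restarts), function(i) {
      starts[[1L]] + stats::rnorm(4L, sd = c(0.3, 0.3, 0.8, 0.8))
    })
  }))
  # candidates fitting to micro-kg precision are tied
  fit <- run_nelder_mead(obj, starts, cfg, ts_index = 4L,
                         tie_eps = (1e-6 * mean(win$weights))^2)
  params <- perturbed_params(W0, exp(fit$par[1L]), exp(fit$par[2L]),
                             exp(fit$par[3L]), H * stats::plogis(fit$par[4L]))
  make_fit_result("perturbed", params, win,
                  perturbed_weight(params, win$times),
                  n_p = 4L, converged = fit$convergence == 0L,
                  n_restarts_used = fit$n_starts)
}

#' Select the unperturbed calibration subset
#'
#' Returns the weaning weighing (t = 0) plus the last four records within the
#' horizon, i.e. the five points (`n_t = 5`) used to approximate the growth
#' curve an animal would have followed without the weaning perturbation.
#'
#' @param traj a [weight_trajectory()].
#' @param horizon fit window in days (default 75).
#' @return A [weight_trajectory()] with exactly 5 records.
#' @export
#' @examples
#' tr <- weight_trajectory("A1", c(0, 3, 7, 14, 21, 28, 35, 42, 49, 56, 63, 70, 77),
#'                         seq(8.9, by = 1, length.out = 13))
#' select_unperturbed_subset(tr)$times  # 0 49 56 63 70
select_unperturbed_subset <- function(traj, horizon = 75) {
  stopifnot(inherits(traj, "weight_trajectory"))
  keep <- traj$times <= horizon
  times <- traj$times[keep]
  weights <- traj$weights[keep]
  if (length(times) == 0L || times[1L] != 0) {
    skip_animal(sprintf("animal %s has no weighing at t = 0", traj$animal_id))
  }
  post <- which(times > 0)
  if (length(post) < 4L) {
    skip_animal(sprintf("animal %s: %d post-weaning records in window, need >= 4",
                        traj$animal_id, length(post)))
  }
  idx <- c(1L, utils::tail(post, 4L))
  weight_trajectory(traj$animal_id, times[idx], weights[idx])
}

#' Fit the unperturbed reference curve
#'
#' A Gompertz fit restricted to [select_unperturbed_subset()]: the weaning
#' weight anchors the start and the last four weighings within the horizon
#' anchor the end, so the fitted curve approximates the trajectory of an
#' animal not experiencing the weaning perturbation.
#'
#' @inheritParams fit_gompertz
#' @return A `fit_result` (model name `"unperturbed_reference"`, `n_p = 2`).
#' @export
fit_unperturbed_reference <- function(traj, cfg = calibration_config()) {
  sub <- select_unperturbed_subset(traj, cfg$horizon_days)
  fit <- fit_gompertz(sub, cfg)
  fit$model_name <- "unperturbed_reference"
  fit
}

#' Rank animals by Gompertz lack of fit
#'
#' The weighted residual sum of squares `J` of the classic Gompertz fit is a
#' first proxy for perturbation severity: the worse the monotone Gompertz
#' curve fits, the deeper the post-weaning growth check. Rank 1 is the most
#' perturbed animal; equal `J` shares a dense rank; row order is made
#' deterministic by breaking ties on `animal_id`.
#'
#' @param fits a list of `fit_result`s, or a data frame with columns
#'   `animal_id` and `J`.
#' @return A data frame `animal_id`, `J`, `J_rank` sorted by decreasing `J`.
#' @export
rank_by_J <- function(fits) {
  df <- if (is.data.frame(fits)) {
    fits[, c("animal_id", "J")]
  } else {
    data.frame(animal_id = vapply(fits, `[[`, character(1), "animal_id"),
               J = vapply(fits, `[[`, numeric(1), "J"))
  }
  df <- df[order(-df$J, df$animal_id), , drop = FALSE]
  df$J_rank <- match(df$J, sort(unique(df$J), decreasing = TRUE))
  rownames(df) <- NULL
  df
}
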