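#' Gompertz body weight
#'
#' Closed-form body weight under the classic Gompertz law,
#' `W(t) = W0 * exp((mu0 / D) * (1 - exp(-D * t)))`, whose specific growth
#' rate decays exponentially from `mu0` at rate `D`. The curve rises from
#' `W0` at weaning towards the mature-weight asymptote `W0 * exp(mu0 / D)`.
#'
#' @param p a [gompertz_params()] (a [perturbed_params()] is accepted; its
#'   `C` and `ts` are ignored).
#' @param t days since weaning, non-negative (vectorised).
#'
#' @return Body weight in kg, same length as `t`.
#' @export
#' @examples
#' p <- gompertz_params(8.91, 0.05, 0.02)
#' gompertz_weight(p, c(0, 30, 75))
gompertz_weight <- function(p, t) {
  stopifnot(inherits(p, c("gompertz_params", "perturbed_params")))
  check_nonneg_times(t)
  p$W0 * exp(p$mu0 / p$D * (1 - exp(-p$D * t)))
}

#' Specific growth rate
#'
#' The relative growth rate `mu(t) = mu0 * exp(-D * t)` shared by the
#' Gompertz and the perturbed model (the perturbation term `C` acts on the
#' weight dynamics, not on `mu` itself).
#'
#' @inheritParams gompertz_weight
#' @return Specific growth rate in 1/day, same length as `t`.
#' @export
specific_growth_rate <- function(p, t) {
  stopifnot(inherits(p, c("gompertz_params", "perturbed_params")))
  check_nonneg_times(t)
  p$mu0 * exp(-p$D * t)
}

#' Perturbed (Gompertz-Makeham) body weight
#'
#' Closed-form body weight under the piecewise perturbed growth model. During
#' the perturbation window `t <= ts` the specific growth rate is reduced by
#' the constant `C`, so
#' `W(t) = W0 * exp((mu0 / D) * (1 - exp(-D t)) - C * t)`;
#' after the recovery switch the deduction stops and
#' `W(t) = W(ts) * exp((mu0 / D) * (exp(-D ts) - exp(-D t)))`.
#' Both branches combine into
#' `W(t) = W0 * exp((mu0 / D) * (1 - exp(-D t)) - C * min(t, ts))`, which is
#' continuous at `ts` by construction. With `C = 0` the curve is identical to
#' [gompertz_weight()]. Weight falls while `mu(t) < C`, so early weight loss
#' is produced whenever `C > mu0`.
#'
#' @param p a [perturbed_params()].
#' @param t days since weaning, non-negative (vectorised).
#' @return Body weight in kg, same length as `t`.
#' @export
#' @examples
#' p <- perturbed_params(8.91, 0.05, 0.02, C = 0.08, ts = 9)
#' perturbed_weight(p, c(0, 1, 9, 30))  # dips below W0, then recovers
perturbed_weight <- function(p, t) {
  stopifnot(inherits(p, "perturbed_params"))
  check_nonneg_times(t)
  p$W0 * exp(p$mu0 / p$D * (1 - exp(-p$D * t)) - p$C * pmin(t, p$ts))
}

#' Numerical ODE reference trajectory for the perturbed model
#'
#' Integrates the underlying two-equation system
#' `dW/dt = (mu - C(t)) * W`, `dmu/dt = -D * mu` with
#' `C(t) = C` for `t <= ts` and `0` afterwards, using a stiff-capable solver
#' at tight tolerance. The recovery switch is an integration breakpoint: the
#' solver is run on `[0, ts]` and restarted on `[ts, max(t)]`, never stepping
#' across the discontinuity. This is the independent oracle against which the
#' closed forms are validated; the closed forms are the production path.
#'
#' @param p a [perturbed_params()].
#' @param times evaluation grid, days since weaning; non-negative, strictly
#'   increasing.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return Body weights in kg at `times`.
#' @export
integrate_ode_oracle <- function(p, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "perturbed_params"))
  check_time_grid(times)
  deriv <- function(t, y, parms) {
    list(c(W = (y[["mu"]] - parms$C_active) * y[["W"]],
           mu = -parms$D * y[["mu"]]))
  }
  y0 <- c(W = p$W0, mu = p$mu0)
  out <- numeric(length(times))

  run_segment <- function(y_start, seg_times, C_active) {
    if (length(seg_times) < 2L) {
      return(matrix(c(seg_times, y_start[1L], y_start[2L]), nrow = 1L,
                    dimnames = list(NULL, c("time", "W", "mu"))))
    }
    sol <- deSolve::ode(y = y_start, times = seg_times, func = deriv,
                        parms = list(C_active = C_active, D = p$D),
                        method = "lsoda", rtol = rtol, atol = atol)
    if (anyNA(sol[, "W"])) {
      stop(sprintf(
        "ODE integration failed for W0=%g mu0=%g D=%g C=%g ts=%g",
        p$W0, p$mu0, p$D, p$C, p$ts), call. = FALSE)
    }
    sol
  }

  pre <- times[times <= p$ts]
  post <- times[times > p$ts]

  # perturbation window: start at 0 and stop exactly at ts
  seg1_times <- sort(unique(c(0, pre, p$ts)))
  sol1 <- run_segment(y0, seg1_times, C_active = p$C)
  if (length(pre)) {
    out[times <= p$ts] <- sol1[match(pre, sol1[, "time"]), "W"]
  }

  if (length(post)) {
    y_ts <- c(W = unname(sol1[nrow(sol1), "W"]),
              mu = unname(sol1[nrow(sol1), "mu"]))
    seg2_times <- c(p$ts, post)
    sol2 <- run_segment(y_ts, seg2_times, C_active = 0)
    out[times > p$ts] <- sol2[match(post, sol2[, "time"]), "W"]
  }
  out
}

check_nonneg_times <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative", call. = FALSE)
  }
  invisible(t)
}
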