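#' Gompertz growth-law parameters
#'
#' Parameter vector for the classic Gompertz growth law in its
#' specific-growth-rate parameterisation, in which the specific growth rate
#' decays exponentially from its value at weaning.
#'
#' @param W0 live weight at weaning (t = 0), kg; must be positive.
#' @param mu0 initial specific growth rate, per day; must be non-negative.
#' @param D decay coefficient of the specific growth rate, per day; must be
#'   positive.
#'
#' @return An object of class `gompertz_params`: a named list with elements
#'   `W0`, `mu0`, `D`.
#' @seealso [perturbed_params()], [gompertz_weight()]
#' @export
#' @examples
#' gompertz_params(W0 = 8.91, mu0 = 0.05, D = 0.02)
gompertz_params <- function(W0, mu0, D) {
  check_scalar(W0, "W0", lower = 0, strict = TRUE)
  check_scalar(mu0, "mu0", lower = 0, strict = FALSE)
  check_scalar(D, "D", lower = 0, strict = TRUE)
  structure(list(W0 = W0, mu0 = mu0, D = D), class = "gompertz_params")
}

#' Perturbed (Gompertz-Makeham) growth-law parameters
#'
#' Extends [gompertz_params()] with a perturbation coefficient `C`, deducted
#' from the specific growth rate during the perturbation window, and a
#' recovery-switch time `ts` after which the deduction is switched off and
#' classic Gompertz growth resumes.
#'
#' @inheritParams gompertz_params
#' @param C perturbation coefficient, per day; non-negative. `C = 0` reduces
#'   the model to the classic Gompertz law.
#' @param ts recovery-switch time, days since weaning; must be positive and
#'   finite.
#'
#' @return An object of class `perturbed_params`: a named list with elements
#'   `W0`, `mu0`, `D`, `C`, `ts`.
#' @export
#' @examples
#' perturbed_params(W0 = 8.91, mu0 = 0.05, D = 0.02, C = 0.08, ts = 9)
perturbed_params <- function(W0, mu0, D, C, ts) {
  check_scalar(W0, "W0", lower = 0, strict = TRUE)
  check_scalar(mu0, "mu0", lower = 0, strict = FALSE)
  check_scalar(D, "D", lower = 0, strict = TRUE)
  check_scalar(C, "C", lower = 0, strict = FALSE)
  check_scalar(ts, "ts", lower = 0, strict = TRUE)
  structure(list(W0 = W0, mu0 = mu0, D = D, C = C, ts = ts),
            class = "perturbed_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz parameters: W0 = %.4g kg, mu0 = %.4g /d, D = %.4g /d\n",
              x$W0, x$mu0, x$D))
  invisible(x)
}

#' @export
print.perturbed_params <- function(x, ...) {
  cat(sprintf(
    "Perturbed (Gompertz-Makeham) parameters: W0 = %.4g kg, mu0 = %.4g /d, D = %.4g /d, C = %.4g /d, ts = %.4g d\n",
    x$W0, x$mu0, x$D, x$C, x$ts))
  invisible(x)
}

# scalar domain check shared by the constructors
check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("`%s` must be %s %g (got %g)", name,
                 if (strict) ">" else ">=", lower, x), call. = FALSE)
  }
  invisible(TRUE)
}

# time grids: non-negative, strictly increasing, duplicate-free
check_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times) ||
      any(!is.finite(times))) {
    stop("`times` must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing with no duplicates",
         call. = FALSE)
  }
  invisible(times)
}

#' One animal's body-weight trajectory
#'
#' @param animal_id identifier (coerced to character).
#' @param times days since weaning; non-negative, strictly increasing; the
#'   first time must be 0 (the weaning weighing).
#' @param weights body weights, kg; positive, same length as `times`.
#'
#' @return An object of class `weight_trajectory`.
#' @export
#' @examples
#' weight_trajectory("A001", c(0, 3, 7), c(8.9, 8.7, 9.2))
weight_trajectory <- function(animal_id, times, weights) {
  check_time_grid(times)
  if (length(weights) != length(times)) {
    stop("`times` and `weights` must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a trajectory needs at least 2 observations", call. = FALSE)
  }
  if (times[1L] != 0) {
    stop("the first observation must be at t = 0 (the weaning weighing)",
         call. = FALSE)
  }
  if (anyNA(weights) || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("`weights` must be finite and positive", call. = FALSE)
  }
  structure(list(animal_id = as.character(animal_id)[1L],
                 times = as.numeric(times),
                 weights = as.numeric(weights)),
            class = "weight_trajectory")
}

#' @export
print.weight_trajectory <- function(x, ...) {
  cat(sprintf("Weight trajectory for animal %s: %d weighings over %g d (%.2f -> %.2f kg)\n",
              x$animal_id, length(x$times), max(x$times),
              x$weights[1L], x$weights[length(x$weights)]))
  invisible(x)
}
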