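#' Plot an animal's observed weights and fitted curves
#'
#' Observed weighings as points, with any of the classic Gompertz fit (solid),
#' the perturbed fit (dashed) and the unperturbed reference curve (dotted)
#' overlaid, in the layout conventional for perturbed-growth studies.
#'
#' @param traj a [weight_trajectory()].
#' @param gompertz,perturbed,reference optional `fit_result`s to overlay.
#' @param horizon right edge of the time axis, days.
#' @return Invisibly, `NULL`. Called for its base-graphics side effect.
#' @export
plot_growth_fit <- function(traj, gompertz = NULL, perturbed = NULL,
                            reference = NULL, horizon = 75) {
  stopifnot(inherits(traj, "weight_trajectory"))
  keep <- traj$times <= horizon
  tt <- seq(0, horizon, length.out = 301)
  curves <- list()
  if (!is.null(gompertz)) curves$Gompertz <-
    list(w = gompertz_weight(gompertz$params, tt), lty = 1)
  if (!is.null(perturbed)) curves$Perturbed <-
    list(w = perturbed_weight(perturbed$params, tt), lty = 2)
  if (!is.null(reference)) curves$Unperturbed <-
    list(w = gompertz_weight(reference$params, tt), lty = 3)

  ylim <- range(traj$weights[keep],
                unlist(lapply(curves, `[[`, "w")), na.rm = TRUE)
  plot(traj$times[keep], traj$weights[keep], xlab = "Days since weaning",
       ylab = "Body weight (kg)", ylim = ylim,
       main = sprintf("Animal %s", traj$animal_id))
  for (nm in names(curves)) {
    graphics::lines(tt, curves[[nm]]$w, lty = curves[[nm]]$lty)
  }
  if (length(curves)) {
    graphics::legend("topleft", bty = "n",
                     legend = c("Observed", names(curves)),
                     pch = c(1, rep(NA, length(curves))),
                     lty = c(NA, vapply(curves, `[[`, numeric(1), "lty")))
  }
  invisible(NULL)
}
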