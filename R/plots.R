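#' Plot thresholds versus relative phase
#'
#' Mirrors the phase-dependence summary panel: leading- and trailing-edge
#' thresholds against relative phase, with the baseline threshold as a
#' dashed line.
#'
#' @param exp Result of \code{\link{experiment_phase_dependence}}.
#' @return Invisibly, the summary data.frame plotted.
#' @export
plot_phase_summary <- function(exp) {
  s <- exp$summary
  phases <- exp$phases
  lead <- s$threshold[match(sprintf("leading_phase_%.3g", phases),
                            s$condition)]
  trail <- s$threshold[match(sprintf("trailing_phase_%.3g", phases),
                             s$condition)]
  ylim <- range(c(lead, trail, exp$baseline_threshold)) * c(0.9, 1.1)
  graphics::plot(phases, trail, type = "b", col = "red", pch = 16,
                 ylim = ylim, xaxt = "n", log = "y",
                 xlab = "relative phase (rad)",
                 ylab = "threshold (% Michelson)",
                 main = "Phase dependence")
  graphics::axis(1, at = phases,
                 labels = c("0", expression(pi / 2), expression(pi),
                            expression(3 * pi / 2))[seq_along(phases)])
  graphics::lines(phases, lead, type = "b", col = "black", pch = 16)
  graphics::abline(h = exp$baseline_threshold, lty = 2)
  graphics::legend("topleft", c("trailing", "leading", "baseline"),
                   col = c("red", "black", "grey30"), lty = c(1, 1, 2),
                   pch = c(16, 16, NA), bty = "n", cex = 0.8)
  invisible(s)
}

#' Plot an interference-profile experiment against its theoretical profile
#'
#' Thresholds versus target offset for the two starting phases, with the
#' forward model's predicted relative threshold overlaid (scaled to the
#' baseline threshold).
#'
#' @param exp Result of \code{\link{experiment_interference_profile}}.
#' @return Invisibly, the empirical data.frame plotted.
#' @export
plot_profile_experiment <- function(exp) {
  emp <- exp$empirical
  cols <- c("black", "darkgreen")
  ylim <- range(emp$threshold, na.rm = TRUE) * c(0.9, 1.1)
  graphics::plot(NA, xlim = range(emp$offset), ylim = ylim, log = "y",
                 xlab = "target offset (deg)",
                 ylab = "threshold (% Michelson)",
                 main = sprintf("Interference profile, theta = %g deg",
                                exp$theta))
  for (i in seq_along(exp$target_phases)) {
    ph <- exp$target_phases[i]
    sub <- emp[emp$phase == ph, ]
    graphics::points(sub$offset, sub$threshold, col = cols[i], pch = 16)
    theo <- exp$theoretical[[i]]
    graphics::lines(theo$offsets,
                    theo$predicted_threshold_factor *
                      min(sub$threshold, na.rm = TRUE) /
                      min(theo$predicted_threshold_factor),
                    col = cols[i])
  }
  invisible(emp)
}

#' Plot a sweep experiment's threshold-difference curve and exponential fit
#'
#' @param x Swept values.
#' @param curve The sweep's curve data.frame (with a \code{difference}
#'   column).
#' @param fit The sweep's \code{exponential_fit}.
#' @param xlab Axis label naming the swept variable and its unit.
#' @return Invisibly, \code{curve}.
#' @export
plot_sweep <- function(x, curve, fit, xlab) {
  graphics::plot(x, curve$difference, pch = 16,
                 xlab = xlab, ylab = "antiphase - inphase threshold (%)",
                 main = if (fit$form == "saturating")
                   sprintf("half constant = %.3g %s", fit$half_constant,
                           fit$units)
                 else sprintf("space constant = %.3g %s",
                              fit$efold_constant, fit$units))
  xs <- seq(min(x), max(x), length.out = 200)
  graphics::lines(xs, predict(fit, xs), col = "blue")
  invisible(curve)
}

#' Export a space-time slice as a PNG image
#'
#' Renders a (space, time) luminance slice (see
#' \code{\link{space_time_profile}}) as a grayscale image, the standard
#' space-time plot of a drifting stimulus.
#'
#' @param slice Matrix from \code{\link{space_time_profile}}.
#' @param path PNG file path.
#' @param main Plot title.
#' @return \code{path}, invisibly.
#' @export
export_space_time_png <- function(slice, path, main = "space-time profile") {
  grDevices::png(path, width = 800, height = 600, res = 120)
  on.exit(grDevices::dev.off())
  graphics::image(attr(slice, "time"), attr(slice, "space"), t(slice),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  xlab = "time (s)", ylab = "space (deg)", main = main,
                  useRaster = TRUE)
  invisible(path)
}
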