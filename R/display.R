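#' One trial's display geometry: target, inducer and their relation
#'
#' Describes a composite display in which a small target grating abuts (or is
#' separated by a gap from) the leading or trailing edge of a large drifting
#' inducer grating, or is shown alone (baseline). The leading edge is the
#' inducer border its pattern drifts toward; the trailing edge is the border
#' it drifts away from. The relative phase is defined at the shared border as
#' the phase advance of the target over the analytic continuation
#' (extrapolation) of the inducer waveform in space and time: 0 is in phase,
#' pi is antiphase.
#'
#' The canonical composed geometry puts the drift axis along y (horizontal
#' bars, orientation 90), the target centered at the origin, and the inducer
#' beyond the target's border; \code{target_offset} displaces the target
#' along the border (the x axis). Eye assignment and the side of fixation are
#' carried as metadata for the observer model; dichoptic means target and
#' inducer go to different eyes.
#'
#' @param target,inducer \code{\link{grating_params}} for the two patches.
#'   With a non-baseline edge the two must share spatial and temporal
#'   frequency (after accounting for \code{relative_orientation_theta}).
#' @param edge "leading", "trailing" or "baseline" (inducer absent).
#' @param relative_phase Radians; phase advance of the target relative to the
#'   extrapolated inducer waveform at the shared border.
#' @param relative_orientation_theta Degrees; rotation of the inducer's
#'   orientation relative to the target's (0 for collinear displays).
#' @param gap Degrees >= 0 between inducer border and target border; 0 means
#'   the patches abut (shared border, no overlap).
#' @param inducer_length Degrees; inducer extent along its drift axis.
#' @param duration Seconds > 0; presentation duration of all stimuli.
#' @param target_offset Degrees, signed; center-to-center displacement of the
#'   target along the inducer edge.
#' @param eye_target,eye_inducer "left" or "right".
#' @param target_side Side of fixation the target appears on (metadata).
#' @param line_cues_arcmin Baseline-only metadata: length of the thin line
#'   cues marking the would-be inducer edges (no luminance modulation).
#' @return A \code{display_config} object.
#' @examples
#' cfg <- display_config(edge = "leading", relative_phase = pi)
#' cfg
#' @export
display_config <- function(target = grating_params(width = 1, height = 1,
                                                   orientation = 90,
                                                   contrast = 0.05),
                           inducer = grating_params(width = 1, height = 6.67,
                                                    orientation = 90,
                                                    contrast = 1),
                           edge = c("leading", "trailing", "baseline"),
                           relative_phase = 0,
                           relative_orientation_theta = 0,
                           gap = 0,
                           inducer_length = inducer$height,
                           duration = 1,
                           target_offset = 0,
                           eye_target = c("left", "right"),
                           eye_inducer = eye_target,
                           target_side = c("left", "right"),
                           line_cues_arcmin = 2) {
  edge <- match.arg(edge)
  eye_target <- match.arg(eye_target)
  eye_inducer <- match.arg(eye_inducer, c("left", "right"))
  target_side <- match.arg(target_side)
  stopifnot(inherits(target, "grating_params"))
  if (gap < 0) stop("gap must be >= 0 (patches tile; they may not overlap)")
  if (duration <= 0) stop("duration must be > 0")
  if (inducer_length <= 0) stop("inducer_length must be > 0")
  if (edge != "baseline") {
    stopifnot(inherits(inducer, "grating_params"))
    if (abs(target$spatial_frequency - inducer$spatial_frequency) > 1e-9 ||
        abs(target$temporal_frequency - inducer$temporal_frequency) > 1e-9)
      stop("target and inducer must share spatial and temporal frequency")
  }
  structure(list(target = target, inducer = inducer, edge = edge,
                 relative_phase = relative_phase,
                 relative_orientation_theta = relative_orientation_theta,
                 gap = gap, inducer_length = inducer_length,
                 duration = duration, target_offset = target_offset,
                 eye_target = eye_target, eye_inducer = eye_inducer,
                 target_side = target_side,
                 line_cues_arcmin = line_cues_arcmin),
            class = "display_config")
}

#' @export
print.display_config <- function(x, ...) {
  cat(sprintf("Display: %s edge, relative phase %.3g rad, theta %.3g deg\n",
              x$edge, x$relative_phase, x$relative_orientation_theta))
  cat(sprintf("  gap %.3g deg, inducer length %.3g deg, duration %.3g s, offset %.3g deg\n",
              x$gap, x$inducer_length, x$duration, x$target_offset))
  cat(sprintf("  eyes: target %s, inducer %s (%s)\n", x$eye_target,
              x$eye_inducer,
              if (identical(x$eye_target, x$eye_inducer)) "monocular" else "dichoptic"))
  invisible(x)
}

#' Is a display dichoptic (target and inducer in different eyes)?
#' @param config A \code{\link{display_config}}.
#' @return Logical.
#' @export
is_dichoptic <- function(config) {
  stopifnot(inherits(config, "display_config"))
  !identical(config$eye_target, config$eye_inducer)
}

#' Render a display configuration into a space-time luminance field
#'
#' Places the target and inducer patches in one sampled field so that the
#' target abuts (or sits \code{gap} degrees beyond) the inducer's leading or
#' trailing edge. The target's phase is anchored to the analytic continuation
#' of the inducer waveform at the target location, advanced by
#' \code{relative_phase}; with an in-phase leading-edge display the waveform
#' therefore crosses the border continuously (up to the contrast scaling
#' between patches), and with a gap the inducer phase is continued across the
#' gap so in-phase targets remain consistent with extrapolation in space and
#' time. Baseline displays contain the target alone (line cues are metadata
#' only and carry no luminance).
#'
#' @param config A \code{\link{display_config}}.
#' @param grid_spacing,time_step Sampling; defaults as in
#'   \code{\link{make_grating}}.
#' @param duration Sampled duration in seconds (default
#'   \code{config$duration}, capped at 0.5 s for memory sanity).
#' @return A \code{space_time_pattern} covering both patches.
#' @export
compose_display <- function(config, grid_spacing = NULL, time_step = 0.01,
                            duration = min(config$duration, 0.5)) {
  stopifnot(inherits(config, "display_config"))
  tg <- config$target
  drift_axis_up <- tg$drift_sign  # +1: pattern drifts toward +y
  t_half <- tg$height / 2
  # target center, displaced along the border (x) by target_offset
  t_center <- c(config$target_offset, 0)

  if (config$edge == "baseline") {
    return(make_grating(tg, duration = duration, grid_spacing = grid_spacing,
                        time_step = time_step, center = t_center))
  }

  ind <- config$inducer
  ind <- grating_params(spatial_frequency = ind$spatial_frequency,
                        temporal_frequency = ind$temporal_frequency,
                        orientation = tg$orientation +
                          config$relative_orientation_theta,
                        phase = ind$phase, contrast = ind$contrast,
                        width = ind$width, height = config$inducer_length,
                        drift_sign = ind$drift_sign,
                        mean_luminance = ind$mean_luminance)
  i_half <- config$inducer_length / 2
  # leading edge: the inducer drifts toward the target, so the inducer sits on
  # the side the drift departs from; trailing: the opposite side.
  side <- if (config$edge == "leading") -drift_axis_up else drift_axis_up
  i_center <- c(0, side * (t_half + config$gap + i_half))

  if (is.null(grid_spacing))
    grid_spacing <- 1 / (64 * max(tg$spatial_frequency,
                                  ind$spatial_frequency))
  ext <- c(min(t_center[1] - tg$width / 2, i_center[1] - ind$width / 2),
           max(t_center[1] + tg$width / 2, i_center[1] + ind$width / 2),
           min(t_center[2] - t_half, i_center[2] - i_half),
           max(t_center[2] + t_half, i_center[2] + i_half))

  base <- make_grating(ind, extent = ext, duration = duration,
                       grid_spacing = grid_spacing, time_step = time_step,
                       center = i_center)
  # target phase: extrapolated inducer phase at the target center, advanced
  # by relative_phase; the sine argument is global so continuity at the
  # border (and across any gap) follows for relative_phase = 0.
  f <- base$field
  inx <- which(base$x >= t_center[1] - tg$width / 2 - 1e-12 &
                 base$x <= t_center[1] + tg$width / 2 + 1e-12)
  iny <- which(base$y >= t_center[2] - t_half - 1e-12 &
                 base$y <= t_center[2] + t_half + 1e-12)
  gx <- rep(base$x[inx], times = length(iny))
  gy <- rep(base$y[iny], each = length(inx))
  # inducer sine argument, extrapolated to the target center at t = 0
  th_i <- ind$orientation * pi / 180
  u_ic <- (t_center[1] - i_center[1]) * cos(th_i) +
    (t_center[2] - i_center[2]) * sin(th_i)
  arg_at_center <- 2 * pi * ind$spatial_frequency * u_ic + ind$phase
  phantom <- grating_params(spatial_frequency = tg$spatial_frequency,
                            temporal_frequency = tg$temporal_frequency,
                            orientation = tg$orientation,
                            phase = arg_at_center + config$relative_phase,
                            contrast = tg$contrast,
                            width = tg$width, height = tg$height,
                            drift_sign = tg$drift_sign,
                            mean_luminance = tg$mean_luminance)
  for (k in seq_along(base$t)) {
    f[inx, iny, k] <- grating_luminance(phantom, gx, gy, base$t[k],
                                        reference = t_center)
  }
  space_time_pattern(f, x = base$x, y = base$y, t = base$t,
                     grid_spacing = base$grid_spacing,
                     time_step = base$time_step, origin = c(0, 0),
                     mean_luminance = tg$mean_luminance)
}
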