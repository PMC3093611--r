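#' Extrapolate an inducer grating beyond its leading edge
#'
#' Continues the inducer's waveform (same spatial frequency, temporal
#' frequency, orientation and phase trajectory) into a region beyond its
#' border, at unit prediction amplitude; any gap between inducer and region is
#' crossed by the analytic continuation, so the extrapolated phase stays
#' consistent with the inducer in space and time. This is the stimulus-level
#' forward model: the pattern the moving inducer predicts ahead of itself.
#'
#' @param inducer \code{\link{grating_params}} for the inducer; its
#'   \code{contrast} is ignored (the prediction has amplitude 1 here and is
#'   scaled by the prediction gain downstream).
#' @param region Length-4 numeric c(xmin, xmax, ymin, ymax), the region to
#'   fill, which must lie beyond the inducer's leading edge (no overlap with
#'   the inducer patch).
#' @param gap Degrees >= 0 separating the inducer border from the region (for
#'   bookkeeping; the continuation is analytic so the gap needs no special
#'   handling).
#' @param inducer_center Inducer patch center (x, y) in degrees.
#' @param duration,grid_spacing,time_step Sampling as in
#'   \code{\link{make_grating}}.
#' @return A \code{space_time_pattern} over the region with unit-amplitude
#'   modulation about the inducer's mean luminance.
#' @export
extrapolate_inducer <- function(inducer, region, gap = 0,
                                inducer_center = c(0, 0), duration = 0.2,
                                grid_spacing = NULL, time_step = 0.01) {
  stopifnot(inherits(inducer, "grating_params"))
  if (gap < 0) stop("gap must be >= 0")
  ix <- c(inducer_center[1] - inducer$width / 2,
          inducer_center[1] + inducer$width / 2)
  iy <- c(inducer_center[2] - inducer$height / 2,
          inducer_center[2] + inducer$height / 2)
  overlap <- region[1] < ix[2] - 1e-9 && region[2] > ix[1] + 1e-9 &&
    region[3] < iy[2] - 1e-9 && region[4] > iy[1] + 1e-9
  if (overlap)
    stop("region overlaps the inducer patch; extrapolation is defined beyond its edge")
  unit <- grating_params(spatial_frequency = inducer$spatial_frequency,
                         temporal_frequency = inducer$temporal_frequency,
                         orientation = inducer$orientation,
                         phase = inducer$phase, contrast = 1,
                         width = region[2] - region[1],
                         height = region[4] - region[3],
                         drift_sign = inducer$drift_sign,
                         mean_luminance = inducer$mean_luminance)
  if (is.null(grid_spacing))
    grid_spacing <- 1 / (64 * inducer$spatial_frequency)
  x <- seq(region[1], region[2], by = grid_spacing)
  y <- seq(region[3], region[4], by = grid_spacing)
  t <- seq(0, duration, by = time_step)
  field <- array(0, dim = c(length(x), length(y), length(t)))
  gx <- rep(x, times = length(y))
  gy <- rep(y, each = length(x))
  for (k in seq_along(t)) {
    field[, , k] <- grating_luminance(unit, gx, gy, t[k],
                                      reference = inducer_center)
  }
  space_time_pattern(field, x = x, y = y, t = t, grid_spacing = grid_spacing,
                     time_step = time_step, origin = inducer_center,
                     mean_luminance = inducer$mean_luminance)
}

#' Superpose a predicted waveform on a target field
#'
#' Adds the modulation components (deviations from mean luminance) of a
#' prediction field, scaled by \code{prediction_gain}, to those of a target
#' field; the mean luminance of the target field is preserved. Both fields
#' must share the same sample grid.
#'
#' @param target_field,prediction_field \code{space_time_pattern}s on
#'   identical grids.
#' @param prediction_gain Unitless scale (in Michelson contrast units when the
#'   prediction has unit amplitude) applied to the prediction's modulation.
#' @return A \code{space_time_pattern}.
#' @export
superpose <- function(target_field, prediction_field, prediction_gain = 1) {
  stopifnot(inherits(target_field, "space_time_pattern"),
            inherits(prediction_field, "space_time_pattern"))
  if (!isTRUE(all.equal(target_field$x, prediction_field$x)) ||
      !isTRUE(all.equal(target_field$y, prediction_field$y)) ||
      !isTRUE(all.equal(target_field$t, prediction_field$t)))
    stop("target and prediction fields must share an identical sample grid")
  m_t <- target_field$mean_luminance
  m_p <- prediction_field$mean_luminance
  mod <- (target_field$field - m_t) +
    prediction_gain * (prediction_field$field - m_p)
  out <- pmax(m_t + mod, 0)
  space_time_pattern(out, x = target_field$x, y = target_field$y,
                     t = target_field$t,
                     grid_spacing = target_field$grid_spacing,
                     time_step = target_field$time_step,
                     origin = target_field$origin, mean_luminance = m_t)
}

#' Michelson local contrast within a window of a space-time pattern
#'
#' Computes (max - min) / (max + min) of the luminance inside an axis-aligned
#' spatial window at one time slice. For a pure sinusoid whose cycle fits in
#' the window this equals its Michelson contrast. The window should cover at
#' least one full spatial cycle of the lowest frequency present; otherwise the
#' result is phase dependent and a warning is raised.
#'
#' @param field A \code{space_time_pattern}.
#' @param window_center (x, y) center of the window in degrees.
#' @param window_size (width, height) in degrees (scalar recycled).
#' @param time_index Index of the time slice (default 1).
#' @param min_cycle Degrees; the longest spatial period expected in the field,
#'   used for the coverage check (default: window assumed adequate).
#' @return Michelson contrast in [0, 1].
#' @export
local_contrast <- function(field, window_center = c(0, 0),
                           window_size = NULL, time_index = 1,
                           min_cycle = NULL) {
  stopifnot(inherits(field, "space_time_pattern"))
  if (is.null(window_size))
    window_size <- c(max(field$x) - min(field$x), max(field$y) - min(field$y))
  window_size <- rep(window_size, length.out = 2)
  if (!is.null(min_cycle) && max(window_size) < min_cycle - 1e-9)
    warning("window smaller than one spatial cycle; local contrast is phase dependent")
  inx <- which(field$x >= window_center[1] - window_size[1] / 2 - 1e-12 &
                 field$x <= window_center[1] + window_size[1] / 2 + 1e-12)
  iny <- which(field$y >= window_center[2] - window_size[2] / 2 - 1e-12 &
                 field$y <= window_center[2] + window_size[2] / 2 + 1e-12)
  if (!length(inx) || !length(iny)) stop("window contains no samples")
  sub <- field$field[inx, iny, time_index]
  (max(sub) - min(sub)) / (max(sub) + min(sub))
}

#' Amplitude of the sum of two equal-frequency sinusoids
#'
#' The phasor formula sqrt(ct^2 + cp^2 + 2 ct cp cos(dphi)): the Michelson
#' contrast that results from superposing a target of contrast \code{c_t}
#' with a predicted waveform of effective contrast \code{c_p} at relative
#' phase \code{delta_phi}. In phase (dphi = 0) the amplitudes add
#' (constructive interference); in antiphase (dphi = pi) they subtract
#' (destructive interference).
#'
#' @param c_t,c_p Non-negative contrasts (any common unit).
#' @param delta_phi Relative phase in radians (vectorized).
#' @return Amplitude of the summed sinusoid, same unit as the inputs.
#' @examples
#' analytic_interference_amplitude(0.5, 0.5, 0)    # 1
#' analytic_interference_amplitude(0.5, 0.5, pi)   # 0
#' @export
analytic_interference_amplitude <- function(c_t, c_p, delta_phi) {
  if (any(c_t < 0) || any(c_p < 0)) stop("contrasts must be >= 0")
  sqrt(pmax(c_t^2 + c_p^2 + 2 * c_t * c_p * cos(delta_phi), 0))
}

#' Spatial interference profile along a rotated inducer's edge
#'
#' When the inducer's orientation is rotated by theta relative to the target,
#' the relative phase between the target and the extrapolated prediction
#' varies with the target's position d along the inducer edge as
#' dphi(d) = 2 pi f sin(theta) d + target_phase, so the local contrast of the
#' superposition traces a periodic interference profile with spatial period
#' 1 / (f sin(theta)). The profile can be computed analytically from the
#' phasor formula or by the pixel-level route (extrapolate the inducer,
#' superpose the target, measure Michelson local contrast in a window at
#' each offset); the two agree to sampling precision.
#'
#' The pixel route samples a thin window aligned with the carrier of the
#' two-grating sum (direction theta / 2 from the target's modulation axis),
#' along which the interference envelope is constant while the carrier
#' completes a full cycle, so the window's Michelson contrast is the local
#' envelope amplitude.
#'
#' @param theta Degrees; inducer orientation relative to the target
#'   (theta = 0 gives a constant profile).
#' @param f Spatial frequency in cycles per degree.
#' @param target_phase Radians; starting phase of the target (shifting it by
#'   pi shifts the profile by half a period).
#' @param prediction_gain Effective contrast of the predicted waveform.
#' @param offsets Signed offsets in degrees along the inducer edge.
#' @param c_t Target contrast (default 1).
#' @param method "analytic" (phasor formula) or "pixel" (brute-force local
#'   contrast of the sampled superposition).
#' @param samples_per_cycle,window_width Pixel-route sampling controls.
#' @return An \code{interference_profile}: data.frame-like object with
#'   \code{offsets}, \code{local_contrast} and
#'   \code{predicted_threshold_factor} (relative detection threshold implied
#'   by the profile, c_t / local_contrast: contrast gain below 1 raises
#'   threshold), plus profile metadata.
#' @export
interference_profile <- function(theta, f, target_phase = 0,
                                 prediction_gain = 0.5, offsets,
                                 c_t = 1,
                                 method = c("analytic", "pixel"),
                                 samples_per_cycle = 512,
                                 window_width = 0.01) {
  method <- match.arg(method)
  if (missing(offsets) || length(offsets) == 0)
    stop("offsets must be a non-empty numeric vector")
  if (f <= 0) stop("spatial frequency must be > 0")
  dphi <- 2 * pi * f * sin(theta * pi / 180) * offsets + target_phase
  if (method == "analytic") {
    lc <- analytic_interference_amplitude(c_t, prediction_gain, dphi)
  } else {
    lc <- vapply(offsets, function(d)
      pixel_local_amplitude(theta, f, target_phase, prediction_gain, d, c_t,
                            samples_per_cycle, window_width),
      numeric(1))
  }
  structure(list(offsets = offsets, local_contrast = lc,
                 predicted_threshold_factor = c_t / pmax(lc, 1e-12),
                 theta = theta, target_phase = target_phase,
                 spatial_frequency = f, prediction_gain = prediction_gain,
                 c_t = c_t, method = method),
            class = "interference_profile")
}

# Brute-force local Michelson amplitude of target + prediction at one offset.
# Samples the summed luminance over a thin window aligned with the carrier
# direction (theta/2), spanning exactly one carrier wavelength, centered on
# the target location (0, d); the envelope is constant along that direction.
pixel_local_amplitude <- function(theta, f, target_phase, gain, d, c_t,
                                  samples_per_cycle = 512,
                                  window_width = 0.01) {
  th <- theta * pi / 180
  half <- th / 2
  lambda_carrier <- 1 / (f * cos(half))        # carrier wavelength along theta/2
  s <- seq(0, lambda_carrier, length.out = samples_per_cycle + 1)
  w <- seq(-window_width / 2, window_width / 2, length.out = 3)
  # window sample coordinates around the target center (0, d)
  xs <- outer(s * cos(half), -w * sin(half), `+`)
  ys <- d + outer(s * sin(half), w * cos(half), `+`)
  # target: modulation along x (orientation 0). target_phase enters the
  # relative phase as dphi(d) = 2 pi f sin(theta) d + target_phase, i.e. it
  # is the phase of the prediction relative to the target at offset 0.
  lum_t <- c_t * sin(2 * pi * f * xs - target_phase)
  # prediction: modulation axis rotated by theta, phase 0 at the origin
  lum_p <- gain * sin(2 * pi * f * (xs * cos(th) + ys * sin(th)))
  lum <- 1 + lum_t + lum_p
  (max(lum) - min(lum)) / (max(lum) + min(lum))
}

#' @export
print.interference_profile <- function(x, ...) {
  cat(sprintf(
    "Interference profile (%s): theta %.3g deg, f %.3g c/deg, phase %.3g rad\n",
    x$method, x$theta, x$spatial_frequency, x$target_phase))
  if (abs(sin(x$theta * pi / 180)) > 1e-9)
    cat(sprintf("  spatial period along edge: %.4g deg\n",
                1 / (x$spatial_frequency * sin(x$theta * pi / 180))))
  cat(sprintf("  %d offsets in [%.3g, %.3g] deg, local contrast [%.3g, %.3g]\n",
              length(x$offsets), min(x$offsets), max(x$offsets),
              min(x$local_contrast), max(x$local_contrast)))
  invisible(x)
}

#' @export
as.data.frame.interference_profile <- function(x, ...) {
  data.frame(offset = x$offsets, local_contrast = x$local_contrast,
             predicted_threshold_factor = x$predicted_threshold_factor)
}

#' Estimate the spatial period of an interference profile
#'
#' Locates successive local maxima of the profile (with quadratic
#' interpolation between samples) and returns their mean spacing.
#'
#' @param profile An \code{\link{interference_profile}} sampled densely over
#'   at least two full periods.
#' @return Period in degrees.
#' @export
profile_period <- function(profile) {
  stopifnot(inherits(profile, "interference_profile"))
  d <- profile$offsets
  v <- profile$local_contrast
  if (length(d) < 5) stop("profile too short to estimate a period")
  peaks <- c()
  for (i in 2:(length(v) - 1)) {
    if (v[i] >= v[i - 1] && v[i] > v[i + 1]) {
      denom <- v[i - 1] - 2 * v[i] + v[i + 1]
      frac <- if (abs(denom) > 1e-12) 0.5 * (v[i - 1] - v[i + 1]) / denom else 0
      peaks <- c(peaks, d[i] + frac * (d[i + 1] - d[i]))
    }
  }
  if (length(peaks) < 2)
    stop("fewer than two maxima found; sample a wider offset range")
  mean(diff(peaks))
}
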