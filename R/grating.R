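#' Parametric description of a drifting sinusoidal grating patch
#'
#' Bundles the parameters of one drifting sinusoidal luminance grating.
#' Orientation is measured in degrees counterclockwise from vertical bars, so
#' \code{orientation = 0} is a vertical grating whose luminance is modulated
#' along x (drifting horizontally) and \code{orientation = 90} is a horizontal
#' grating modulated along y (drifting vertically). Phase is defined at the
#' patch reference point (the patch center unless a display re-anchors it).
#'
#' @param spatial_frequency Spatial frequency in cycles per degree (> 0).
#' @param temporal_frequency Drift temporal frequency in Hz (>= 0).
#' @param orientation Degrees counterclockwise from vertical bars.
#' @param phase Phase in radians at the reference point at t = 0.
#' @param contrast Michelson contrast as a fraction in [0, 1].
#' @param width,height Patch extent in degrees of visual angle (> 0).
#' @param drift_sign +1 or -1: drift direction along the modulation axis.
#' @param mean_luminance Mean luminance in arbitrary units (> 0).
#' @return An object of class \code{grating_params}.
#' @examples
#' g <- grating_params(spatial_frequency = 1, temporal_frequency = 5,
#'                     contrast = 1, width = 1, height = 6.67)
#' g
#' @export
grating_params <- function(spatial_frequency = 1, temporal_frequency = 5,
                           orientation = 0, phase = 0, contrast = 1,
                           width = 1, height = 1, drift_sign = 1,
                           mean_luminance = 1) {
  stopifnot(is.numeric(spatial_frequency), length(spatial_frequency) == 1)
  if (spatial_frequency <= 0) stop("spatial_frequency must be > 0")
  if (temporal_frequency < 0) stop("temporal_frequency must be >= 0")
  if (contrast < 0 || contrast > 1)
    stop("contrast must be a Michelson fraction in [0, 1], got ", contrast)
  if (width <= 0 || height <= 0) stop("width and height must be > 0")
  if (!drift_sign %in% c(-1, 1)) stop("drift_sign must be +1 or -1")
  if (mean_luminance <= 0) stop("mean_luminance must be > 0")
  structure(list(spatial_frequency = spatial_frequency,
                 temporal_frequency = temporal_frequency,
                 orientation = orientation, phase = phase,
                 contrast = contrast, width = width, height = height,
                 drift_sign = drift_sign, mean_luminance = mean_luminance),
            class = "grating_params")
}

#' @export
print.grating_params <- function(x, ...) {
  cat(sprintf(
    "Drifting grating: %.3g c/deg, %.3g Hz, orientation %.3g deg, contrast %.3g\n",
    x$spatial_frequency, x$temporal_frequency, x$orientation, x$contrast))
  cat(sprintf("  patch %.3g x %.3g deg, phase %.3g rad, drift %+d, mean %.3g\n",
              x$width, x$height, x$phase, x$drift_sign, x$mean_luminance))
  invisible(x)
}

#' Closed-form grating luminance at arbitrary sample points
#'
#' Evaluates L(x, y, t) = mean * (1 + c * sin(2*pi*f*u - s*2*pi*tf*t + phi))
#' where u = (x - x0) cos(theta) + (y - y0) sin(theta) is the coordinate along
#' the modulation axis after rotating by the grating orientation, and (x0, y0)
#' is the phase reference point. No patch windowing is applied; use
#' \code{\link{make_grating}} for a windowed, sampled patch.
#'
#' @param params A \code{\link{grating_params}} object.
#' @param x,y,t Numeric vectors (recycled to a common length) of sample
#'   coordinates in degrees and seconds.
#' @param reference Length-2 numeric: the (x, y) point at which \code{phase}
#'   holds at t = 0. Default c(0, 0).
#' @return Numeric vector of luminance values.
#' @export
grating_luminance <- function(params, x, y, t = 0, reference = c(0, 0)) {
  stopifnot(inherits(params, "grating_params"))
  th <- params$orientation * pi / 180
  u <- (x - reference[1]) * cos(th) + (y - reference[2]) * sin(th)
  arg <- 2 * pi * params$spatial_frequency * u -
    params$drift_sign * 2 * pi * params$temporal_frequency * t + params$phase
  params$mean_luminance * (1 + params$contrast * sin(arg))
}

#' Sample a grating patch into a space-time luminance field
#'
#' Produces a regularly sampled luminance field L(x, y, t) for a drifting
#' grating patch centered at \code{center}, equal to the closed-form sinusoid
#' inside the patch window and to the mean luminance outside it. Sampling must
#' provide at least 4 samples per spatial and temporal cycle (a Nyquist-safe
#' margin); coarser sampling is rejected.
#'
#' @param params A \code{\link{grating_params}}.
#' @param extent Length-4 numeric c(xmin, xmax, ymin, ymax) in degrees, or NULL
#'   for the patch's own bounding box.
#' @param duration Sampled duration in seconds.
#' @param grid_spacing Spatial sample spacing in degrees (default 64 samples
#'   per cycle of the grating).
#' @param time_step Temporal sample spacing in seconds (default 0.01 s, a
#'   100 Hz frame rate).
#' @param center Patch center (x, y) in degrees; also the phase reference.
#' @return A \code{space_time_pattern}: a 3-D array (x, y, t) of luminance
#'   with grid metadata attributes.
#' @export
make_grating <- function(params, extent = NULL, duration = 0.2,
                         grid_spacing = NULL, time_step = 0.01,
                         center = c(0, 0)) {
  stopifnot(inherits(params, "grating_params"))
  if (is.null(grid_spacing))
    grid_spacing <- 1 / (64 * params$spatial_frequency)
  if (1 / grid_spacing < 4 * params$spatial_frequency)
    stop(sprintf(paste0("grid_spacing %.4g deg gives fewer than 4 samples per ",
                        "cycle of the %.4g c/deg spatial frequency"),
                 grid_spacing, params$spatial_frequency))
  if (params$temporal_frequency > 0 &&
      1 / time_step < 4 * params$temporal_frequency)
    stop(sprintf(paste0("time_step %.4g s gives fewer than 4 samples per ",
                        "cycle of the %.4g Hz temporal frequency"),
                 time_step, params$temporal_frequency))
  if (is.null(extent))
    extent <- c(center[1] - params$width / 2, center[1] + params$width / 2,
                center[2] - params$height / 2, center[2] + params$height / 2)
  x <- seq(extent[1], extent[2], by = grid_spacing)
  y <- seq(extent[3], extent[4], by = grid_spacing)
  t <- seq(0, duration, by = time_step)
  field <- array(params$mean_luminance, dim = c(length(x), length(y), length(t)))
  inx <- which(x >= center[1] - params$width / 2 - 1e-12 &
                 x <= center[1] + params$width / 2 + 1e-12)
  iny <- which(y >= center[2] - params$height / 2 - 1e-12 &
                 y <= center[2] + params$height / 2 + 1e-12)
  if (length(inx) && length(iny)) {
    gx <- rep(x[inx], times = length(iny))
    gy <- rep(y[iny], each = length(inx))
    for (k in seq_along(t)) {
      field[inx, iny, k] <- grating_luminance(params, gx, gy, t[k],
                                              reference = center)
    }
  }
  space_time_pattern(field, x = x, y = y, t = t,
                     grid_spacing = grid_spacing, time_step = time_step,
                     origin = center,
                     mean_luminance = params$mean_luminance)
}

#' Construct a space-time luminance pattern
#'
#' @param field 3-D numeric array indexed (x, y, t); all finite and >= 0.
#' @param x,y,t Sample coordinate vectors matching \code{dim(field)}.
#' @param grid_spacing,time_step Sample spacings (degrees, seconds).
#' @param origin Reference (x0, y0) in degrees.
#' @param mean_luminance Mean luminance of the field background.
#' @return A \code{space_time_pattern} object.
#' @export
space_time_pattern <- function(field, x, y, t, grid_spacing, time_step,
                               origin = c(0, 0), mean_luminance = 1) {
  stopifnot(length(dim(field)) == 3,
            dim(field)[1] == length(x),
            dim(field)[2] == length(y),
            dim(field)[3] == length(t))
  if (any(!is.finite(field)) || any(field < 0))
    stop("luminance samples must be finite and >= 0")
  structure(list(field = field, x = x, y = y, t = t,
                 grid_spacing = grid_spacing, time_step = time_step,
                 origin = origin, mean_luminance = mean_luminance),
            class = "space_time_pattern")
}

#' @export
print.space_time_pattern <- function(x, ...) {
  cat(sprintf("Space-time pattern: %d x %d spatial samples, %d frames\n",
              length(x$x), length(x$y), length(x$t)))
  cat(sprintf("  extent x [%.3g, %.3g] deg, y [%.3g, %.3g] deg, t [0, %.3g] s\n",
              min(x$x), max(x$x), min(x$y), max(x$y), max(x$t)))
  cat(sprintf("  grid %.4g deg/sample, %.4g s/frame, luminance [%.3g, %.3g]\n",
              x$grid_spacing, x$time_step, min(x$field), max(x$field)))
  invisible(x)
}

#' Extract a (space, time) slice from a space-time pattern
#'
#' Returns the 2-D luminance slice along one spatial axis at a fixed position
#' on the other axis, i.e. the space-time plot used to visualize drifting
#' stimuli and to test waveform continuity across patch borders.
#'
#' @param pattern A \code{space_time_pattern}.
#' @param axis "y" to keep the y axis (slice at a fixed x position), "x" to
#'   keep the x axis (slice at a fixed y).
#' @param position Position in degrees on the collapsed axis; must lie inside
#'   the sampled extent. The nearest sample is used.
#' @return A matrix (space along rows, time along columns) with the retained
#'   coordinate in \code{attr(, "space")} and times in \code{attr(, "time")}.
#' @export
space_time_profile <- function(pattern, axis = c("y", "x"), position = 0) {
  stopifnot(inherits(pattern, "space_time_pattern"))
  axis <- match.arg(axis)
  if (axis == "y") {
    if (position < min(pattern$x) - 1e-9 || position > max(pattern$x) + 1e-9)
      stop("position ", position, " outside sampled x extent")
    i <- which.min(abs(pattern$x - position))
    m <- pattern$field[i, , , drop = TRUE]
    space <- pattern$y
  } else {
    if (position < min(pattern$y) - 1e-9 || position > max(pattern$y) + 1e-9)
      stop("position ", position, " outside sampled y extent")
    i <- which.min(abs(pattern$y - position))
    m <- pattern$field[, i, , drop = TRUE]
    space <- pattern$x
  }
  m <- matrix(m, nrow = length(space))
  attr(m, "space") <- space
  attr(m, "time") <- pattern$t
  m
}
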