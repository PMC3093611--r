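#' Fit a logistic psychometric function to 2AFC trial data
#'
#' Maximum-likelihood fit of
#' p(c) = 0.5 + (0.5 - lapse) * logistic(beta * (log10 c - log10 alpha)),
#' with a binomial likelihood on the per-level correct counts. The guess rate
#' is fixed at 0.5 (2AFC) and the lapse rate at \code{lapse_rate} (default
#' 0), in which case the fitted curve evaluated at \code{alpha} is exactly
#' 0.75: \code{alpha} is the 75\%-correct contrast detection threshold,
#' reported directly in Michelson \%. Optimization is a bounded
#' quasi-Newton search multi-started from a 3 x 3 grid of slopes and
#' thresholds; ties are broken by lowest deviance, then lowest threshold.
#'
#' Degenerate data are flagged rather than silently fitted: if responses
#' never leave chance the fit is marked non-converged with an NA threshold;
#' if the data are perfectly separated (all correct above some level, at
#' chance below, with no overlap) the threshold is bracketed between the
#' adjacent levels and flagged.
#'
#' @param table A \code{trial_table} data.frame (columns \code{condition},
#'   \code{contrast}, \code{correct}), or any data.frame with those columns.
#' @param condition Condition label to fit; NULL fits all rows.
#' @param lapse_rate Fixed lapse rate in [0, 0.5).
#' @return A \code{psychometric_fit}: list with \code{threshold} (alpha,
#'   Michelson \%), \code{slope} (beta on log10 contrast), \code{n_trials},
#'   \code{converged}, \code{deviance}, \code{flags},
#'   \code{bootstrap_se} (NA until \code{\link{bootstrap_se}} is run),
#'   \code{levels} (per-level counts) and \code{lapse_rate}.
#' @export
fit_logistic <- function(table, condition = NULL, lapse_rate = 0) {
  rows <- if (is.null(condition)) table else
    table[table$condition == condition, , drop = FALSE]
  if (nrow(rows) == 0) stop("no trials for condition ", condition)
  agg <- stats::aggregate(correct ~ contrast, data = rows,
                          FUN = function(z) c(k = sum(z), n = length(z)))
  lev <- data.frame(contrast = agg$contrast, k = agg$correct[, "k"],
                    n = agg$correct[, "n"])
  lev <- lev[order(lev$contrast), ]
  if (nrow(lev) < 2)
    stop("need >= 2 distinct contrast levels to fit a psychometric function")
  n_trials <- sum(lev$n)
  x <- log10(lev$contrast)
  phat <- lev$k / lev$n

  nll <- function(par) {
    alpha_log <- par[1]; beta <- exp(par[2])
    p <- 0.5 + (0.5 - lapse_rate) * stats::plogis(beta * (x - alpha_log))
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(lev$k * log(p) + (lev$n - lev$k) * log(1 - p))
  }
  # saturated log-likelihood for the deviance
  ps <- pmin(pmax(phat, 1e-9), 1 - 1e-9)
  ll_sat <- sum(lev$k * log(ps) + (lev$n - lev$k) * log(1 - ps))

  # all-at-chance check: binomial test against p = 0.5 pooled
  pooled <- sum(lev$k) / n_trials
  at_chance <- pooled < 0.5 + 2 * sqrt(0.25 / n_trials) &&
    max(phat) < 0.625
  if (at_chance) {
    return(new_psychometric_fit(NA_real_, NA_real_, n_trials, FALSE,
                                NA_real_, "all responses at chance; no finite threshold",
                                lev, lapse_rate))
  }

  starts <- expand.grid(alpha_log = stats::quantile(x, c(0.15, 0.5, 0.85),
                                                    names = FALSE),
                        beta_log = log(c(3, 10, 30)))
  lower <- c(min(x) - 1, log(0.5))
  upper <- c(max(x) + 1, log(200))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1]))
      best <- fit
  }
  if (is.null(best))
    return(new_psychometric_fit(NA_real_, NA_real_, n_trials, FALSE,
                                NA_real_, "optimization failed", lev,
                                lapse_rate))
  alpha <- 10^best$par[1]
  beta <- exp(best$par[2])
  deviance <- 2 * (ll_sat + best$value)
  flags <- character(0)
  # perfect separation: the fitted 55-95% rise is narrower than the level
  # spacing around the threshold, i.e. the data constrain only a bracket
  rise_width <- 2 * log(9) / beta
  if (rise_width < min(diff(x))) {
    below <- lev$contrast[lev$contrast < alpha]
    above <- lev$contrast[lev$contrast >= alpha]
    flags <- c(flags, sprintf(
      "perfect separation: threshold bracketed in (%.4g, %.4g)",
      if (length(below)) max(below) else min(lev$contrast),
      if (length(above)) min(above) else max(lev$contrast)))
  }
  if (alpha < min(lev$contrast) || alpha > max(lev$contrast))
    flags <- c(flags, "threshold extrapolated beyond the spanned contrast range")
  new_psychometric_fit(alpha, beta, n_trials, TRUE, deviance,
                       flags, lev, lapse_rate)
}

new_psychometric_fit <- function(threshold, slope, n_trials, converged,
                                 deviance, flags, levels, lapse_rate) {
  structure(list(threshold = threshold, slope = slope, n_trials = n_trials,
                 converged = converged, deviance = deviance,
                 flags = flags, bootstrap_se = NA_real_,
                 levels = levels, lapse_rate = lapse_rate),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Psychometric fit: DID NOT CONVERGE —", x$flags, "\n")
    return(invisible(x))
  }
  cat(sprintf("Psychometric fit: threshold %.4g%% Michelson (75%% correct), slope %.3g\n",
              x$threshold, x$slope))
  cat(sprintf("  %d trials over %d levels, deviance %.3g",
              x$n_trials, nrow(x$levels), x$deviance))
  if (!is.na(x$bootstrap_se)) cat(sprintf(", bootstrap SE %.3g%%", x$bootstrap_se))
  cat("\n")
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Predicted proportion correct from a psychometric fit
#'
#' @param object A \code{psychometric_fit}.
#' @param contrast Michelson \% contrasts at which to evaluate the curve.
#' @param ... Unused.
#' @return Probability of a correct response at each contrast.
#' @export
predict.psychometric_fit <- function(object, contrast, ...) {
  stopifnot(object$converged)
  0.5 + (0.5 - object$lapse_rate) *
    stats::plogis(object$slope * (log10(contrast) - log10(object$threshold)))
}

#' Bootstrap standard error of a fitted threshold
#'
#' Nonparametric bootstrap respecting the MOCS structure: within each
#' contrast level, trials are resampled with replacement, the psychometric
#' function is refitted, and the SD of the bootstrap threshold distribution
#' is returned. If more than 10\% of refits are degenerate the SE is flagged
#' unreliable.
#'
#' @param table Trial data (as in \code{\link{fit_logistic}}).
#' @param condition Condition label.
#' @param n_boot Number of bootstrap resamples (>= 1; default 1000).
#' @param seed Integer seed for reproducibility.
#' @param lapse_rate Fixed lapse rate passed to the refits.
#' @return Numeric SE in Michelson \%, with attributes \code{n_ok} (number of
#'   convergent refits) and \code{reliable} (logical).
#' @export
bootstrap_se <- function(table, condition = NULL, n_boot = 1000, seed = 1L,
                         lapse_rate = 0) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  rows <- if (is.null(condition)) table else
    table[table$condition == condition, , drop = FALSE]
  fit0 <- fit_logistic(rows, NULL, lapse_rate)
  if (!fit0$converged) stop("cannot bootstrap a non-convergent fit")
  by_level <- split(rows$correct, rows$contrast)
  contrasts <- as.numeric(names(by_level))
  thr <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      res <- lapply(by_level, function(z) sample(z, length(z),
                                                 replace = TRUE))
      tab <- data.frame(condition = "boot",
                        contrast = rep(contrasts, lengths(by_level)),
                        correct = unlist(res, use.names = FALSE))
      f <- fit_logistic(tab, "boot", lapse_rate)
      if (f$converged) f$threshold else NA_real_
    }, numeric(1))
  })
  ok <- !is.na(thr)
  se <- stats::sd(thr[ok])
  attr(se, "n_ok") <- sum(ok)
  attr(se, "reliable") <- mean(!ok) <= 0.10
  if (!attr(se, "reliable"))
    warning(sprintf("%.0f%% of bootstrap refits degenerate; SE unreliable",
                    100 * mean(!ok)))
  se
}

#' Threshold elevation relative to baseline
#'
#' @param threshold,baseline_threshold Michelson \% contrasts (> 0).
#' @return List with \code{log_units} = log10(threshold / baseline) and
#'   \code{percent} = 100 * (threshold / baseline - 1).
#' @examples
#' suppression_stats(1.49, 1)   # 0.173 log units, 49%
#' @export
suppression_stats <- function(threshold, baseline_threshold) {
  if (threshold <= 0 || baseline_threshold <= 0)
    stop("thresholds must be > 0")
  ratio <- threshold / baseline_threshold
  list(log_units = log10(ratio), percent = 100 * (ratio - 1))
}

#' Fit a saturating exponential y = A (1 - 2^(-x / x50))
#'
#' Least-squares fit of the half-life saturating form, so the reported
#' \code{half_constant} is exactly the abscissa at which the curve reaches
#' half its asymptote (the "semisaturation constant"). Used to summarize the
#' growth of the interference effect with inducer length (arcmin) and
#' stimulus duration (ms).
#'
#' @param x Non-negative abscissae (>= 3 points).
#' @param y Fitted quantity (threshold differences).
#' @param units Unit label for \code{x} ("arcmin" or "ms").
#' @return An \code{exponential_fit}: list with \code{asymptote},
#'   \code{half_constant}, \code{form = "saturating"}, \code{residual_ss},
#'   \code{units} and \code{flags} (non-saturating data are flagged).
#' @export
fit_saturating_exponential <- function(x, y, units = "arcmin") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  check_exp_input(x, y)
  A0 <- max(max(y), 1e-6)
  x50_0 <- half_point_guess(x, y, A0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - 2^(-x / x50)),
                      start = list(A = A0, x50 = x50_0),
                      lower = c(A = 0, x50 = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(asymptote = NA_real_, half_constant = NA_real_,
                          form = "saturating", residual_ss = NA_real_,
                          units = units,
                          flags = "fit failed: data do not follow a saturating exponential"),
                     class = "exponential_fit"))
  co <- stats::coef(fit)
  flags <- character(0)
  if (co[["x50"]] > 5 * max(x))
    flags <- "non-saturating data: half-constant unbounded by the sampled range"
  structure(list(asymptote = co[["A"]], half_constant = co[["x50"]],
                 form = "saturating",
                 residual_ss = sum(stats::resid(fit)^2),
                 units = units, flags = flags),
            class = "exponential_fit")
}

#' Fit a decaying exponential y = A exp(-x / lambda)
#'
#' Least-squares fit of the e-folding decay, so the reported
#' \code{efold_constant} is the conventional "space constant". Used to
#' summarize the attenuation of the interference effect with the gap between
#' inducer and target.
#'
#' @inheritParams fit_saturating_exponential
#' @return An \code{exponential_fit} with \code{efold_constant} and
#'   \code{form = "decaying"}.
#' @export
fit_decaying_exponential <- function(x, y, units = "arcmin") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  check_exp_input(x, y)
  A0 <- max(max(y), 1e-6)
  pos <- y > 0.05 * A0
  lam0 <- if (sum(pos) >= 2) {
    cf <- unname(stats::coef(stats::lm(log(y[pos]) ~ x[pos])))
    if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else max(x) / 2
  } else max(x) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x / lambda),
                      start = list(A = A0, lambda = lam0),
                      lower = c(A = 0, lambda = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(asymptote = NA_real_, efold_constant = NA_real_,
                          form = "decaying", residual_ss = NA_real_,
                          units = units,
                          flags = "fit failed: data do not follow a decaying exponential"),
                     class = "exponential_fit"))
  co <- stats::coef(fit)
  flags <- character(0)
  if (co[["lambda"]] > 5 * max(x))
    flags <- "non-decaying data: space constant unbounded by the sampled range"
  structure(list(asymptote = co[["A"]], efold_constant = co[["lambda"]],
                 form = "decaying",
                 residual_ss = sum(stats::resid(fit)^2),
                 units = units, flags = flags),
            class = "exponential_fit")
}

check_exp_input <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x))
    stop("need >= 3 (x, y) points of equal length")
  if (any(x < 0)) stop("x must be >= 0")
}

half_point_guess <- function(x, y, A) {
  i <- which(y >= A / 2)[1]
  if (is.na(i) || i == 1) return(max(x[1], min(x[x > 0]) / 2))
  g <- tryCatch(stats::approx(y[c(i - 1, i)], x[c(i - 1, i)],
                              xout = A / 2, ties = "ordered")$y,
                error = function(e) NA_real_)
  if (!is.finite(g)) stats::median(x) else unname(g)
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (x$form == "saturating") {
    cat(sprintf("Saturating exponential: asymptote %.4g, semisaturation constant %.4g %s\n",
                x$asymptote, x$half_constant, x$units))
  } else {
    cat(sprintf("Decaying exponential: amplitude %.4g, space constant %.4g %s\n",
                x$asymptote, x$efold_constant, x$units))
  }
  cat(sprintf("  residual SS %.4g\n", x$residual_ss))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Evaluate an exponential fit at new abscissae
#' @param object An \code{exponential_fit}.
#' @param x Abscissae.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.exponential_fit <- function(object, x, ...) {
  if (object$form == "saturating")
    object$asymptote * (1 - 2^(-x / object$half_constant))
  else
    object$asymptote * exp(-x / object$efold_constant)
}
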