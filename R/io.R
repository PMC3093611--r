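#' Save or load observer parameters as JSON or YAML
#'
#' Serialization round-trips every field of an
#' \code{\link{observer_params}}. Loading validates the file: unknown keys
#' are rejected by name, missing required fields are reported, and field
#' constraints (positivity, the [0, 1] transfer bound) are re-checked by the
#' constructor.
#'
#' @param params An \code{observer_params}.
#' @param path File path; format chosen by extension (.json, .yaml/.yml).
#' @return \code{save_observer} returns \code{path} invisibly;
#'   \code{load_observer} returns an \code{observer_params}.
#' @export
save_observer <- function(params, path) {
  stopifnot(inherits(params, "observer_params"))
  obj <- unclass(params)
  obj$guess_rate <- NULL  # fixed at 0.5; not a free field
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname save_observer
#' @export
load_observer <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- setdiff(names(formals(observer_params)), "...")
  extra <- setdiff(names(obj), c(allowed, "guess_rate"))
  if (length(extra))
    stop("unknown observer field(s): ", paste(extra, collapse = ", "))
  required <- c("baseline_threshold")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("missing required observer field(s): ",
         paste(missing, collapse = ", "))
  if (!is.null(obj$guess_rate) && obj$guess_rate != 0.5)
    stop("guess_rate is fixed at 0.5 for 2AFC")
  obj$guess_rate <- NULL
  do.call(observer_params, obj)
}

#' The packaged study-calibrated observer
#'
#' Loads the default observer file shipped with the package
#' (\code{inst/extdata/observer_default.json}), whose suppression and
#' prediction parameters invert the study's printed suppression means and
#' whose attenuation constants are the sweep-experiment values (15 arcmin,
#' 25 arcmin, 122 ms).
#'
#' @return An \code{\link{observer_params}}.
#' @export
default_observer <- function() {
  load_observer(system.file("extdata", "observer_default.json",
                            package = "motionforecast", mustWork = TRUE))
}

#' Write or read a trial table as CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal; contrasts in Michelson
#' percent. Reading restores the \code{trial_table} class so downstream fits
#' are identical after a round trip.
#'
#' @param table A \code{trial_table}.
#' @param path CSV file path.
#' @return \code{write_trial_table} returns \code{path} invisibly;
#'   \code{read_trial_table} returns a \code{trial_table}.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "data.frame"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  needed <- c("condition", "contrast", "correct")
  missing <- setdiff(needed, names(out))
  if (length(missing))
    stop("trial table missing column(s): ", paste(missing, collapse = ", "))
  if (!all(out$correct %in% c(0, 1))) stop("correct must be 0/1")
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write an interference profile as CSV
#'
#' Columns: offset, local_contrast, predicted_threshold_factor.
#'
#' @param profile An \code{\link{interference_profile}}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "interference_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Regenerate every figure-level analysis from one seed
#'
#' Runs all six experiment drivers (phase dependence, interference profiles
#' at 30 and 15 degrees, length, gap and duration sweeps, interocular
#' transfer) with the packaged calibrated observer, writes trial tables,
#' threshold summaries and plots under \code{out_dir}, and returns a run
#' manifest listing seeds and output files. Trial counts default to a
#' reduced-but-informative scale; pass \code{trials_per_level = 120} for the
#' full study scale.
#'
#' @param seed Integer master seed; every driver derives its own seed from
#'   it.
#' @param out_dir Writable output directory (created if absent).
#' @param observer An \code{\link{observer_params}} (default: the packaged
#'   calibration).
#' @param trials_per_level Trials per contrast level (default 40 for a quick
#'   run).
#' @param profile_offsets Offsets for the interference-profile experiments.
#' @param make_plots Write PNG summary plots.
#' @return A \code{run_manifest} list (also written as
#'   \code{manifest.json}).
#' @export
run_all <- function(seed, out_dir, observer = default_observer(),
                    trials_per_level = 40,
                    profile_offsets = seq(-5, 5, by = 1),
                    make_plots = TRUE) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("out_dir is not a writable directory: ", out_dir)
  seed <- as.integer(seed)
  design <- function(k) mocs_design(trials_per_level = trials_per_level,
                                    seed = seed + 1000L * k)
  stages <- list()
  outputs <- character(0)
  run_stage <- function(name, expr) {
    message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }
  save_stage <- function(name, exp) {
    tt <- file.path(out_dir, paste0(name, "_trials.csv"))
    write_trial_table(exp$trials, tt)
    th <- file.path(out_dir, paste0(name, "_thresholds.csv"))
    utils::write.csv(exp$thresholds, th, row.names = FALSE)
    outputs <<- c(outputs, tt, th)
    stages[[name]] <<- list(trials = tt, thresholds = th,
                            n_trials = nrow(exp$trials))
  }

  phase <- run_stage("phase", experiment_phase_dependence(observer,
                                                          design(1)))
  save_stage("phase", phase)
  sm <- file.path(out_dir, "phase_summary.csv")
  utils::write.csv(phase$summary, sm, row.names = FALSE)
  outputs <- c(outputs, sm)

  prof30 <- run_stage("profile_theta30",
                      experiment_interference_profile(observer, design(2),
                                                      theta = 30,
                                                      offsets = profile_offsets))
  save_stage("profile_theta30", prof30)
  prof15 <- run_stage("profile_theta15",
                      experiment_interference_profile(observer, design(3),
                                                      theta = 15,
                                                      offsets = profile_offsets))
  save_stage("profile_theta15", prof15)

  support <- run_stage("support", experiment_support(observer, design(4)))
  save_stage("support", support)
  projection <- run_stage("projection",
                          experiment_projection(observer, design(5)))
  save_stage("projection", projection)
  timecourse <- run_stage("timecourse",
                          experiment_timecourse(observer, design(6)))
  save_stage("timecourse", timecourse)
  interocular <- run_stage("dichoptic",
                           experiment_interocular(observer, design(7)))
  save_stage("dichoptic", interocular)

  constants <- list(
    support_semisat_arcmin = support$fit$half_constant,
    projection_efold_arcmin = projection$fit$efold_constant,
    temporal_semisat_ms = timecourse$fit$half_constant,
    interocular_transfer_ratio = interocular$transfer_ratio)
  cj <- file.path(out_dir, "sweep_constants.json")
  jsonlite::write_json(constants, cj, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, cj)

  if (make_plots) {
    pf <- file.path(out_dir, "summary_plots.png")
    grDevices::png(pf, width = 1600, height = 1000, res = 150)
    graphics::par(mfrow = c(2, 3))
    plot_phase_summary(phase)
    plot_profile_experiment(prof30)
    plot_profile_experiment(prof15)
    plot_sweep(support$curve[[1]], support$curve, support$fit,
               "inducer length (arcmin)")
    plot_sweep(projection$curve[[1]], projection$curve, projection$fit,
               "gap (arcmin)")
    plot_sweep(timecourse$curve[[1]], timecourse$curve, timecourse$fit,
               "duration (ms)")
    grDevices::dev.off()
    outputs <- c(outputs, pf)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("motionforecast")),
                   seed = seed,
                   trials_per_level = trials_per_level,
                   observer = unclass(observer)[c("baseline_threshold",
                                                  "suppression_trailing",
                                                  "suppression_leading",
                                                  "prediction_amplitude")],
                   stages = stages,
                   sweep_constants = constants,
                   outputs = outputs,
                   timestamp = format(Sys.time(), tz = "UTC"))
  empty <- outputs[!file.exists(outputs) | file.size(outputs) == 0]
  if (length(empty))
    stop("manifest invariant violated; missing or empty outputs: ",
         paste(empty, collapse = ", "))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Run manifest: seed %d, %d stages, %d output files\n",
              x$seed, length(x$stages), length(x$outputs)))
  cat(sprintf("  sweep constants: L50 %.3g arcmin, gap e-fold %.3g arcmin, T50 %.3g ms\n",
              x$sweep_constants$support_semisat_arcmin,
              x$sweep_constants$projection_efold_arcmin,
              x$sweep_constants$temporal_semisat_ms))
  invisible(x)
}
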