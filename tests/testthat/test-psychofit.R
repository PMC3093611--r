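# simulate per-level binomial counts from the observer's own psychometric
# shape: the generating truth for recovery studies
simulate_mocs_table <- function(alpha, beta, levels, n_per_level) {
  p <- 0.5 + 0.5 * stats::plogis(beta * (log10(levels) - log10(alpha)))
  k <- stats::rbinom(length(levels), n_per_level, p)
  data.frame(condition = "sim",
             contrast = rep(levels, each = n_per_level),
             correct = unlist(lapply(seq_along(levels), function(i)
               c(rep(1, k[i]), rep(0, n_per_level - k[i])))))
}

test_that("the fitted logistic passes through 75% at the reported threshold", {
  levels <- make_levels(1, 0.4, 7)
  tab <- withr::with_seed(2, simulate_mocs_table(1, 10, levels, 120))
  fit <- fit_logistic(tab, "sim")
  expect_true(fit$converged)
  expect_equal(predict(fit, fit$threshold), 0.75, tolerance = 1e-9)
  expect_equal(fit$n_trials, 840)
  expect_equal(fit$threshold, 1, tolerance = 0.15)
})

test_that("threshold recovery is accurate at the study's trial count", {
  # Monte-Carlo coverage: |log10 error| < 0.05 in at least 95% of replicates
  levels <- make_levels(1, 0.4, 7)
  errs <- withr::with_seed(77, replicate(300, {
    fit <- fit_logistic(simulate_mocs_table(1, 10, levels, 120), "sim")
    abs(log10(fit$threshold))
  }))
  expect_gte(mean(errs < 0.05), 0.95)
})

test_that("threshold bias shrinks as trials grow", {
  levels <- make_levels(1, 0.4, 7)
  bias_at <- function(n, reps) {
    errs <- replicate(reps, {
      log10(fit_logistic(simulate_mocs_table(1, 10, levels, n),
                         "sim")$threshold)
    })
    abs(mean(errs))
  }
  withr::with_seed(13, {
    expect_lt(bias_at(480, 60), 0.01)
  })
})

test_that("degenerate data are flagged, not silently fitted", {
  # all responses at chance: no finite threshold
  chance <- data.frame(condition = "c",
                       contrast = rep(c(1, 2, 4), each = 100),
                       correct = rep(rep(c(0, 1), 50), 3))
  f <- fit_logistic(chance, "c")
  expect_false(f$converged)
  expect_true(is.na(f$threshold))
  # perfect separation: threshold bracketed between adjacent levels
  sep <- data.frame(condition = "s",
                    contrast = rep(c(1, 2, 4, 8), each = 40),
                    correct = c(rep(c(0, 1), 20), rep(c(0, 1), 20),
                                rep(1, 40), rep(1, 40)))
  fs <- fit_logistic(sep, "s")
  expect_true(any(grepl("separation", fs$flags)))
  expect_gt(fs$threshold, 2 - 1e-9)
  expect_lt(fs$threshold, 4 + 1e-9)
  expect_error(fit_logistic(chance, "missing"), "no trials")
  expect_error(fit_logistic(data.frame(condition = "x", contrast = 1,
                                       correct = 1), "x"),
               ">= 2 distinct")
})

test_that("deviance behaves like chi-square with levels - 2 df on model data", {
  levels <- make_levels(1, 0.4, 7)
  devs <- withr::with_seed(5, replicate(150, {
    fit_logistic(simulate_mocs_table(1, 10, levels, 120), "sim")$deviance
  }))
  # chi-square_5: mean 5; loose Monte-Carlo band
  expect_gt(mean(devs), 3.6)
  expect_lt(mean(devs), 6.4)
})

test_that("fits are scale-equivariant in contrast", {
  levels <- make_levels(2, 0.4, 7)
  tab <- withr::with_seed(3, simulate_mocs_table(2, 10, levels, 120))
  f1 <- fit_logistic(tab, "sim")
  tab2 <- tab
  tab2$contrast <- tab$contrast * 3.7
  f2 <- fit_logistic(tab2, "sim")
  expect_equal(f2$threshold / f1$threshold, 3.7, tolerance = 1e-4)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-4)
})

test_that("bootstrap SE tracks the Monte-Carlo SD of the estimator", {
  levels <- make_levels(1, 0.4, 7)
  mc_sd <- withr::with_seed(8, stats::sd(replicate(120, {
    fit_logistic(simulate_mocs_table(1, 10, levels, 120), "sim")$threshold
  })))
  tab <- withr::with_seed(9, simulate_mocs_table(1, 10, levels, 120))
  se <- bootstrap_se(tab, "sim", n_boot = 300, seed = 10)
  expect_lt(abs(se - mc_sd) / mc_sd, 0.3)
  expect_true(attr(se, "reliable"))
  expect_error(bootstrap_se(tab, "sim", n_boot = 0), "n_boot")
})

test_that("bootstrap SE shrinks roughly as 1/sqrt(trials)", {
  levels <- make_levels(1, 0.4, 7)
  tab1 <- withr::with_seed(21, simulate_mocs_table(1, 10, levels, 120))
  tab2 <- withr::with_seed(22, simulate_mocs_table(1, 10, levels, 240))
  se1 <- bootstrap_se(tab1, "sim", n_boot = 300, seed = 1)
  se2 <- bootstrap_se(tab2, "sim", n_boot = 300, seed = 1)
  expect_equal(as.numeric(se1 / se2), sqrt(2), tolerance = 0.35)
})

test_that("a near-deterministic observer leaves a quantization floor", {
  # step-like psychometric data: the bootstrap SE reflects level spacing,
  # not zero
  levels <- make_levels(1, 0.6, 7)
  tab <- withr::with_seed(31, simulate_mocs_table(1, 200, levels, 120))
  se <- suppressWarnings(bootstrap_se(tab, "sim", n_boot = 200, seed = 2))
  expect_gt(se, 0)
  expect_lt(se, diff(levels)[3])  # below one central level step
})

test_that("suppression statistics match the printed log/percent pairs", {
  s <- suppression_stats(1.49, 1)
  expect_equal(s$log_units, log10(1.49), tolerance = 1e-12)  # 0.173
  expect_equal(s$percent, 49, tolerance = 1e-9)
  s2 <- suppression_stats(2.06, 1)
  expect_equal(s2$log_units, log10(2.06))                    # 0.314
  expect_equal(s2$percent, 106)
  expect_equal(suppression_stats(3, 3)$log_units, 0)
  expect_error(suppression_stats(-1, 1), "> 0")
})

test_that("exponential fits recover noiseless parameters exactly", {
  x <- c(2, 5, 10, 15, 25, 40, 80, 160)
  y <- 1.3 * (1 - 2^(-x / 15))
  f <- fit_saturating_exponential(x, y, "arcmin")
  expect_equal(f$asymptote, 1.3, tolerance = 1e-6)
  expect_equal(f$half_constant, 15, tolerance = 1e-6)
  # y(x50)/A = 0.5 by definition
  expect_equal(predict(f, f$half_constant) / f$asymptote, 0.5,
               tolerance = 1e-9)
  yd <- 0.9 * exp(-x / 25)
  fd <- fit_decaying_exponential(x, yd, "arcmin")
  expect_equal(fd$asymptote, 0.9, tolerance = 1e-6)
  expect_equal(fd$efold_constant, 25, tolerance = 1e-6)
  expect_equal(predict(fd, fd$efold_constant) / fd$asymptote, exp(-1),
               tolerance = 1e-9)
  expect_error(fit_saturating_exponential(c(1, 2), c(1, 2)), ">= 3")
})

test_that("non-saturating data are flagged as unbounded", {
  x <- c(1, 2, 3, 4, 5)
  y <- 0.01 * x  # linear growth, no curvature
  f <- fit_saturating_exponential(x, y)
  expect_true(any(grepl("unbounded", f$flags)))
})

test_that("sweep-style parameter recovery stays within 20% under noise", {
  # parameter-recovery Monte-Carlo at the simulation's noise scale
  xs <- c(4, 8, 12, 18, 25, 40, 60, 120, 200)
  rec <- withr::with_seed(41, replicate(60, {
    y <- 1.04 * (1 - 2^(-xs / 15)) + stats::rnorm(length(xs), 0, 0.07)
    fit_saturating_exponential(xs, y)$half_constant
  }))
  expect_gt(mean(abs(rec - 15) / 15 < 0.2), 0.8)
  gs <- c(4, 8, 12, 16, 22, 30, 40, 55, 75, 100, 140, 200)
  recd <- withr::with_seed(42, replicate(60, {
    y <- 1.04 * exp(-gs / 25) + stats::rnorm(length(gs), 0, 0.07)
    fit_decaying_exponential(gs, y)$efold_constant
  }))
  expect_gt(mean(abs(recd - 25) / 25 < 0.2), 0.8)
})
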