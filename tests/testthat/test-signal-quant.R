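test_that("normalization maps the reference band to 1 and is idempotent", {
  tc <- make_tc("E-EGF", "pERK", c(0, 10, 20),
                list(c(50, 100, 200)))
  ref <- list(condition = "E-EGF", target = "pERK", time = 10)
  n1 <- normalize_timecourse(tc, ref)
  expect_equal(n1$intensity, c(0.5, 1.0, 2.0))
  # normalizing twice is a no-op
  n2 <- normalize_timecourse(n1, ref)
  expect_identical(n2$intensity, n1$intensity)

  # replicate-matched normalization: each replicate divides by its own ref
  tc2 <- make_tc("E-EGF", "pERK", c(0, 10), list(c(1, 2), c(3, 6)))
  n3 <- normalize_timecourse(tc2, ref)
  expect_equal(n3$intensity[n3$time_min == 10], c(1, 1))

  expect_error(normalize_timecourse(tc, list(condition = "zz",
                                             target = "pERK", time = 10)),
               class = "invalid_reference")
  tc0 <- make_tc("E-EGF", "pERK", c(0, 10), list(c(1, 0)))
  expect_error(normalize_timecourse(tc0, ref), class = "invalid_reference")
})

test_that("trapezoidal AUC matches closed forms and edge interpolation", {
  # rectangle: constant 1 over [0, 60]
  expect_equal(integrated_signal(make_norm_tc(seq(0, 60, 10),
                                              rep(1, 7)),
                                 c(0, 60))$auc, 60)
  # linear ramp f = t/60: trapezoid is exact, integral 30
  expect_equal(integrated_signal(make_norm_tc(c(0, 30, 60),
                                              c(0, 0.5, 1)),
                                 c(0, 60))$auc, 30)
  # all-zero signal
  expect_equal(integrated_signal(make_norm_tc(c(0, 30, 60), c(0, 0, 0)),
                                 c(0, 60))$auc, 0)
  # sampling beyond the window: interpolate the linear ramp to the edges
  tc <- make_norm_tc(seq(0, 80, 20), seq(0, 80, 20) / 60)
  expect_equal(integrated_signal(tc, c(10, 50))$auc,
               (50^2 - 10^2) / (2 * 60))
  # a window not covered by the sampling is an error
  expect_error(integrated_signal(make_norm_tc(c(0, 10, 20), c(1, 1, 1)),
                                 c(0, 60)),
               class = "insufficient_coverage")
})

test_that("AUC is linear in the signal and additive over windows", {
  t <- seq(0, 310, 10)
  y <- perk_curve(t, list(peak_time = 10, peak_width = 0.9,
                          second_onset = 160, second_amp = 0.8,
                          second_rise = 20, second_width = 0.8))
  a_full <- integrated_signal(make_norm_tc(t, y), c(0, 310))$auc
  a1 <- integrated_signal(make_norm_tc(t, y), c(0, 60))$auc
  a2 <- integrated_signal(make_norm_tc(t, y), c(60, 310))$auc
  expect_equal(a1 + a2, a_full, tolerance = 1e-9)
  a_scaled <- integrated_signal(make_norm_tc(t, 3.7 * y), c(0, 310))$auc
  expect_equal(a_scaled, 3.7 * a_full, tolerance = 1e-12)
})

test_that("trapezoid on a dense grid agrees with a Riemann-sum oracle", {
  shape <- list(peak_time = 10, peak_width = 0.9,
                second_onset = NA_real_, second_amp = 0,
                second_rise = 20, second_width = 0.8)
  t <- seq(0, 60, 1)
  a_trap <- integrated_signal(make_norm_tc(t, perk_curve(t, shape)),
                              c(0, 60))$auc
  a_riem <- riemann_auc(function(x) perk_curve(x, shape), c(0, 60))
  expect_lt(abs(a_trap - a_riem) / a_riem, 0.005)
})

test_that("per-replicate AUC summarizes with mean and SD", {
  tc <- make_tc("c", "pERK", c(0, 30, 60),
                list(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)))
  attr(tc, "normalized") <- TRUE
  s <- integrated_signal(tc, c(0, 60))
  expect_equal(s$n_replicates, 3L)
  expect_equal(s$auc_replicates, c(60, 120, 180))
  expect_equal(s$auc, 120)
  expect_equal(s$auc_sd, sd(c(60, 120, 180)))
})

test_that("fold change is a ratio with reciprocity and scale invariance", {
  mk <- function(v) integrated_signal(make_norm_tc(c(0, 30, 60),
                                                   rep(v, 3)), c(0, 60))
  a <- mk(1); b <- mk(0.1)
  expect_equal(fold_change(a, a), 1)
  expect_equal(fold_change(a, b), 10)
  expect_equal(fold_change(a, b) * fold_change(b, a), 1)
  # common rescaling of both inputs cancels
  expect_equal(fold_change(mk(0.25), mk(0.025)), 10)
  b2 <- integrated_signal(make_norm_tc(c(0, 30, 60), rep(1, 3)), c(0, 30))
  expect_error(fold_change(a, b2), class = "window_mismatch")
  z <- mk(0)
  expect_error(fold_change(a, z), class = "undefined_ratio")
})

test_that("onset detection follows the peak-trough-rise definition", {
  # monotone decay has no re-activation
  t <- seq(0, 100, 10)
  r <- reactivation_onset(make_norm_tc(t, exp(-t / 20)))
  expect_true(is.na(r))
  expect_identical(attr(r, "reason"), "no-reactivation")

  # rise_fraction = 0 fires on the first post-trough uptick
  y <- c(0.1, 1, 0.6, 0.3, 0.1, 0.15, 0.4, 0.6)
  tt <- seq(0, 70, 10)
  expect_equal(reactivation_onset(make_norm_tc(tt, y), rise_fraction = 0),
               50)

  # agreement with a literal brute-force scan on varied synthetic shapes
  presets <- scenario_presets()
  for (seed in 1:6) {
    for (amp in c(0.4, 0.8)) {
      shape <- list(peak_time = 10, peak_width = 0.9,
                    second_onset = 160, second_amp = amp,
                    second_rise = 20, second_width = 0.8)
      sc <- scenario_config(sprintf("s%d", seed), ligand_spec("EGF"),
                            r_scale = 10,
                            sampling_times = seq(0, 310, 10),
                            pERK_shape = shape)
      gen <- gen_timecourse(sc, receptor_params(), seed = seed)
      tc <- gen$timecourse
      attr(tc, "normalized") <- TRUE
      got <- reactivation_onset(tc, condition = sc$name, target = "pERK")
      d <- tc[tc$target == "pERK", ]
      ym <- as.numeric(tapply(d$intensity, d$time_min, mean))
      tm <- sort(unique(d$time_min))
      expect_equal(as.numeric(got), brute_onset_scan(tm, ym, 0.2))
    }
  }
})
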