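noiseless_curve <- function(t_half, times = seq(0, 300, by = 60),
                            n_rep = 4L, C0 = 100, peak_time = 0) {
  simulate_decay(decay_truth(t_half = t_half, C0 = C0, sample_times = times,
                             n_replicates = n_rep, noise_cv = 0,
                             peak_time = peak_time, seed = 1))
}

test_that("baseline normalization scales each replicate independently", {
  rec <- data.frame(
    time_min = c(0, 120, 0, 120),
    conc_ng_ml = c(80, 40, 200, 50),
    replicate_id = c("a", "a", "b", "b"))
  norm <- normalize_to_baseline(decay_curve(rec))
  r <- norm$records
  expect_equal(r$conc_ng_ml[r$replicate_id == "a"], c(100, 50))
  expect_equal(r$conc_ng_ml[r$replicate_id == "b"], c(100, 25))
  # already-percent input passes through unchanged
  expect_equal(normalize_to_baseline(norm)$records$conc_ng_ml, r$conc_ng_ml)
  # missing or zero baselines are errors
  expect_error(normalize_to_baseline(decay_curve(rec, baseline_time = 60)),
               "baseline")
  rec0 <- rec; rec0$conc_ng_ml[1] <- 0
  expect_error(normalize_to_baseline(decay_curve(rec0)), "zero baseline")
})

test_that("noiseless mono-exponential data is fitted exactly by both methods", {
  curve <- normalize_to_baseline(noiseless_curve(120))
  for (method in c("loglinear", "nls")) {
    est <- fit_first_order(curve, method = method, n_boot = 0)
    expect_equal(est$t_half, 120, tolerance = 1e-6)
    expect_equal(est$rate_k * est$t_half, log(2), tolerance = 1e-12)
    expect_false(est$stable)
  }
})

test_that("a flat curve is reported stable", {
  est <- fit_first_order(normalize_to_baseline(noiseless_curve(Inf)),
                         n_boot = 0)
  expect_true(est$stable)
  expect_gt(est$t_half, 4 * 300)
})

test_that("declining-phase fits reproduce the post-peak half-life exactly", {
  for (th in c(108, 182)) {
    curve <- noiseless_curve(th, times = c(30, 60, 90, 120), n_rep = 5L,
                             peak_time = 30)
    est <- fit_declining_phase(curve, t_peak = 30, n_boot = 0)
    expect_equal(est$t_half, th, tolerance = 1e-6)
    expect_equal(est$mode, "in_vivo_declining")
  }
})

test_that("declining-phase fits ignore everything before the peak", {
  with_rise <- noiseless_curve(108, times = c(10, 15, 30, 60, 90, 120),
                               n_rep = 3L, peak_time = 30)
  without <- noiseless_curve(108, times = c(30, 60, 90, 120), n_rep = 3L,
                             peak_time = 30)
  e1 <- fit_declining_phase(with_rise, n_boot = 0)
  e2 <- fit_declining_phase(without, n_boot = 0)
  expect_equal(e1$t_half, e2$t_half, tolerance = 1e-9)
  expect_error(fit_declining_phase(noiseless_curve(108, times = c(0, 10)),
                                   t_peak = 30), "after t_peak")
})

test_that("log-linear and nonlinear fits agree under moderate noise", {
  tc <- normalize_to_baseline(
    simulate_decay(decay_truth(t_half = 120, noise_cv = 0.05, seed = 9)))
  a <- fit_first_order(tc, method = "loglinear", seed = 2)
  b <- fit_first_order(tc, method = "nls", seed = 2)
  expect_lt(abs(a$t_half - b$t_half) / a$t_half, 0.1)
  # bootstrap CI brackets the point estimate
  expect_lte(a$ci_low, a$t_half)
  expect_gte(a$ci_high, a$t_half)
})

test_that("estimators are calibrated across the study's half-life range", {
  for (truth_th in c(108, 120, 182)) {
    rs <- recovery_study(decay_truth(t_half = truth_th), n_sim = 200,
                         seed = 17)
    expect_lt(abs(rs$median - truth_th) / truth_th, 0.05)
    expect_gte(mean(abs(rs$estimates - truth_th) / truth_th < 0.15), 0.90)
  }
})

test_that("percent_remaining follows the half-life law", {
  expect_equal(percent_remaining(180, 180), 50)
  expect_equal(percent_remaining(0, 42), 100)
  expect_equal(percent_remaining(240, 120), 25)
  expect_error(percent_remaining(10, 0), "positive")
})

test_that("condition summaries are descriptive means with SEM", {
  mk <- function(vals2h) {
    recs <- do.call(rbind, lapply(seq_along(vals2h), function(i) {
      data.frame(time_min = c(0, 120), conc_ng_ml = c(100, vals2h[i]),
                 replicate_id = sprintf("r%d", i))
    }))
    decay_curve(recs)
  }
  tab <- condition_summary(list(ctrl = mk(c(100, 100)), hot = mk(c(50, 50))),
                           eval_time = 120)
  expect_equal(tab$mean_percent_remaining, c(100, 50))
  expect_equal(tab$sem, c(0, 0))
  single <- condition_summary(list(one = mk(90)), eval_time = 120)
  expect_true(is.na(single$sem))
  expect_error(condition_summary(list(x = mk(50)), eval_time = 60),
               "no record at time")
})

test_that("a protease-gradient design yields a monotone summary", {
  doses <- c(0, 0.03, 0.1, 0.3)
  curves <- lapply(seq_along(doses), function(i) {
    th <- c(Inf, 240, 90, 30)[i]
    normalize_to_baseline(
      simulate_decay(decay_truth(t_half = th, sample_times = c(0, 120),
                                 n_replicates = 2L, noise_cv = 0, seed = i)))
  })
  names(curves) <- sprintf("plasmin_%g", doses)
  tab <- condition_summary(curves, eval_time = 120)
  expect_false(is.unsorted(rev(tab$mean_percent_remaining[order(doses)])))
})
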