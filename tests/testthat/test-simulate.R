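test_that("reference design yields the stated sampling layout", {
  cfg <- simulation_config(n_genes = 10, seed = 11)
  ref <- generate_reference_timecourse(cfg)
  es <- ref$expression
  # 2-h grid over 48 h in triplicate: 24 timepoints, 72 samples
  expect_equal(ncol(es$values), 72)
  expect_equal(length(unique(es$samples$time_abs_hours)), 24)
  expect_equal(unname(table(es$samples$regime)[c("LD", "DD")]),
               c(36L, 36L), ignore_attr = TRUE)
  # day 0 is LD, day 1 is DD
  expect_true(all(es$samples$regime[es$samples$day == 0] == "LD"))
  expect_true(all(es$samples$regime[es$samples$day == 1] == "DD"))
  expect_equal(nrow(ref$truth), 10)
})

test_that("noiseless cyclers are exact cosines peaking at their phase", {
  cfg <- simulation_config(n_genes = 8, cycler_fraction = 0.25,
                           amplitude_to_noise = Inf, replicates = 1)
  ref <- generate_reference_timecourse(cfg, true_phases = c(6, 18))
  t <- ref$expression$samples$time_abs_hours
  g1 <- ref$expression$values[1, ]
  expect_equal(unname(g1), 150 + 100 * cos(2 * pi * (t - 6) / 24),
               tolerance = 1e-12)
  # maximum attained at the ground-truth phase (within one grid step)
  expect_equal(t[which.max(g1)] %% 24, 6)
  # non-cyclers are flat at the mesor
  expect_true(all(ref$expression$values[3:8, ] == 150))
})

test_that("generators are bitwise reproducible given the seed", {
  cfg <- simulation_config(n_genes = 15, seed = 42)
  a <- generate_reference_timecourse(cfg)
  b <- generate_reference_timecourse(cfg)
  expect_identical(a$expression$values, b$expression$values)

  eff <- lapply(1:5, function(i) line_effect(paste0("L", i)))
  ca <- generate_static_cohort(cfg, eff)
  cb <- generate_static_cohort(cfg, eff)
  expect_identical(ca$expression$values, cb$expression$values)

  cfg2 <- simulation_config(n_genes = 15, seed = 43)
  expect_false(identical(a$expression$values,
                         generate_reference_timecourse(cfg2)$expression$values))
})

test_that("static cohort emulates the around-the-clock collection", {
  cfg <- simulation_config(n_genes = 12, seed = 5)
  eff <- lapply(1:141, function(i) line_effect(sprintf("DGRP-%03d", i)))
  coh <- generate_static_cohort(cfg, eff, interval_minutes = 9.5)
  expect_equal(ncol(coh$expression$values), 141)
  ht <- coh$expression$samples$time_hours
  gaps <- diff(ht) %% 24
  expect_equal(unique(round(gaps, 10)), 9.5 / 60)
  expect_equal(nrow(coh$truth), 141)
})

test_that("line effects act through internal clock time", {
  cfg <- simulation_config(n_genes = 8, cycler_fraction = 0.5,
                           amplitude_to_noise = Inf,
                           sampling_interval_hours = 6)
  # a line advanced 6 h with a 24-h period matches the reference 6 h later
  eff <- list(line_effect("ref", 0), line_effect("adv", phase_offset_hours = 6))
  coh <- generate_static_cohort(cfg, eff, interval_minutes = 0.0001)
  t0 <- coh$expression$samples$time_hours[1]
  phases <- attr(coh$truth, "gene_truth")$phase_hours[1:4]
  expected <- 150 + 100 * cos(2 * pi * (t0 + 6 - phases) / 24)
  expect_equal(unname(coh$expression$values[1:4, "adv"]), expected,
               tolerance = 1e-6)

  # a disrupted line (damping 0) is flat at the mesor
  coh2 <- generate_static_cohort(
    cfg, list(line_effect("ok"), line_effect("dead", disrupted = TRUE)))
  expect_true(all(coh2$expression$values[, "dead"] == 150))
  expect_false(all(coh2$expression$values[, "ok"] == 150))

  # zero-effect line equals the reference evaluated at its harvest time
  tau <- coh$expression$samples$time_hours[1]
  expect_equal(unname(coh$expression$values[1:4, "ref"]),
               150 + 100 * cos(2 * pi * (tau - phases) / 24))
})

test_that("deviating trace lives on the 144-point day grid", {
  cfg <- simulation_config(amplitude_to_noise = Inf)
  tr <- make_deviating_trace(24, 0, cfg)
  expect_equal(nrow(tr), 144)
  expect_equal(tr$value, 100 * sin(2 * pi * tr$time_hours / 24),
               tolerance = 1e-12)
  # a 30-h clock completes 24/30 of a cycle over the day
  tr30 <- make_deviating_trace(30, 0, cfg)
  expect_equal(tr30$value, 100 * sin(2 * pi * tr30$time_hours / 30),
               tolerance = 1e-12)
  expect_equal(nrow(make_deviating_trace(20, 3, cfg)), 144)
})

test_that("invalid simulation configs are rejected with all problems listed", {
  expect_error(simulation_config(mesor = 0), "mesor")
  expect_error(simulation_config(sampling_interval_hours = 7),
               "integer multiple")
  expect_error(simulation_config(mesor = 50, amplitude = 100),
               "allow_negative")
  expect_silent(simulation_config(mesor = 50, amplitude = 100,
                                  allow_negative = TRUE))
  # several violations reported at once
  err <- tryCatch(simulation_config(mesor = -1, cycler_fraction = 2),
                  error = conditionMessage)
  expect_match(err, "mesor")
  expect_match(err, "cycler_fraction")
})

test_that("noiseless CV follows a/(m*sqrt(2)) and clears the amplitude filter", {
  cfg <- simulation_config(n_genes = 4, cycler_fraction = 0.5,
                           amplitude_to_noise = Inf, replicates = 1,
                           amplitude = 45, mesor = 150)   # a/m = 0.3
  ref <- generate_reference_timecourse(cfg)
  cv <- gene_summary(ref$expression)$cv[1:2]
  # finite-grid sample SD inflates 1/sqrt(2) by sqrt(n/(n-1))
  expect_equal(cv, rep(45 / (150 * sqrt(2)), 2), tolerance = 0.03)
  expect_true(all(cv > 0.20))
})
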