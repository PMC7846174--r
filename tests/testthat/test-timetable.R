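test_that("cosine bundle tiles the period at the requested increment", {
  b <- build_cosine_bundle(24, 10 / 60)
  expect_length(b$peak_times, 144)
  expect_equal(b$peak_times[1:3], c(0, 1, 2) / 6)
  expect_true(all(diff(b$peak_times) > 0))

  expect_equal(build_cosine_bundle(24, 6)$peak_times, c(0, 6, 12, 18))
  expect_length(build_cosine_bundle(20, 10 / 60)$peak_times, 120)
  expect_error(build_cosine_bundle(24, 0.7), "integer multiple")
})

test_that("cosine waves peak at their peak time and trough at the antipode", {
  b <- build_cosine_bundle(24, 6)
  w <- circatime:::bundle_values(b, c(6, 18))
  expect_equal(w[1, 2], 1)    # wave peaking at 6, evaluated at t = 6
  expect_equal(w[2, 2], -1)   # same wave half a period later
})

test_that("rhythmicity score recovers the phase of a clean cosine", {
  t <- seq(0, 46, by = 2)
  rs <- rhythmicity_score(cos(2 * pi * (t - 6) / 24), t)
  expect_equal(rs$r_max, 1, tolerance = 1e-12)
  expect_equal(rs$peak_time_hours, 6)
  expect_error(rhythmicity_score(rep(2, 24), t), "constant")
})

test_that("rhythmicity score agrees with a brute-force wave scan", {
  set.seed(33)
  t <- seq(0, 46, by = 2)
  bundle <- build_cosine_bundle()
  for (i in 1:5) {
    y <- 3 + 2 * cos(2 * pi * (t - runif(1, 0, 24)) / 24) + rnorm(24, sd = 0.8)
    got <- rhythmicity_score(y, t, bundle)
    # independent scan: one cor() call per wave
    rs <- vapply(bundle$peak_times, function(p)
      cor(y, cos(2 * pi * (t - p) / 24)), numeric(1))
    expect_equal(got$r_max, max(rs), tolerance = 1e-12)
    expect_equal(got$peak_time_hours, bundle$peak_times[which.max(rs)])
  }
})

test_that("TIG selection applies both the correlation and the CV filter", {
  t <- seq(0, 46, by = 2)
  set.seed(9)
  m <- rbind(
    strong1 = 150 + 100 * cos(2 * pi * (t - 4) / 24),
    strong2 = 150 + 100 * cos(2 * pi * (t - 16) / 24),
    low_cv  = 150 + 5 * cos(2 * pi * (t - 8) / 24),     # r = 1, CV ~ 0.024
    low_r   = 150 + 40 * rnorm(24))                     # high CV, no rhythm
  es <- tiny_eset(m, times = t,
                  regime = rep(c("LD", "DD"), each = 12))
  model <- select_tigs(es)
  expect_setequal(model$tigs$gene_id, c("strong1", "strong2"))
  expect_equal(sort(model$tigs$mpt_hours), c(4, 16))
  expect_true(all(model$tigs$r_max > 0.5 & model$tigs$cv > 0.20))

  # with only rejected genes the timetable is unusable
  expect_error(select_tigs(tiny_eset(m[3:4, , drop = FALSE], times = t)),
               "unusable")
})

test_that("selection recovers exactly the true cyclers with accurate MPTs", {
  cfg <- simulation_config(n_genes = 40, cycler_fraction = 0.25,
                           amplitude_to_noise = Inf)
  ref <- generate_reference_timecourse(cfg)
  model <- select_tigs(ref$expression)
  truth <- ref$truth[ref$truth$cycling, ]
  expect_setequal(model$tigs$gene_id, truth$gene_id)
  mpt <- model$tigs$mpt_hours[match(truth$gene_id, model$tigs$gene_id)]
  err <- abs(circular_difference(mpt, truth$phase_hours))
  expect_true(all(err <= 10 / 60 + 1e-9))
})

test_that("per-regime selection excludes genes rhythmic in only one regime", {
  t <- seq(0, 46, by = 2)
  regime <- rep(c("LD", "DD"), each = 12)
  damp <- ifelse(regime == "LD", 1, 0)         # cycles only under LD
  m <- rbind(both1 = 150 + 100 * cos(2 * pi * (t - 2) / 24),
             both2 = 150 + 100 * cos(2 * pi * (t - 14) / 24),
             ld_only = 150 + 100 * damp * cos(2 * pi * (t - 6) / 24))
  es <- tiny_eset(m, times = t, regime = regime)
  unified <- select_tigs(es, mode = "LDDD_05")
  split_mode <- select_tigs(es, mode = "LD_DD_05")
  expect_true("ld_only" %in% unified$tigs$gene_id)
  expect_false("ld_only" %in% split_mode$tigs$gene_id)
  expect_setequal(split_mode$tigs$gene_id, c("both1", "both2"))
  # MPT of surviving genes comes from the unified fit
  expect_equal(split_mode$tigs$mpt_hours,
               unified$tigs$mpt_hours[match(split_mode$tigs$gene_id,
                                            unified$tigs$gene_id)])
})

test_that("prediction is self-consistent and shift-equivariant when noiseless", {
  ref <- tiling_reference(n_tigs = 12)
  model <- select_tigs(ref$expression)
  truth <- ref$truth

  # sample harvested at ZT8 predicts 8.0
  j <- which(ref$expression$samples$time_abs_hours == 8)[1]
  p <- predict_time(model, ref$expression$values[, j])
  expect_equal(p$predicted_time_hours, 8)
  expect_equal(p$r_at_max, 1, tolerance = 1e-9)

  # a line advanced 6 h but harvested at 8 reads out internal time 14
  v <- 150 + 100 * cos(2 * pi * (14 - truth$phase_hours) / 24)
  names(v) <- truth$gene_id
  expect_equal(predict_time(model, v)$predicted_time_hours, 14)

  # shift equivariance across the bundle grid
  for (delta in c(1 / 6, 5, 11.5, 17 + 1 / 6)) {
    v2 <- 150 + 100 * cos(2 * pi * (8 + delta - truth$phase_hours) / 24)
    names(v2) <- truth$gene_id
    expect_equal(predict_time(model, v2)$predicted_time_hours,
                 (8 + delta) %% 24)
  }
})

test_that("prediction needs at least two TIGs with distinct peak times", {
  ref <- tiling_reference(n_tigs = 6)
  model <- select_tigs(ref$expression)
  v <- ref$expression$values[, 3]
  expect_error(predict_time(model, v[1]), "2 TIGs")
  expect_error(predict_time(model, unname(v)), "named")
  flat <- setNames(rep(1, 6), names(v))
  expect_error(predict_time(model, flat), "zero-variance")
})

test_that("argmax over the bundle matches an exhaustive 1-min phase scan", {
  ref <- tiling_reference(n_tigs = 8)
  model <- select_tigs(ref$expression)
  truth <- ref$truth
  set.seed(71)
  for (i in 1:5) {
    tau <- runif(1, 0, 24)
    v <- 150 + 100 * cos(2 * pi * (tau - truth$phase_hours) / 24) +
      rnorm(8, sd = 25)
    names(v) <- truth$gene_id
    got <- predict_time(model, v, scale = FALSE)$predicted_time_hours
    phis <- seq(0, 24 - 1 / 60, by = 1 / 60)
    rs <- vapply(phis, function(phi)
      cor(v, cos(2 * pi * (model$tigs$mpt_hours - phi) / 24)), numeric(1))
    oracle <- phis[which.max(rs)]
    expect_lte(abs(circular_difference(got, oracle)), 10 / 60 + 1e-9)
  }
})

test_that("circular difference wraps onto (-12, 12]", {
  expect_equal(circular_difference(1, 23), 2)
  expect_equal(circular_difference(12, 0), 12)
  expect_equal(circular_difference(7.25, 7.25), 0)
  expect_equal(circular_difference(23, 1), -2)
  set.seed(3)
  a <- runif(200, 0, 24); b <- runif(200, 0, 24)
  d <- circular_difference(a, b)
  expect_true(all(d > -12 & d <= 12))
  # antisymmetry away from the antipode
  expect_equal(circular_difference(b, a)[abs(d) < 12 - 1e-9],
               -d[abs(d) < 12 - 1e-9])
})
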