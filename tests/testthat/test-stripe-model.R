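# Generative stripe model and synthetic profiles.

test_that("a noiseless single-stripe model peaks at its centre with its amplitude", {
  par <- single_stripe_params(mu = 40, sigma = 1, A = 1)
  expect_equal(eval_stripe_model(par, 36, 40), 1)
  expect_equal(which.max(eval_stripe_model(par, 36, seq(0, 100, 0.01))),
               4001L)   # x = 40 on the dense grid
  pr <- generate_profile(par, t = 36, seed = 1)
  # sampled at nucleus spacing: the maximum sits within one spacing of 40
  expect_lt(abs(pr$ap[which.max(pr$intensity)] - 40), 0.9)
  expect_gt(max(pr$intensity), 0.99)
})

test_that("profiles are deterministic given the seed and distinct across seeds", {
  par <- stripe_model_params("WT")
  p1 <- generate_profile(par, 36, seed = 7)
  p2 <- generate_profile(par, 36, seed = 7)
  p3 <- generate_profile(par, 36, seed = 8)
  expect_identical(p1$intensity, p2$intensity)
  expect_false(identical(p1$intensity, p3$intensity))
})

test_that("times outside the modeled window are rejected", {
  par <- stripe_model_params("WT")
  expect_error(generate_profile(par, 5, seed = 1), "outside the modeled window")
  expect_error(generate_profile(par, 200, seed = 1), "outside the modeled window")
  expect_error(generate_embryo_profiles(par, times = c(30, 90), seed = 1),
               "outside the modeled window")
})

test_that("preset amplitude-ratio trajectories have the contracted shapes", {
  ts <- seq(30, 48, by = 3)
  ratio <- function(par) vapply(ts, function(t)
    stripeflow:::stripe_amplitude(par, 2, t) /
      stripeflow:::stripe_amplitude(par, 1, t), numeric(1))
  r_wt <- ratio(stripe_model_params("WT"))
  r_mse <- ratio(stripe_model_params("MSE"))
  r_inv <- ratio(stripe_model_params("INV_MSE"))
  expect_true(all(diff(r_wt) > 0))
  expect_true(all(diff(r_mse) < 0))
  expect_true(all(abs(diff(r_inv)) < 1e-8))
  # the ratio is larger late than at first stripe individuation
  expect_gt(r_wt[length(ts)], r_wt[1])
})

test_that("parameter validation rejects malformed models", {
  expect_error(stripe_model_params(mu = c(40, 35, 50)), "strictly increasing")
  expect_error(stripe_model_params(sigma = rep(-1, 7)), "positive")
  expect_error(stripe_model_params(amp = matrix(-1, 7, 11)), "nonnegative")
})

test_that("zero positional jitter gives identical true borders; sd is recovered at large n", {
  par0 <- stripe_model_params("WT", sigma_pos = 0, border_jitter_sd = 0,
                              rel_amp_sd = 0)
  f <- lapply(1:5, function(i) {
    eff <- stripeflow:::with_seed(i, stripeflow:::draw_embryo_effects(par0))
    true_stripe_features(par0, 45, embryo = eff, step = 0.02)
  })
  pos <- vapply(f, function(x) x$stripe2$anterior_border, numeric(1))
  expect_lt(diff(range(pos)), 0.05)

  # law of large numbers: sample sd of true anterior borders ~ sigma_pos
  par <- stripe_model_params("WT", sigma_pos = 1.5)
  sh <- stripeflow:::with_seed(42, stats::rnorm(500, 0, 1.5))
  expect_equal(stats::sd(sh), 1.5, tolerance = 0.12)
  borders <- vapply(seq_along(sh), function(i) {
    eff <- list(z_pos = sh[i] / 1.5, a2_factor = 1, da = 0, dp = 0)
    true_stripe_features(par, 45, embryo = eff, step = 0.05)$stripe2$anterior_border
  }, numeric(1))
  expect_equal(stats::sd(borders), 1.5, tolerance = 0.12)
})

test_that("29C preset compresses the developmental timeline by the landmark ratio", {
  p25 <- stripe_model_params("WT", temperature = "25C")
  p29 <- stripe_model_params("WT", temperature = "29C")
  sc <- 38.2 / 30.6
  expect_equal(p29$time_scale, sc)
  # amplitude at absolute time t at 29C equals amplitude at t*sc at 25C
  expect_equal(stripeflow:::stripe_amplitude(p29, 2, 30),
               stripeflow:::stripe_amplitude(p25, 2, 30 * sc))
})

test_that("cohorts record per-embryo seeds and share parameters", {
  par <- stripe_model_params("WT")
  coh <- generate_cohort(par, 3, times = c(36, 39, 42), seed = 5)
  expect_length(coh, 3)
  expect_identical(attr(coh, "params")$preset, "WT")
  expect_false(identical(coh[[1]]$profiles[[1]]$intensity,
                         coh[[2]]$profiles[[1]]$intensity))
  expect_error(generate_cohort(par, 1), "at least 2")
})

test_that("rendered nucleus means match the profile model when noiseless", {
  # flat expression: every nucleus mean ~ the constant, within quantization
  par <- single_stripe_params(mu = 50, sigma = 5, A = 0, baseline = 0.5)
  sc <- small_scene(read_noise = 0, shot_scale = 0)
  ser <- generate_embryo_series(par, sc, times = 36, seed = 2)
  fr <- ser$frames[["36"]]
  seg <- segment_frame(fr$nuclear, fr$reporter)
  m <- match_to_truth(seg$records, ser$truth$nuclei, max_dist = 4)
  expect_gte(nrow(m), 0.95 * nrow(ser$truth$nuclei))
  tv <- ser$truth$values_rendered[m$truth_row, 1]
  ev <- seg$records$mean_fluo[m$record_row]
  expect_lt(max(abs(ev - tv) / tv), 0.01)
})

test_that("truth AP positions span the egg with anterior at the left edge", {
  par <- stripe_model_params("WT")
  ser <- generate_embryo_series(par, small_scene(), times = 36, seed = 3)
  tn <- ser$truth$nuclei
  expect_true(all(tn$ap_percent_el >= 0 & tn$ap_percent_el <= 100))
  expect_lt(tn$ap_percent_el[which.min(tn$x_px)], 10)
  expect_gt(tn$ap_percent_el[which.max(tn$x_px)], 90)
  expect_setequal(unique(tn$side), c("dorsal", "ventral"))
})

test_that("the membrane-artifact schedule is recorded per injected split", {
  sched <- data.frame(time = 36, nucleus = c(3, 9, 15))
  ser <- generate_embryo_series(stripe_model_params("WT"),
                                small_scene(membrane_schedule = sched),
                                times = 36, seed = 4)
  expect_identical(nrow(ser$truth$splits), 3L)
  expect_setequal(ser$truth$splits$nucleus, c(3, 9, 15))
})

test_that("infeasible scene geometry is rejected", {
  expect_error(scene_spec(n_nuclei = 500), "do not fit")
  expect_error(scene_spec(band_px = 6), "thinner than a nucleus")
})

test_that("count tables follow the scaled multinomial and are reproducible", {
  cross <- standard_intercross()
  t1 <- generate_count_table(cross, 1000, seed = 9)
  t2 <- generate_count_table(cross, 1000, seed = 9)
  expect_identical(t1, t2)
  expect_identical(sum(t1$count), 1000L)
  # multiplier 0 silences a class
  fx <- cross_expectation(cross)
  victim <- fx$class[1]
  mult <- stats::setNames(0, victim)
  t3 <- generate_count_table(cross, 2000, viability_multipliers = mult, seed = 9)
  expect_identical(sum(t3$count[t3$class == victim]), 0L)
  # multinomial consistency: observed/expected -> 1 at large n
  t4 <- generate_count_table(cross, 2e5, seed = 10)
  obs <- tapply(t4$count, t4$class, sum)[fx$class]
  expect_lt(max(abs(obs / (2e5 * fx$freq) - 1)), 0.05)
  expect_error(generate_count_table(cross, 100,
                                    viability_multipliers = c(bogus = 0.5)),
               "unknown genotype class")
})
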