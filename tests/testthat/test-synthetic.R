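test_that("the same seed reproduces a session exactly", {
  cfg <- small_generator_config(seed = 123)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1, s2)
  expect_equal(length(s1$train), 4 * 8)
  expect_equal(length(s1$test), 4 * 8)
  s3 <- generate_session(small_generator_config(seed = 124))
  expect_false(identical(s1$train[[1]]$envelope$values, s3$train[[1]]$envelope$values))
})

test_that("noise-free envelopes equal the synergy reconstruction exactly", {
  cfg <- generator_config(seed = 2, snr = Inf, baseline_level = 0,
                          amplitude_cv = 0, activation_cv = 0, angle_jitter_deg = 0)
  set.seed(2)
  tr <- generate_trial("NE", cfg)
  tune <- pmax(0, cos((45 - cfg$preferred_angles_deg) * pi / 180))
  n <- length(tr$time_s)
  t_on <- (tr$onset_index - 1) / 100
  t_peak <- t_on + 0.5 * cfg$movement_duration_s
  sig <- cfg$bell_width_frac * cfg$movement_duration_s
  bell <- exp(-(tr$time_s - t_peak)^2 / (2 * sig^2))
  bell[tr$time_s < t_on] <- 0
  expect_equal(tr$envelope$values, cfg$W_true %*% outer(tune, bell),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero tuning exponent removes direction dependence of amplitudes", {
  cfg <- generator_config(seed = 3, tuning_exponent = 0, snr = Inf,
                          baseline_level = 0, amplitude_cv = 0,
                          activation_cv = 0, angle_jitter_deg = 0)
  set.seed(1); a <- generate_trial("N", cfg)
  set.seed(1); b <- generate_trial("SE", cfg)
  expect_equal(a$envelope$values, b$envelope$values)
})

test_that("minimum-jerk reaches end on target with zero boundary velocity", {
  mj <- min_jerk(c(0, 0, 0), c(0.25, 0, 0), 1.2, 100)
  expect_equal(mj$position[1, ], c(0, 0, 0))
  expect_lt(max(abs(mj$position[nrow(mj$position), ] - c(0.25, 0, 0))), 1e-9)
  expect_equal(mj$velocity[1, ], c(0, 0, 0))
  expect_lt(max(abs(mj$velocity[nrow(mj$velocity), ])), 1e-9)
  # midpoint passes through half the displacement (symmetry)
  mid <- mj$position[(nrow(mj$position) + 1) / 2, 1]
  expect_equal(mid, 0.125, tolerance = 1e-9)
})

test_that("kinematic onset lags EMG onset by the electromechanical delay", {
  cfg <- generator_config(seed = 4, endpoint_sd_m = 0)
  set.seed(4)
  tr <- generate_trial("W", cfg)
  disp <- sqrt(rowSums(sweep(tr$trajectory, 2, cfg$layout$home)^2))
  first_move <- which(disp > 1e-9)[1]
  expect_equal(first_move - tr$onset_index,
               round(cfg$electromechanical_delay_s * 100), tolerance = 1)
  expect_equal(tr$trajectory[1, ], cfg$layout$home)
  final <- tr$trajectory[nrow(tr$trajectory), ]
  expect_lt(sqrt(sum((final - cfg$layout$targets["W", ])^2)), 0.05)
})

test_that("envelopes are non-negative under extreme noise settings", {
  cfg <- generator_config(seed = 5, snr = 1, baseline_level = 0.5)
  set.seed(5)
  for (d in c("N", "SW")) {
    tr <- generate_trial(d, cfg)
    expect_true(all(tr$envelope$values >= 0))
  }
})

test_that("rotating preferred angles by 45 degrees permutes direction tuning", {
  cfg1 <- generator_config(seed = 6)
  cfg2 <- generator_config(seed = 6,
                           preferred_angles_deg = cfg1$preferred_angles_deg + 45)
  for (i in seq_along(DIRECTIONS)[-8]) {
    t1 <- synid:::synergy_tuning(DIRECTIONS[i + 1], cfg2)
    t2 <- synid:::synergy_tuning(DIRECTIONS[i], cfg1)
    expect_equal(t1, t2, tolerance = 1e-12)
  }
})

test_that("NMF on a noise-free session recovers the true synergies", {
  cfg <- generator_config(seed = 7, n_train = 3, n_test = 0, snr = Inf,
                          baseline_level = 0)
  ses <- generate_session(cfg)
  E <- do.call(cbind, lapply(ses$train, function(tr)
    tr$envelope$values[, tr$onset_index:(tr$onset_index + 60)]))
  fit <- extract_synergies(E, n_syn = 4, seed = 7)
  cs <- matched_cosines(fit$model$W, cfg$W_true)
  expect_gte(mean(cs), 0.99)
  expect_gte(min(cs), 0.95)
})

test_that("raw-mode trials pass through the envelope chain to the right scale", {
  cfg <- small_generator_config(seed = 8)
  set.seed(8)
  raw <- generate_raw_trial("N", cfg)
  expect_s3_class(raw, "emg_trial")
  expect_equal(raw$fs_raw, 1000)
  env <- decimate_envelope(compute_envelope(raw), 100)
  set.seed(8)
  ref <- generate_trial("N", cfg)
  # peak envelope of the reconstruction tracks the generating profile
  peak_ratio <- max(env$values) / max(ref$envelope$values)
  expect_gt(peak_ratio, 0.6)
  expect_lt(peak_ratio, 1.4)
})
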