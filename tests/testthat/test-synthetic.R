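model <- bruise_model()

test_that("model constructor validates its parameters", {
  expect_error(bruise_model(pool_depth_final = 0.6), "shallower")
  expect_error(bruise_model(epidermal_amp = -1), "non-negative")
  expect_error(bruise_model(pool_rise_time = 0), "positive")
})

test_that("zero-amplitude model yields identically zero profiles", {
  m0 <- bruise_model(epidermal_amp = 0, pool_amp_peak = 0)
  g <- depth_grid(100L, 2.0)
  for (tt in c(0, 24, 200)) {
    expect_true(all(bruise_profile(m0, 532, tt, g)$delta_T_K == 0))
    expect_true(all(bruise_profile(m0, 1064, tt, g)$delta_T_K == 0))
  }
  expect_true(all(healthy_profile(m0, 532, g)$delta_T_K == 0))
})

test_that("pool center follows the stated linear migration", {
  # z_b(tau) = 0.55 - (0.55 - 0.30) * min(tau, 168)/168
  expect_equal(pptrbruise:::pool_center(model, 0), 0.55)
  expect_equal(pptrbruise:::pool_center(model, 72), 0.55 - 0.25 * 72 / 168,
               tolerance = 1e-12)
  expect_equal(pptrbruise:::pool_center(model, 168), 0.30)
  expect_equal(pptrbruise:::pool_center(model, 400), 0.30)
  zb72 <- pptrbruise:::pool_center(model, 72)
  expect_true(zb72 > 0.30 && zb72 < 0.55)
})

test_that("1064 nm bruise carries heat beyond 2 mm, 532 nm does not", {
  g <- depth_grid(400L, 3.0)
  deep_1064 <- bruise_profile(model, 1064, 48, g)
  expect_gt(max(deep_1064$delta_T_K[deep_1064$depth_mm > 2]), 1e-3)
  deep_532 <- bruise_profile(model, 532, 48, g)
  expect_lt(max(deep_532$delta_T_K[deep_532$depth_mm > 2]), 1e-3)
})

test_that("healthy profiles show the expected vascular peak structure", {
  g <- depth_grid(400L, 3.0)
  h1064 <- healthy_profile(model, 1064, g)
  pk <- find_profile_peaks(h1064)
  expect_gte(nrow(pk), 3)
  expect_lt(pk$depth_mm[1], 0.1)
  expect_lt(abs(pk$depth_mm[2] - 0.25), 0.05)   # papillary dermis
  expect_gt(pk$depth_mm[3], 1.0)                # deep blood net
  h532 <- healthy_profile(model, 532, depth_grid(400L, 2.0))
  expect_lt(max(h532$delta_T_K[h532$depth_mm > 1.2]), 1e-6)
  # removing the epidermal component removes the superficial peak
  m_no_epi <- bruise_model(epidermal_amp = 0)
  pk0 <- find_profile_peaks(healthy_profile(m_no_epi, 532, g),
                            min_prominence = 1e-9)
  expect_true(nrow(pk0) == 0 || all(pk0$depth_mm > 0.15))
})

test_that("swelling adds a deep 1064 nm component strongest early", {
  g <- depth_grid(400L, 3.5)
  m_sw <- bruise_model(swelling_amp = 0.2)
  plain <- bruise_profile(model, 1064, 24, g)
  swollen <- bruise_profile(m_sw, 1064, 24, g)
  extra_early <- integral_under_curve(swollen) - integral_under_curve(plain)
  expect_gt(extra_early, 0)
  late_extra <- integral_under_curve(bruise_profile(m_sw, 1064, 240, g)) -
    integral_under_curve(bruise_profile(model, 1064, 240, g))
  expect_gt(extra_early, late_extra)
  expect_error(bruise_profile(model, 800, 24, g), "532 or 1064")
})

test_that("simulated repeats are reproducible with calibrated noise", {
  k <- build_kernel_matrix(depth_grid(60L, 1.5), time_grid(0.5, 0.005))
  prof <- bruise_profile(model, 532, 72, k$depth_grid)
  clean <- simulate_measurement(prof, k, noise_sd = 0, n_repeats = 2, seed = 5)
  projected <- forward_project(prof, k)$delta_T_K
  for (r in 1:2)
    expect_identical(clean$delta_T_K[clean$`repeat` == r], projected)
  a <- simulate_measurement(prof, k, noise_sd = 0.005, n_repeats = 5, seed = 5)
  b <- simulate_measurement(prof, k, noise_sd = 0.005, n_repeats = 5, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_measurement(prof, k, noise_sd = 0.005, n_repeats = 5, seed = 6)
  expect_false(identical(a$delta_T_K, c2$delta_T_K))
  # per-sample SD across repeats ~ noise_sd; SD of the repeat mean ~ /sqrt(5)
  wide <- matrix(a$delta_T_K, ncol = 5)
  per_sample_sd <- apply(wide, 1, sd)
  expect_lt(abs(mean(per_sample_sd) - 0.005) / 0.005, 0.4)
  mean_resid_sd <- sd(rowMeans(wide) - projected)
  expect_lt(abs(mean_resid_sd - 0.005 / sqrt(5)) / (0.005 / sqrt(5)), 0.4)
  expect_error(simulate_measurement(prof, k, noise_sd = -1), "non-negative")
  expect_error(simulate_measurement(prof, k, n_repeats = 11), "between 1 and 10")
})

test_that("a simulated study retains ground truth and session structure", {
  st <- simulate_bruise_study(model, session_times = c(24, 96),
                              noise_sd = 0, seed = 3,
                              settings = small_settings())
  counts <- dplyr::count(st$signals, .data$site, .data$wavelength_nm,
                         .data$time_h, .data$`repeat`)
  reps <- dplyr::count(dplyr::distinct(counts, .data$site, .data$wavelength_nm,
                                       .data$time_h, .data$`repeat`),
                       .data$site, .data$wavelength_nm, .data$time_h)
  expect_true(all(reps$n >= 3 & reps$n <= 5))
  # ground truth retained for every (site, wavelength, session)
  truth_groups <- dplyr::distinct(st$truth, .data$site, .data$wavelength_nm,
                                  .data$time_h)
  expect_identical(nrow(truth_groups), 8L)
  # noiseless signals equal the forward projection of the retained truth
  sig1 <- dplyr::filter(st$signals, site == "bruise", wavelength_nm == 532,
                        time_h == 24, `repeat` == 1)
  tru1 <- dplyr::filter(st$truth, site == "bruise", wavelength_nm == 532,
                        time_h == 24)
  expect_equal(sig1$delta_T_K,
               forward_project(tru1, st$kernels[["532"]])$delta_T_K,
               tolerance = 1e-12)
  expect_error(simulate_bruise_study(model, session_times = c(48, 24)),
               "increasing")
})

test_that("zero-amplitude zero-noise study produces silent signals", {
  m0 <- bruise_model(epidermal_amp = 0, pool_amp_peak = 0)
  st <- simulate_bruise_study(m0, session_times = 24, noise_sd = 0,
                              seed = 1, settings = small_settings())
  expect_true(all(st$signals$delta_T_K == 0))
})

test_that("study generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(simulate_bruise_study(model, session_times = c(24),
                                  noise_sd = 0.005, seed = 9,
                                  settings = small_settings()))
  expect_identical(rnorm(3), before)
})
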