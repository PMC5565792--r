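test_that("success probability follows the psychometric model", {
  m <- patient_ability_model(ability = list(paretic = 0.5, nonparetic = 0.8),
                             lapse = 0)
  # far-below-ability difficulty saturates
  easy <- rep(0.5 - 10 / m$slope, 4)
  expect_gt(trial_success_prob(m, easy, "paretic"), 0.99)
  # difficulty equal to ability is the midpoint
  expect_equal(trial_success_prob(m, rep(0.5, 4), "paretic"), 0.5)
  # lapse scales the ceiling
  ml <- patient_ability_model(ability = list(paretic = 0.5, nonparetic = 0.8),
                              lapse = 0.1)
  expect_equal(trial_success_prob(ml, rep(0.5, 4), "paretic"), 0.45)
  # the minimum margin is binding
  mixed <- c(trajectory_range = 0.1, sphere_size = 0.1,
             sphere_velocity = 0.1, flexion_range = 0.5)
  expect_equal(trial_success_prob(m, mixed, "paretic"), 0.5)
})

test_that("dimension mismatches are rejected with the offending name", {
  m <- patient_ability_model()
  expect_error(trial_success_prob(m, rep(0.5, 3)), "3 dimension")
  expect_error(
    trial_success_prob(m, c(trajectory_range = 0.5, sphere_size = 0.5,
                            sphere_velocity = 0.5, wrong_dim = 0.5)),
    "wrong_dim")
})

test_that("simulated outcomes are calibrated to the closed-form probability", {
  m <- patient_ability_model(ability = list(paretic = 0.55, nonparetic = 0.75))
  d <- rep(0.52, 4)
  p <- trial_success_prob(m, d, "paretic")
  set.seed(71)
  n <- 10000
  hits <- sum(replicate(n, simulate_trial_outcome(m, d, "paretic")))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})

test_that("kinematic streams honour the task geometry and glove range", {
  frozen <- patient_ability_model(reach_factor = c(paretic = 0, nonparetic = 1))
  still <- generate_kinematic_session(frozen, "wipe", "paretic",
                                      duration_s = 5, noise_sd = 0)
  expect_true(all(still$x_m == still$x_m[1]))
  expect_true(all(still$y_m == still$y_m[1]))

  full <- patient_ability_model(flexion_ceiling = c(paretic = 1, nonparetic = 1))
  sq <- generate_kinematic_session(full, "squeeze", "paretic",
                                   duration_s = 10, noise_sd = 0)
  expect_equal(max(sq$flex_f1), 1.0)

  set.seed(5)
  noisy <- generate_kinematic_session(patient_ability_model(), "squeeze",
                                      duration_s = 20, noise_sd = 0.05)
  flex <- as.matrix(noisy[paste0("flex_f", 1:5)])
  expect_true(all(flex >= 0 & flex <= 1))
  expect_true(all(diff(noisy$time_s) > 0))
  expect_equal(median(diff(noisy$time_s)), 1 / 30)

  expect_error(generate_kinematic_session(full, "wipe", duration_s = -1),
               "positive")
})

test_that("map acquisition reproduces the truth at the centroid and escalates", {
  tr <- map_truth(centroid = c(ml = 10, ap = -5), noise_cv = 0)
  map <- acquire_motor_map(tr, session = "pre")
  at_centre <- map[map$ml_mm == 10 & map$ap_mm == -5, ]
  expect_equal(at_centre$mep_uv[1], tr$peak)
  expect_equal(attr(map, "rmt"), tr$rmt)

  post <- acquire_motor_map(map_truth(excitability = 1.5, noise_cv = 0),
                            session = "post")
  centre_amp <- post$mep_uv[post$ml_mm == 0 & post$ap_mm == 0]
  expect_equal(centre_amp[1], 400 * 1.5)

  # intensity capped at the stimulator ceiling leaves the map silent
  weak <- map_truth(peak = 52, rmt = 95, noise_cv = 0)
  silent <- acquire_motor_map(weak)
  expect_true(attr(silent, "unmappable"))
  expect_equal(sum(silent$mep_uv > 50), 0)
})

test_that("ray-wise acquisition stops after two consecutive silent sites", {
  tr <- map_truth(centroid = c(0, 0), extent = 4, noise_cv = 0)
  map <- acquire_motor_map(tr, grid_spacing_mm = 5,
                           protocol = map_protocol(max_radius_mm = 40))
  # along +ml axis expected amplitudes fall below threshold; at most two
  # consecutive silent sites are recorded per ray
  axis <- map[map$ap_mm == 0 & map$ml_mm > 0, ]
  axis <- axis[order(axis$ml_mm), ]
  silent <- axis$mep_uv <= 50
  runs <- rle(silent)
  expect_lte(max(runs$lengths[runs$values]), 2)
})

test_that("a cohort with the same seed is byte-identical", {
  a <- generate_cohort(n_treated = 2, n_control = 2, seed = 9,
                       n_sessions = 2, trials_per_subtask = 10, n_nbs = 2,
                       eval_duration_s = 5)
  b <- generate_cohort(n_treated = 2, n_control = 2, seed = 9,
                       n_sessions = 2, trials_per_subtask = 10, n_nbs = 2,
                       eval_duration_s = 5)
  expect_identical(a$panels, b$panels)
  expect_identical(a$training, b$training)
  expect_identical(a$kinematics, b$kinematics)
  expect_identical(a$map_sites, b$map_sites)
  c2 <- generate_cohort(n_treated = 2, n_control = 2, seed = 10,
                        n_sessions = 2, trials_per_subtask = 10, n_nbs = 2,
                        eval_duration_s = 5)
  expect_false(identical(a$panels, c2$panels))
})

test_that("a null cohort yields a near-zero effect size", {
  set.seed(31)
  panel <- generate_outcome_panels(1000, 1000, effects_w3 = c(CAHAI = 0),
                                   effects_w12 = c(CAHAI = 0),
                                   scales = "CAHAI")
  cah <- panel[panel$scale == "CAHAI", ]
  imp <- cah$t3 - cah$t0
  a <- imp[cah$group == "RGS"]; b <- imp[cah$group == "control"]
  d <- cohens_d(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
  expect_lt(abs(d), 0.1)
})

test_that("Monte-Carlo power at a moderate effect matches the analytic value", {
  set.seed(17)
  power <- mc_power_mann_whitney(0.48, 17, 18, replicates = 600)
  # normal-approximation power of the two-sided two-sample comparison
  ncp <- 0.48 * sqrt(17 * 18 / 35)
  analytic <- pnorm(ncp - qnorm(0.975)) + pnorm(-ncp - qnorm(0.975))
  se <- sqrt(analytic * (1 - analytic) / 600)
  expect_lt(abs(power - analytic), 4 * se + 0.02)
})

test_that("recruitment series respond at chance exactly at threshold", {
  set.seed(23)
  r <- simulate_recruitment_series(45, intensities = 45, pulses = 4000)
  expect_lt(abs(mean(r$mep_uv > 50) - 0.5), 3 * sqrt(0.25 / 4000))
})
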