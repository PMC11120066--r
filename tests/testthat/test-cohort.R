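test_that("generate_cohort recovers the specified moments at large n", {
  spec <- cohort_spec(n_patients = 1e4, seed = 21)
  co <- generate_cohort(spec)
  checks <- list(
    list(col = "wet_ant_cm", mean = 10.33, sd = 1.42),
    list(col = "wet_post_cm", mean = 10.41, sd = 0.92),
    list(col = "wet_left_cm", mean = 17.19, sd = 1.51),
    list(col = "wet_right_cm", mean = 17.24, sd = 1.53),
    list(col = "sk_U", mean = 35.15, sd = 8.73))
  for (ck in checks) {
    x <- co[[ck$col]]
    se <- ck$sd / sqrt(length(x))
    expect_lt(abs(mean(x) - ck$mean), 3 * se)
    expect_lt(abs(sd(x) - ck$sd) / ck$sd, 0.05)
  }
  expect_true(all(co$sk_U > 0))
})

test_that("generation is a pure function of (spec, seed)", {
  a <- generate_cohort(cohort_spec(seed = 5))
  b <- generate_cohort(cohort_spec(seed = 5))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_spec(seed = 6))
  expect_false(identical(a$sk_U, c2$sk_U))
  # SD = 0 degenerates to the means
  d <- generate_cohort(cohort_spec(n_patients = 5,
                                   wet_sd_cm = c(anterior = 0, posterior = 0,
                                                 left = 0, right = 0),
                                   sk_sd_U = 0, seed = 1))
  expect_true(all(d$wet_ant_cm == 10.33))
  expect_true(all(d$sk_U == 35.15))
})

test_that("measurement emulator adds background, clips to range, and round-trips", {
  noiseless <- measurement_spec(background_uSv_h = 0, rel_noise = 0)
  expect_identical(emulate_measurement(c(0.3, 7), noiseless), c(0.3, 7))
  # range floor applies after background addition
  expect_equal(emulate_measurement(0, measurement_spec(rel_noise = 0)), 0.20)
  bg <- measurement_spec(background_uSv_h = 0.20, rel_noise = 0)
  m <- emulate_measurement(2.5, bg)
  expect_equal(m, 2.7)
  expect_equal(subtract_background(m, bg), 2.5)
  # detector floor: 1e-6 uSv/h (no background) reads as the 50 nSv/h minimum
  expect_equal(emulate_measurement(1e-6, noiseless), 0.05)
  expect_error(emulate_measurement(-1, bg), ">= 0")
})

test_that("phantom sessions decay weekly and spread consistently with the noise level", {
  s <- data.frame(depth_cm = 1:10, value = 10 * exp(-0.35 * (1:10)))
  quiet <- measurement_spec(background_uSv_h = 0, rel_noise = 0)
  nine <- generate_phantom_sessions(s, quiet, seed = 2, decay = NULL)
  expect_equal(nrow(nine), 90L)
  expect_equal(unique(table(nine$session)), 10L)
  for (k in 2:9)
    expect_identical(nine$measured_uSv_h[nine$session == k],
                     nine$measured_uSv_h[nine$session == 1])
  # with decay: session 9 / session 1 = exp(-lambda * 56 d) ~ 0.520
  dec <- generate_phantom_sessions(s, quiet, seed = 2, decay = decay_data())
  ratio <- dec$measured_uSv_h[dec$session == 9] /
    dec$measured_uSv_h[dec$session == 1]
  expect_equal(ratio, rep(exp(-log(2) / 59.4 * 56), 10), tolerance = 1e-12)
  expect_equal(ratio[1], 0.520, tolerance = 1e-3)
  # full defaults: per-depth CoV across sessions <= 2.5% at the 2% noise level
  full <- generate_phantom_sessions(s, measurement_spec(background_uSv_h = 0),
                                    seed = 3, decay = NULL)
  cov <- tapply(full$measured_uSv_h, full$depth_cm,
                function(x) sd(x) / mean(x))
  expect_true(all(cov <= 0.025 * 2.5))  # 9 samples: allow sampling slack
  expect_lt(median(cov), 0.025)
})

test_that("synthetic patient measurements carry the configured bias", {
  co <- generate_cohort(cohort_spec(n_patients = 40, seed = 9))
  m <- simulate_patient_measurements(co,
                                     spec = measurement_spec(rel_noise = 0),
                                     seed = 4)
  d0 <- m[m$distance_cm == 0, ]
  expect_equal(d0$measured_uSv_h / d0$predicted_uSv_h,
               rep(0.90, nrow(d0)), tolerance = 1e-12)
  far <- m[m$distance_cm != 0, ]
  expect_equal(far$measured_uSv_h, far$predicted_uSv_h, tolerance = 1e-12)
})

test_that("optional correlation structure and WET measurement error are honoured", {
  rho <- diag(5)
  rho[1, 2] <- rho[2, 1] <- 0.8        # anterior-posterior WET correlation
  co <- generate_cohort(cohort_spec(n_patients = 5000, correlation = rho,
                                    seed = 13))
  r_ap <- cor(co$wet_ant_cm, co$wet_post_cm)
  expect_gt(r_ap, 0.7); expect_lt(r_ap, 0.9)
  expect_lt(abs(cor(co$wet_ant_cm, co$wet_left_cm)), 0.06)
  expect_lt(abs(mean(co$wet_ant_cm) - 10.33), 0.1)
  expect_error(cohort_spec(correlation = diag(4)), "5x5")
  # WET error inflates the per-direction spread in quadrature
  noisy <- generate_cohort(cohort_spec(n_patients = 5000,
                                       wet_error_sd_cm = 0.5, seed = 14))
  expect_lt(abs(sd(noisy$wet_post_cm) - sqrt(0.92^2 + 0.5^2)), 0.05)
})
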