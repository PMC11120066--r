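test_that("predict_h10_rate follows the published equation and its unit chain", {
  # hand computation with the study-mean inputs:
  # 35.15 U * 0.954 cGy/h/U * 1e4 uSv/cGy * 1.00 Sv/Gy * 1.7811 e^(-0.5841*10.33)
  imp <- source_implant(sk_U = 35.15, lambda_cGy_h_U = 0.954, cf_Sv_Gy = 1)
  hand <- 35.15 * 0.954 * 1e4 * 1.7811 * exp(-0.5841 * 10.33)
  expect_equal(predict_h10_rate(imp, 10.33, 0), hand, tolerance = 1e-12)
  expect_equal(hand, 1431.32, tolerance = 1e-5)
  # unit prefactor isolates the amplitude as z -> 0
  unit <- source_implant(sk_U = 1e-4, lambda_cGy_h_U = 1, cf_Sv_Gy = 1)
  expect_equal(predict_h10_rate(unit, 1e-12, 0), 1.7811, tolerance = 1e-9)
  # Sk = 0 -> 0 everywhere; linear in Sk, Lambda, CF
  zero <- source_implant(0)
  for (d in c(0, 30, 100))
    expect_equal(predict_h10_rate(zero, 10, d), 0)
  r1 <- predict_h10_rate(imp, 12, 30)
  expect_equal(predict_h10_rate(source_implant(2 * 35.15, 0.954), 12, 30),
               2 * r1)
  # strictly decreasing in z
  zs <- seq(1, 20, by = 0.5)
  expect_false(is.unsorted(rev(predict_h10_rate(imp, zs, 100))))
  expect_error(predict_h10_rate(imp, 0, 0), "> 0")
  expect_error(predict_h10_rate(imp, 10, 55), "no model")
})

test_that("predict_patient honours symmetry, monotonicity and decay", {
  imp <- source_implant(35, implant_date = "2026-01-01")
  sym <- patient_geometry(12, 12, 12, 12)
  p <- predict_patient(imp, sym)
  expect_equal(nrow(p), 12L)
  for (d in unique(p$distance_cm))
    expect_equal(length(unique(p$h10_uSv_h[p$distance_cm == d])), 1L)
  asym <- patient_geometry(10.33, 10.41, 17.19, 17.24)
  q <- predict_patient(imp, asym)
  for (d in unique(q$distance_cm)) {
    g <- q[q$distance_cm == d, ]
    expect_lt(g$h10_uSv_h[g$direction == "left"],
              g$h10_uSv_h[g$direction == "anterior"])
  }
  # one half-life later -> exactly half the day-0 rates
  later <- predict_patient(imp, asym, eval_date = as.Date("2026-01-01") + 59.4)
  expect_equal(later$h10_uSv_h, q$h10_uSv_h / 2, tolerance = 1e-9)
})

test_that("far_field_rate composes multiplicatively and encodes the 2 cm HVL", {
  expect_equal(far_field_rate(8, 50, 50, 0), 8)
  expect_equal(far_field_rate(8, 50, 100, 0), 2)          # inverse square
  expect_equal(far_field_rate(8, 50, 50, 2), 4)           # one HVL halves
  # two hops equal the direct hop
  ab <- far_field_rate(10, 30, 60, 1.2)
  abc <- far_field_rate(ab, 60, 150, 0.8)
  expect_equal(abc, far_field_rate(10, 30, 150, 2.0), tolerance = 1e-12)
  expect_error(far_field_rate(1, 0, 10), "> 0")
})

test_that("cumulative_dose matches the closed form and numerical quadrature", {
  dec <- decay_data(59.4)
  cont <- exposure_scenario("caregiver", daily_hours = 24, occupancy = 1,
                            horizon_days = Inf)
  # R * T_half * 24 / ln 2, in mSv
  expect_equal(cumulative_dose(10, cont, dec),
               10 * (59.4 * 24) / log(2) / 1000, tolerance = 1e-9)
  expect_equal(cumulative_dose(10, cont, dec), 20.567, tolerance = 1e-4)
  # horizon 0 and occupancy 0 give 0
  expect_equal(cumulative_dose(10, exposure_scenario(horizon_days = 0), dec), 0)
  expect_equal(cumulative_dose(10, exposure_scenario(occupancy = 0), dec), 0)
  # monotone in horizon, converging to the infinite-horizon value
  horizons <- c(7, 30, 90, 365, 1000)
  doses <- vapply(horizons, function(h)
    cumulative_dose(10, exposure_scenario(horizon_days = h), dec), 0)
  expect_false(is.unsorted(doses))
  expect_lt(doses[5], cumulative_dose(10, cont, dec))
  expect_equal(doses[5], cumulative_dose(10, cont, dec), tolerance = 1e-5)
  # independent quadrature oracle at a finite horizon
  lam_h <- log(2) / (59.4 * 24)
  quad <- stats::integrate(function(t) 10 * exp(-lam_h * t), 0, 90 * 24,
                           rel.tol = 1e-12)$value / 1000
  expect_equal(doses[3], quad, tolerance = 1e-9)
})

test_that("check_release applies category limits with an inclusive boundary", {
  r <- check_release(4.9, "caregiver")
  expect_true(r$compliant); expect_equal(r$margin_mSv, 0.1)
  b <- check_release(1.0, "public")
  expect_true(b$compliant); expect_equal(b$margin_mSv, 0)
  expect_false(check_release(1.2, "public")$compliant)
  expect_false(check_release(5.4, "caregiver")$compliant)
  expect_error(check_release(1, "visitor"))
  expect_error(check_release(-1, "public"), "negative")
})

test_that("uncertainty arithmetic reproduces the published budget and consensus", {
  expect_equal(combine_quadrature(c(0.50, 6.90, 4.00)), 7.988, tolerance = 1e-3)
  expect_equal(round(combine_quadrature(c(0.50, 6.90, 4.00)), 1), 8.0)
  expect_equal(combine_quadrature(3.7), 3.7)
  expect_equal(combine_quadrature(c(3, 4)), 5)
  expect_error(combine_quadrature(numeric(0)), "empty")
  expect_equal(consensus_lambda(c(0.954, 0.938)), 0.946)
  expect_equal(consensus_lambda(0.954), 0.954)
  expect_equal(consensus_lambda(c(0.954, 0.938), c(1, 0)), 0.954)
  expect_error(consensus_lambda(c(1, 2), c(0, 0)), "weights")
})
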