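test_that("normalize_series maps the reference depth to exactly 1 and is idempotent", {
  s <- data.frame(depth_cm = 1:2, value = c(10, 5))
  n1 <- normalize_series(s)
  expect_identical(n1$value, c(1.0, 0.5))
  expect_identical(normalize_series(n1)$value, n1$value)
  big <- data.frame(depth_cm = 1:20, value = exp(-0.3 * (1:20)) * 7)
  expect_equal(normalize_series(big)$value[1], 1)
  expect_error(normalize_series(data.frame(depth_cm = 2:3, value = 1:2)),
               "reference depth")
  expect_error(normalize_series(data.frame(depth_cm = 1:2, value = c(0, 1))),
               "> 0")
})

test_that("fit_exponential recovers noiseless parameters exactly and is scale-equivariant", {
  z <- 1:20
  s <- data.frame(depth_cm = z, value = 1.4026 * exp(-0.3273 * z))
  f <- fit_exponential(s)
  expect_equal(f$A, 1.4026, tolerance = 1e-8)
  expect_equal(f$b_per_cm, 0.3273, tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # round-trip: evaluate_model reproduces the inputs
  expect_equal(evaluate_model(f, z), s$value, tolerance = 1e-7)
  # scale equivariance: value * c -> A * c, b and R^2 unchanged
  s2 <- transform(s, value = value * 37.5)
  f2 <- fit_exponential(s2)
  expect_equal(f2$A, f$A * 37.5, tolerance = 1e-6)
  expect_equal(f2$b_per_cm, f$b_per_cm, tolerance = 1e-6)
  # two-point closed form: {(1, 1), (2, e^-0.5)} -> b = 0.5, A = e^0.5
  f3 <- fit_exponential(data.frame(depth_cm = 1:2,
                                   value = c(1, exp(-0.5))))
  expect_equal(f3$b_per_cm, 0.5, tolerance = 1e-10)
  expect_equal(f3$A, exp(0.5), tolerance = 1e-10)
  expect_error(fit_exponential(data.frame(depth_cm = 1:3, value = c(1, -1, 2))),
               "> 0")
  expect_error(fit_exponential(data.frame(depth_cm = 1:3, value = rep(2, 3))),
               "degenerate")
})

test_that("r_squared matches hand arithmetic and rejects degenerate input", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # 1 - 1/2
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero total variance")
  expect_error(r_squared(1, 1), "lengths")
})

test_that("the registry stores the printed coefficients and is self-consistent at z = 1", {
  reg <- paper_model_registry()
  expect_identical(names(reg), c("0", "30", "100"))
  expect_identical(reg$`0`$A, 1.7811);  expect_identical(reg$`0`$b_per_cm, 0.5841)
  expect_identical(reg$`30`$A, 1.4360); expect_identical(reg$`30`$b_per_cm, 0.3555)
  expect_identical(reg$`100`$A, 1.4026); expect_identical(reg$`100`$b_per_cm, 0.3273)
  # per-series normalization: each model evaluates to ~1 at z = 1 cm
  # (recomputed bounds: 0.99315, 1.00600, 1.01108 -> all within 1.2%)
  for (m in reg)
    expect_lt(abs(evaluate_model(m, 1) - 1), 0.012)
  # decay constants steepen toward the surface
  expect_gt(reg$`0`$b_per_cm, reg$`30`$b_per_cm)
  expect_gt(reg$`30`$b_per_cm, reg$`100`$b_per_cm)
})

test_that("evaluate_model and half_value_layer match direct evaluation", {
  m0 <- paper_model_registry()$`0`
  expect_equal(evaluate_model(m0, 0), 1.7811)
  expect_equal(evaluate_model(m0, 1), 1.7811 * exp(-0.5841))
  expect_equal(evaluate_model(m0, 1), 0.99315, tolerance = 1e-4)
  expect_error(evaluate_model(m0, -1), ">= 0")
  flat <- exponential_model(2.5, 0)
  expect_equal(evaluate_model(flat, c(0, 5, 50)), rep(2.5, 3))
  expect_equal(half_value_layer(0.3273), 2.118, tolerance = 1e-3)
  expect_equal(round(half_value_layer(0.3273)), 2)
  expect_equal(half_value_layer(log(2)), 1)
  expect_equal(half_value_layer(0.5841), 1.187, tolerance = 1e-3)
  expect_error(half_value_layer(0), "> 0")
})

test_that("fit results round-trip through JSON", {
  fits <- list(`30` = exponential_model(1.43, 0.356, r2 = 0.9995,
                                        distance_cm = 30))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fits, path)
  back <- read_fit_json(path)
  expect_equal(back$`30`$A, 1.43)
  expect_equal(back$`30`$b_per_cm, 0.356)
  expect_equal(back$`30`$r2, 0.9995)
})
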