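test_that("sample_emission draws lines at intensity fractions and isotropic directions", {
  sp <- i125_spectrum()
  n <- 2e5
  set.seed(11)
  em <- sample_emission(sp, n)
  p <- sp$intensity / sum(sp$intensity)
  for (i in seq_len(nrow(sp))) {
    freq <- mean(abs(em$energy_keV - sp$energy_keV[i]) < 1e-9)
    se <- sqrt(p[i] * (1 - p[i]) / n)
    expect_lt(abs(freq - p[i]), 4 * se)
  }
  # isotropy: mean direction components within 4 SE of zero; SE = 1/sqrt(3n)
  m <- colMeans(em$direction)
  expect_true(all(abs(m) < 4 / sqrt(3 * n)))
  expect_equal(rowSums(em$direction^2), rep(1, n), tolerance = 1e-9)
  # single-line spectrum -> that energy always
  one <- sample_emission(emission_spectrum(27.4, 1), 50)
  expect_true(all(one$energy_keV == 27.4))
})

test_that("compton_scatter follows the Compton relation and the Klein-Nishina law", {
  # forward scatter leaves the energy unchanged
  a <- 27.4 / 510.99895
  expect_equal(27.4 / (1 + a * (1 - cos(0))), 27.4)
  # backscatter by hand: E' = E / (1 + 2 E / m_e c^2)
  expect_equal(27.4 / (1 + 2 * a), 24.746, tolerance = 1e-3)
  set.seed(7)
  cs <- compton_scatter(rep(27.4, 2e5))
  # energies never increase and match the relation at the sampled angle
  expect_true(all(cs$energy_keV <= 27.4 + 1e-12))
  expect_equal(cs$energy_keV, 27.4 / (1 + a * (1 - cos(cs$theta))),
               tolerance = 1e-12)
  # angular histogram vs numerically-integrated Klein-Nishina pdf
  total <- oracle_kn_total(27.4)
  expect_equal(total, klein_nishina_total(27.4), tolerance = 1e-8)
  breaks <- seq(-1, 1, by = 0.1)
  obs <- table(cut(cos(cs$theta), breaks))
  probs <- vapply(seq_len(length(breaks) - 1L), function(i)
    stats::integrate(function(ct)
      2 * pi * klein_nishina_dcs(27.4, ct) / total,
      breaks[i], breaks[i + 1L])$value, 0)
  chi <- suppressWarnings(stats::chisq.test(as.vector(obs), p = probs))
  expect_gt(chi$p.value, 1e-3)
})

test_that("next-event contribution reduces to inverse square in vacuum and to the analytic attenuation form", {
  g <- phantom_geometry(5)
  c100 <- next_event_contribution(c(0, 0, 0.0001), 27.4,
                                  detector_point(100), g, vacuum = TRUE)
  c50 <- next_event_contribution(c(0, 0, 0.0001), 27.4,
                                 detector_point(50), g, vacuum = TRUE)
  conv <- fluence_to_h10(energy_keV = 27.4)
  expect_equal(c100, conv / (4 * pi * 100.0001^2), tolerance = 1e-9)
  expect_equal(c50 / c100, (100.0001 / 50.0001)^2, tolerance = 1e-9)
  # attenuated: source at z = 5 toward the surface detector
  c0 <- next_event_contribution(c(0, 0, 5), 27.4, detector_point(0), g)
  mu <- interpolate_mu(water_attenuation(), 27.4)
  expect_equal(c0, conv * exp(-mu * 5) / (4 * pi * 25), tolerance = 1e-9)
})

test_that("scatter-disabled tallies match the closed-form primary beam", {
  det <- detector_point(100)
  for (z in c(2, 5, 10)) {
    t <- simulate_h10(phantom_geometry(z), det, 2e4, seed = 5,
                      include_scatter = FALSE)
    a <- oracle_primary_h10(z, 100)
    expect_lt(abs(t$h10_pSv_per_decay - a),
              3 * t$rel_se * t$h10_pSv_per_decay + 1e-15)
  }
})

test_that("simulate_h10 is deterministic given a seed and SE scales as 1/sqrt(n)", {
  g <- phantom_geometry(5); det <- detector_point(30)
  t1 <- simulate_h10(g, det, 5000, seed = 99)
  t2 <- simulate_h10(g, det, 5000, seed = 99)
  expect_identical(t1$h10_pSv_per_decay, t2$h10_pSv_per_decay)
  expect_identical(t1$rel_se, t2$rel_se)
  t4 <- simulate_h10(g, det, 20000, seed = 99)
  ratio <- t4$rel_se / t1$rel_se          # expect ~ 1/2
  expect_lt(abs(ratio - 0.5), 0.2 * 0.5)
  expect_error(simulate_h10(g, det, 100), "seed")
})

test_that("depth series decreases with depth and flags high-SE tallies", {
  s <- simulate_depth_series(c(1, 3, 6, 10, 15), 100, 2e4, seed = 3)
  expect_equal(attr(s, "distance_cm"), 100)
  # strictly decreasing within 3 combined SE
  v <- s$h10_pSv_per_decay
  se <- v * s$rel_se
  for (i in seq_len(nrow(s) - 1L))
    expect_gt(v[i] + 3 * sqrt(se[i]^2 + se[i + 1]^2), v[i + 1])
  expect_type(s$flagged, "logical")
  # an absurdly short run must be flagged, not silently accepted
  t <- simulate_h10(phantom_geometry(10), detector_point(0), 50, seed = 1)
  expect_true(t$rel_se <= 0.03 || t$flagged)
  expect_error(simulate_depth_series(c(5, 1), 100, 10, seed = 1),
               "ascending")
})

test_that("transverse symmetry: the tally geometry treats mirrored vertices identically", {
  g <- phantom_geometry(5)
  for (d in c(0, 30)) {
    det <- detector_point(d)
    a <- next_event_contribution(c(3, 2, 4), 27.4, det, g)
    b <- next_event_contribution(c(-3, -2, 4), 27.4, det, g)
    cc <- next_event_contribution(c(2, -3, 4), 27.4, det, g)
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(a, cc, tolerance = 1e-12)
  }
})
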