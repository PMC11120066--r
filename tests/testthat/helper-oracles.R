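# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: interpolation is re-derived from the shipped CSV
# tables with different arithmetic, the Mann-Whitney oracle counts pairs and
# enumerates labelings directly, and the Klein-Nishina normalization is
# obtained by numerical quadrature rather than the closed form.

.fixture <- function(name)
  utils::read.csv(system.file("extdata", name, package = "brachysafe"))

# hand-rolled log-log interpolation (findInterval arithmetic, not approx())
oracle_loglog <- function(xs, ys, x) {
  i <- findInterval(x, xs, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(xs) - 1L)
  f <- (log(x) - log(xs[i])) / (log(xs[i + 1L]) - log(xs[i]))
  exp((1 - f) * log(ys[i]) + f * log(ys[i + 1L]))
}

oracle_linear <- function(xs, ys, x) {
  i <- findInterval(x, xs, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(xs) - 1L)
  f <- (x - xs[i]) / (xs[i + 1L] - xs[i])
  (1 - f) * ys[i] + f * ys[i + 1L]
}

# closed-form primary-beam H*(10) per decay at a point detector, straight
# from the shipped tables: sum over lines of
# I * conv(E) * exp(-mu_w(E) * z) / (4 pi (z + d)^2)
oracle_primary_h10 <- function(z_cm, distance_cm) {
  sp <- .fixture("i125_spectrum_v1.csv")
  mu <- .fixture("mu_water_v1.csv")
  cv <- .fixture("h10_fluence_v1.csv")
  mu_tot <- 0.998 * (mu$photoelectric_cm2_g + mu$incoherent_cm2_g +
                       mu$coherent_cm2_g)
  mu_e <- oracle_loglog(mu$energy_keV, mu_tot, sp$energy_keV)
  conv <- oracle_linear(cv$energy_keV, cv$h10_per_fluence_pSv_cm2,
                        sp$energy_keV)
  r <- z_cm + distance_cm
  sum(sp$intensity_per_decay * conv * exp(-mu_e * z_cm) / (4 * pi * r^2))
}

# Mann-Whitney oracle: U by direct pair counting (ties count half), exact
# two-tailed p by explicit enumeration of every C(n1+n2, n1) labeling
oracle_mw <- function(x, y) {
  u_of <- function(a, b) {
    s <- 0
    for (ai in a) s <- s + sum(ai > b) + 0.5 * sum(ai == b)
    s
  }
  U <- u_of(x, y)
  v <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  labs <- utils::combn(length(v), n1)
  us <- apply(labs, 2L, function(ix) u_of(v[ix], v[-ix]))
  p <- min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
  list(U = U, p = p)
}

# Klein-Nishina normalization by numerical quadrature
oracle_kn_total <- function(energy_keV) {
  f <- function(ct) 2 * pi * brachysafe::klein_nishina_dcs(energy_keV, ct)
  stats::integrate(f, -1, 1, rel.tol = 1e-10)$value
}
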