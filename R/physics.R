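#' @title Embedded physics data for I-125 dosimetry
#' @description Constructors and interpolation services for the physical
#'   data every other module consumes: the I-125 emission spectrum, photon
#'   interaction coefficients for water and air in the 5-60 keV band,
#'   ICRP-style conversion coefficients from fluence and from air kerma to
#'   the ambient dose equivalent H*(10), and I-125 decay data.
#'
#'   All tables ship as versioned CSV fixtures under `inst/extdata/` and can
#'   be overridden by passing a path to the loader functions.  Interpolation
#'   never extrapolates: energies outside a table's grid are errors, because
#'   silently clamped coefficients in safety-relevant code hide mistakes.
#' @name physics
NULL

# ---- emission spectrum -----------------------------------------------------

#' Discrete photon emission spectrum
#'
#' @param energy_keV photon line energies (keV), strictly positive.
#' @param intensity emission intensities (photons per decay), strictly
#'   positive.  Need not sum to 1; I-125 emits ~1.48 photons per decay.
#' @return an `emission_spectrum` object (data.frame with class attribute),
#'   lines sorted ascending by energy.
#' @export
emission_spectrum <- function(energy_keV, intensity) {
  if (length(energy_keV) == 0L)
    .bs_stop("emission_spectrum: at least one line is required")
  if (length(energy_keV) != length(intensity))
    .bs_stop("emission_spectrum: energy and intensity lengths differ")
  if (any(energy_keV <= 0) || any(intensity <= 0))
    .bs_stop("emission_spectrum: energies and intensities must be > 0")
  o <- order(energy_keV)
  s <- data.frame(energy_keV = energy_keV[o], intensity = intensity[o])
  class(s) <- c("emission_spectrum", "data.frame")
  s
}

#' Bare-source I-125 emission spectrum
#'
#' The standard five-line set (Ka/Kb tellurium fluorescence plus the
#' 35.5 keV gamma) used throughout the package as the transport source term.
#'
#' @param path optional CSV override (columns `energy_keV`,
#'   `intensity_per_decay`).
#' @return an [emission_spectrum()].
#' @export
i125_spectrum <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.bs_cache$i125)) return(.bs_cache$i125)
    path <- system.file("extdata", "i125_spectrum_v1.csv",
                        package = "brachysafe", mustWork = TRUE)
    d <- utils::read.csv(path)
    .bs_cache$i125 <- emission_spectrum(d$energy_keV, d$intensity_per_decay)
    return(.bs_cache$i125)
  }
  d <- utils::read.csv(path)
  emission_spectrum(d$energy_keV, d$intensity_per_decay)
}

#' Intensity-weighted mean photon energy
#'
#' @param spectrum an [emission_spectrum()].
#' @return mean energy in keV, `sum(E * I) / sum(I)`.
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (nrow(spectrum) == 0L) .bs_stop("mean_energy: empty spectrum")
  sum(spectrum$energy_keV * spectrum$intensity) / sum(spectrum$intensity)
}

# ---- attenuation tables ----------------------------------------------------

#' Photon interaction coefficient table for one material
#'
#' Linear attenuation coefficients on an energy grid.  The total is defined
#' as the sum of the stored partials (photoelectric + incoherent + coherent),
#' so the partial-sum invariant holds by construction.
#'
#' @param material material name.
#' @param energy_keV strictly ascending energy grid (keV).
#' @param photoelectric,incoherent,coherent mass coefficients (cm^2/g).
#' @param density_g_cm3 material density; linear coefficients are
#'   `mass coefficient * density` (1/cm).
#' @return an `attenuation_table`.
#' @export
attenuation_table <- function(material, energy_keV, photoelectric,
                              incoherent, coherent, density_g_cm3) {
  if (is.unsorted(energy_keV, strictly = TRUE))
    .bs_stop("attenuation_table: energy grid must be strictly ascending")
  if (any(photoelectric < 0) || any(incoherent < 0) || any(coherent < 0))
    .bs_stop("attenuation_table: negative coefficient")
  if (density_g_cm3 <= 0) .bs_stop("attenuation_table: density must be > 0")
  tab <- list(material = material,
              energy_keV = energy_keV,
              mu = cbind(photoelectric = photoelectric * density_g_cm3,
                         incoherent   = incoherent * density_g_cm3,
                         coherent     = coherent * density_g_cm3),
              density_g_cm3 = density_g_cm3)
  tab$mu <- cbind(tab$mu, total = rowSums(tab$mu))
  # pre-computed logs for fast log-log interpolation in the transport loop
  tab$log_e <- log(energy_keV)
  tab$log_mu <- log(pmax(tab$mu, 1e-300))
  class(tab) <- "attenuation_table"
  tab
}

.load_mu <- function(file, material, density) {
  d <- utils::read.csv(file)
  attenuation_table(material, d$energy_keV, d$photoelectric_cm2_g,
                    d$incoherent_cm2_g, d$coherent_cm2_g, density)
}

#' Embedded water / air attenuation tables (5-60 keV)
#'
#' Transcribed from standard photon cross-section compilations; liquid water
#' at 0.998 g/cm^3 and dry air at 1.205e-3 g/cm^3.
#'
#' @param path optional CSV override (columns `energy_keV`,
#'   `photoelectric_cm2_g`, `incoherent_cm2_g`, `coherent_cm2_g`).
#' @return an [attenuation_table()].
#' @export
water_attenuation <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.bs_cache$mu_water))
      .bs_cache$mu_water <- .load_mu(
        system.file("extdata", "mu_water_v1.csv", package = "brachysafe",
                    mustWork = TRUE), "water", 0.998)
    return(.bs_cache$mu_water)
  }
  .load_mu(path, "water", 0.998)
}

#' @rdname water_attenuation
#' @export
air_attenuation <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.bs_cache$mu_air))
      .bs_cache$mu_air <- .load_mu(
        system.file("extdata", "mu_air_v1.csv", package = "brachysafe",
                    mustWork = TRUE), "air", 1.205e-3)
    return(.bs_cache$mu_air)
  }
  .load_mu(path, "air", 1.205e-3)
}

.check_in_grid <- function(energy_keV, grid, what) {
  if (any(energy_keV < grid[1L] - 1e-12) ||
      any(energy_keV > grid[length(grid)] + 1e-12))
    .bs_stop(sprintf(
      "%s: energy outside tabulated grid [%g, %g] keV (no extrapolation)",
      what, grid[1L], grid[length(grid)]))
}

#' Interpolate a linear attenuation coefficient
#'
#' Log-log interpolation between grid nodes (exact at nodes); energies
#' outside the grid are an error.
#'
#' @param table an [attenuation_table()].
#' @param energy_keV photon energy or vector of energies (keV).
#' @param component one of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`.
#' @return linear coefficient(s), 1/cm.
#' @export
interpolate_mu <- function(table, energy_keV,
                           component = c("total", "photoelectric",
                                         "incoherent", "coherent")) {
  stopifnot(inherits(table, "attenuation_table"))
  component <- match.arg(component)
  .check_in_grid(energy_keV, table$energy_keV, "interpolate_mu")
  y <- stats::approx(table$log_e, table$log_mu[, component],
                     xout = log(energy_keV), rule = 1)$y
  exp(y)
}

# ---- conversion curves -----------------------------------------------------

#' Conversion-coefficient curve to ambient dose equivalent H*(10)
#'
#' @param kind `"fluence"` (pSv cm^2 per unit fluence) or `"kerma"`
#'   (Sv/Gy from air kerma).
#' @param energy_keV strictly ascending grid.
#' @param value non-negative coefficients.
#' @return a `conversion_curve`.  Interpolation between nodes is linear in
#'   energy; both linear and log-log choices round the air-kerma factor at
#'   27.4 keV to 1.0.
#' @export
conversion_curve <- function(kind = c("fluence", "kerma"), energy_keV, value) {
  kind <- match.arg(kind)
  if (is.unsorted(energy_keV, strictly = TRUE))
    .bs_stop("conversion_curve: grid must be strictly ascending")
  if (any(value < 0)) .bs_stop("conversion_curve: negative coefficient")
  structure(list(kind = kind, energy_keV = energy_keV, value = value),
            class = "conversion_curve")
}

#' Embedded H*(10) conversion curves (10-60 keV)
#'
#' @param path optional CSV override.
#' @return a [conversion_curve()].
#' @export
fluence_to_h10_curve <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.bs_cache$conv_fl)) {
      d <- utils::read.csv(system.file("extdata", "h10_fluence_v1.csv",
                                       package = "brachysafe", mustWork = TRUE))
      .bs_cache$conv_fl <- conversion_curve("fluence", d$energy_keV,
                                            d$h10_per_fluence_pSv_cm2)
    }
    return(.bs_cache$conv_fl)
  }
  d <- utils::read.csv(path)
  conversion_curve("fluence", d$energy_keV, d$h10_per_fluence_pSv_cm2)
}

#' @rdname fluence_to_h10_curve
#' @export
kerma_to_h10_curve <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.bs_cache$conv_k)) {
      d <- utils::read.csv(system.file("extdata", "h10_kerma_v1.csv",
                                       package = "brachysafe", mustWork = TRUE))
      .bs_cache$conv_k <- conversion_curve("kerma", d$energy_keV,
                                           d$h10_per_kerma_Sv_Gy)
    }
    return(.bs_cache$conv_k)
  }
  d <- utils::read.csv(path)
  conversion_curve("kerma", d$energy_keV, d$h10_per_kerma_Sv_Gy)
}

#' Evaluate a conversion curve
#'
#' @param curve a [conversion_curve()].
#' @param energy_keV energy (keV), scalar or vector, within the grid.
#' @return interpolated coefficient(s).
#' @export
convert_h10 <- function(curve, energy_keV) {
  stopifnot(inherits(curve, "conversion_curve"))
  .check_in_grid(energy_keV, curve$energy_keV, "convert_h10")
  stats::approx(curve$energy_keV, curve$value, xout = energy_keV, rule = 1)$y
}

#' Air-kerma to H*(10) conversion factor CF
#'
#' At the I-125 effective energy of 27.4 keV the interpolated factor rounds
#' to 1.0 Sv/Gy, the conventional CF for this source.
#'
#' @param curve a `"kerma"` [conversion_curve()]; default embedded table.
#' @param energy_keV energy (keV).
#' @return CF in Sv/Gy.
#' @export
kerma_to_h10 <- function(curve = kerma_to_h10_curve(), energy_keV) {
  if (!identical(curve$kind, "kerma"))
    .bs_stop("kerma_to_h10: curve is not an air-kerma curve")
  convert_h10(curve, energy_keV)
}

#' Fluence to H*(10) conversion coefficient
#'
#' @param curve a `"fluence"` [conversion_curve()]; default embedded table.
#' @param energy_keV energy (keV).
#' @return coefficient in pSv cm^2.
#' @export
fluence_to_h10 <- function(curve = fluence_to_h10_curve(), energy_keV) {
  if (!identical(curve$kind, "fluence"))
    .bs_stop("fluence_to_h10: curve is not a fluence curve")
  convert_h10(curve, energy_keV)
}

# ---- decay -----------------------------------------------------------------

#' Radioactive decay data
#'
#' @param half_life_days half-life in days; I-125 default 59.4 d (TG-43).
#' @return a `decay_data` with derived decay constant `lambda_per_day`.
#' @export
decay_data <- function(half_life_days = 59.4) {
  if (!is.numeric(half_life_days) || half_life_days <= 0)
    .bs_stop("decay_data: half-life must be > 0")
  structure(list(half_life_days = half_life_days,
                 lambda_per_day = log(2) / half_life_days),
            class = "decay_data")
}

#' Decay factor after an elapsed time
#'
#' @param decay a [decay_data()].
#' @param elapsed_days non-negative elapsed time (days); vectorized.
#' @return `exp(-lambda * elapsed)`, in (0, 1].
#' @export
decay_factor <- function(decay, elapsed_days) {
  stopifnot(inherits(decay, "decay_data"))
  if (any(elapsed_days < 0))
    .bs_stop("decay_factor: elapsed time must be >= 0")
  exp(-decay$lambda_per_day * elapsed_days)
}
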