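#' @title Predictive dose-rate model and radiation-safety assessment
#' @description Combines the normalized exponential models with TG-43
#'   source-strength quantities into absolute external H*(10) rates:
#'   `H*(10) = Sk * Lambda * CF * A * exp(-b z)`, with the unit chain
#'   Sk \[U\] x Lambda \[cGy/h/U\] -> cGy/h, x 1e4 uSv/cGy x CF \[Sv/Gy\]
#'   -> uSv/h.  Adds the far-field shortcut (inverse-square plus ~2 cm WET
#'   half-value layer), cumulative-dose integration over radioactive decay,
#'   regulatory release checks and the uncertainty arithmetic.
#' @name dose_assess
NULL

#' Implanted source description (TG-43 quantities)
#'
#' @param sk_U total air-kerma strength of all implanted seeds
#'   (U = uGy m^2 / h).
#' @param lambda_cGy_h_U dose-rate constant (cGy/h per U); 0.954 is the
#'   Karaiskos Monte Carlo value for this seed model, 0.938 the TLD value,
#'   0.946 their consensus.
#' @param cf_Sv_Gy air-kerma to H*(10) conversion factor; ~1.00 at the
#'   27.4 keV effective energy.
#' @param implant_date implant date (`Date` or ISO-8601 string).
#' @return a `source_implant`.
#' @export
source_implant <- function(sk_U, lambda_cGy_h_U = 0.954, cf_Sv_Gy = 1.00,
                           implant_date = Sys.Date()) {
  if (sk_U < 0) .bs_stop("source_implant: Sk must be >= 0")
  if (lambda_cGy_h_U <= 0) .bs_stop("source_implant: Lambda must be > 0")
  if (cf_Sv_Gy <= 0) .bs_stop("source_implant: CF must be > 0")
  structure(list(sk_U = sk_U, lambda_cGy_h_U = lambda_cGy_h_U,
                 cf_Sv_Gy = cf_Sv_Gy,
                 implant_date = as.Date(implant_date)),
            class = "source_implant")
}

#' Patient geometry: water-equivalent thickness in four directions
#'
#' @param anterior_cm,posterior_cm,left_cm,right_cm WET from the prostate
#'   centre to the body surface (cm), all > 0.
#' @return a `patient_geometry`.
#' @export
patient_geometry <- function(anterior_cm, posterior_cm, left_cm, right_cm) {
  w <- c(anterior = anterior_cm, posterior = posterior_cm,
         left = left_cm, right = right_cm)
  if (any(w <= 0)) .bs_stop("patient_geometry: all WETs must be > 0")
  structure(list(wet_cm = w), class = "patient_geometry")
}

#' Predict the external H*(10) rate for one depth and distance
#'
#' `Sk * Lambda * 1e4 * CF * A * exp(-b z)` in uSv/h, with `A`, `b` taken
#' from the published registry by default or from a user-fitted model set.
#'
#' @param implant a [source_implant()].
#' @param z_cm water-equivalent depth of the source (cm, > 0).
#' @param distance_cm detector distance class (0, 30 or 100 for the
#'   registry).
#' @param models model set keyed by distance class (default
#'   [paper_model_registry()]).
#' @return dose rate in uSv/h (vectorized over `z_cm`).
#' @export
predict_h10_rate <- function(implant, z_cm, distance_cm,
                             models = paper_model_registry()) {
  stopifnot(inherits(implant, "source_implant"))
  if (any(z_cm <= 0)) .bs_stop("predict_h10_rate: z must be > 0")
  key <- as.character(distance_cm)
  if (!key %in% names(models))
    .bs_stop(sprintf("predict_h10_rate: no model for distance %s cm", key))
  m <- models[[key]]
  implant$sk_U * implant$lambda_cGy_h_U * 1e4 * implant$cf_Sv_Gy *
    evaluate_model(m, z_cm)
}

#' Predict the full four-direction, three-distance patient profile
#'
#' @param implant a [source_implant()].
#' @param patient a [patient_geometry()].
#' @param eval_date evaluation date; the rate is decay-corrected from the
#'   implant date (a day-0 snapshot when equal to it).
#' @param decay a [decay_data()].
#' @param distances_cm distance classes to evaluate.
#' @param models model set keyed by distance class.
#' @return data.frame of `dose_prediction`s: `direction`, `distance_cm`,
#'   `wet_cm`, `h10_uSv_h`, `eval_date`.
#' @export
predict_patient <- function(implant, patient, eval_date = NULL,
                            decay = decay_data(),
                            distances_cm = c(0, 30, 100),
                            models = paper_model_registry()) {
  stopifnot(inherits(patient, "patient_geometry"))
  eval_date <- if (is.null(eval_date)) implant$implant_date
               else as.Date(eval_date)
  elapsed <- as.numeric(eval_date - implant$implant_date)
  if (elapsed < 0) .bs_stop("predict_patient: evaluation before implant")
  f <- decay_factor(decay, elapsed)
  grid <- expand.grid(direction = names(patient$wet_cm),
                      distance_cm = distances_cm,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$wet_cm <- patient$wet_cm[grid$direction]
  grid$h10_uSv_h <- f * mapply(function(w, d)
    predict_h10_rate(implant, w, d, models = models),
    grid$wet_cm, grid$distance_cm)
  grid$eval_date <- eval_date
  rownames(grid) <- NULL
  class(grid) <- c("dose_prediction", "data.frame")
  grid
}

#' Far-field dose-rate shortcut
#'
#' Beyond about three times the prostate size the implant behaves as a
#' point source at its centre of gravity, so a known rate scales by the
#' inverse-square law and halves per ~2 cm of additional WET.
#'
#' @param rate_uSv_h known rate at `reference_cm`.
#' @param reference_cm,target_cm source-to-point distances (cm, > 0).
#' @param extra_wet_cm additional water-equivalent material in the path.
#' @param hvl_cm half-value layer (default 2 cm WET).
#' @return rate at the target position, uSv/h.
#' @export
far_field_rate <- function(rate_uSv_h, reference_cm, target_cm,
                           extra_wet_cm = 0, hvl_cm = 2) {
  if (reference_cm <= 0 || target_cm <= 0)
    .bs_stop("far_field_rate: distances must be > 0")
  rate_uSv_h * (reference_cm / target_cm)^2 * 0.5^(extra_wet_cm / hvl_cm)
}

#' Exposure scenario for a person near the patient
#'
#' @param category `"caregiver"` or `"public"`.
#' @param distance_cm distance class the person occupies.
#' @param daily_hours exposure hours per day (0-24).
#' @param occupancy occupancy factor in \[0, 1\].
#' @param horizon_days integration horizon (days); `Inf` for total dose to
#'   complete decay.
#' @return an `exposure_scenario`.
#' @export
exposure_scenario <- function(category = c("caregiver", "public"),
                              distance_cm = 100, daily_hours = 24,
                              occupancy = 1, horizon_days = Inf) {
  category <- match.arg(category)
  if (daily_hours < 0 || daily_hours > 24)
    .bs_stop("exposure_scenario: daily_hours must be in [0, 24]")
  if (occupancy < 0 || occupancy > 1)
    .bs_stop("exposure_scenario: occupancy must be in [0, 1]")
  if (horizon_days < 0) .bs_stop("exposure_scenario: negative horizon")
  structure(list(category = category, distance_cm = distance_cm,
                 daily_hours = daily_hours, occupancy = occupancy,
                 horizon_days = horizon_days),
            class = "exposure_scenario")
}

#' Cumulative dose over a decaying source
#'
#' `R0 * f * (1 - exp(-lambda T)) / lambda` with `f = daily_hours/24 *
#' occupancy` and lambda in 1/h; the infinite horizon gives
#' `R0 * f * T_half * 24 / ln 2`.
#'
#' @param initial_rate_uSv_h dose rate at the start (uSv/h, >= 0).
#' @param scenario an [exposure_scenario()].
#' @param decay a [decay_data()].
#' @return cumulative dose in mSv.
#' @export
cumulative_dose <- function(initial_rate_uSv_h, scenario,
                            decay = decay_data()) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (initial_rate_uSv_h < 0) .bs_stop("cumulative_dose: negative rate")
  f <- scenario$daily_hours / 24 * scenario$occupancy
  lambda_h <- decay$lambda_per_day / 24
  Th <- scenario$horizon_days * 24
  uSv <- if (is.infinite(Th)) initial_rate_uSv_h * f / lambda_h
         else initial_rate_uSv_h * f * (1 - exp(-lambda_h * Th)) / lambda_h
  uSv / 1000
}

#' Regulatory annual release limits
#'
#' @return named limits in mSv/year: caregiver 5, public 1.
#' @export
regulatory_limits <- function() c(caregiver = 5, public = 1)

#' Check a dose against the release limit
#'
#' The boundary is inclusive: a dose exactly at the limit is compliant.
#'
#' @param annual_dose_mSv dose to check (>= 0).
#' @param category `"caregiver"` (5 mSv/year) or `"public"` (1 mSv/year).
#' @param limits named limit vector, default [regulatory_limits()].
#' @return list `compliant` (logical), `margin_mSv` (limit - dose),
#'   `limit_mSv`, `category`.
#' @export
check_release <- function(annual_dose_mSv,
                          category = c("caregiver", "public"),
                          limits = regulatory_limits()) {
  category <- match.arg(category, names(limits))
  if (annual_dose_mSv < 0) .bs_stop("check_release: negative dose")
  lim <- limits[[category]]
  list(compliant = annual_dose_mSv <= lim,
       margin_mSv = lim - annual_dose_mSv,
       limit_mSv = lim, category = category)
}

#' Combine an uncertainty budget in quadrature
#'
#' @param components named or unnamed vector of 1-sigma percentage
#'   components, all >= 0.  The published budget
#'   `{0.50, 6.90, 4.00}%` combines to 8.0%.
#' @return `sqrt(sum(components^2))`, %.
#' @export
combine_quadrature <- function(components) {
  if (length(components) == 0L) .bs_stop("combine_quadrature: empty budget")
  if (any(components < 0))
    .bs_stop("combine_quadrature: components must be >= 0")
  sqrt(sum(components^2))
}

#' Weighted consensus dose-rate constant
#'
#' @param lambdas candidate values (cGy/h/U).
#' @param weights non-negative weights, not all zero (default equal).
#' @return weighted mean; equal weights over 0.954 and 0.938 give 0.946.
#' @export
consensus_lambda <- function(lambdas, weights = rep(1, length(lambdas))) {
  if (length(lambdas) != length(weights))
    .bs_stop("consensus_lambda: lengths differ")
  if (any(weights < 0) || sum(weights) == 0)
    .bs_stop("consensus_lambda: weights must be >= 0, not all zero")
  sum(lambdas * weights) / sum(weights)
}
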