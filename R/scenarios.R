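#' Prebuilt validation scenarios for the synthetic generator
#'
#' Three simulation designs used to validate the pipeline; each returns
#' ready-made [gcmm_sim_params()].
#'
#' `sim_params_recovery()` plants known linear mediation paths for one
#' focal type (electronic gaming machines) and generates the PGSI score
#' in linear outcome mode with a mid-scale intercept, so the planted
#' coefficients are the exact OLS truth and estimates can be compared
#' to it. The companion `recovery_config()` leaves the PGSI outcome
#' uncapped (cap 27), since coefficient recovery is defined on the
#' untransformed linear outcome; missing-value injection is off so the
#' planted paths stay exact.
#'
#' `sim_params_calibration()` is the same design with a *zero*
#' frequency-beyond coefficient: that mediator has a nonzero a-path but
#' an exactly null b-path, so its indirect effect is truly zero, which
#' calibrates the type-I error of the percentile bootstrap intervals on
#' a mediator with a regular, well-spread test statistic. (The sparse
#' spending-within mediator, a point mass at zero for all
#' non-participants, is a known anti-conservative corner for percentile
#' intervals and is not a fair probe of the nominal level; see the
#' package vignette.)
#'
#' `sim_params_profile_plant()` plants the published 10/5 profile
#' split: frequency-within effects on the five game types found
#' frequency-dominant (EGMs, scratch cards, live betting, poker offline
#' and online) and a breadth effect carrying the other ten, with
#' coefficients chosen so every type's true largest-to-second
#' indirect-effect ratio is at least 3.
#'
#' `sim_params_propensity()` exercises the demographic propensity
#' stage: mixture outcome mode with the published odds ratios as truth
#' and the high-risk rate raised to 10% so a single survey carries
#' enough outcome events to estimate each odds ratio precisely.
#'
#' @param n_per_year respondents per survey year.
#' @param seed generator seed.
#' @return A `"gcmm_sim_params"` (or `"gcmm_config"` for
#'   `recovery_config()`).
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
recovery_config <- function() {
  gcmm_config(pgsi_cap = 27)
}

#' @rdname scenarios
#' @export
sim_params_recovery <- function(n_per_year = c(2000, 2000, 2000), seed = 1L) {
  gcmm_sim_params(
    n_per_year = n_per_year,
    outcome_mode = "linear",
    beta = list(propensity = 0, breadth = 0.35,
                freq_within = c(egm_off = 0.45), freq_beyond = 0.25,
                spend_within = 2e-4, spend_beyond = 1e-4),
    outcome_intercept = 8, noise_sd = 2,
    missing_rates = list(freq = 0, spend = 0, demographics = 0),
    analysis_config = recovery_config(),
    rng_seed = seed
  )
}

#' @rdname scenarios
#' @export
sim_params_calibration <- function(n_per_year = c(400, 400, 400), seed = 1L) {
  p <- sim_params_recovery(n_per_year = n_per_year, seed = seed)
  p$beta$freq_beyond <- 0
  p
}

#' @rdname scenarios
#' @export
sim_params_profile_plant <- function(n_per_year = c(1500, 1500, 1500),
                                     seed = 1L) {
  catalog <- default_catalog()
  freq_types <- c("egm_off", "scratch_off", "live_on", "poker_off",
                  "poker_on_foreign")
  part <- stats::setNames(rep(0.30, nrow(catalog)), catalog$type_id)
  part[freq_types] <- 0.15
  freq_probs <- c(0.55, 0.25, 0.12, 0.05, 0.03)
  gcmm_sim_params(
    n_per_year = n_per_year,
    participation = part,
    rho = 0,
    freq_probs = freq_probs,
    outcome_mode = "linear",
    beta = list(propensity = 0, breadth = 1.1,
                freq_within = stats::setNames(rep(2.2, 5), freq_types),
                freq_beyond = 0, spend_within = 0, spend_beyond = 0,
                freq_centering = sum(1:5 * freq_probs)),
    focal_type = "egm_off",
    outcome_intercept = 6, noise_sd = 2,
    missing_rates = list(freq = 0, spend = 0, demographics = 0),
    analysis_config = recovery_config(),
    rng_seed = seed
  )
}

#' @rdname scenarios
#' @export
sim_params_propensity <- function(n_per_year = c(20000, 20000, 20000),
                                  seed = 1L) {
  gcmm_sim_params(
    n_per_year = n_per_year,
    target_highrisk_rate = 0.10,
    outcome_mode = "mixture",
    rng_seed = seed
  )
}
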