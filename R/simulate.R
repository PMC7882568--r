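#' Synthetic survey generator parameters
#'
#' Parameters of the synthetic gambling-survey generator. The generator
#' emulates the structure the mediation pipeline assumes: 15 game types
#' with marginal participation spanning roughly 0.2% to 76%, positively
#' correlated participation across types through one latent involvement
#' factor, ordinal frequency categories tied to that factor, heavy-tailed
#' lognormal spending with a rare inflated-outlier component, demographic
#' effects on a rare (about 1.2%) moderate-risk-plus outcome with the
#' published odds ratios as defaults, and a zero-inflated PGSI score
#' driven by configurable true mediation paths.
#'
#' Two outcome modes are supported. `"mixture"` (default, realistic):
#' a logistic model in the demographics decides a rare high-risk
#' indicator (PGSI >= 5 branch, intercept calibrated so the rate among
#' last-year gamblers matches `target_highrisk_rate`); everyone else
#' gets a zero-inflated 0-4 score driven by the behaviour constructs.
#' `"linear"` (validation): the PGSI score is the rounded linear
#' predictor `outcome_intercept + sum(beta_j * M_j)` over the
#' post-feature-engineering mediator constructs plus Gaussian noise,
#' with a mid-scale intercept so floor/ceiling truncation is negligible
#' and the planted coefficients are recoverable by OLS.
#'
#' @param n_per_year respondents per survey year (defaults mirror the
#'   Icelandic surveys: 2631, 1887, 2703).
#' @param years survey-year labels.
#' @param participation named per-type participation probabilities.
#' @param rho cross-type involvement correlation (share of latent-factor
#'   variance in each type's participation latent).
#' @param freq_probs probabilities of frequency categories 1-5 given
#'   participation (monotone mapping from the latent intensity).
#' @param spend_meanlog,spend_sdlog lognormal usual-spending body (Krona).
#' @param spend_freq_cor loading of spending on the type latent (induces
#'   a moderate positive within-type frequency-spending correlation).
#' @param outlier_rate,outlier_scale rare inflated spending tail.
#' @param demographics list: `p_male`, `age_mean`, `age_sd`, `age_range`,
#'   `educ_probs` (3 levels), `p_partnered`.
#' @param demo_odds odds ratios of the high-risk outcome per demographic
#'   predictor (male, education level, single, age per year).
#' @param target_highrisk_rate calibration target for the rate of
#'   PGSI >= 5 among last-year gamblers (mixture mode).
#' @param outcome_mode `"mixture"` or `"linear"` (see above).
#' @param beta true outcome coefficients on the mediator constructs:
#'   list with `propensity`, `breadth`, `freq_within` (named vector over
#'   one or more focal types), `freq_beyond`, `spend_within`,
#'   `spend_beyond`. `freq_beyond`/`spend_beyond` refer to the focal
#'   type named first in `freq_within`. An optional `freq_centering`
#'   constant `c` plants each frequency effect as
#'   `beta * (freq - c * participation)`: the within-type b-path is
#'   still `beta` (the participation term folds into the direct
#'   effect), but the effect no longer loads on breadth through the
#'   participation indicator — used to plant several frequency-driven
#'   types without cross-contaminating the breadth mediator.
#' @param focal_type focal type for beyond-construct truth bookkeeping.
#' @param outcome_intercept,noise_sd linear-mode latent intercept and
#'   noise; `mixture_intercept` and `mixture_noise_sd` drive the 0-4
#'   branch of mixture mode.
#' @param mixture_intercept,mixture_noise_sd see above.
#' @param missing_rates list of `freq`, `spend` (per-cell rates) and
#'   `demographics` (per-row rate) used by [inject_missing()].
#' @param analysis_config [gcmm_config()] used to build the mediator
#'   constructs that the outcome model is defined on.
#' @param rng_seed integer seed; generation is fully reproducible.
#' @param catalog a [gcmm_catalog()].
#' @return A list of class `"gcmm_sim_params"`.
#' @export
gcmm_sim_params <- function(
    n_per_year = c(2631, 1887, 2703),
    years = c(2007, 2011, 2017),
    participation = default_participation(catalog),
    rho = 0.3,
    freq_probs = c(0.55, 0.25, 0.12, 0.05, 0.03),
    spend_meanlog = log(1000), spend_sdlog = 1.0,
    spend_freq_cor = 0.4,
    outlier_rate = 0.01, outlier_scale = 10,
    demographics = list(p_male = 0.498, age_mean = 42.57, age_sd = 14.39,
                        age_range = c(18, 70),
                        educ_probs = c(0.244, 0.424, 0.333),
                        p_partnered = 0.632),
    demo_odds = c(male = 5.026, education = 0.527, single = 1.671,
                  age = 0.951),
    target_highrisk_rate = 0.012,
    outcome_mode = c("mixture", "linear"),
    beta = list(propensity = 1.0, breadth = 0.30,
                freq_within = c(egm_off = 0.25), freq_beyond = 0.10,
                spend_within = 0, spend_beyond = 0),
    focal_type = names(beta$freq_within)[1],
    outcome_intercept = 8, noise_sd = 2,
    mixture_intercept = -1.6, mixture_noise_sd = 1.2,
    missing_rates = list(freq = 0.01, spend = 0.02, demographics = 0.0294),
    analysis_config = gcmm_config(),
    rng_seed = 20070101,
    catalog = default_catalog()) {
  check_catalog(catalog)
  outcome_mode <- match.arg(outcome_mode)
  if (any(n_per_year < 0))
    stop("n_per_year must be non-negative", call. = FALSE)
  if (sum(n_per_year) == 0)
    warning("zero respondents requested; the table will be empty")
  if (length(n_per_year) != length(years))
    stop("n_per_year and years must align", call. = FALSE)
  participation <- participation[catalog$type_id]
  if (any(is.na(participation)))
    stop("participation must name every catalog type", call. = FALSE)
  if (any(participation < 0 | participation > 1))
    stop("participation probabilities must lie in [0, 1]", call. = FALSE)
  if (!(rho >= 0 && rho < 1)) stop("rho must be in [0, 1)", call. = FALSE)
  if (any(freq_probs < 0) || sum(freq_probs) <= 0 || length(freq_probs) != 5)
    stop("infeasible frequency category configuration: freq_probs must be ",
         "5 non-negative weights with positive sum", call. = FALSE)
  freq_probs <- freq_probs / sum(freq_probs)
  if (any(demo_odds <= 0)) stop("odds ratios must be positive", call. = FALSE)
  for (rt in unlist(missing_rates))
    if (rt < 0 || rt > 1) stop("missing rates must lie in [0, 1]", call. = FALSE)
  if (!all(names(beta$freq_within) %in% catalog$type_id))
    stop("beta$freq_within names must be catalog type_ids", call. = FALSE)
  structure(list(n_per_year = n_per_year, years = years,
                 participation = participation, rho = rho,
                 freq_probs = freq_probs,
                 spend_meanlog = rep_len(spend_meanlog, nrow(catalog)),
                 spend_sdlog = rep_len(spend_sdlog, nrow(catalog)),
                 spend_freq_cor = spend_freq_cor,
                 outlier_rate = outlier_rate, outlier_scale = outlier_scale,
                 demographics = demographics, demo_odds = demo_odds,
                 target_highrisk_rate = target_highrisk_rate,
                 outcome_mode = outcome_mode, beta = beta,
                 focal_type = focal_type,
                 outcome_intercept = outcome_intercept, noise_sd = noise_sd,
                 mixture_intercept = mixture_intercept,
                 mixture_noise_sd = mixture_noise_sd,
                 missing_rates = missing_rates,
                 analysis_config = analysis_config,
                 rng_seed = as.integer(rng_seed), catalog = catalog),
            class = "gcmm_sim_params")
}

#' Default per-type participation probabilities
#'
#' Participation rates among last-year gamblers as observed across the
#' three Icelandic surveys (lotto offline 73.7% down to online foreign
#' gambling 1.4%), used as the generator's marginal targets.
#'
#' @param catalog a [gcmm_catalog()].
#' @return Named probability vector over `catalog$type_id`.
#' @export
default_participation <- function(catalog = default_catalog()) {
  p <- c(lotto_off = 0.737, lotto_on_is = 0.135, egm_off = 0.125,
         scratch_off = 0.314, pools_off = 0.069, pools_on_is = 0.038,
         sport_off = 0.034, sport_on_is = 0.028, live_on = 0.023,
         sport_on_foreign = 0.025, poker_off = 0.106,
         poker_on_foreign = 0.018, skill_off = 0.025, bingo_off = 0.156,
         other_on_foreign = 0.014)
  out <- p[catalog$type_id]
  out[is.na(out)] <- 0.05
  names(out) <- catalog$type_id
  out
}

# internal: run expr with a private RNG stream, restoring caller state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a synthetic gambling survey
#'
#' Draws a complete respondent-level survey table under the generator
#' model described in [gcmm_sim_params()], injects missing values at the
#' configured rates, assigns the PGSI outcome, and records the ground
#' truth of the planted mediation paths (realized a-paths from the same
#' draws, the planted b-path coefficients, and their products) so that
#' downstream estimates can be validated against truth.
#'
#' @param params a [gcmm_sim_params()].
#' @return A list with elements `table` (a `"gcmm_survey"`) and `truth`
#'   (class `"gcmm_truth"`: `mode`, `beta`, per-focal-type `a`, `b`,
#'   `indirect` vectors over the six mediators, plus bookkeeping counts).
#' @export
simulate_survey <- function(params) {
  stopifnot(inherits(params, "gcmm_sim_params"))
  with_seed(params$rng_seed, simulate_survey_impl(params))
}

simulate_survey_impl <- function(params) {
  catalog <- params$catalog
  n <- sum(params$n_per_year)
  k <- nrow(catalog)
  year <- rep(params$years, params$n_per_year)

  dg <- params$demographics
  gender <- ifelse(stats::runif(n) < dg$p_male, "male", "female")
  age <- round(stats::qnorm(stats::runif(n,
           stats::pnorm(dg$age_range[1], dg$age_mean, dg$age_sd),
           stats::pnorm(dg$age_range[2], dg$age_mean, dg$age_sd)),
           dg$age_mean, dg$age_sd))
  age <- pmin(pmax(age, dg$age_range[1]), dg$age_range[2])
  education <- sample.int(3L, n, replace = TRUE,
                          prob = dg$educ_probs / sum(dg$educ_probs))
  partnered <- as.integer(stats::runif(n) < dg$p_partnered)

  # one latent involvement factor per respondent + type-specific noise;
  # thresholding its normal quantile gives the target marginals and a
  # positive cross-type participation correlation
  V <- stats::rnorm(n)
  freq <- matrix(0L, n, k, dimnames = list(NULL, catalog$freq_column))
  spend <- matrix(0, n, k, dimnames = list(NULL, catalog$spend_column))
  cum_fp <- cumsum(params$freq_probs)
  for (j in seq_len(k)) {
    pi_j <- params$participation[j]
    L <- sqrt(params$rho) * V + sqrt(1 - params$rho) * stats::rnorm(n)
    q <- stats::pnorm(L)
    part <- pi_j > 0 & q > 1 - pi_j
    if (any(part)) {
      v <- (q[part] - (1 - pi_j)) / pi_j   # uniform within participants
      freq[part, j] <- 1L + findInterval(v, cum_fp[-5])
      lam <- params$spend_freq_cor
      z <- lam * L[part] + sqrt(1 - lam^2) * stats::rnorm(sum(part))
      s <- exp(params$spend_meanlog[j] + params$spend_sdlog[j] * z)
      out <- stats::runif(sum(part)) < params$outlier_rate
      s[out] <- s[out] * params$outlier_scale
      spend[part, j] <- round(s)
    }
  }

  df <- data.frame(respondent_id = sprintf("r%06d", seq_len(n)),
                   year = year, gender = gender, age = age,
                   education = education, partnered = partnered,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(freq), as.data.frame(spend))
  df$pgsi_raw <- rep(0L, n)
  table <- as_survey(df, catalog)

  # missing values go in before the outcome so planted paths are defined
  # on exactly the (imputed) constructs the analysis will see
  table <- inject_missing(table, params$missing_rates,
                          seed = sample.int(.Machine$integer.max, 1L))

  gam <- filter_last_year_gamblers(table)
  idx <- match(gam$respondent_id, table$respondent_id)
  pgsi <- rep(0L, n)
  truth <- structure(list(mode = params$outcome_mode, beta = params$beta,
                          paths = list(), n_gamblers = nrow(gam),
                          highrisk_rate = NA_real_),
                     class = "gcmm_truth")
  if (nrow(gam) > 0) {
    cfg <- params$analysis_config
    dc <- depth_components(as.data.frame(gam), catalog, cfg)
    # true demographic propensity (probability scale) for the gamblers
    lp <- log(params$demo_odds["male"]) * (gam$gender == "male") +
      log(params$demo_odds["education"]) * as.numeric(gam$education) +
      log(params$demo_odds["single"]) * (gam$partnered == 0) +
      log(params$demo_odds["age"]) * as.numeric(gam$age)
    lp[is.na(lp)] <- mean(lp, na.rm = TRUE)

    prob_m <- stats::plogis(lp)   # true-probability propensity construct
    m_of <- function(focal) {
      i <- match(focal, catalog$type_id)
      cbind(M1 = prob_m, M2 = dc$breadth, M3 = dc$freq[, i],
            M4 = beyond_max(dc$freq, i), M5 = dc$spend_w[, i],
            M6 = beyond_max(dc$spend_w, i))
    }
    focal0 <- params$focal_type
    if (is.null(focal0) || is.na(focal0)) focal0 <- catalog$type_id[1]
    b <- params$beta
    # behaviour linear predictor: per-type frequency-within terms plus
    # shared propensity/breadth/beyond/spending terms defined on the
    # first focal type
    M0 <- m_of(focal0)
    eta <- b$propensity * M0[, "M1"] + b$breadth * M0[, "M2"] +
      b$freq_beyond * M0[, "M4"] +
      b$spend_within * M0[, "M5"] + b$spend_beyond * M0[, "M6"]
    fc <- b$freq_centering %||% 0
    for (tn in names(b$freq_within)) {
      i <- match(tn, catalog$type_id)
      eta <- eta + b$freq_within[[tn]] * (dc$freq[, i] - fc * dc$part[, i])
    }
    if (params$outcome_mode == "linear") {
      lat <- params$outcome_intercept + eta +
        stats::rnorm(nrow(gam), 0, params$noise_sd)
      pg <- pmin(pmax(round(lat), 0L), 27L)
    } else {
      g0 <- stats::uniroot(function(c0)
        mean(stats::plogis(c0 + lp)) - params$target_highrisk_rate,
        c(-40, 40))$root
      H <- stats::runif(nrow(gam)) < stats::plogis(g0 + lp)
      low <- pmin(pmax(round(params$mixture_intercept + eta +
        stats::rnorm(nrow(gam), 0, params$mixture_noise_sd)), 0L), 4L)
      pg <- ifelse(H, 5L + pmin(stats::rpois(nrow(gam), 1.5), 22L), low)
      truth$highrisk_rate <- mean(H)
    }
    pgsi[idx] <- as.integer(pg)

    # realized a-paths (simple OLS slopes of each construct on X) for
    # every planted focal type, from the same draws
    focals <- unique(c(focal0, names(b$freq_within)))
    for (tn in focals) {
      i <- match(tn, catalog$type_id)
      x <- dc$part[, i]
      if (length(unique(x)) < 2) next
      Mt <- m_of(tn)
      xc <- x - mean(x)
      av <- colSums(xc * Mt) / sum(xc^2)
      bt <- c(M1 = unname(b$propensity), M2 = unname(b$breadth),
              M3 = if (tn %in% names(b$freq_within))
                unname(b$freq_within[[tn]]) else 0,
              M4 = unname(b$freq_beyond), M5 = unname(b$spend_within),
              M6 = unname(b$spend_beyond))
      truth$paths[[tn]] <- list(a = av, b = bt, indirect = av * bt)
    }
  }
  table$pgsi_raw <- pgsi
  list(table = table, truth = truth)
}

#' Inject missing values block-wise
#'
#' Marks cells missing at the given rates without removing rows: `freq`
#' and `spend` rates act per cell of the respective column blocks;
#' `demographics` is a per-row rate, blanking one randomly chosen
#' demographic field (gender, age, education or partnership) of each
#' affected row — mirroring how case-wise exclusion in the propensity
#' model produced 2.94% missing scores in the source surveys.
#'
#' @param table a `"gcmm_survey"`.
#' @param rates list with elements `freq`, `spend`, `demographics` in
#'   `[0, 1]` (absent elements default to 0).
#' @param seed RNG seed.
#' @return The table with `NA`s injected.
#' @export
inject_missing <- function(table, rates = list(), seed = 1L) {
  stopifnot(inherits(table, "gcmm_survey"))
  catalog <- attr(table, "catalog")
  r_freq <- rates$freq %||% 0
  r_spend <- rates$spend %||% 0
  r_demo <- rates$demographics %||% 0
  for (rt in c(r_freq, r_spend, r_demo))
    if (rt < 0 || rt > 1) stop("missing rates must lie in [0, 1]", call. = FALSE)
  n <- nrow(table)
  if (n == 0) return(table)
  with_seed(seed, {
    if (r_freq > 0)
      for (col in catalog$freq_column)
        table[[col]][stats::runif(n) < r_freq] <- NA
    if (r_spend > 0)
      for (col in catalog$spend_column)
        table[[col]][stats::runif(n) < r_spend] <- NA
    if (r_demo > 0) {
      hit <- which(stats::runif(n) < r_demo)
      fields <- c("gender", "age", "education", "partnered")
      pick <- sample(fields, length(hit), replace = TRUE)
      for (f in fields) {
        rows <- hit[pick == f]
        if (length(rows)) table[[f]][rows] <- NA
      }
    }
    table
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the generator ground truth as YAML
#'
#' @param truth a `"gcmm_truth"` from [simulate_survey()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "gcmm_truth"))
  out <- list(mode = truth$mode,
              beta = lapply(truth$beta, function(v) as.list(v)),
              n_gamblers = truth$n_gamblers,
              highrisk_rate = truth$highrisk_rate,
              paths = lapply(truth$paths, function(p)
                list(a = as.list(p$a), b = as.list(p$b),
                     indirect = as.list(p$indirect))))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.gcmm_truth <- function(x, ...) {
  cat("Synthetic-survey ground truth (outcome mode:", x$mode, ")\n")
  cat("  last-year gamblers:", x$n_gamblers, "\n")
  if (!is.na(x$highrisk_rate))
    cat(sprintf("  realized moderate-risk+ rate: %.3f%%\n",
                100 * x$highrisk_rate))
  for (tn in names(x$paths)) {
    cat("  focal", tn, "true indirect (a*b):\n")
    print(round(x$paths[[tn]]$indirect, 4))
  }
  invisible(x)
}
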