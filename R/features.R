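#' Winsorize a numeric vector
#'
#' Replaces non-missing values below the lower percentile by the
#' percentile value and values above the upper percentile by that value;
#' missing entries are left untouched. Percentiles follow the package's
#' single quantile rule (linear interpolation between closest ranks).
#' Used for the open-ended spending variables (1st/99th percentile by
#' default), whose outliers would otherwise bias the OLS path estimates.
#'
#' @param values numeric vector, possibly with `NA`.
#' @param lower_pct,upper_pct percentiles in 0-100, lower < upper.
#' @return The winsorized vector, same length and `NA` pattern.
#' @export
winsorize <- function(values, lower_pct = 1, upper_pct = 99) {
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stop("need 0 <= lower_pct < upper_pct <= 100", call. = FALSE)
  obs <- values[!is.na(values)]
  if (!length(obs)) stop("winsorize: all values missing", call. = FALSE)
  q <- gcmm_quantile(obs, c(lower_pct, upper_pct) / 100)
  out <- values
  out[!is.na(out) & out < q[1]] <- q[1]
  out[!is.na(out) & out > q[2]] <- q[2]
  out
}

#' Last-year participation from a frequency category
#'
#' 1 when the frequency category is 1 (a few times in the past year) or
#' higher; 0 for "never" and for missing responses (missing depth
#' responses among last-year gamblers are treated as non-participation).
#'
#' @param freq ordinal frequency categories 0-5, possibly `NA`.
#' @return Integer vector of 0/1.
#' @export
derive_participation <- function(freq) {
  as.integer(!is.na(freq) & freq >= 1)
}

#' Breadth of involvement
#'
#' Number of game types played at least once in the last year, capped to
#' curb outliers (published cap: 7 types, the 99th percentile).
#'
#' @param participation matrix (respondents x types) of 0/1 indicators.
#' @param cap upper cap applied after summation.
#' @return Integer vector of capped per-respondent counts.
#' @export
compute_breadth <- function(participation, cap = 7) {
  participation <- as.matrix(participation)
  pmin(as.integer(rowSums(participation)), as.integer(cap))
}

#' Maximum beyond the focal type
#'
#' Row-wise maximum of a per-type value matrix over every type except
#' the focal one; used to aggregate gambling frequency and usual
#' spending beyond the game type of interest (the maximum is preferred
#' to the sum to avoid near-collinearity with breadth).
#'
#' @param values matrix (respondents x types), missing already imputed.
#' @param focal_index column index or column name of the focal type.
#' @return Numeric vector of row maxima over the non-focal columns.
#' @export
beyond_max <- function(values, focal_index) {
  values <- as.matrix(values)
  if (is.character(focal_index))
    focal_index <- match(focal_index, colnames(values))
  if (is.na(focal_index) || focal_index < 1 || focal_index > ncol(values))
    stop("beyond_max: focal type not found among columns", call. = FALSE)
  apply(values[, -focal_index, drop = FALSE], 1L, max)
}

#' PGSI severity groups
#'
#' Standard four-group scoring of the Problem Gambling Severity Index
#' sum score: 0 = no problem; 1-4 = low-risk; 5-7 = moderate-risk;
#' 8+ = problem gambling.
#'
#' @param score integer PGSI sum scores in 0-27.
#' @return Factor with levels `no_problem`, `low_risk`, `moderate_risk`,
#'   `problem`.
#' @export
pgsi_group <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 27))
    stop("PGSI scores must lie in [0, 27]", call. = FALSE)
  cut(score, breaks = c(-Inf, 0, 4, 7, Inf),
      labels = c("no_problem", "low_risk", "moderate_risk", "problem"))
}

#' Demographic problem-gambling propensity
#'
#' Binary logistic regression predicting the outcome of being at least
#' at moderate risk (PGSI >= `threshold`) from four demographics: male
#' gender, education (three ascending levels entered as one metric
#' term), being single/divorced/widowed, and age in years. The fitted
#' probability is saved per respondent as the metric propensity score;
#' respondents with missing demographics (excluded case-wise from the
#' fit) receive the mean score of all scored respondents.
#'
#' @param table a `"gcmm_survey"`, already filtered to last-year gamblers.
#' @param threshold PGSI cut defining the outcome (default 5).
#' @param scale `"response"` (probability, the default score scale) or
#'   `"link"` (linear predictor).
#' @return A list of class `"gcmm_propensity"`: `coefficients` (log-odds),
#'   `odds_ratios`, `score` (per respondent, in (0,1) on the response
#'   scale), `n_missing_imputed`, `fit` (the `glm` object).
#' @export
fit_propensity <- function(table, threshold = 5,
                           scale = c("response", "link")) {
  scale <- match.arg(scale)
  stopifnot(inherits(table, "gcmm_survey"))
  d <- data.frame(
    outcome = as.integer(table$pgsi_raw >= threshold),
    male = as.integer(table$gender == "male"),
    education = as.numeric(table$education),
    single = as.integer(table$partnered == 0),
    age = as.numeric(table$age)
  )
  complete <- stats::complete.cases(d)
  dc <- d[complete, , drop = FALSE]
  if (length(unique(dc$outcome)) < 2)
    stop("propensity outcome has a single class; cannot fit", call. = FALSE)
  fit <- stats::glm(outcome ~ male + education + single + age,
                    family = stats::binomial(), data = dc)
  if (!fit$converged)
    stop("propensity logistic regression did not converge", call. = FALSE)
  score <- rep(NA_real_, nrow(d))
  score[complete] <- stats::predict(fit, type = scale)
  n_imp <- sum(!complete)
  score[!complete] <- mean(score[complete])
  structure(list(coefficients = stats::coef(fit),
                 odds_ratios = exp(stats::coef(fit)),
                 score = score,
                 n_missing_imputed = n_imp,
                 fit = fit),
            class = "gcmm_propensity")
}

#' @export
print.gcmm_propensity <- function(x, ...) {
  cat("Demographic propensity model (logistic, outcome: at least moderate risk)\n")
  or <- x$odds_ratios
  cat(sprintf("  OR male %.3f | education %.3f | single %.3f | age/yr %.3f\n",
              or["male"], or["education"], or["single"], or["age"]))
  cat(sprintf("  %d respondent(s) with missing demographics imputed to the mean score\n",
              x$n_missing_imputed))
  invisible(x)
}

# internal: depth constructs shared by the analysis and the synthetic
# generator. Order of operations: impute missing depth responses to 0
# (so imputed zeros enter the percentile computation), winsorize
# spending per type pooled over survey years, derive participation and
# the capped breadth count.
depth_components <- function(df, catalog, config) {
  freq <- as.matrix(df[, catalog$freq_column, drop = FALSE])
  spend <- as.matrix(df[, catalog$spend_column, drop = FALSE])
  freq[is.na(freq)] <- 0
  spend[is.na(spend)] <- 0
  spend_w <- apply(spend, 2L, winsorize,
                   lower_pct = config$winsor_lower_pct,
                   upper_pct = config$winsor_upper_pct)
  spend_w <- matrix(spend_w, nrow = nrow(spend),
                    dimnames = dimnames(spend))
  part <- matrix(derive_participation(freq), nrow = nrow(freq),
                 dimnames = dimnames(freq))
  bcap <- if (config$breadth_cap_mode == "fixed") config$breadth_cap else
    gcmm_quantile(rowSums(part), 0.99)
  breadth <- compute_breadth(part, cap = bcap)
  list(freq = freq, spend_w = spend_w, part = part,
       breadth = breadth, breadth_cap = bcap)
}

# internal: shared per-table feature components, computed once and reused
# across the 15 focal types; depth constructs plus the fitted propensity
# model and the capped PGSI outcome.
prepare_features <- function(table, config = gcmm_config()) {
  stopifnot(inherits(table, "gcmm_survey"))
  catalog <- attr(table, "catalog")
  df <- as.data.frame(table)
  dc <- depth_components(df, catalog, config)
  freq <- dc$freq; spend_w <- dc$spend_w; part <- dc$part
  breadth <- dc$breadth; bcap <- dc$breadth_cap
  prop <- fit_propensity(table, threshold = config$propensity_threshold)
  ycap <- if (config$pgsi_cap_mode == "fixed") config$pgsi_cap else
    gcmm_quantile(df$pgsi_raw, 0.99)
  y <- pmin(df$pgsi_raw, ycap)
  list(catalog = catalog, freq = freq, spend_w = spend_w, part = part,
       breadth = breadth, breadth_cap = bcap, propensity = prop,
       y = y, pgsi_cap = ycap)
}

#' Build the mediation feature set for one focal game type
#'
#' Derives, per respondent, the predictor and the six mediators of the
#' parallel mediation model: `X` last-year participation in the focal
#' type (0/1); `M1_propensity` demographic propensity score;
#' `M2_breadth` capped number of game types played; `M3_freq_within`
#' frequency category within the focal type; `M4_freq_beyond` maximum
#' frequency over the 14 other types; `M5_spend_within` winsorized usual
#' spending within; `M6_spend_beyond` maximum winsorized spending over
#' the other types; and `Y`, the capped PGSI sum score.
#'
#' @param table a `"gcmm_survey"` of last-year gamblers.
#' @param focal_type a `type_id` from the table's catalog.
#' @param config a [gcmm_config()].
#' @param prepared internal: reuse of shared components across types.
#' @return Data frame of class `"gcmm_features"` with columns `X`,
#'   `M1_propensity` ... `M6_spend_beyond`, `Y`; attributes `focal_type`,
#'   `propensity` (the fitted model), `breadth_cap`, `pgsi_cap`.
#' @export
build_featureset <- function(table, focal_type, config = gcmm_config(),
                             prepared = NULL) {
  if (is.null(prepared)) prepared <- prepare_features(table, config)
  catalog <- prepared$catalog
  i <- match(focal_type, catalog$type_id)
  if (is.na(i))
    stop("unknown focal type: ", focal_type, call. = FALSE)
  agg <- config$beyond_aggregate %||% "max"
  beyond <- switch(agg,
                   max = function(v) beyond_max(v, i),
                   mean = function(v) rowMeans(as.matrix(v)[, -i, drop = FALSE]),
                   median = function(v) apply(as.matrix(v)[, -i, drop = FALSE],
                                              1L, stats::median))
  fs <- data.frame(
    X = prepared$part[, i],
    M1_propensity = prepared$propensity$score,
    M2_breadth = prepared$breadth,
    M3_freq_within = prepared$freq[, i],
    M4_freq_beyond = beyond(prepared$freq),
    M5_spend_within = prepared$spend_w[, i],
    M6_spend_beyond = beyond(prepared$spend_w),
    Y = prepared$y
  )
  rownames(fs) <- NULL
  structure(fs, focal_type = focal_type,
            propensity = prepared$propensity,
            breadth_cap = prepared$breadth_cap,
            pgsi_cap = prepared$pgsi_cap,
            class = c("gcmm_features", "data.frame"))
}

#' Export a feature set as a tidy CSV
#'
#' One row per respondent, columns `X`, `M1_propensity` ...
#' `M6_spend_beyond`, `Y`.
#'
#' @param fs a [build_featureset()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_featureset <- function(fs, path) {
  stopifnot(inherits(fs, "gcmm_features"))
  utils::write.csv(as.data.frame(fs), path, row.names = FALSE)
  invisible(path)
}

# labels of the six mediators, in fixed model order
mediator_names <- function() {
  c("M1_propensity", "M2_breadth", "M3_freq_within",
    "M4_freq_beyond", "M5_spend_within", "M6_spend_beyond")
}
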