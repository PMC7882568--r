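#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline: spending winsorization
#' percentiles, outlier caps for breadth and the PGSI outcome, the PGSI
#' threshold defining the demographic-propensity outcome, bootstrap
#' settings, and the dominance-ratio threshold of the profile rule.
#'
#' Defaults reproduce the published analysis: spending winsorized within
#' the 1st and 99th percentile; breadth capped at 7 game types and PGSI at
#' 6 points (both the published fixed 99th-percentile caps); propensity
#' outcome PGSI >= 5 (at least moderate risk); 5000 bootstrap resamples
#' and 95% percentile intervals; dominance ratio threshold 2.
#'
#' @param winsor_lower_pct,winsor_upper_pct spending winsorization
#'   percentiles (0-100).
#' @param breadth_cap_mode,breadth_cap `"fixed"` (use `breadth_cap`) or
#'   `"percentile99"` (re-derive the cap as the empirical 99th percentile).
#' @param pgsi_cap_mode,pgsi_cap as above, for the PGSI outcome.
#' @param propensity_threshold PGSI score at or above which a respondent
#'   counts as the propensity-model outcome (moderate risk or worse).
#' @param bootstrap_B number of bootstrap resamples.
#' @param ci_level confidence level for percentile intervals.
#' @param rng_seed integer seed used when none is passed explicitly.
#' @param dominance_ratio_threshold profile rule threshold on the ratio of
#'   the largest to second-largest relevant positive indirect effect.
#' @param beyond_aggregate how depth beyond the focal type is
#'   aggregated over the other 14 types: `"max"` (the default; avoids
#'   near-collinearity with breadth), or the exploratory `"mean"` /
#'   `"median"` alternatives.
#' @return A list of class `"gcmm_config"`.
#' @export
gcmm_config <- function(winsor_lower_pct = 1, winsor_upper_pct = 99,
                        breadth_cap_mode = c("fixed", "percentile99"),
                        breadth_cap = 7,
                        pgsi_cap_mode = c("fixed", "percentile99"),
                        pgsi_cap = 6,
                        propensity_threshold = 5,
                        bootstrap_B = 5000,
                        ci_level = 0.95,
                        rng_seed = 20070101,
                        dominance_ratio_threshold = 2.0,
                        beyond_aggregate = c("max", "mean", "median")) {
  beyond_aggregate <- match.arg(beyond_aggregate)
  breadth_cap_mode <- match.arg(breadth_cap_mode)
  pgsi_cap_mode <- match.arg(pgsi_cap_mode)
  if (!(winsor_lower_pct >= 0 && winsor_lower_pct < winsor_upper_pct &&
        winsor_upper_pct <= 100))
    stop("need 0 <= winsor_lower_pct < winsor_upper_pct <= 100", call. = FALSE)
  if (bootstrap_B < 1) stop("bootstrap_B must be >= 1", call. = FALSE)
  if (!(ci_level > 0 && ci_level < 1))
    stop("ci_level must be in (0, 1)", call. = FALSE)
  if (dominance_ratio_threshold <= 0)
    stop("dominance_ratio_threshold must be positive", call. = FALSE)
  structure(list(winsor_lower_pct = winsor_lower_pct,
                 winsor_upper_pct = winsor_upper_pct,
                 breadth_cap_mode = breadth_cap_mode,
                 breadth_cap = breadth_cap,
                 pgsi_cap_mode = pgsi_cap_mode,
                 pgsi_cap = pgsi_cap,
                 propensity_threshold = propensity_threshold,
                 bootstrap_B = as.integer(bootstrap_B),
                 ci_level = ci_level,
                 rng_seed = as.integer(rng_seed),
                 dominance_ratio_threshold = dominance_ratio_threshold,
                 beyond_aggregate = beyond_aggregate),
            class = "gcmm_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns a `"gcmm_config"`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(gcmm_config, vals)
}

#' @rdname read_config
#' @param config a `"gcmm_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "gcmm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.gcmm_config <- function(x, ...) {
  cat("gcmm analysis configuration\n")
  cat(sprintf("  spending winsorization : %g-%g percentile\n",
              x$winsor_lower_pct, x$winsor_upper_pct))
  cat(sprintf("  breadth cap            : %s (%g)\n", x$breadth_cap_mode, x$breadth_cap))
  cat(sprintf("  PGSI cap               : %s (%g)\n", x$pgsi_cap_mode, x$pgsi_cap))
  cat(sprintf("  propensity outcome     : PGSI >= %g\n", x$propensity_threshold))
  cat(sprintf("  bootstrap              : B = %d, %g%% percentile CI\n",
              x$bootstrap_B, 100 * x$ci_level))
  cat(sprintf("  dominance threshold    : %g\n", x$dominance_ratio_threshold))
  invisible(x)
}

# internal: shared quantile rule (linear interpolation between closest
# ranks, stats::quantile type 7) used for winsorization, percentile caps
# and bootstrap CIs alike
gcmm_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7, na.rm = FALSE)
}
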