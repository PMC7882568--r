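#' Ordinary least squares fit with rank diagnostics
#'
#' Thin wrapper around the QR least-squares solver that refuses
#' rank-deficient designs and names the offending columns (a constant
#' mediator is the typical culprit in this pipeline).
#'
#' @param y numeric response vector.
#' @param design numeric design matrix including the intercept column.
#' @return Named coefficient vector.
#' @export
ols_fit <- function(y, design) {
  design <- as.matrix(design)
  if (nrow(design) < ncol(design))
    stop("fewer rows than columns in the design", call. = FALSE)
  fit <- stats::.lm.fit(design, y)
  if (fit$rank < ncol(design)) {
    qrd <- qr(design)
    dropped <- colnames(design)[qrd$pivot[seq(qrd$rank + 1L, ncol(design))]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  stats::setNames(fit$coefficients, colnames(design))
}

# internal: all path estimates for one (x, M, y) draw, on bare matrices.
# Returns NULL when the outcome design is rank deficient (bootstrap
# resamples use this to trigger a redraw). The a-paths are the simple
# OLS slopes of each mediator on x; b-paths and c' come from the joint
# outcome regression of y on x and all mediators.
med_point <- function(x, M, y) {
  xc <- x - mean(x)
  sxx <- sum(xc * xc)
  if (sxx == 0) return(NULL)
  a <- colSums(xc * M) / sxx
  Z <- cbind(1, x, M)
  fit <- stats::.lm.fit(Z, y)
  if (fit$rank < ncol(Z)) return(NULL)
  cf <- fit$coefficients
  b <- cf[3:length(cf)]
  c_prime <- cf[2L]
  indirect <- a * b
  total <- c_prime + sum(indirect)
  simple <- sum(xc * y) / sxx
  list(a = a, b = b, c_prime = c_prime, indirect = indirect,
       total = total, simple = simple, coef = cf,
       fitted = drop(Z %*% cf))
}

# internal: flatten one med_point result into the 20-slot effect vector
effect_vector <- function(pt) {
  c(pt$a, pt$b, pt$indirect, c_prime = unname(pt$c_prime),
    total = unname(pt$total))
}

effect_names <- function() {
  m <- mediator_names()
  c(paste0("a_", m), paste0("b_", m), paste0("indirect_", m),
    "c_prime", "total")
}

#' Fit a parallel multiple mediation model for one game type
#'
#' The central model of the package. For a focal game type, last-year
#' participation `X` (0/1) is related to the capped PGSI outcome `Y`
#' through six parallel mediators: demographic propensity, breadth of
#' involvement, frequency and usual spending within the focal type, and
#' maximum frequency and spending beyond it. Estimation is OLS path
#' analysis: the a-path of each mediator is the simple regression of the
#' mediator on `X`; the b-paths and the direct effect `c'` come from one
#' joint OLS regression of `Y` on `X` and all six mediators. The
#' indirect effect through mediator j is the product `a_j * b_j`, and
#' the total effect is `c' + sum(a_j * b_j)`, which equals the simple
#' regression slope of `Y` on `X` (an OLS identity that is verified on
#' every fit and every bootstrap resample).
#'
#' Inference is by nonparametric percentile bootstrap: rows are
#' resampled with replacement `B` times, all paths are re-estimated per
#' resample, and each effect's confidence interval is the empirical
#' (alpha/2, 1-alpha/2) quantile interval of its bootstrap distribution.
#' Resamples with a rank-deficient outcome design are redrawn (the count
#' is recorded) so the distribution always holds exactly `B` draws. An
#' effect is flagged *relevant* when its interval excludes zero. No
#' multiplicity adjustment is applied by default, matching the
#' exploratory use of the model.
#'
#' @param data a `"gcmm_survey"` of last-year gamblers, or a prebuilt
#'   [build_featureset()] result.
#' @param focal_type catalog `type_id` (required when `data` is a survey).
#' @param config a [gcmm_config()]; supplies defaults for `B`,
#'   `ci_level` and `seed`.
#' @param B number of bootstrap resamples; `B = 0` skips the bootstrap
#'   and returns point estimates only.
#' @param ci_level confidence level of the percentile intervals.
#' @param seed integer RNG seed for the bootstrap (the caller's RNG
#'   state is left untouched).
#' @param keep_features keep the feature data frame on the object (needed
#'   by `residuals()`/`fitted()`/`predict()`).
#' @return An object of class `"gcmm"`; see [summary.gcmm()].
#' @examples
#' sim <- simulate_survey(gcmm_sim_params(n_per_year = c(300, 300, 300),
#'                                        rng_seed = 1))
#' gam <- filter_last_year_gamblers(sim$table)
#' fit <- gcmm(gam, "lotto_off", B = 200, seed = 7)
#' summary(fit)
#' @export
gcmm <- function(data, focal_type = NULL, config = gcmm_config(),
                 B = config$bootstrap_B, ci_level = config$ci_level,
                 seed = config$rng_seed, keep_features = TRUE) {
  fs <- if (inherits(data, "gcmm_features")) data
        else {
          if (is.null(focal_type))
            stop("focal_type is required when fitting from a survey table",
                 call. = FALSE)
          build_featureset(data, focal_type, config)
        }
  focal_type <- attr(fs, "focal_type")
  mn <- mediator_names()
  x <- fs$X
  M <- as.matrix(fs[, mn])
  y <- fs$Y
  n <- length(y)
  if (length(unique(x)) < 2)
    stop("participation X is constant; the focal type was played by ",
         "all or none of the sample", call. = FALSE)
  const <- mn[apply(M, 2L, function(v) length(unique(v)) < 2)]
  if (length(const))
    stop("constant mediator(s): ", paste(const, collapse = ", "),
         "; remove them or enlarge the sample", call. = FALSE)

  pt <- med_point(x, M, y)
  if (is.null(pt))
    stop("outcome design is rank deficient (collinear mediators)",
         call. = FALSE)
  decomp_err <- abs(pt$total - pt$simple)

  est <- effect_vector(pt)
  names(est) <- effect_names()
  ci <- NULL; relevant <- NULL; n_redraws <- 0L
  if (B > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
    boot <- matrix(NA_real_, nrow = B, ncol = length(est),
                   dimnames = list(NULL, names(est)))
    max_bad <- ceiling(0.10 * B)
    r <- 1L
    while (r <= B) {
      idx <- sample.int(n, n, replace = TRUE)
      bpt <- med_point(x[idx], M[idx, , drop = FALSE], y[idx])
      if (is.null(bpt)) {
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_bad)
          stop("more than 10% of bootstrap resamples were rank ",
               "deficient; the data are too sparse for this model",
               call. = FALSE)
        next
      }
      decomp_err <- max(decomp_err, abs(bpt$total - bpt$simple))
      boot[r, ] <- effect_vector(bpt)
      r <- r + 1L
    }
    alpha <- 1 - ci_level
    ci <- t(apply(boot, 2L, gcmm_quantile,
                  probs = c(alpha / 2, 1 - alpha / 2)))
    colnames(ci) <- c("lower", "upper")
    relevant <- ci[, "lower"] > 0 | ci[, "upper"] < 0
  }

  structure(list(
    focal_type = focal_type,
    a = stats::setNames(pt$a, mn),
    b = stats::setNames(pt$b, mn),
    c_prime = unname(pt$c_prime),
    indirect = stats::setNames(pt$indirect, mn),
    total = unname(pt$total),
    total_simple = unname(pt$simple),
    estimates = est,
    ci = ci,
    relevant = relevant,
    n = n, B = as.integer(B), ci_level = ci_level, seed = seed,
    n_redraws = n_redraws,
    decomp_max_err = decomp_err,
    outcome_coef = pt$coef,
    fitted_values = if (keep_features) pt$fitted else NULL,
    features = if (keep_features) fs else NULL,
    call = match.call()
  ), class = "gcmm")
}

#' Fit the mediation model for every catalog type
#'
#' Runs [gcmm()] once per game type in the table's catalog, reusing the
#' shared feature components (winsorized spending, breadth, propensity
#' score, capped outcome) across types. Each type gets its own seed
#' derived from the master seed, so runs are reproducible type by type.
#' Per-type failures (e.g. a type nobody played) are collected and
#' reported; the run continues.
#'
#' @inheritParams gcmm
#' @param table a `"gcmm_survey"` of last-year gamblers.
#' @param types subset of catalog `type_id`s (default: all).
#' @param bonferroni widen every interval to the Bonferroni-adjusted
#'   level `1 - (1 - ci_level) / n_types`; off by default, matching the
#'   unadjusted exploratory analysis.
#' @return An object of class `"gcmm_list"`: named list of `"gcmm"` fits
#'   plus a `failures` attribute (named character vector of error
#'   messages).
#' @export
gcmm_all <- function(table, config = gcmm_config(), types = NULL,
                     B = config$bootstrap_B, ci_level = config$ci_level,
                     seed = config$rng_seed, bonferroni = FALSE) {
  stopifnot(inherits(table, "gcmm_survey"))
  catalog <- attr(table, "catalog")
  if (is.null(types)) types <- catalog$type_id
  if (bonferroni)
    ci_level <- 1 - (1 - ci_level) / length(types)
  prep <- prepare_features(table, config)
  fits <- list()
  failures <- character()
  for (i in seq_along(types)) {
    t_id <- types[i]
    fit <- tryCatch(
      gcmm(build_featureset(table, t_id, config, prepared = prep),
           config = config, B = B, ci_level = ci_level,
           seed = (seed + i) %% .Machine$integer.max,
           keep_features = FALSE),
      error = function(e) conditionMessage(e))
    if (inherits(fit, "gcmm")) fits[[t_id]] <- fit
    else failures[t_id] <- fit
  }
  structure(fits, failures = failures, class = "gcmm_list")
}

#' @export
print.gcmm_list <- function(x, ...) {
  cat("Parallel multiple mediation fits:", length(x), "game type(s)\n")
  fails <- attr(x, "failures")
  if (length(fails))
    cat("Failed types:",
        paste(names(fails), fails, sep = ": ", collapse = "; "), "\n")
  for (f in x)
    cat(sprintf("  %-18s total %8.4f  direct %8.4f  (n = %d, B = %d)\n",
                f$focal_type, f$total, f$c_prime, f$n, f$B))
  invisible(x)
}
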