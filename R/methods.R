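#' @export
print.gcmm <- function(x, digits = 4, ...) {
  cat("Parallel multiple mediation model (OLS paths, percentile bootstrap)\n")
  cat("Focal game type:", x$focal_type, "  n =", x$n,
      if (x$B > 0) paste0(" B = ", x$B) else " (point estimates only)", "\n")
  cat(sprintf("Total effect %s  direct (c') %s\n",
              format(x$total, digits = digits),
              format(x$c_prime, digits = digits)))
  cat("Indirect effects (a*b):\n")
  print(round(x$indirect, digits))
  invisible(x)
}

#' Summarise a fitted mediation model
#'
#' @param object a `"gcmm"` fit.
#' @param ... unused.
#' @return A list of class `"summary.gcmm"` whose `table` element is a
#'   data frame with one row per effect (six a-paths, six b-paths, six
#'   indirect effects, the direct effect `c_prime` and the `total`
#'   effect) and columns `estimate`, `lower`, `upper`, `relevant`
#'   (interval bounds `NA` when fitted with `B = 0`).
#' @export
summary.gcmm <- function(object, ...) {
  en <- names(object$estimates)
  tab <- data.frame(
    effect = en,
    estimate = unname(object$estimates),
    lower = if (is.null(object$ci)) NA_real_ else object$ci[, "lower"],
    upper = if (is.null(object$ci)) NA_real_ else object$ci[, "upper"],
    relevant = if (is.null(object$relevant)) NA else unname(object$relevant),
    row.names = NULL
  )
  structure(list(focal_type = object$focal_type, n = object$n,
                 B = object$B, ci_level = object$ci_level,
                 n_redraws = object$n_redraws,
                 decomp_max_err = object$decomp_max_err,
                 table = tab),
            class = "summary.gcmm")
}

#' @export
print.summary.gcmm <- function(x, digits = 4, ...) {
  cat(sprintf("Parallel multiple mediation: %s (n = %d, B = %d, %g%% percentile CI)\n",
              x$focal_type, x$n, x$B, 100 * x$ci_level))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, digits)
  tab$lower <- signif(tab$lower, digits)
  tab$upper <- signif(tab$upper, digits)
  print(tab, row.names = FALSE)
  if (x$n_redraws > 0)
    cat(x$n_redraws, "rank-deficient resample(s) redrawn\n")
  invisible(x)
}

#' @export
coef.gcmm <- function(object, ...) object$estimates

#' @export
confint.gcmm <- function(object, parm, level, ...) {
  if (is.null(object$ci))
    stop("fit has no bootstrap intervals (B = 0)", call. = FALSE)
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.gcmm <- function(object, ...) {
  if (is.null(object$fitted_values))
    stop("fit was made with keep_features = FALSE", call. = FALSE)
  object$fitted_values
}

#' @export
residuals.gcmm <- function(object, ...) {
  if (is.null(object$features))
    stop("fit was made with keep_features = FALSE", call. = FALSE)
  object$features$Y - object$fitted_values
}

#' Predict the outcome from the fitted outcome regression
#'
#' @param object a `"gcmm"` fit with `keep_features = TRUE`.
#' @param newdata optional data frame with columns `X` and the six
#'   mediators; defaults to the training features.
#' @param ... unused.
#' @return Predicted capped PGSI scores.
#' @export
predict.gcmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  Z <- cbind(1, newdata$X, as.matrix(newdata[, mediator_names()]))
  drop(Z %*% object$outcome_coef)
}

#' Forest-style plot of the indirect effects
#'
#' Point estimates and percentile bootstrap intervals of the six
#' indirect effects, with relevant effects (interval excluding zero)
#' drawn solid.
#'
#' @param x a `"gcmm"` fit with bootstrap intervals.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gcmm <- function(x, ...) {
  if (is.null(x$ci))
    stop("fit has no bootstrap intervals (B = 0)", call. = FALSE)
  mn <- mediator_names()
  idx <- paste0("indirect_", mn)
  est <- x$estimates[idx]
  ci <- x$ci[idx, , drop = FALSE]
  k <- length(est)
  ylim <- rev(c(0.5, k + 0.5))
  graphics::plot(est, seq_len(k), xlim = range(c(ci, 0)), ylim = ylim,
                 yaxt = "n", xlab = "indirect effect (a*b)", ylab = "",
                 pch = ifelse(x$relevant[idx], 19, 1),
                 main = paste("Indirect effects:", x$focal_type), ...)
  graphics::segments(ci[, 1], seq_len(k), ci[, 2], seq_len(k))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = sub("^M\\d_", "", mn),
                 las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Tidy effect table of a fit
#'
#' One row per effect with estimate, interval bounds and relevance flag;
#' the layout written by the pipeline's per-type CSV output.
#'
#' @param fit a `"gcmm"` fit.
#' @return A data frame with columns `focal_type`, `effect`, `estimate`,
#'   `lower`, `upper`, `relevant`.
#' @export
effect_table <- function(fit) {
  stopifnot(inherits(fit, "gcmm"))
  cbind(focal_type = fit$focal_type, summary(fit)$table)
}
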