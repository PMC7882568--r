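#' Assemble a mediation fit from reported effect estimates
#'
#' Builds a minimal `"gcmm"` object from given indirect-effect
#' estimates and interval bounds, so the profile rule can be applied to
#' effect tables reported elsewhere (published model output, external
#' software) without refitting.
#'
#' @param indirect named (or length-6) vector of indirect-effect
#'   estimates in mediator order M1-M6.
#' @param lower,upper interval bounds per effect.
#' @param type_id label for the game type.
#' @param ci_level nominal level of the supplied intervals.
#' @return A `"gcmm"` object carrying the indirect effects only.
#' @export
fit_from_effects <- function(indirect, lower, upper,
                             type_id = "external", ci_level = 0.95) {
  mn <- mediator_names()
  if (length(indirect) != 6 || length(lower) != 6 || length(upper) != 6)
    stop("need six indirect effects with interval bounds", call. = FALSE)
  if (any(lower > upper))
    stop("lower bounds must not exceed upper bounds", call. = FALSE)
  en <- effect_names()
  est <- stats::setNames(rep(NA_real_, length(en)), en)
  ci <- matrix(NA_real_, length(en), 2,
               dimnames = list(en, c("lower", "upper")))
  idx <- paste0("indirect_", mn)
  est[idx] <- indirect
  ci[idx, "lower"] <- lower
  ci[idx, "upper"] <- upper
  relevant <- ci[, "lower"] > 0 | ci[, "upper"] < 0
  structure(list(focal_type = type_id, estimates = est, ci = ci,
                 relevant = relevant,
                 indirect = stats::setNames(as.numeric(indirect), mn),
                 n = NA_integer_, B = NA_integer_, ci_level = ci_level),
            class = "gcmm")
}

#' Dominant-mediator profile of one game type
#'
#' Implements the descriptive profile rule: among the six indirect
#' effects of a fitted mediation model, keep those that are both
#' statistically relevant (percentile interval excluding zero) and
#' positive (problem-increasing); rank them by their unrounded point
#' estimates; the largest is the *dominant* mediator. When at least two
#' such effects exist, the dominance ratio is largest / second-largest;
#' a ratio below the threshold marks the profile *equivocal*. With no
#' relevant positive effect the profile is `none_relevant`. Ties are
#' broken by the fixed mediator order M1-M6.
#'
#' @param fit a `"gcmm"` fit with bootstrap intervals.
#' @param threshold dominance-ratio threshold (default 2: the published
#'   distinct profiles had ratios of 2.20-3.96 against a single
#'   equivocal 1.64).
#' @return A list of class `"gcmm_profile"`: `type_id`,
#'   `relevant_positive` (data frame, descending), `dominant`,
#'   `dominance_ratio` (`NA` when fewer than two relevant positive
#'   effects), `profile` in `breadth_dominant`,
#'   `frequency_within_dominant`, `other_dominant`, `equivocal`,
#'   `none_relevant`.
#' @export
classify_profile <- function(fit, threshold = 2.0) {
  stopifnot(inherits(fit, "gcmm"))
  if (is.null(fit$ci))
    stop("fit has no bootstrap intervals; refit with B > 0", call. = FALSE)
  mn <- mediator_names()
  idx <- paste0("indirect_", mn)
  est <- fit$estimates[idx]
  rel <- fit$relevant[idx]
  keep <- which(rel & est > 0)
  ord <- keep[order(-est[keep], keep)]   # ties: fixed M1..M6 order
  rp <- data.frame(mediator = mn[ord], estimate = unname(est[ord]),
                   row.names = NULL)
  dominant <- if (nrow(rp)) rp$mediator[1] else NA_character_
  ratio <- if (nrow(rp) >= 2) rp$estimate[1] / rp$estimate[2] else NA_real_
  profile <- if (!nrow(rp)) "none_relevant"
    else if (!is.na(ratio) && ratio < threshold) "equivocal"
    else switch(dominant,
                M2_breadth = "breadth_dominant",
                M3_freq_within = "frequency_within_dominant",
                "other_dominant")
  structure(list(type_id = fit$focal_type, relevant_positive = rp,
                 dominant = dominant, dominance_ratio = ratio,
                 profile = profile, threshold = threshold),
            class = "gcmm_profile")
}

#' @export
print.gcmm_profile <- function(x, ...) {
  cat(sprintf("%s: %s", x$type_id, x$profile))
  if (!is.na(x$dominant))
    cat(sprintf(" (dominant %s%s)", x$dominant,
                if (!is.na(x$dominance_ratio))
                  sprintf(", ratio %.2f", x$dominance_ratio) else ""))
  cat("\n")
  invisible(x)
}

#' Tabulate mediator profiles over game types
#'
#' @param profiles list of `"gcmm_profile"` results (e.g. from
#'   classifying every fit of a [gcmm_all()] run).
#' @return A list of class `"gcmm_profile_summary"`: `counts` (named
#'   integer vector per profile label), `members` (type lists per
#'   label), `table` (tidy data frame: type, dominant mediator, ratio,
#'   label).
#' @export
summarize_profiles <- function(profiles) {
  labels <- c("breadth_dominant", "frequency_within_dominant",
              "other_dominant", "equivocal", "none_relevant")
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(type_id = p$type_id, dominant = p$dominant,
               dominance_ratio = p$dominance_ratio, profile = p$profile,
               row.names = NULL)))
  if (is.null(tab))
    tab <- data.frame(type_id = character(), dominant = character(),
                      dominance_ratio = numeric(), profile = character())
  counts <- vapply(labels, function(l) sum(tab$profile == l), 0L)
  members <- lapply(labels, function(l) tab$type_id[tab$profile == l])
  names(members) <- labels
  structure(list(counts = counts, members = members, table = tab),
            class = "gcmm_profile_summary")
}

#' @export
print.gcmm_profile_summary <- function(x, ...) {
  cat("Dominant-mediator profiles:\n")
  for (l in names(x$counts)) {
    if (x$counts[[l]] == 0) next
    cat(sprintf("  %-26s %2d : %s\n", l, x$counts[[l]],
                paste(x$members[[l]], collapse = ", ")))
  }
  invisible(x)
}
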