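#' Participation-by-year contingency test
#'
#' Asymptotic chi-square test (no continuity correction) of the
#' participant yes/no by survey-year table for one game type, with
#' Cramer's V as effect size, `V = sqrt(chi2 / (N * min(r-1, c-1)))`.
#' Expected cells below 5 raise a `sparse_flag`; a Monte-Carlo exact p
#' can be requested for such tables.
#'
#' @param table a `"gcmm_survey"` with at least two survey years.
#' @param type_id catalog `type_id` of the game type.
#' @param exact also compute a Monte-Carlo exact p-value (resampled
#'   tables with fixed margins).
#' @return A list of class `"gcmm_contingency"`: `type_id`, `counts`
#'   (participants per year), `totals`, `chi2`, `df`, `p`, `cramers_v`,
#'   `min_expected_cell`, `sparse_flag`, optionally `p_exact`.
#' @export
participation_table <- function(table, type_id, exact = FALSE) {
  stopifnot(inherits(table, "gcmm_survey"))
  catalog <- attr(table, "catalog")
  i <- match(type_id, catalog$type_id)
  if (is.na(i)) stop("unknown type_id: ", type_id, call. = FALSE)
  years <- sort(unique(table$year))
  if (length(years) < 2)
    stop("need at least two survey years", call. = FALSE)
  freq <- table[[catalog$freq_column[i]]]
  part <- derive_participation(freq)
  totals <- as.vector(table(factor(table$year, levels = years)))
  if (any(totals == 0))
    stop("survey year with zero respondents", call. = FALSE)
  counts <- vapply(years, function(y) sum(part[table$year == y]), 0L)
  contingency_from_counts(counts, totals, type_id = type_id,
                          years = years, exact = exact)
}

#' Contingency statistics from printed counts
#'
#' Same computation as [participation_table()], but fed directly with
#' per-year participant counts and year totals — the form in which
#' published cohort tables report participation.
#'
#' @param counts participants per year.
#' @param totals respondents per year.
#' @param type_id,years labels carried through.
#' @param exact see [participation_table()].
#' @return A `"gcmm_contingency"`; see [participation_table()].
#' @export
contingency_from_counts <- function(counts, totals, type_id = NA_character_,
                                    years = seq_along(counts),
                                    exact = FALSE) {
  if (length(counts) != length(totals) || length(counts) < 2)
    stop("counts and totals must align over >= 2 years", call. = FALSE)
  if (any(counts < 0) || any(counts > totals))
    stop("counts must lie in [0, totals]", call. = FALSE)
  m <- rbind(yes = counts, no = totals - counts)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  N <- sum(m)
  chi2 <- unname(ct$statistic)
  v <- sqrt(chi2 / (N * min(dim(m) - 1L)))
  min_exp <- min(ct$expected)
  res <- list(type_id = type_id, years = years, counts = counts,
              totals = totals, rates = counts / totals,
              chi2 = chi2, df = unname(ct$parameter),
              p = unname(ct$p.value), cramers_v = v,
              min_expected_cell = min_exp,
              sparse_flag = min_exp < 5)
  if (exact)
    res$p_exact <- suppressWarnings(
      stats::chisq.test(m, simulate.p.value = TRUE, B = 10000)$p.value)
  structure(res, class = "gcmm_contingency")
}

#' @export
print.gcmm_contingency <- function(x, ...) {
  cat(sprintf("%s: chi2(%d) = %.3f, p = %.3g, Cramer's V = %.3f%s\n",
              if (is.na(x$type_id)) "contingency" else x$type_id,
              x$df, x$chi2, x$p, x$cramers_v,
              if (x$sparse_flag) "  [sparse cells]" else ""))
  invisible(x)
}

#' Kruskal-Wallis comparison across survey years
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p-value and the
#' effect size `eta^2 = (H - k + 1) / (n - k)`. Identical values in
#' every group give H = 0 (not an error).
#'
#' @param values numeric vector (ties allowed).
#' @param years group labels, at least two non-empty groups.
#' @param variable name carried through.
#' @return A list of class `"gcmm_kruskal"`: `variable`, `H`, `df`, `p`,
#'   `eta_squared`, `n`, `k`.
#' @export
kruskal_by_year <- function(values, years, variable = "value") {
  g <- factor(years)
  if (nlevels(g) < 2 || any(table(g) == 0))
    stop("need >= 2 non-empty groups", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; g <- droplevels(g[keep])
  n <- length(values); k <- nlevels(g)
  if (length(unique(values)) < 2) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, g)
    H <- unname(kt$statistic); p <- unname(kt$p.value)
  }
  structure(list(variable = variable, H = H, df = k - 1L, p = p,
                 eta_squared = (H - k + 1) / (n - k), n = n, k = k),
            class = "gcmm_kruskal")
}

#' @export
print.gcmm_kruskal <- function(x, ...) {
  cat(sprintf("%s: Kruskal-Wallis H(%d) = %.3f, p = %.3g, eta^2 = %.4f\n",
              x$variable, x$df, x$H, x$p, x$eta_squared))
  invisible(x)
}

#' Participation growth ratios between first and last survey
#'
#' Per-type ratio of the last-year over the first-year participation
#' rate, with unweighted group means for offline and online game types.
#' Types with a zero first-year rate are excluded with a warning.
#'
#' @param results list of `"gcmm_contingency"` results (one per type).
#' @param catalog a [gcmm_catalog()] supplying each type's mode.
#' @return A list of class `"gcmm_growth"`: per-type data frame
#'   (`type_id`, `mode`, `rate_first`, `rate_last`, `ratio`) and
#'   `mean_ratio` named by mode group.
#' @export
growth_ratios <- function(results, catalog = default_catalog()) {
  check_catalog(catalog)
  rows <- lapply(results, function(r) {
    data.frame(type_id = r$type_id,
               rate_first = r$rates[1],
               rate_last = r$rates[length(r$rates)])
  })
  df <- do.call(rbind, rows)
  df$mode <- catalog$mode[match(df$type_id, catalog$type_id)]
  df$ratio <- ifelse(df$rate_first > 0, df$rate_last / df$rate_first,
                     NA_real_)
  if (anyNA(df$ratio))
    warning("zero first-year rate; ratio undefined for: ",
            paste(df$type_id[is.na(df$ratio)], collapse = ", "))
  mean_ratio <- tapply(df$ratio, df$mode, mean, na.rm = TRUE)
  structure(list(per_type = df[, c("type_id", "mode", "rate_first",
                                   "rate_last", "ratio")],
                 mean_ratio = mean_ratio),
            class = "gcmm_growth")
}

#' @export
print.gcmm_growth <- function(x, ...) {
  cat("Participation growth (last survey / first survey):\n")
  for (m in names(x$mean_ratio))
    cat(sprintf("  mean ratio, %s types: %.2f\n", m, x$mean_ratio[[m]]))
  invisible(x)
}

#' PGSI severity-group distribution
#'
#' Counts and fractions of the four PGSI groups among last-year
#' gamblers.
#'
#' @param table a `"gcmm_survey"` of last-year gamblers, or an integer
#'   vector of PGSI scores.
#' @return Data frame with `group`, `count`, `fraction`.
#' @export
group_distribution <- function(table) {
  scores <- if (inherits(table, "gcmm_survey")) table$pgsi_raw else table
  g <- pgsi_group(scores)
  tab <- table(g)
  data.frame(group = names(tab), count = as.vector(tab),
             fraction = as.vector(tab) / length(g))
}

#' Published per-year participation counts
#'
#' The participant counts per survey year (2007, 2011, 2017; year
#' totals 1398, 1264, 1760 last-year gamblers) for the 15 game types of
#' the Icelandic cohort table; usable as direct input to
#' [contingency_from_counts()] and [growth_ratios()].
#'
#' @return Data frame with `type_id` and one count column per year,
#'   plus attribute `"totals"`.
#' @export
iceland_participation_counts <- function() {
  df <- data.frame(
    type_id = default_catalog()$type_id,
    y2007 = c(1057, 121, 210, 428, 107, 30, 49, 21, 11, 3, 104, 4, 44, 125, 7),
    y2011 = c(1003, 133, 163, 383, 98, 47, 53, 37, 10, 15, 196, 41, 40, 192, 17),
    y2017 = c(1197, 344, 181, 576, 101, 92, 49, 66, 81, 94, 169, 36, 27, 371, 38)
  )
  attr(df, "totals") <- c(y2007 = 1398, y2011 = 1264, y2017 = 1760)
  df
}
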