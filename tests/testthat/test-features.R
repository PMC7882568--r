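test_that("winsorization clamps to the interpolated percentiles", {
  expect_equal(winsorize(c(5, 5, 5, 5), 1, 99), c(5, 5, 5, 5))
  # the published PGSI treatment: everything above the cap collapses to it
  pgsi <- c(rep(0, 90), rep(2, 7), 6, 12, 27)
  w <- winsorize(pgsi, 0, 97)
  expect_true(all(w <= quantile(pgsi, 0.97, type = 7)))
  set.seed(1)
  for (r in 1:20) {
    x <- runif(1000)
    w <- winsorize(x, 1, 99)
    expect_equal(min(w), oracle_percentile(x, 0.01))
    expect_equal(max(w), oracle_percentile(x, 0.99))
    expect_equal(w, oracle_winsorize(x, 1, 99))
  }
})

test_that("winsorization is idempotent, monotone and NA-preserving", {
  set.seed(2)
  # with 101 observations the 1st/99th interpolated percentiles land on
  # exact order statistics, so re-winsorizing is an exact no-op
  x1 <- rlnorm(101, 5, 1)
  w1 <- winsorize(x1, 1, 99)
  expect_identical(winsorize(w1, 1, 99), w1)
  # in general the cut points move only within the clamped tail mass
  x <- c(rlnorm(500, 5, 1), NA, NA)
  w <- winsorize(x, 1, 99)
  expect_equal(winsorize(w, 1, 99), w, tolerance = 1e-2)
  expect_identical(is.na(w), is.na(x))
  ord <- order(x[!is.na(x)])
  expect_true(all(diff(w[!is.na(w)][ord]) >= 0))
  expect_error(winsorize(c(NA_real_, NA_real_)), "all values missing")
  expect_error(winsorize(1:10, 99, 1), "lower_pct")
})

test_that("participation derivation treats missing as never played", {
  expect_equal(derive_participation(c(0, 1, 5, NA)), c(0L, 1L, 1L, 0L))
})

test_that("breadth is the capped count of played types", {
  one <- matrix(c(1, rep(0, 14)), nrow = 1)
  expect_equal(compute_breadth(one, 7), 1L)
  many <- matrix(c(rep(1, 10), rep(0, 5)), nrow = 1)
  expect_equal(compute_breadth(many, 7), 7L)
  set.seed(3)
  for (r in 1:20) {
    m <- matrix(rbinom(15 * 40, 1, 0.3), ncol = 15)
    expect_equal(compute_breadth(m, 7), as.integer(oracle_breadth(m, 7)))
  }
})

test_that("beyond-max aggregates over the 14 non-focal types", {
  v <- matrix(0, 1, 15); v[1, 3] <- 5
  expect_equal(beyond_max(v, 3), 0)     # plays only the focal type
  v[1, 9] <- 4
  expect_equal(beyond_max(v, 3), 4)
  set.seed(4)
  for (r in 1:20) {
    m <- matrix(sample(0:5, 15 * 30, replace = TRUE), nrow = 30)
    focal <- sample(15, 1)
    expect_equal(beyond_max(m, focal), oracle_beyond_max(m, focal))
  }
  expect_error(beyond_max(m, 99), "focal")
})

test_that("PGSI groups follow the published cut points", {
  expect_equal(as.character(pgsi_group(c(0, 1, 4, 5, 7, 8, 27))),
               c("no_problem", "low_risk", "low_risk", "moderate_risk",
                 "moderate_risk", "problem", "problem"))
  expect_error(pgsi_group(-1), "0, 27")
  expect_error(pgsi_group(28), "0, 27")
})

test_that("propensity model recovers a null and imputes mean scores", {
  # outcome independent of demographics: all odds ratios near 1
  rs <- make_random_survey(n = 4000, p_gambler = 1, seed = 5)
  tab <- rs$table
  set.seed(6)
  tab$pgsi_raw <- ifelse(runif(nrow(tab)) < 0.05, 6L, 0L)
  pm <- fit_propensity(tab, threshold = 5)
  expect_true(all(abs(log(pm$odds_ratios[c("male", "single")])) < 0.4))
  expect_true(all(pm$score > 0 & pm$score < 1))
  # rows with missing demographics get the mean score of the rest
  tab2 <- inject_missing(tab, list(demographics = 0.0294), seed = 7)
  pm2 <- fit_propensity(tab2, threshold = 5)
  miss <- !complete.cases(as.data.frame(tab2)[, c("gender", "age",
                                                  "education", "partnered")])
  expect_equal(pm2$n_missing_imputed, sum(miss))
  expect_true(all(pm2$score[miss] == mean(pm2$score[!miss])))
  # single-class outcome is an error
  tab$pgsi_raw <- 0L
  expect_error(fit_propensity(tab, 5), "single class")
})

test_that("feature sets follow the derivation chain on known rows", {
  cat <- default_catalog()
  df <- make_survey_df(80, seed = 8)
  # respondent 1 plays only the focal type weekly, spending 100
  df[1, "freq_egm_off"] <- 3L
  df[1, "spend_egm_off"] <- 100
  # enough other gamblers, with outcome events spread over the
  # demographic cells, for a stable propensity fit
  df[2:70, "freq_lotto_off"] <- 1L
  df$pgsi_raw[c(2, 9, 17, 25, 33, 41, 49, 57)] <- 6L
  df$pgsi_raw[3:5] <- 2L
  tab <- filter_last_year_gamblers(as_survey(df, cat))
  fs <- build_featureset(tab, "egm_off", gcmm_config(bootstrap_B = 10))
  expect_equal(fs$X[1], 1L)
  expect_equal(fs$M3_freq_within[1], 3)
  expect_equal(fs$M4_freq_beyond[1], 0)
  expect_equal(fs$M6_spend_beyond[1], 0)
  expect_equal(fs$M2_breadth[1], 1L)
  # nobody plays scratch cards: X, M3, M5 identically zero
  fs2 <- build_featureset(tab, "scratch_off")
  expect_true(all(fs2$X == 0) && all(fs2$M3_freq_within == 0) &&
                all(fs2$M5_spend_within == 0))
})

test_that("alternative beyond-aggregations and score scales are wired", {
  sim <- simulate_survey(gcmm_sim_params(n_per_year = c(150, 150, 150),
                                         rng_seed = 22))
  gam <- filter_last_year_gamblers(sim$table)
  cat <- default_catalog()
  i <- match("lotto_off", cat$type_id)
  fm <- as.matrix(as.data.frame(gam)[, cat$freq_column]); fm[is.na(fm)] <- 0
  fs_mean <- build_featureset(gam, "lotto_off",
                              gcmm_config(beyond_aggregate = "mean"))
  expect_equal(fs_mean$M4_freq_beyond, unname(rowMeans(fm[, -i])))
  fs_med <- build_featureset(gam, "lotto_off",
                             gcmm_config(beyond_aggregate = "median"))
  expect_equal(fs_med$M4_freq_beyond, unname(apply(fm[, -i], 1, median)))
  # propensity score on the linear-predictor scale is the logit of the
  # probability-scale score for scored (complete-case) respondents
  p_resp <- fit_propensity(gam, 5, scale = "response")
  p_link <- fit_propensity(gam, 5, scale = "link")
  cc <- complete.cases(as.data.frame(gam)[, c("gender", "age",
                                              "education", "partnered")])
  expect_equal(p_link$score[cc], qlogis(p_resp$score[cc]),
               tolerance = 1e-10)
  # tidy export round-trips
  path <- withr::local_tempfile(fileext = ".csv")
  write_featureset(fs_mean, path)
  back <- utils::read.csv(path)
  expect_equal(back$M2_breadth, fs_mean$M2_breadth)
  expect_named(back, c("X", paste0("M", 1:6, c("_propensity", "_breadth",
                                               "_freq_within", "_freq_beyond",
                                               "_spend_within", "_spend_beyond")),
                       "Y"))
})

test_that("feature-set invariants hold on synthetic data", {
  sim <- simulate_survey(gcmm_sim_params(n_per_year = c(300, 300, 300),
                                         rng_seed = 12))
  gam <- filter_last_year_gamblers(sim$table)
  cfg <- gcmm_config()
  fs <- build_featureset(gam, "lotto_off", cfg)
  expect_false(anyNA(fs))
  expect_equal(fs$X == 1, fs$M3_freq_within >= 1)
  expect_true(all(fs$M2_breadth >= 1 & fs$M2_breadth <= 7))
  expect_true(all(fs$Y <= cfg$pgsi_cap))

  # M4/M6 are invariant to randomizing the focal type's own columns
  # (same rows, focal frequency permuted and focal spending rewritten)
  gam2 <- gam
  set.seed(13)
  gam2$freq_lotto_off <- sample(gam2$freq_lotto_off)
  gam2$spend_lotto_off <- round(runif(nrow(gam2), 0, 5000))
  fs3 <- build_featureset(gam2, "lotto_off", cfg)
  expect_equal(fs3$M4_freq_beyond, fs$M4_freq_beyond)
  expect_equal(fs3$M6_spend_beyond, fs$M6_spend_beyond)

  # row-level spot check against manual recomputation
  df <- as.data.frame(gam)
  cat <- default_catalog()
  fm <- as.matrix(df[, cat$freq_column]); fm[is.na(fm)] <- 0
  sm <- as.matrix(df[, cat$spend_column]); sm[is.na(sm)] <- 0
  smw <- apply(sm, 2, oracle_winsorize, lower_pct = 1, upper_pct = 99)
  i <- match("lotto_off", cat$type_id)
  set.seed(14)
  for (row in sample(nrow(df), 5)) {
    expect_equal(fs$M2_breadth[row], min(sum(fm[row, ] >= 1), 7))
    expect_equal(fs$M4_freq_beyond[row], max(fm[row, -i]))
    expect_equal(fs$M5_spend_within[row], unname(smw[row, i]))
    expect_equal(fs$M6_spend_beyond[row], max(smw[row, -i]))
  }
})
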