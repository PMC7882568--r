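test_that("OLS solver matches the normal equations and flags collinearity", {
  set.seed(1)
  X <- cbind(1, matrix(rnorm(8 * 2), 8, 2))
  colnames(X) <- c("(Intercept)", "p1", "p2")
  y <- X[, 2]
  cf <- ols_fit(y, X)
  expect_equal(unname(cf), c(0, 1, 0), tolerance = 1e-12)
  y2 <- rnorm(8)
  expect_equal(unname(ols_fit(y2, X)), unname(oracle_ols(y2, X)),
               tolerance = 1e-10)
  expect_equal(unname(ols_fit(rep(3, 8), X))[-1], c(0, 0), tolerance = 1e-12)
  Xc <- cbind(X, p3 = X[, "p1"])
  expect_error(ols_fit(y2, Xc), "rank deficient.*p3")
  expect_error(ols_fit(rnorm(2), X[1:2, ]), "fewer rows")
})

test_that("a constructed identity path is recovered exactly", {
  set.seed(2)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  # M3 tracks X up to a sliver of noise (exact equality would make the
  # outcome design singular); Y is exactly M3, so b3 = 1 and c' = 0
  m3 <- x + 1e-3 * rnorm(n)
  fs <- data.frame(X = x,
                   M1_propensity = rnorm(n), M2_breadth = rnorm(n),
                   M3_freq_within = m3, M4_freq_beyond = rnorm(n),
                   M5_spend_within = rnorm(n), M6_spend_beyond = rnorm(n))
  fs$Y <- fs$M3_freq_within
  fs <- structure(fs, focal_type = "t",
                  class = c("gcmm_features", "data.frame"))
  fit <- gcmm(fs, B = 0)
  expect_equal(unname(fit$a["M3_freq_within"]), 1, tolerance = 1e-2)
  expect_equal(unname(fit$b["M3_freq_within"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$indirect["M3_freq_within"]),
               unname(fit$a["M3_freq_within"]), tolerance = 1e-10)
  expect_equal(fit$c_prime, 0, tolerance = 1e-10)
})

test_that("permuting X against everything else nulls all effects", {
  fs <- make_features(n = 3000, seed = 3,
                      fx = function(x, e) 2 * e)
  set.seed(4)
  fs$X <- sample(fs$X)
  fs$M2_breadth <- 1 + rpois(nrow(fs), 1)          # break X links too
  fs$M3_freq_within <- sample(0:5, nrow(fs), TRUE)
  fs$M5_spend_within <- round(rlnorm(nrow(fs), 6, 1))
  fit <- gcmm(fs, B = 200, seed = 5)
  expect_true(all(abs(fit$indirect) < 0.15))
  expect_lt(abs(fit$total), 0.3)
})

test_that("the OLS decomposition identity holds on fits and resamples", {
  for (seed in 1:5) {
    fs <- make_features(n = 300, seed = seed,
                        fx = function(x, e) x + e)
    fit <- gcmm(fs, B = 200, seed = seed)
    expect_equal(fit$total, fit$c_prime + sum(fit$indirect),
                 tolerance = 1e-12)
    expect_equal(fit$total, fit$total_simple, tolerance = 1e-10)
    expect_lt(fit$decomp_max_err, 1e-10)   # max over all 200 resamples
    expect_equal(unname(fit$estimates[paste0("indirect_", names(fit$a))]),
                 unname(fit$a * fit$b), tolerance = 1e-14)
  }
})

test_that("effects and intervals are equivariant to rescaling Y", {
  fs <- make_features(n = 500, seed = 6, fx = function(x, e) x + e)
  f1 <- gcmm(fs, B = 300, seed = 7)
  fs$Y <- fs$Y * 10
  f2 <- gcmm(fs, B = 300, seed = 7)
  idx <- c(paste0("indirect_", names(f1$a)), "c_prime", "total")
  expect_equal(f2$estimates[idx], 10 * f1$estimates[idx], tolerance = 1e-10)
  expect_equal(f2$ci[idx, ], 10 * f1$ci[idx, ], tolerance = 1e-10)
  expect_identical(f2$relevant, f1$relevant)
  p1 <- classify_profile(f1); p2 <- classify_profile(f2)
  expect_equal(p2$dominance_ratio, p1$dominance_ratio, tolerance = 1e-10)
  expect_identical(p2$profile, p1$profile)
})

test_that("bootstrap intervals are deterministic given the seed", {
  fs <- make_features(n = 200, seed = 8, fx = function(x, e) x + e)
  f1 <- gcmm(fs, B = 150, seed = 42)
  f2 <- gcmm(fs, B = 150, seed = 42)
  expect_identical(f1$ci, f2$ci)
  f3 <- gcmm(fs, B = 150, seed = 43)
  expect_false(identical(f1$ci, f3$ci))
})

test_that("a constant outcome collapses slope intervals to zero", {
  fs <- make_features(n = 120, seed = 9, fx = function(x, e) 0 * e)
  fit <- gcmm(fs, B = 100, seed = 1)
  idx <- c(paste0("b_", names(fit$a)), paste0("indirect_", names(fit$a)),
           "c_prime", "total")
  expect_true(all(abs(fit$ci[idx, ]) < 1e-12))
  expect_true(all(abs(fit$estimates[idx]) < 1e-12))
})

test_that("engine agrees with an independent reference implementation", {
  fs <- make_features(n = 50, seed = 10, fx = function(x, e) x + e)
  B <- 200
  fit <- gcmm(fs, B = B, seed = 77)
  ref <- reference_mediation(as.data.frame(fs), B = B, ci_level = 0.95,
                             seed = 77)
  expect_equal(unname(fit$estimates), ref$est, tolerance = 1e-10)
  # matched resample sequences: identical intervals
  expect_equal(unname(fit$ci), ref$ci, tolerance = 1e-10)
})

test_that("interval width shrinks roughly like 1/sqrt(n)", {
  width <- function(n) {
    fs <- make_features(n = n, seed = 11,
                        fx = function(x, e) x + e)
    fit <- gcmm(fs, B = 400, seed = 12)
    ci <- fit$ci["indirect_M2_breadth", ]
    unname(diff(ci))
  }
  r <- width(400) / width(6400)
  expect_gt(r, 2.2)   # expected factor 4, generous Monte-Carlo band
  expect_lt(r, 7)
})

test_that("degenerate designs raise informative errors", {
  fs <- make_features(n = 100, seed = 13, fx = function(x, e) e)
  fs$X <- 1L
  expect_error(gcmm(fs, B = 0), "constant")
  fs <- make_features(n = 100, seed = 14, fx = function(x, e) e)
  fs$M4_freq_beyond <- 2
  expect_error(gcmm(fs, B = 0), "constant mediator.*M4_freq_beyond")
})

test_that("per-type runs cover the catalog and collect failures", {
  sim <- simulate_survey(gcmm_sim_params(n_per_year = c(250, 250, 250),
                                         rng_seed = 15))
  gam <- filter_last_year_gamblers(sim$table)
  cfg <- gcmm_config()
  fits <- gcmm_all(gam, cfg, B = 30, seed = 1)
  expect_lte(length(fits) + length(attr(fits, "failures")), 15)
  expect_gte(length(fits), 10)
  two <- gcmm_all(gam, cfg, types = c("lotto_off", "scratch_off"),
                  B = 30, seed = 1)
  expect_named(two, c("lotto_off", "scratch_off"))
  # a type nobody plays fails without stopping the run
  gam2 <- gam
  gam2$freq_bingo_off[] <- 0L
  res <- gcmm_all(gam2, cfg, types = c("lotto_off", "bingo_off"),
                  B = 30, seed = 1)
  expect_named(res, "lotto_off")
  expect_match(attr(res, "failures")[["bingo_off"]], "constant")
  # same master seed reproduces every interval
  again <- gcmm_all(gam, cfg, types = "lotto_off", B = 30, seed = 1)
  expect_identical(again$lotto_off$ci, two$lotto_off$ci)
  # Bonferroni option widens the intervals per the number of types
  ts <- c("lotto_off", "scratch_off")
  bonf <- gcmm_all(gam, cfg, types = ts, B = 200, seed = 1,
                   bonferroni = TRUE)
  plain <- gcmm_all(gam, cfg, types = ts, B = 200, seed = 1)
  idx <- "indirect_M2_breadth"
  expect_gt(diff(bonf$lotto_off$ci[idx, ]), diff(plain$lotto_off$ci[idx, ]))
  expect_equal(bonf$lotto_off$ci_level, 1 - 0.05 / 2)
})
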