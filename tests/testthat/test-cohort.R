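test_that("contingency statistics match a brute-force oracle", {
  set.seed(1)
  for (r in 1:100) {
    k <- sample(2:4, 1)
    totals <- sample(50:300, k)
    counts <- rbinom(k, totals, runif(1, 0.05, 0.9))
    counts <- pmax(counts, 1)            # keep both rows populated
    res <- contingency_from_counts(counts, totals)
    m <- rbind(counts, totals - counts)
    expect_equal(res$chi2, oracle_chi2(m), tolerance = 1e-10)
    expect_equal(res$cramers_v, oracle_cramers_v(m), tolerance = 1e-10)
    expect_equal(res$df, k - 1)
  }
})

test_that("Cramer's V is invariant to swapping the yes/no rows", {
  totals <- c(1398, 1264, 1760)
  counts <- c(210, 163, 181)
  a <- contingency_from_counts(counts, totals)
  b <- contingency_from_counts(totals - counts, totals)
  expect_equal(a$cramers_v, b$cramers_v, tolerance = 1e-12)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
})

test_that("equal participation across years gives a null chi-square", {
  res <- contingency_from_counts(c(50, 100, 150), c(100, 200, 300))
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$cramers_v, 0, tolerance = 1e-12)
})

test_that("participation tables are built correctly from a survey", {
  rs <- make_random_survey(n = 600, p_gambler = 0.7, seed = 2)
  gam <- filter_last_year_gamblers(rs$table)
  res <- participation_table(gam, "lotto_off")
  cat <- default_catalog()
  for (j in seq_along(res$years)) {
    sub <- gam[gam$year == res$years[j], ]
    expect_equal(res$counts[j],
                 sum(derive_participation(sub[[cat$freq_column[1]]])))
  }
  one_year <- gam[gam$year == 2007, ]
  expect_error(participation_table(one_year, "lotto_off"), "two survey years")
  expect_error(participation_table(gam, "nope"), "unknown type_id")
})

test_that("Kruskal-Wallis H matches a hand-computed tie-corrected oracle", {
  # identical distributions across groups
  v <- rep(c(1, 2, 2, 3), 3)
  g <- rep(1:3, each = 4)
  expect_equal(kruskal_by_year(v, g)$H, 0, tolerance = 1e-12)
  # identical values everywhere: H = 0 by convention, not an error
  expect_equal(kruskal_by_year(rep(5, 9), rep(1:3, 3))$H, 0)
  set.seed(3)
  for (r in 1:100) {
    k <- sample(2:4, 1)
    g <- rep(seq_len(k), times = sample(5:15, k, replace = TRUE))
    v <- sample(0:6, length(g), replace = TRUE)   # plenty of ties
    if (length(unique(v)) < 2) next
    res <- kruskal_by_year(v, g)
    expect_equal(res$H, oracle_kruskal_H(v, g), tolerance = 1e-10)
    expect_equal(res$eta_squared,
                 (res$H - k + 1) / (length(v) - k), tolerance = 1e-12)
  }
})

test_that("Kruskal H is invariant under strictly monotone transforms", {
  set.seed(4)
  g <- rep(1:3, each = 40)
  v <- rpois(120, 3)
  h1 <- kruskal_by_year(v, g)$H
  expect_equal(kruskal_by_year(exp(v), g)$H, h1, tolerance = 1e-12)
  expect_equal(kruskal_by_year(rank(v), g)$H, h1, tolerance = 1e-12)
})

test_that("eta-squared grows with group separation", {
  set.seed(5)
  eta <- vapply(c(0, 0.5, 1, 2), function(shift) {
    g <- rep(1:3, each = 400)
    v <- rnorm(1200) + shift * (g - 1)
    kruskal_by_year(v, g)$eta_squared
  }, 0)
  expect_true(all(diff(eta) > 0))
})

test_that("growth ratios average per mode and handle zero baselines", {
  counts <- iceland_participation_counts()
  totals <- attr(counts, "totals")
  res <- lapply(seq_len(nrow(counts)), function(i)
    contingency_from_counts(unlist(counts[i, -1]), totals,
                            type_id = counts$type_id[i]))
  g <- growth_ratios(res)
  expect_equal(g$per_type$ratio,
               g$per_type$rate_last / g$per_type$rate_first,
               tolerance = 1e-12)
  # invariant to catalog ordering
  g2 <- growth_ratios(rev(res))
  expect_equal(g2$mean_ratio, g$mean_ratio, tolerance = 1e-12)
  # zero baseline excluded with a warning
  res0 <- c(res[1:2], list(contingency_from_counts(c(0, 5, 9), totals,
                                                   type_id = "egm_off")))
  expect_warning(g0 <- growth_ratios(res0), "zero first-year")
  expect_true(is.na(g0$per_type$ratio[g0$per_type$type_id == "egm_off"]))
})

test_that("identical rates in both years give ratio one", {
  res <- contingency_from_counts(c(30, 40, 60), c(100, 133, 200))
  g <- growth_ratios(list(res), gcmm_catalog("x", mode = "offline",
                                             freq_column = "f",
                                             spend_column = "s"))
  expect_equal(g$per_type$ratio, (60 / 200) / (30 / 100), tolerance = 1e-12)
})

test_that("PGSI group distribution matches a brute-force recount", {
  scores <- c(rep(0, 50), rep(2, 10), rep(6, 3), rep(9, 2))
  gd <- group_distribution(scores)
  expect_equal(gd$count, c(50, 10, 3, 2))
  expect_equal(gd$fraction, c(50, 10, 3, 2) / 65)
  gd0 <- group_distribution(rep(0L, 10))
  expect_equal(gd0$fraction, c(1, 0, 0, 0))
  rs <- make_random_survey(n = 300, seed = 6)
  gam <- filter_last_year_gamblers(rs$table)
  gd2 <- group_distribution(gam)
  expect_equal(gd2$count[1], sum(gam$pgsi_raw == 0))
  expect_equal(gd2$count[4], sum(gam$pgsi_raw >= 8))
})
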