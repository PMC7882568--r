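# Fixture builders: small surveys and feature sets constructed in code.

# a minimal valid survey data frame; freq/spend defaults are all-zero
make_survey_df <- function(n = 6, catalog = default_catalog(), seed = 1) {
  set.seed(seed)
  df <- data.frame(
    year = rep(c(2007, 2011, 2017), length.out = n),
    gender = sample(c("male", "female"), n, replace = TRUE),
    age = sample(18:70, n, replace = TRUE),
    education = sample(1:3, n, replace = TRUE),
    partnered = sample(0:1, n, replace = TRUE),
    pgsi_raw = 0L,
    stringsAsFactors = FALSE
  )
  for (col in catalog$freq_column) df[[col]] <- 0L
  for (col in catalog$spend_column) df[[col]] <- 0
  df
}

# a randomly filled valid survey with a known set of gambler rows
make_random_survey <- function(n = 200, p_gambler = 0.6, seed = 1,
                               catalog = default_catalog()) {
  set.seed(seed)
  df <- make_survey_df(n, catalog, seed = seed)
  gambler <- runif(n) < p_gambler
  for (i in which(gambler)) {
    k <- sample(1:4, 1)
    cols <- sample(nrow(catalog), k)
    df[i, catalog$freq_column[cols]] <- sample(1:5, k, replace = TRUE)
    df[i, catalog$spend_column[cols]] <- round(rlnorm(k, log(500), 1))
  }
  df$pgsi_raw <- ifelse(gambler, sample(0:8, n, replace = TRUE,
                                        prob = c(8, 4, 2, 1, 1, .5, .3, .2, .1)),
                        0L)
  list(df = df, gambler = gambler,
       table = as_survey(df, catalog))
}

# a feature set built directly (bypassing survey derivation) for
# mediation-engine tests with controlled structure
make_features <- function(n = 200, seed = 1,
                          fx = function(x, e) e) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  fs <- data.frame(
    X = x,
    M1_propensity = runif(n, 0.01, 0.2),
    M2_breadth = pmin(1 + rpois(n, 1) + x, 7),
    M3_freq_within = x * sample(1:5, n, replace = TRUE),
    M4_freq_beyond = sample(0:5, n, replace = TRUE),
    M5_spend_within = x * round(rlnorm(n, log(800), 0.8)),
    M6_spend_beyond = round(rlnorm(n, log(300), 1))
  )
  fs$Y <- fx(x, rnorm(n))
  structure(fs, focal_type = "test_type",
            class = c("gcmm_features", "data.frame"))
}

# independent reference implementation of the parallel mediation model
# with percentile bootstrap, written on lm()/normal equations and its
# own resampling loop (matched RNG protocol: sequential sample.int
# draws after set.seed)
reference_mediation <- function(fs, B, ci_level, seed) {
  mn <- grep("^M", names(fs), value = TRUE)
  point <- function(d) {
    a <- vapply(mn, function(m)
      coef(lm(d[[m]] ~ d$X))[2], 0)
    om <- lm(stats::reformulate(c("X", mn), "Y"), data = d)
    b <- coef(om)[mn]
    cp <- coef(om)["X"]
    ind <- a * b
    c(a, b, ind, cp, cp + sum(ind))
  }
  est <- point(fs)
  set.seed(seed)
  boot <- t(replicate(B, point(fs[sample.int(nrow(fs), replace = TRUE), ])))
  alpha <- 1 - ci_level
  ci <- t(apply(boot, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                type = 7, names = FALSE))
  list(est = unname(est), ci = unname(ci))
}
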