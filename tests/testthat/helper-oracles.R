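# Brute-force reference implementations, independent of the package's
# code paths; used to cross-check every statistic the package computes.

oracle_chi2 <- function(m) {
  N <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / N
  sum((m - E)^2 / E)
}

oracle_cramers_v <- function(m) {
  sqrt(oracle_chi2(m) / (sum(m) * min(dim(m) - 1)))
}

# tie-corrected Kruskal-Wallis H from first principles: mid-ranks,
# rank-sum statistic, tie correction factor
oracle_kruskal_H <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)             # mid-ranks for ties
  Rg <- tapply(r, groups, sum)
  ng <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# type-7 percentile by explicit sort-and-index interpolation
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_winsorize <- function(x, lower_pct, upper_pct) {
  obs <- x[!is.na(x)]
  lo <- oracle_percentile(obs, lower_pct / 100)
  hi <- oracle_percentile(obs, upper_pct / 100)
  out <- x
  out[!is.na(out)] <- pmin(pmax(out[!is.na(out)], lo), hi)
  out
}

oracle_breadth <- function(part, cap) {
  vapply(seq_len(nrow(part)), function(i) min(sum(part[i, ]), cap), 0)
}

oracle_beyond_max <- function(values, focal) {
  vapply(seq_len(nrow(values)), function(i) max(values[i, -focal]), 0)
}

# least squares via explicit normal equations
oracle_ols <- function(y, X) {
  drop(solve(crossprod(X), crossprod(X, y)))
}
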