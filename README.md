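# gcmm — parallel multiple mediation for gambling survey data

`gcmm` is an R package for epidemiologists and gambling researchers who
want to know not just *whether* playing a particular game type is
associated with problem gambling, but *through which mechanism*. It
implements a gambling consumption mediation model as a complete,
tested pipeline: from respondent-level survey microdata (per-game-type
frequency and usual spending, demographics, PGSI scores) through
feature engineering, parallel multiple mediation with
percentile-bootstrap inference, cohort comparison statistics, and
dominant-mediator profile classification. A synthetic survey generator
with plantable true mediation paths makes every stage testable without
access to restricted survey data.

## The model

For each focal game type, last-year participation X (0/1) relates to
the capped PGSI sum score Y through six parallel mediators M1–M6:
demographic propensity, breadth of involvement (number of game types
played, capped at 7), frequency and usual spending *within* the focal
type, and maximum frequency and spending *beyond* it. OLS path
analysis estimates

    a_j : M_j = i_j + a_j X + e_j                (six simple fits)
    b_j, c' : Y = i + c' X + Σ_j b_j M_j + e     (one joint fit)

with indirect effects a_j·b_j, direct effect c′, and total effect
c′ + Σ_j a_j b_j — equal, as an OLS identity, to the simple regression
slope of Y on X (verified to 1e-10 on every fit and every bootstrap
resample). Confidence intervals are percentile-bootstrap (default
B = 5000, 95%); an effect is *relevant* when its interval excludes 0.
Per game type, the largest relevant positive indirect effect names the
dominant mediator, and the ratio to the second largest (threshold 2)
separates distinct from equivocal profiles.

The cohort stage reports participation-by-year chi-square tests with
Cramér's V = √(χ²/(N·min(r−1, c−1))), tie-corrected Kruskal–Wallis H
with η² = (H − k + 1)/(n − k), participation growth ratios, and the
PGSI severity-group distribution (0 / 1–4 / 5–7 / 8+).

## Worked example

```r
library(gcmm)

sim      <- simulate_survey(gcmm_sim_params(rng_seed = 2026))
gamblers <- filter_last_year_gamblers(sim$table)   # retains 82.3%

fit <- gcmm(gamblers, "egm_off", B = 2000, seed = 11)
summary(fit)
```

```
Parallel multiple mediation: egm_off (n = 5944, B = 2000, 95% percentile CI)
                   effect   estimate      lower      upper relevant
             a_M2_breadth  1.826e+00  1.710e+00  1.941e+00     TRUE
         a_M3_freq_within  1.790e+00  1.721e+00  1.858e+00     TRUE
 ...
      indirect_M2_breadth  2.364e-01  1.882e-01  2.836e-01     TRUE
  indirect_M3_freq_within  3.101e-01  1.891e-01  4.358e-01     TRUE
  indirect_M4_freq_beyond  3.005e-02  1.648e-02  4.448e-02     TRUE
 indirect_M5_spend_within -1.597e-02 -8.139e-02  5.333e-02    FALSE
 indirect_M6_spend_beyond -9.282e-03 -1.772e-02 -1.489e-03     TRUE
                  c_prime -3.684e-02 -1.790e-01  1.099e-01    FALSE
                    total  5.139e-01  4.457e-01  5.914e-01     TRUE
```

Playing machines raises the problem score by 0.51 points in total; the
direct effect is indistinguishable from zero — the association runs
through the mediators. Frequency within (0.310) and breadth (0.236)
carry most of it, and their ratio is below 2:

```r
classify_profile(fit)
#> egm_off: equivocal (dominant M3_freq_within, ratio 1.31)
```

On this realistic default draw the machine profile is equivocal
between frequency-within and breadth; the planted-truth scenarios in
`?scenarios` show the classifier separating the two cleanly when the
generating mechanism does. Running all 15 types and the cohort stage
end to end, writing tidy CSVs, a text report and a JSON manifest:

```r
res <- gcmm_run("survey.csv", out_dir = "results", seed = 1)
print(res$profiles)
```

The cohort stage works directly from printed count tables too:

```r
contingency_from_counts(c(1057, 1003, 1197), c(1398, 1264, 1760))
#> contingency: chi2(2) = 52.772, p = 3.47e-12, Cramer's V = 0.109
```

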