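# tsmr — two-sample Mendelian randomization from GWAS summary statistics

`tsmr` is an R package for desk-scale two-sample Mendelian randomization
(MR) with binary exposures and outcomes. It is aimed at genetic
epidemiologists who have two GWAS summary-statistics tables — one for an
exposure (e.g. asthma), one for an outcome (e.g. an infection phenotype) —
and want the standard causal-inference workflow end to end: instrument
selection, harmonization, estimation, sensitivity analysis, and power.

## What it computes

For instruments $j$ with exposure effects $\hat\gamma_j$ (SE
$\sigma_{X,j}$) and outcome effects $\hat\Gamma_j$ (SE $\sigma_{Y,j}$),
each Wald ratio $\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ estimates the
causal log-odds effect $\beta$. The package provides:

- **Selection / harmonization**: greedy p-ranked LD clumping
  ($p < 5\times10^{-8}$, $r^2 < 0.001$), proxy substitution
  ($r^2 > 0.6$), allele harmonization with palindrome exclusion
  (EAF in (0.4, 0.6)), per-SNP $R^2$ and the instrument-strength
  F-statistic $R^2 (N-2)/(1-R^2)$.
- **Estimators**: inverse-variance weighted (IVW, multiplicative random
  effects), MR-Egger (slope + pleiotropy intercept), weighted median, and
  weighted mode, all reported as OR with 95% CI.
- **Diagnostics**: Cochran Q, Egger intercept test, MR-PRESSO
  (global / outlier / distortion), leave-one-out, and scatter/funnel/forest
  plot tables.
- **Power**: the binary-outcome approximation
  $\mathrm{power} = \Phi(\sqrt{N R^2 K(1-K)}\,|\log\mathrm{OR}| -
  z_{1-\alpha/2})$ and its closed-form inversion to the smallest detectable
  OR.
- **Synthetic data**: a seeded generator of two-sample summary statistics
  with known causal effect, pleiotropy regime, palindromes, strand flips,
  LD blocks and planted outliers, so the whole pipeline is testable with no
  downloads.

## Worked example

Everything below is generated — no external data. Simulate a
moderate-to-severe-asthma-sized exposure panel (24 instruments, 10,549
cases / 47,146 controls) against a susceptibility-sized outcome study
(38,984 cases / 1,644,784 controls) with a true causal log-odds effect of
0.2, and run the full pipeline:

```r
library(tsmr)
dir <- tempfile(); dir.create(dir)
make_fixture("msasthma_susceptibility", dir, seed = 7, beta_causal = 0.2)

cfg <- analysis_config(exposure = file.path(dir, "exposure.tsv"),
                       outcome  = file.path(dir, "outcome.tsv"),
                       ld       = file.path(dir, "ld.tsv"),
                       seed = 11, out_dir = file.path(dir, "out"))
bundle <- run_analysis(cfg)
bundle
#> ReportBundle: 4 estimate rows across 1 outcome(s)
#>   exposure outcome          method nsnp       or    ci_low  ci_high         pval
#> 1 exposure outcome             IVW   18 1.240008 1.1921835 1.289751 8.218308e-27
#> 2 exposure outcome weighted_median   18 1.215018 1.1574954 1.275399 3.533265e-15
#> 3 exposure outcome   weighted_mode   18 1.205898 1.1352668 1.280923 1.203762e-09
#> 4 exposure outcome        MR_Egger   18 1.108456 0.9569309 1.283974 1.569805e-01
```

All four estimators cover the generating truth (OR $e^{0.2} = 1.221$
falls in every CI). The diagnostics table is the machine-readable twin of a
standard heterogeneity/pleiotropy report (this draw happens to show mild
heterogeneity, Q p $\approx$ 0.027, with no MR-PRESSO outlier flagged):

```r
bundle$diagnostics[c("q", "q_df", "q_pval", "presso_global_p",
                     "egger_intercept", "egger_intercept_pval")]
#>          q q_df     q_pval presso_global_p egger_intercept egger_intercept_pval
#> 1 29.93432   17 0.02682264           0.025       0.0158825            0.1119254
```

and the power summary answers "what OR could this design have seen?":

```r
bundle$power[c("r2", "k", "detectable_or")]
#>           r2          k detectable_or
#> 1 0.01713438 0.02315283      1.115917
```

With the published cumulative $R^2 = 2.35\%$ for a large asthma instrument
panel against the same outcome-study size, the smallest OR detectable with
80% power is:

```r
detectable_or(1683768, 38984 / 1683768, r2 = 0.0235, target_power = 0.8)
#> [1] 1.098177
```

Output files (`estimates.tsv`, `diagnostics.tsv`, `outliers.tsv`,
`loo.tsv`, `provenance.tsv`, `power.tsv`, plot tables, `run.log`) land in
`out_dir` and are byte-identical across reruns of the same config.

A command-line interface wraps the same operations:

```sh
exec/tsmr simulate --preset asthma_susceptibility --out fixtures --seed 1
exec/tsmr power --cases 38984 --controls 1644784 --r2 0.0235
exec/tsmr run --config analysis.cfg --out results
exec/tsmr validate --path fixtures/exposure.tsv
```

## Documentation

See `vignettes/two-sample-mr.Rmd` for the model, every tunable parameter
with its default and rationale, what the synthetic generator does and does
not emulate, and known limitations.
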