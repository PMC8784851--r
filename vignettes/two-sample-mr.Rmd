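---
title: "Two-sample Mendelian randomization with tsmr: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with tsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmr)
```

## The problem and the model

Two-sample Mendelian randomization (MR) asks whether an exposure causally
affects an outcome using only GWAS summary statistics from two
non-overlapping studies. Each genetic instrument $j$ carries an estimated
effect on the exposure, $\hat\gamma_j$ (SE $\sigma_{X,j}$), and on the
outcome, $\hat\Gamma_j$ (SE $\sigma_{Y,j}$). Under the instrumental-variable
assumptions — the variant is associated with the exposure, independent of
confounders, and affects the outcome only through the exposure — each
Wald ratio $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the same
causal log-odds effect $\beta$, with first-order SE
$\sigma_{Y,j}/|\hat\gamma_j|$.

`tsmr` implements the full desk workflow around that model:

1. **Instrument selection** (`select_instruments`): variants with exposure
   $p < 5\times10^{-8}$, greedily clumped so that every retained pair has
   pairwise $r^2 < 0.001$ in a user-supplied LD table. Ordering is by
   ascending p-value with lexicographic ID tie-break, so the result is
   deterministic and row-order invariant.
2. **Proxy substitution** (`find_proxy`): an instrument missing from the
   outcome study is replaced by the variant with maximal $r^2 > 0.6$ that
   is present in both studies (ties: smaller exposure p, then ID); with no
   candidate, the instrument is removed.
3. **Harmonization** (`harmonize`): outcome effects are re-expressed on the
   exposure's effect allele, resolving allele swaps (negate, reflect EAF)
   and strand complements; palindromic variants (A/T, C/G) with exposure
   EAF in (0.4, 0.6) are dropped as strand-unresolvable.
4. **Estimation**: IVW, MR-Egger, weighted median, weighted mode.
5. **Diagnostics**: Cochran Q, Egger intercept, MR-PRESSO global / outlier
   / distortion tests, leave-one-out, and plot tables.
6. **Power** (`mr_power_binary`, `detectable_or`): the binary-outcome
   approximation used by the mRnd calculator.

## Estimators

**IVW** is the inverse-variance-weighted mean of the Wald ratios,
equivalently weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through
the origin with weights $1/\sigma_{Y,j}^2$. The default standard error is
multiplicative random effects: the fixed-effect SE is inflated by
$\sqrt{Q/\mathrm{df}}$ when Cochran's $Q$ exceeds its degrees of freedom and
never deflated. The alternative (`random_effects = "fixed"`) is exposed
because conventions differ between published analyses; the point estimate
is identical either way.

**MR-Egger** regresses outcome on exposure effects with a free intercept
(weights $1/\sigma_{Y,j}^2$) after re-orienting all exposure effects to be
non-negative. The slope is consistent even when all instruments are
pleiotropic, provided instrument strength is independent of the direct
effects (InSIDE); the intercept estimates the mean directional pleiotropic
effect and its $t_{n-2}$ test is the pleiotropy diagnostic. Residual
over-dispersion scales the SEs multiplicatively with a floor of 1.

**Weighted median**: order the ratios, form cumulative weight midpoints
$s_j = \sum_{k<j} w'_k + w'_j/2$ on normalized inverse-variance weights,
and interpolate linearly at $s = 0.5$. Consistent while valid instruments
hold more than half the weight. Its SE comes from a parametric bootstrap:
per-SNP betas are redrawn from normal laws with their reported SEs, the
estimator recomputed, and the SD across replicates taken. The bootstrap is
seeded through the package's derived-stream contract, so results are
bit-reproducible.

**Weighted mode**: the argmax (on a fixed 1024-point grid) of a
normal-kernel density over the ratios with inverse-variance weights.
Bandwidth is `bandwidth_factor` (default 1) times the Silverman-type rule
$0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.349)\,n^{-1/5}$ on the ratio spread.
Consistent when the largest homogeneous cluster of instruments is valid.
SE by the same bootstrap.

P-values are two-sided normal for IVW/median/mode and $t_{n-2}$ for
MR-Egger, matching each method's source convention. Estimates are reported
as OR with 95% CI via $\exp(\beta \pm 1.96\,\mathrm{SE})$.

## Diagnostics

Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2$ with
$\chi^2_{n-1}$ upper-tail p tests heterogeneity. MR-PRESSO builds, for each
SNP, the leave-one-out IVW fit and its weighted squared residual; the
observed residual sum of squares is compared against `n_sim` parametric
simulations in which outcome betas are redrawn around their leave-one-out
fitted values. The global p is the empirical exceedance proportion (zero
exceedances are reported as "< 1/n_sim" and stored as $1/(2\,n_{sim})$ to
keep downstream logs finite while staying conservative); per-SNP empirical
p-values are Bonferroni-adjusted by the instrument count, and a distortion
test compares the all-SNP and outlier-removed estimates against random
same-size removals of non-outlying SNPs.

Two numerical points matter in practice. First, because the per-SNP
Bonferroni threshold is $\alpha/n_{snp}$, the empirical p has no resolution
at that scale unless $n_{sim} \gg n_{snp}/\alpha$ (3000 for 150 SNPs at
$\alpha = 0.05$); the package default of 1000 follows the method's
convention and suffices for the global test, but outlier hunts on large
panels should raise `n_sim` — the acceptance suite uses 20000. Second, the
random-number contract is one root seed with per-purpose derived streams
(simulation draws are a single column-major normal matrix), so results are
independent of iteration order and exactly reproducible.

## Power

For a binary outcome with case fraction $K$ in a study of size $N$, and
instruments explaining $R^2$ of exposure variance, power for true odds
ratio OR at two-sided level $\alpha$ is approximated by
$\Phi\!\big(\sqrt{N R^2 K(1-K)}\,|\log \mathrm{OR}| - z_{1-\alpha/2}\big)$,
and the smallest detectable OR at target power $1-\beta$ inverts it in
closed form: $\log \mathrm{OR} = (z_{1-\alpha/2} + z_{1-\beta}) /
\sqrt{N R^2 K(1-K)}$. The inversion round-trips to machine precision and
the detectable OR below 1 is the reciprocal of the one above 1. A
one-sided variant is exposed (`one_sided = TRUE`) because published uses of
the calculator differ; note that under either convention a smaller outcome
study cannot yield a smaller detectable OR at fixed $R^2$, so an external
report claiming that pattern cannot be reproduced by this (or any standard)
formula and `tsmr` makes no attempt to match it.

```{r power}
detectable_or(1683768, 38984 / 1683768, r2 = 0.0235, target_power = 0.8)
```

## The synthetic-data generator: its world and its limits

`sim_config()`/`simulate_two_sample()` emulate a *post-selection* panel of
instruments for a binary exposure against a binary outcome:

- **Allele frequencies** uniform on (0.05, 0.95) — common variants, as
  genome-wide-significant instruments overwhelmingly are.
- **Standard errors** from the binary-trait approximation
  $SE = 1/\sqrt{2 N f(1-f) K(1-K)}$ on each side; written p-values are the
  Wald p of beta/SE, so the z–p round trip holds exactly.
- **True SNP-exposure effects** $\gamma_j$: half-normal (scale 0.065),
  rejection-truncated so every $|\gamma_j|$ exceeds the genome-wide
  significance boundary at its own SE. With the default cohort sizes
  (394,283 exposure participants, case fraction 0.119; 1,683,768 outcome
  participants, case fraction 0.023 — the scale of a large biobank asthma
  panel against a population-scale infection meta-analysis) this puts
  per-SNP F statistics in the tens-to-hundreds range and a 150-SNP panel's
  cumulative $R^2$ near 2%, matching what strong published binary-trait
  panels report. Effects are oriented to the exposure-increasing allele
  ($\gamma_j \ge 0$, the convention for reported instruments); without a
  fixed orientation, "directional" pleiotropy would have no stable
  direction relative to MR-Egger's own re-orientation and its intercept
  would be inestimable by construction.
- **Pleiotropy** $\alpha_j$: none, balanced ($N(0, sd)$), or directional
  ($N(mean, sd)$); `inside_violated = TRUE` adds $0.3\gamma_j$ to
  $\alpha_j$, correlating strength with direct effects.
- **Truth** $\Gamma_j = \beta\,\gamma_j + \alpha_j$ holds exactly in the
  emitted truth table.
- **Representation noise**: configurable fractions of non-palindromic SNPs
  are written with swapped alleles or on the complementary strand, and a
  configurable count of palindromic variants is injected, exercising every
  harmonization path. Planted outliers displace an observed outcome beta by
  a stated number of its SEs. Optional LD blocks emit within-block $r^2$
  for clumping tests.

What the generator does *not* model: individual-level genotypes, realistic
genome-wide LD beyond block constants, winner's curse in the exposure
effects, sample overlap between studies, and allele-frequency differences
between studies. A green simulation-based test therefore establishes
calibration and recovery *within this stated world*, not robustness to
those real-data pathologies.

## Numerical and design choices

- **Seeds.** Every stochastic routine takes one root seed; internal streams
  are derived by a fixed counter scheme (`derive_seed`), all below
  $2^{31}$. Two runs of one config produce byte-identical reports (numbers
  are written with 17 significant digits, enough to round-trip doubles).
- **Zero p-values** in input are clamped to the smallest positive double
  with a warning, since downstream code takes logs and quantiles.
- **Palindrome window.** "Intermediate allele frequency" is the open
  interval (0.4, 0.6): the ambiguity is symmetric about 0.5, so a
  one-sided reading would be incoherent. Palindromic variants lacking an
  exposure EAF cannot be checked and are dropped with their own provenance
  reason.
- **Per-SNP variance explained** uses the summary-statistic approximation
  $R^2_j = \beta_j^2 / (\beta_j^2 + N\sigma_j^2)$ (the $2f(1-f)$ factors
  cancel); cumulative $R^2$ is the per-SNP sum, ignoring residual LD —
  acceptable after clumping at $r^2 < 0.001$.
- **Proxy alleles.** A proxy replaces the instrument on *both* sides (it
  must be present in both studies), avoiding any phasing assumption between
  proxy and index variant that summary data cannot support.
- **Clump-then-proxy order** follows the natural narrative order of
  selection before outcome lookup; with ID-keyed LD input the reverse order
  would need LD rows for candidate proxies against all candidates, which
  callers rarely have.
- **Ties.** Clumping ranks by (p, ID); proxy search by (r², exposure p,
  ID). Both documented, both deterministic.
- **Insufficient instruments** raise errors at the method minima (IVW 2,
  Egger/median/mode 3, PRESSO 4); single-SNP IVW is available behind
  `min_snp = 1` and reduces exactly to the Wald ratio.
- **No multiple-testing correction** is applied across exposure-outcome
  pairs by default (each analysis stands alone, two-sided $p<0.05$); this
  mirrors common practice and is trivially added downstream.

## Known limitations

No Steiger directionality filtering, multivariable MR, RAPS, or radial
variants; LD must be supplied, never computed; genomic coordinates are out
of scope (analyses are rsID-keyed); the distortion test's resampling
scheme is a documented adaptation (random same-size removals among
non-outliers) rather than a line-by-line port of the original software.
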