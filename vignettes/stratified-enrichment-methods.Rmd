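---
title: "Methods: stratified GWAS enrichment in annotated variant sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified GWAS enrichment in annotated variant sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratenrich)
```

This vignette is the package's own account of the statistical machinery:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where reasonable alternatives existed.

## The question and the model

The analysis asks whether variants carrying an annotation (a tissue's
cis-eQTLs, a chromatin-state category, promoter-proximal variants) show an
excess of trait associations in GWAS summary statistics. Three confounders
make the naive comparison misleading: annotated variants differ from the
genomic background in minor allele frequency, in distance to
transcription start sites, and — most importantly — in how much of the
genome they tag through linkage disequilibrium. The package addresses the
first two by matched-control selection, and the third by LD-based pruning
plus an explicit total-LD covariate.

The quantitative core is a general linear model of the per-variant 1-df
association chi-squared. A two-sided p-value is converted back to the
chi-squared it came from,

$$z^2 = \left(\Phi^{-1}(p/2)\right)^2,$$

and the model

$$E[z^2_i] = \beta_0 + \sum_k \beta_k\, x_{ik} + \beta_{LD}\,(\ell_i - 1)$$

is fitted by ordinary least squares, where $x_{ik}$ are 0/1 annotation
indicators and $\ell_i$ is the total LD score
($1 + \sum_j r^2_{ij}$ within 1 Mb). Under a polygenic alternative the
expected chi-squared of an annotated class exceeds the baseline by an
additive amount, so $\beta_k$ reads directly as *excess association signal
attributable to the annotation*, holding the other covariates fixed.
Interaction terms ($x_{eqtl} \times x_{category}$,
$x_{eqtl} \times \ell$) ask whether the eQTL excess is modified by
chromatin context or by LD-tagging power.

Chi-squared responses are right-skewed and heteroskedastic; OLS point
estimates remain unbiased for the conditional mean, and the conventional
t-based standard errors are the deliberate default (a
heteroskedasticity-consistent option, `robust = TRUE`, exists). This is
the standard practice for this model family and keeps coefficients
comparable with the literature that uses it.

## LD pruning replicates and why the meta-analysis is anti-conservative

Because annotated variants are correlated through LD, model rows are not
independent. The package prunes to near-independent subsets: a replicate
draws a random permutation of the variants and greedily retains a variant
iff no already-retained variant within 1 Mb has $r^2 \ge 0.2$ with it.
Each replicate is maximal for its own ordering; ten replicates (the
default) reduce the sampling arbitrariness of any single pruning. Seeds
are derived per replicate and recorded, so replicates replay exactly.

Replicates are *overlapping by construction*: a variant with no strong LD
partner appears in every replicate. The per-term results are combined
across replicates by reporting the plain mean coefficient
$\bar\beta$ alongside a fixed-effect inverse-variance pooled estimate,
standard error and p-value. The pooled standard error treats replicates
as independent, which they are not, and is therefore anti-conservative —
deliberately so, because this mirrors the replicate-averaging convention
of the analyses this package implements, and "fixing" it silently would
change the meaning of the reported p-values. The practical magnitude is
large, not cosmetic: in the package's own null calibration (200 null
simulations at 20,000 variants, `test-acceptance.R`), the pooled meta
p-value rejects a true-null eQTL term at $\alpha = 0.05$ about 40–50% of
the time, while the per-replicate GLM p is essentially calibrated
(≈ 0.06–0.07). Readers should treat the meta p as a ranking device and
the per-replicate spread as the honest uncertainty. For the same reason,
the interaction screen in the test suite bounds estimates by the
*dispersion of replicate coefficients* (not the pooled SE divided by
$\sqrt{10}$): when replicates are strongly correlated, the spread of
their coefficients approximates the sampling error of their mean.

## Genomic control

The intergenic correction factor is estimated on the same pruned sets the
models use: per replicate, the median chi-squared over intergenic members;
then

$$\hat\lambda = \frac{\mathrm{median}_r(\mathrm{median}\ z^2_{r,\ intergenic})}{\mathrm{median}(\chi^2_1)},$$

with $\mathrm{median}(\chi^2_1) \approx 0.4549$ computed from the quantile
function rather than hard-coded. All chi-squared are divided by
$\hat\lambda$ and p-values regenerated from the corrected statistics, so
every downstream quantity — Q-Q curves, fold enrichment, rank tests,
$\pi_1$, models — sees corrected values. The correction preserves p-value
ranks, and re-estimating after correction returns exactly 1. Genic extent
is taken as an input flag on the variant table; the package does not
re-derive gene boundaries.

## Curves, rank tests and pi1

Q-Q points use midpoint plotting positions, expected
$-\log_{10}((i - 0.5)/n)$ for rank $i$ — a choice the package makes
explicitly since plotting positions are rarely stated; expected values are
distribution-free and depend only on $n$. Fold enrichment is the ratio of
complementary empirical CDFs of $-\log_{10} p$ between a set and its
baseline on a 0.1-wide threshold grid, truncated at the last threshold
with at least `min_denominator` (default 10) baseline survivors so the
curve never ends in a ratio of near-empty tails. The baseline defaults to
the matched control set but can be any set (e.g. one catalogue relative to
another).

Mann–Whitney comparisons use the exact null distribution when both
samples are small (min $n \le 8$) and tie-free, and the normal
approximation with tie and continuity corrections otherwise; the
size-based switch is the package's choice, validated against a
full-enumeration oracle in the tests.

$\pi_1 = 1 - \pi_0$ uses the Storey grid estimator
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (n(1-\lambda))$ over
$\lambda = 0.05, \dots, 0.95$, with a cubic smoothing spline (df = 3)
evaluated at the largest $\lambda$ and clamped to $[0,1]$. The grid,
spline flavour and df are exposed; `method = "fixed"` skips the smoother.
Rank tests and $\pi_1$ run on the full (unpruned) variant set — they are
distribution comparisons, not regression fits, and benefit from the full
sample.

## Matched controls

Controls are drawn without replacement from the candidate pool, stratified
exactly on MAF bins (2% width) and deciles of $\log_{10}(1 + d_{TSS})$
computed from the pool, after excluding any candidate with minimum
expression-association p below $10^{-4}$. Exhausted strata report their
targets as unmatched rather than failing. Bin widths, the decile count,
the matching ratio and the exclusion threshold are all parameters; the
exact-bin stratified scheme (rather than propensity or caliper matching)
is the package's choice for transparency and replayability.

## Locus overlap

A genome-wide-significant locus is represented by its lead variant's LD
window: the lead plus all variants with $r^2 \ge 0.8$ to it (membership by
LD, not by spanning interval, by default; interval mode exists). The
enrichment ratio compares the annotation's genome-wide footprint $K/N$
(both supplied as inputs, since the number of independent genomic loci is
estimated outside any one GWAS) to the observed overlap fraction $k/n$,
as a ratio of proportions — the computation that reproduces the printed
two-decimal values of the motivating analysis — with the conventional
odds ratio and the reciprocal also emitted, and Fisher's exact test on
the 2×2 table for significance.

## The synthetic-data generator

The generator is first-class, tested code. It emulates the statistical
structure the analysis assumes:

* **LD blocks.** Variants sit in blocks of mean size 20 (0.5–5 kb
  spacing, so blocks span tens of kb; ≥ 2 Mb between blocks), each with a
  one-factor correlation structure: variant $i$ loads on its block factor
  with loading $l_i$, giving pairwise $r^2_{ij} = (l_i l_j)^2$. Squared
  loadings are Beta(10, 10), centring pairwise $r^2$ near 0.25 so most
  block-mate pairs conflict at the 0.2 pruning threshold while an
  appreciable minority do not — pruning and genomic control are
  consequential, not cosmetic.
* **Jointly drawn z-scores.** Within a block,
  $z_i = \sigma_i (l_i U + \sqrt{1 - l_i^2}\,\varepsilon_i)$ with a shared
  block factor $U$, so z correlations match the emitted $r^2$ exactly.
* **Effects on the expected-chi-squared scale.**
  $\sigma_i^2 = \lambda (1 + \sum_k \beta_k x_{ik} \eta_{ik} + \beta_{LD}(\ell_i - 1))$,
  with $\eta_{ik} \sim \mathrm{Bernoulli}(\pi_{1,k})$ non-null indicators
  (default all 1). Variance inflation of z is additive in expected
  chi-squared, so the linear model above is *correctly specified* and
  parameter recovery is a meaningful end-to-end check.
* **Tissue sharing.** Each tissue's eQTL set is drawn from a common
  eQTL-prone pool of size $m / 0.10$, making the expected pairwise overlap
  fraction 10%; sharing = 1 collapses all tissues onto one set.
* **The rest.** MAF ~ U(0.01, 0.5); TSS distance log-normal with median
  25 kb (so the 25-kb proximal/distal split is non-degenerate); genic
  fraction 0.5; mutually exclusive chromatin-state categories at 3–5%
  each; expression-association p-values strong ($10^{-12}$–$10^{-5}$) for
  pool members and uniform elsewhere, so control exclusion at $10^{-4}$
  bites exactly where it should. All randomness flows from one master
  seed through a documented per-stage splitting scheme; fixtures
  regenerate byte-identically.

What the generator does **not** emulate: real human LD maps (block sizes
and $r^2$ are stylized, there is no MAF–LD coupling and no inter-block
LD), allele-level effects (everything lives on the summary-statistic
scale), winner's-curse in eQTL designation, or population stratification
beyond a scalar inflation $\lambda$. Passing tests therefore demonstrate
that the *procedures* behave as designed under the assumed structure —
not that any particular real-data result would replicate.

## Problem sizes and numerical choices

The test suite uses 2,000-variant fixtures for unit tests, ~20,000 for
calibration sweeps and 50,000–100,000 for recovery checks — sizes chosen
so the full suite runs comfortably on a laptop while keeping Monte-Carlo
error small relative to the asserted tolerances. Other choices worth
stating: p = 0 inputs are clamped to $10^{-300}$ (not dropped) with a
warning; missing LD pairs mean $r^2 = 0$; the total LD score includes the
conventional self-count of 1 (any constant offset is absorbed by the
model intercept); BED intervals are 0-based half-open against 1-based
variant positions with the conversion centralized in one place; pruning
replicates may be forced disjoint (`disjoint = TRUE`) for sensitivity
analysis, with overlapping draws the default since mutually disjoint
maximal independent sets generally cannot exist; and multi-tissue eQTLs
("double agents") keep all their tissue labels, with exclusion available
through set difference rather than hard-wired.

## Known limitations

The meta-analysis anti-conservatism quantified above is the main one. In
addition: retained variants within a replicate can still share $r^2$ up
to 0.2, so even per-replicate standard errors are slightly optimistic;
$\pi_1$ from the spline smoother is noisy below a few hundred p-values
(the package warns under 100); and the locus-overlap baseline counts
$K$ and $N$ are inputs whose quality bounds the ratio's meaning.
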