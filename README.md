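# stratenrich

Stratified enrichment of GWAS associations in functionally annotated
variant sets.

## The problem

Given genome-wide association summary statistics for a complex trait, do
variants carrying a functional annotation — cis-eQTLs designated in a
particular tissue, variants inside chromatin-state categories (active/weak
promoter, strong/weak enhancer), promoter-proximal versus distal regulatory
variants — show an *excess* of trait associations beyond what their allele
frequency, distance to the nearest transcription start site, and
LD-tagging power already predict?

`stratenrich` implements the full analysis as a reusable, tested pipeline:

1. **Ingest** — summary statistics (TSV), annotations (BED4, eQTL tables),
   pairwise LD (`SNP_A/BP_A/SNP_B/BP_B/R2`), matched-control sets, and a
   high-quality variant template; plus annotation-set algebra
   (union / intersection / difference) for consensus-set construction.
2. **LD pruning** — ten (configurable) near-independent variant subsets:
   each replicate is a fresh random greedy maximal set with pairwise
   r² < 0.2 within 1 Mb, with recorded seeds for exact replay.
3. **Genomic control** — two-sided p-values are converted to 1-df
   chi-squared via z² = (Φ⁻¹(p/2))²; the intergenic correction factor
   λ = median-of-replicate-medians / median(χ²₁) is estimated on the pruned
   sets and divided out of every statistic before all downstream analysis.
4. **Curves and rank tests** — stratified Q-Q points, conditional
   fold-enrichment curves as complementary-CDF ratios
   ratio(t) = P(−log₁₀p ≥ t | S) / P(−log₁₀p ≥ t | baseline),
   Mann–Whitney comparisons of chi-squared between a set and its matched
   controls, and Storey-type π₁ (proportion of non-null associations) with
   a df = 3 smoothing spline over the λ-grid.
5. **Chi-squared general linear model** — OLS of per-variant χ² on
   annotation indicators, total LD score, and eQTL×category interaction
   terms, fitted on every pruning replicate and combined across replicates
   (mean coefficient, inverse-variance pooled p).
6. **Locus overlap** — LD windows (r² ≥ 0.8) around genome-wide-significant
   lead variants intersected with an annotation set; the enrichment ratio
   (K/N)/(k/n) against a genome-wide baseline with Fisher's exact test.
7. **Matched controls** — stratified draws on MAF (2% bins) and
   log₁₀(1 + TSS distance) deciles, excluding candidates with any
   expression-association p < 10⁻⁴, with balance diagnostics.
8. **Synthetic data** — a generator producing block-LD variant maps,
   tissue-tagged eQTL sets with ~10% pairwise sharing, chromatin-state
   tracks, matched-control pools, and z-scores drawn jointly within LD
   blocks with annotation-dependent variance inflation — so the whole
   pipeline runs and is validated with no external data.

## Worked example

```r
library(stratenrich)

# a complete synthetic input directory: 2 tissues, enrichment injected
cfg <- sim_config(n_variants = 20000, tissues = c("adipose", "blood"),
                  eqtl_fraction = 0.05,
                  beta = c("eqtl:adipose" = 0.8, "eqtl:blood" = 0.8),
                  seed = 42)
make_fixture(config = cfg, dir = "demo", seed = 42)

res <- run_enrichment_pipeline("demo", out_dir = "demo-results", n_sets = 10)
res
```

```
ingest: 20000 variants, 190000 LD pairs, 12 annotation sets, 1 GWAS
prune: 10 replicates, sizes 4362-4578
gc[trait1]: lambda = 1.0258
<stratenrich_results>
  traits: trait1
  lambda_gc[trait1] = 1.0258
  summary:
   trait          set   pi1 mw_neglog10_p beta_bar    glm_p
1 trait1 eqtl:adipose 0.236          18.2    0.923 1.30e-72
2 trait1   eqtl:blood 0.258          14.6    0.800 2.72e-55
```

Reading the output: the genomic-control λ near 1 says the simulated trait
carries no global inflation (the estimate's small excess is divided out of
all statistics). For each eQTL set, `pi1` estimates the fraction of its
variants with non-null associations, `mw_neglog10_p` is the Mann–Whitney
evidence that its chi-squared distribution exceeds the matched controls',
and `beta_bar`/`glm_p` are the meta-analysed model coefficient (excess
expected chi-squared attributable to eQTL status, controlling for
chromatin-state membership and total LD) with its pooled p-value — here
consistent with the injected effects of 0.8 on the expected-χ² scale
(the pooled p-value overstates certainty; see the replicate-overlap
discussion in the methods vignette).

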