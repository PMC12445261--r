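# adgreml

Additive **and** dominance genomic analysis for small, divergently selected
livestock cohorts.

Designed selection experiments — a handful of extreme-EBV sires mated to
extreme-EBV ewes, a few hundred lambs phenotyped at birth, sequence-level
genotypes — need an analysis chain that treats dominance as a first-class
citizen and stays honest at small n. `adgreml` provides that chain for
quantitative geneticists and animal breeders:

* **Synthetic cohorts** (`simulate_cohort()`): pedigree, gene-dropped
  genotypes and traits with controlled additive (`h²`) and dominance (`d²`)
  architecture, divergent parent selection, Gaussian/count/binary traits,
  and ungenotyped contemporaries — so the whole pipeline is testable
  without any download.
* **Variant QC** (`filter_variants()`, `hwe_exact_test()`): call rate
  > 0.95, MAF > 0.05, Hardy–Weinberg exact test at p ≥ 1e-6;
  `pca_from_grm()` for stratification correction;
  `effective_n_variants()` for the LD-pruning-based effective number of
  independent tests (r² > 0.5, window 5000, step 500).
* **Relationship matrices** (`grm_additive()`, `grm_dominance()`,
  `pedigree_additive()`, `pedigree_dominance()`): genomic G (Yang-style
  diagonal), dominance D with the `(-2p², 2pq, -2q²)` coding, pedigree A
  (tabular method with inbreeding) and pedigree dominance.
* **Variance components** (`reml_fit()`): average-information REML with EM
  fallback for models `y = Xb + g + e` and `y = Xb + g + d + e`;
  `heritability()`, `dominance_fraction()`, and `liability_transform()`
  for binary traits recorded 0/1 (`h²_l = h²_obs · K(1−K)/z² ·
  K(1−K)/(P(1−P))`).
* **Breeding values** (`blup_solve()`, `ebv_correlations()`,
  `descriptive_stats()`): BLUP EBVs at the REML estimates and their
  Pearson correlation table with significance stars.
* **Association** (`assoc_scan()`): per-variant GLS fit of
  `y = Xb + x_a b_a + x_d b_d + g + e` with `V = Gσ²_g + Iσ²_e` fixed at
  the null fit; `χ²_a = b̂²_a/var(b̂_a)`, `χ²_d` analogously, 1 df each;
  `inflation_factor()` (`λ = median(χ²)/0.4549`),
  `thresholds_from_meff()` (`p_Bonf = 0.05/Meff`, `p_Sug = 1/Meff`),
  `manhattan_export()`/`manhattan_plot()`.
* **Annotation** (`annotate_variants()`, `summarize_candidates()`):
  candidate genes by the ±1 kb proximity rule, GFF3/BED input.

## Worked example

Simulate the default experiment (4 sires, 254 lambs split 62/65/64/63 into
short×short and long×long groups, 38 ungenotyped contemporaries, 5,000
variants, focal trait h² = 0.80 and d² = 0.15) and analyse tail length:

```r
library(adgreml)
cfg    <- cohort_config(n_variants = 5000, seed = 42)
cohort <- simulate_cohort(cfg)
qc     <- filter_variants(subset_genotyped(cohort$genotypes))
G      <- grm_additive(qc$genotypes)
D      <- grm_dominance(qc$genotypes)
pcs    <- pca_from_grm(G, 20)
spec   <- mm_spec(cohort$traits, "TL", list(G = G, D = D), pcs = pcs$scores)
fit    <- reml_fit(spec)
print(fit)
```

```
REML variance components (converged, 9 iterations)
  sigma_G2   1.3625 (0.5637)
  sigma_D2   0.9320 (0.5608)
  sigma_e2   0.0339 (0.4060)
  sigma_p2   2.3284
  h2         0.5852 (0.1994)
  d2         0.4003
```

At n = 254 in four sire families the variance partition is volatile — the
SEs say so — and the fixed effects plus two PCs (which explained 6.98% and
6.79% of variance here) absorb part of the between-group genetic
divergence. Continuing:

```r
meff <- effective_n_variants(qc$genotypes)$meff
thr  <- thresholds_from_meff(meff)
scan <- assoc_scan(spec$y, spec$X,
                   subset_genotypes(qc$genotypes, animals = spec$ids),
                   G, fit$estimates[1], fit$estimates["sigma_e2"])
inflation_factor(scan$chi2_a)
```

prints `Meff = 4666` (4,668 variants survived QC), −log10 thresholds 4.97
(Bonferroni) and 3.67 (suggestive), and λ_additive = 1.90 — inflated not by
mis-calibration but by a genuinely polygenic, highly heritable trait in a
structured cohort (the null-calibration test in the suite shows λ ≈ 1 and a
5% type-I rate when the trait is pure polygenic noise). The strongest
additive signal in this run was a planted QTL region on chromosome 20
(p_a = 6.4e-08). The worked examples from printed components reproduce
exactly, e.g.:

```r
heritability(4.19, 4.95)$h2        # 0.8465  -> 0.85, tail length
heritability(0.05, 0.24)$h2        # 0.2083  -> 0.21, tail circumference
dominance_fraction(0.74, 4.95)     # 14.95 (%), tail length dominance share
thresholds_from_meff(477627)$p_bonf  # 1.047e-07
```

## Command line

A thin CLI wraps the pipeline (`simulate`, `qc`, `kinship`, `reml`,
`gwas`):

```sh
Rscript -e 'adgreml::adgreml_cli()' qc --vcf cohort.vcf --out qc_out
```

See the vignette (`vignettes/additive-dominance-pipeline.Rmd`) for the
models, the generator's design choices, numerical conventions, and known
limitations.
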