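# hlafinemap

Fine-mapping of case-control association signals across the major
histocompatibility complex (MHC). The package is aimed at statistical
geneticists who have phased classical HLA calls (two- and four-digit), SNPs
and HLA amino-acid polymorphisms for a stratified case-control collection and
want to know which of the heavily correlated variants carry **statistically
independent** effects.

## The method

All variants are coded as biallelic presence/absence dosages (0/1/2 copies
per subject). A variant with *p* alleles — a multi-allelic SNP, an amino-acid
position, or a whole HLA gene — enters the logistic model through *p−1*
terms, the reference allele being the most frequent among controls:

    logit P(y=1) = β₀ + Σⱼ βⱼ dⱼ + Σₖ γₖ PCₖ + Σₛ δₛ Sₛ

with 5 principal components and n−1 study-stratum dummies, genetic effects
fixed across strata. The **omnibus test** is the likelihood-ratio statistic
D = 2(L₁ − L₀) ~ χ²(k) over all p−1 terms jointly, with p-values held in
log10 space so extreme signals do not underflow. Independent effects are
found by **conditional forward stepwise** selection: add the top-ranked
variant, re-test everything conditional on it, repeat until no variant and no
gene-level residual test reaches the a-priori threshold 0.05/5000 = 1e-5.
The toolkit also provides diplotype (cis allele-pair) dosages, interaction
and carrier-stratified analyses, Nagelkerke's pseudo-R² for variance
explained, penalized-regression cross-checks of allele selection (lasso,
elastic net, LARS, forward stagewise with the 1-SE cross-validation rule),
and a cis-eQTL screen with per-gene permutation calibration of the minimum
Spearman p-value. A synthetic MHC cohort generator with known ground truth
(haplotype-pool LD, additive log-odds effects, stratum baselines) backs the
test suite.

## Worked example

```r
library(hlafinemap)

pool <- default_mhc_pool()                       # fixed synthetic MHC LD structure
cfg <- simulation_config(
  strata  = data.frame(name = c("A", "B"), n_cases = c(1200, 1300),
                       n_controls = c(2300, 2500)),
  effects = c("DRB1*15:01" = log(2.9), "A*02:01" = log(1.5),
              "rs2516489_T" = log(1.4)),
  n_pcs = 2, seed = 83)
coh <- sample_cohort(pool, cfg)                  # phased cohort, known truth
dm  <- encode_cohort(coh)                        # presence/absence markers + MAF filter
scan <- forward_scan(dm, coh$pheno,
                     genes = c("DRB1", "DQA1", "DQB1", "A", "B", "DPB1"))
scan
```

```
Forward stepwise scan: 3 effect(s) selected (threshold 1e-05, stop: no-variant-and-no-gene-significant)
  step 1: DRB1*15 (df = 1, D = 346.5, log10 p = -76.62)  [equivalent: DRB1*15:01, snp_32742280_A, snp_32742280_G]
  step 2: A*02 (df = 1, D = 121.2, log10 p = -27.46)  [equivalent: A*02:01]
  step 3: rs2516489 (df = 1, D = 90.6, log10 p = -20.75)
```

The scan recovered each planted effect: step 1 selects the two-digit family
DRB1\*15, a perfect r² = 1 proxy of the planted DRB1\*15:01 (the equivalence
class is annotated), the omnibus deviance 346.5 on 1 df corresponds to
p ≈ 10⁻⁷⁷, and the conditional steps isolate the class I and SNP effects.
`summary(scan)` returns the per-step table, and

```r
variance_report(dm, coh$pheno, list(first = scan$selected[1], all = scan$selected))
#>   model n_groups df         r2
#> 1 first        1  1 0.06410047
#> 2   all        3  3 0.10179935
```

reports the Nagelkerke R² of nested effect sets — the strongest effect alone
explains 6.4% of phenotypic variance here, all three together 10.2%.
`within_locus_selection()` / `selection_crosscheck()` replay the within-gene
allele selection with the four penalized methods.

A thin command-line wrapper (`inst/cli/hlafinemap.R`) exposes
`simulate`, `encode`, `scan` and `eqtl` subcommands over TSV/VCF/BED files.

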