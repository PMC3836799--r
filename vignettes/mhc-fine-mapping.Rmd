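---
title: "Dissecting MHC association signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting MHC association signals: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlafinemap)
```

## The problem

The major histocompatibility complex carries the strongest genetic signals of
many immune-mediated diseases, but its long-range linkage disequilibrium (LD)
makes it hard to tell which of the correlated variants — SNPs, classical HLA
alleles at two- or four-digit resolution, amino-acid residues in the HLA
proteins — carry statistically independent effects. hlafinemap implements a
complete fine-mapping workflow for phased case-control data: presence/absence
encoding of every variant type, multi-allelic omnibus testing in stratified
logistic regression, conditional forward stepwise selection with locus-level
residual tests, penalized-regression cross-checks of the selection, variance
explained, and a permutation-calibrated cis-eQTL screen. A synthetic-cohort
generator with known ground truth accompanies the analysis code so that every
stage can be validated end to end.

## The statistical model

Every marker is coded as a biallelic presence/absence dosage: the number of a
subject's two haplotypes carrying the allele (0/1/2 for hard calls). For a
variant with $p$ alleles (a multi-allelic SNP, the residues of an amino-acid
position, or the four-digit alleles of a gene) the model includes $p-1$
dosage terms, the omitted allele being the reference — chosen as the most
frequent allele among controls. The univariate model for case status $y$ is

$$\mathrm{logit}\,P(y=1) = \beta_0 + \sum_{j \ne \mathrm{ref}} \beta_j d_j
  + \sum_{k=1}^{5} \gamma_k \mathrm{PC}_k + \sum_{s=2}^{n} \delta_s S_s,$$

with five principal components and $n-1$ dummy variables for $n$ study
strata; genetic effects are treated as fixed across strata (one pooled model,
not a meta-analysis). The omnibus test of a variant is the likelihood-ratio
test of all its $p-1$ terms jointly: $D = 2(L_1 - L_0)$ referred to
$\chi^2_k$, where $k$ is the difference in estimable parameters. Locus-level
("residual gene") tests put all of a gene's four-digit alleles not yet
conditioned on into one model. Variance explained is Nagelkerke's
pseudo-$R^2$,

$$R^2 = \frac{1 - \exp\{\tfrac{2}{N}(L_0 - L_1)\}}{1 - \exp\{\tfrac{2}{N}L_0\}}.$$

P-values are computed and stored in log10 space; the chi-square tail is
evaluated with `log.p = TRUE`, so signals far below the double underflow
limit (p ≈ 1e-234 and smaller) remain representable.

## Conditional forward stepwise selection

`forward_scan()` ranks all variants by omnibus p-value, moves the top variant
(all its $p-1$ columns) into the conditioning set, re-tests everything, and
repeats. The stopping rule is two-sided: the scan ends only when no variant
*and* no gene-level residual test reaches the significance threshold; if only
a gene remains significant, variants keep being added until the gene residual
clears the threshold. The threshold defaults to `bonferroni_threshold()` =
0.05/5000 = 1e-5, applied unchanged at every step. Within-locus selection
(`within_locus_selection()`) runs the same engine over one gene's four-digit
alleles under the same two-sided rule — stop only when neither the best
remaining allele nor the locus residual test clears the threshold. A
residual-only stopping rule was considered and rejected: the residual test's
many degrees of freedom can dilute a single strongly associated rare allele
(conditional p near 1e-8) above the threshold and truncate the selection.
Finally,
`aa_stepwise()` does the same over amino-acid positions, finishing with a
paired conditional-LRT comparison of the selected positions against a
classical-allele model (each block tested given the other).

Numerical choices, made once:

* **Aliasing.** Because each locus' markers sum to 2 per subject and
  conditioning sets overlap loci, designs are routinely rank-deficient.
  Collinear columns are dropped by the pivoted-QR rank detection inside the
  IRLS fit and degrees of freedom count only estimable parameters; for locus
  tests both `k` (post-aliasing) and `k_all` (columns offered) are reported.
* **Separation.** A fit with runaway coefficients and fitted probabilities at
  the boundary is flagged `unstable`; such variants are excluded from
  ranking rather than reported with spurious p-values.
* **Ties.** Ranking order is (smaller log10 p, larger deviance,
  lexicographic id), making scans deterministic.
* **Equivalence classes.** Markers with $r^2 = 1$ to a selected variant are
  annotated as statistically equivalent instead of being re-tested.
* **Convergence.** IRLS with relative deviance tolerance 1e-10, at most 100
  iterations, no random initialization.
* **Degenerate inputs.** A variant fully aliased by the conditioning set has
  df 0 and an undefined (NA) test; an LRT between identical parameter spaces
  reports p = 1.

## Penalized cross-checks

`penalized_select()` re-runs the within-locus selection with lasso and
elastic-net (binomial deviance, via glmnet) and with least-angle and
incremental forward-stagewise regression (the classical squared-error path
algorithms, implemented in the package since no LARS implementation is
available in the dependency set). Covariates are never penalized: for
lasso/enet they carry zero penalty factors, for the path methods the outcome
and allele dosages are residualized on the covariates first. The allele block
is reference-coded exactly like the association models (the control-major
allele is dropped); fitting the full compositional block would let common
null alleles absorb intercept-confounded signal. The penalty (or path step)
is chosen by 10-fold cross-validation with the one-standard-error rule —
`one_se_penalty()` picks the largest penalty whose mean CV error is within
one SE of the minimum; fold assignment is stratified by case status and
seeded.

Cross-validated penalized solutions routinely carry trailing extras with
coefficients of OR ≈ 1 that enter the path after the real signals. The
`selection_crosscheck()` agreement verdict therefore asks whether every
method selects the stepwise set *and* ranks it ahead of any extras (largest
|coefficient| for lasso/enet, first path entries for lars/stagewise);
`agree_exact` additionally demands no extras at all and is expected to fail
on realistic data.

## The cis-eQTL screen

`run_cis_eqtl()` associates each SNP's minor-allele dosage with
covariate-adjusted expression by Spearman rank correlation (mid-ranks for
ties; two-sided p from the $t$ approximation), restricted to SNPs within 2 Mb
of the gene's TSS (inclusive boundary, strand ignored; HLA class I/II genes
may be exempted from the distance rule). Significance is calibrated per gene:
expression is permuted 10,000 times, the minimum nominal p across the gene's
cis SNPs is recorded each time, and a pair is called significant when its
nominal p falls below the 5% tail of that min-p null. Because genotypes stay
fixed under permutation, the null preserves the LD among cis SNPs — the
threshold tightens with the number of *effective* tests and is provably
unchanged by duplicating a SNP column.

## What the synthetic cohorts emulate — and what they do not

`default_mhc_pool()` is a fixed pool of extended MHC haplotypes emulating the
features the analysis depends on: a DRB1\*15:01 class II core in near-perfect
LD with DQA1\*01:02/DQB1\*06:02 and perfectly tagged by one SNP; a realistic
spread of DR-DQ cores; class I, DPB1 and SNP backgrounds recombined across
cores with coprime cycle lengths so that cross-locus LD is strong but —
except where stated — imperfect; and a SNP in strong partial LD with
DPB1\*03:01. `sample_cohort()` draws two independent haplotypes per subject
(Hardy–Weinberg within stratum) and Bernoulli case status from a logistic
model with additive per-allele log-odds, stratum intercepts and optional PC
effects; exact per-stratum case/control counts are available via rejection
sampling, natural (intercept-driven) sampling is the default. PCs are
simulated as standard normal covariates rather than computed from genotypes;
imputation uncertainty can be mimicked by per-call posteriors that the
encoder turns into expected dosages.

The generator does *not* model recombination, mutation, population structure
with genuine genotype-PC correlation, imputation error correlated with LD, or
genomic inflation. Passing the recovery suites therefore demonstrates that
the statistical machinery is correct under its stated assumptions, not that
real MHC data meet those assumptions.

The standard study conditions used by the test suites: the eight strata with
the printed per-study case/control sizes (5,091 cases; the printed control
counts sum to 9,599); a planted OR of 2.92 on the 15:01-like allele at
haplotype frequency 0.15 for recovery checks (n = 4,000/4,000, 50
replicates); a three-effect whole-region benchmark (log-ORs log 2.9, log 1.4,
log 1.3; n = 5,000 cases / 9,500 controls, 25 replicates); and a six-allele
DRB1 benchmark (ORs 2.92, 1.6, 2.4, 1.6, 1.5, 0.5 at pool frequencies 0.15,
0.11, 0.015, 0.04, 0.08, 0.02; n = 15,000). The six-allele effect sizes were
set so that every planted allele carries a clearly detectable margin at this
sample size: with weaker effects (OR ≤ 1.35 on a common allele) the
compositional correlation among presence/absence markers pushes common null
alleles into the squared-error selection paths ahead of the true signals, and
no selection method — stepwise or penalized — can be expected to separate
them. The amino-acid dictionary shipped in `inst/extdata/` is synthetic,
loosely modelled on the polymorphic peptide-binding-groove positions of DRβ1
(71, 74, 57, 86, 11, 13, and one leader-peptide position with negative
numbering); it is a stand-in for real allele-to-residue alignment tables,
which are not redistributed here.

## Worked example

```{r example, eval = FALSE}
pool <- default_mhc_pool()
cfg <- simulation_config(
  strata = data.frame(name = c("A", "B"), n_cases = c(1200, 1300),
                      n_controls = c(2300, 2500)),
  effects = c("DRB1*15:01" = log(2.9), "A*02:01" = log(1.5),
              "rs2516489_T" = log(1.4)),
  n_pcs = 2, seed = 83)
coh <- sample_cohort(pool, cfg)
dm  <- encode_cohort(coh, dict = read_aa_dictionary(
  system.file("extdata", "drb1_aa_synthetic.tsv", package = "hlafinemap")))
scan <- forward_scan(dm, coh$pheno,
                     genes = c("DRB1", "DQA1", "DQB1", "A", "B", "DPB1"))
scan
variance_report(dm, coh$pheno, list(first = scan$selected[1],
                                    all = scan$selected))
```

## Known limitations

* The stepwise engine refits every candidate at every step; with thousands
  of markers and tens of thousands of subjects a scan step is quadratic-ish
  in practice. The suites run at a few hundred markers, where a full scan
  takes seconds per step.
* LARS and stagewise operate on squared-error loss after covariate
  residualization — the classical formulation — rather than the binomial
  likelihood; lasso and elastic net use the binomial deviance. Whether the
  original analyses ran the path methods on the binary outcome directly is
  not specified anywhere authoritative; both conventions are defensible and
  the squared-error default matches the classical algorithms.
* Per-gene permutation thresholds are recomputed independently per gene; no
  attempt is made to share permutations across genes.
* Expected-dosage (posterior-weighted) calls relax the group-sum invariant
  to expectation; downstream tests treat such dosages like any other design
  column, without an imputation-aware likelihood.
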