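# Forward stepwise engine: ranking, whole-region scan, within-locus
# selection, amino-acid stepwise, variance explained.

test_that("ranking is deterministic with lexicographic tie-breaks", {
  set.seed(71)
  n <- 200
  x <- rbinom(n, 2, 0.3)
  d <- cbind(m_a = x, m_b = x, m_c = rbinom(n, 2, 0.3))
  dm <- new_dosage_matrix(d, data.frame(id = colnames(d), kind = "SNP",
                                        group = colnames(d)))
  ph <- data.frame(subject_id = seq_len(n), status = rbinom(n, 1, 0.5),
                   stratum = "S1")
  r <- rank_variants(dm, ph)
  ia <- which(r$group == "m_a"); ib <- which(r$group == "m_b")
  expect_equal(abs(ia - ib), 1L)   # identical columns rank adjacently
  expect_lt(ia, ib)                # ties broken by id
  expect_identical(r, rank_variants(dm, ph))
})

test_that("null top-hit p behaves like the minimum of uniforms", {
  # independent markers, so min-p ~ Beta(1, m) exactly
  set.seed(73)
  n <- 150; m <- 15; reps <- 250
  minp <- replicate(reps, {
    d <- matrix(rbinom(n * m, 2, 0.4), n, m)
    y <- rbinom(n, 1, 0.5)
    X0 <- matrix(1, n, 1)
    f0 <- fit_logistic(X0, y)
    min(vapply(seq_len(m), function(j)
      hlafinemap:::lrt_add(y, X0, d[, j, drop = FALSE], fit0 = f0)$p, 1))
  })
  expect_gt(suppressWarnings(ks.test(minp, function(q) pbeta(q, 1, m)))$p.value, 0.01)
})

test_that("the strongest planted effect ranks first at large n", {
  cfg <- simulation_config(
    strata = data.frame(name = "S1", n = 4000, intercept = -0.5),
    effects = c("DRB1*15:01" = log(2.9), "rs2516489_T" = log(1.2)),
    n_pcs = 2, seed = 79)
  coh <- sample_cohort(default_mhc_pool(), cfg)
  dm <- encode_cohort(coh)
  r <- rank_variants(dm, coh$pheno)
  # top group must be the planted allele or one of its perfect proxies
  top <- r$group[1]
  proxies <- c("DRB1*15:01", "DRB1*15", "snp_32742280",
               equivalent_markers_of(dm, "DRB1*15:01"))
  expect_true(top %in% proxies)
})

test_that("forward scan recovers planted effects and its audit trail replays", {
  pool <- default_mhc_pool()
  cfg <- simulation_config(
    strata = data.frame(name = c("A", "B"), n_cases = c(1200, 1300),
                        n_controls = c(2300, 2500)),
    effects = c("DRB1*15:01" = log(2.9), "A*02:01" = log(1.5),
                "rs2516489_T" = log(1.4)),
    n_pcs = 2, seed = 83)
  coh <- sample_cohort(pool, cfg)
  dm <- encode_cohort(coh)
  ph <- coh$pheno
  sc <- forward_scan(dm, ph, genes = c("DRB1", "DQA1", "DQB1", "A", "B", "DPB1"))
  expect_equal(sc$stop_reason, "no-variant-and-no-gene-significant")
  # every planted effect is captured by the selection or its equivalents
  truthy <- c("DRB1*15:01", "A*02:01", "rs2516489_T")
  captured <- selection_covers(dm, sc, truthy)
  expect_true(all(captured))
  # selection soundness: each selected variant met the threshold at its step
  sel <- Filter(function(s) !is.na(s$selected), sc$steps)
  expect_true(all(vapply(sel, `[[`, 1, "log10p") <= log10(sc$threshold)))
  # stop soundness: at termination nothing reaches the threshold
  last <- sc$steps[[length(sc$steps)]]
  expect_true(is.na(last$selected))
  expect_gt(min(last$ranking$log10p, na.rm = TRUE), log10(sc$threshold))
  expect_gt(min(last$gene_residuals$log10p, na.rm = TRUE), log10(sc$threshold))
  # audit completeness: replaying each step reproduces the recorded p
  conditioning <- character(0)
  for (s in sel) {
    r <- test_variant(dm, ph, s$selected, conditioning)
    expect_equal(r$log10p, s$log10p, tolerance = 1e-8)
    conditioning <- c(conditioning, s$selected)
  }
})

test_that("a significant gene keeps the scan going when no variant qualifies", {
  # many weak spread-out DRB1 effects: no single variant reaches 1e-5 but
  # the joint locus test does, so the scan must keep adding variants until
  # the locus residual clears the threshold
  pool <- default_mhc_pool()
  cfg <- simulation_config(
    strata = data.frame(name = "S1", n = 6000, intercept = -0.4),
    effects = c("DRB1*03:01" = 0.16, "DRB1*04:01" = 0.18, "DRB1*11:01" = -0.16,
                "DRB1*07:01" = -0.15, "DRB1*12:01" = 0.17, "DRB1*01:01" = -0.16),
    n_pcs = 0, seed = 6)
  coh <- sample_cohort(pool, cfg)
  dm <- encode_cohort(coh, two_digit = FALSE)
  ph <- coh$pheno
  # the intended configuration: locus significant, no single variant is
  expect_gt(min(rank_variants(dm, ph)$log10p, na.rm = TRUE), -5)
  expect_lt(test_locus(dm, ph, "DRB1")$log10p, -5)
  sc <- forward_scan(dm, ph, genes = "DRB1")
  expect_gt(length(sc$selected), 0)
  final_gene <- sc$steps[[length(sc$steps)]]$gene_residuals
  expect_true(all(final_gene$log10p > -5 | is.na(final_gene$log10p)))
})

test_that("threshold 1 selects until variants are exhausted or aliased", {
  coh <- cohort_null(n = 300, seed = 97, pool = pool_four_hap())
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  sc <- forward_scan(dm, coh$pheno, threshold = 1, max_steps = 50)
  expect_true(sc$stop_reason %in% c("variants-exhausted", "no-testable-variant"))
  expect_gte(length(sc$selected), 3)
})

test_that("within-locus selection stops once the seed explains the locus", {
  pool <- pool_four_hap()
  cfg <- simulation_config(
    strata = data.frame(name = "S1", n = 3000, intercept = -0.5),
    effects = c("DRB1*15:01" = 0.9), n_pcs = 0, seed = 101)
  coh <- sample_cohort(pool, cfg)
  dm <- encode_cohort(coh, two_digit = FALSE)
  wl <- within_locus_selection(dm, coh$pheno, "DRB1", seed_allele = "DRB1*15:01")
  expect_equal(wl$selected, "DRB1*15:01")  # no additional alleles
  expect_equal(wl$stop_reason, "no-allele-and-no-residual-significant")
  expect_error(within_locus_selection(dm, coh$pheno, "DRB1", seed_allele = "DRB1*99"),
               "not in locus")
})

test_that("a residue partition matching the causal set wins the amino-acid stepwise", {
  # alleles A/B share residue X at position 71 and carry equal effects, so
  # position 71 perfectly captures the signal and classical alleles add nothing
  pool <- build_haplotype_pool(
    data.frame(DRB1 = c("15:01", "15:02", "03:01", "01:01")), c(0.2, 0.1, 0.3, 0.4))
  dict <- aa_dictionary(data.frame(
    gene = "DRB1",
    allele = rep(c("15:01", "15:02", "03:01", "01:01"), 2),
    position = rep(c(71L, 86L), each = 4),
    residue = c("X", "X", "Y", "Y", "V", "G", "V", "G")))
  cfg <- simulation_config(
    strata = data.frame(name = "S1", n = 4000, intercept = -0.5),
    effects = c("DRB1*15:01" = 0.7, "DRB1*15:02" = 0.7), n_pcs = 0, seed = 103)
  coh <- sample_cohort(pool, cfg)
  dm <- encode_cohort(coh, dict = dict, two_digit = FALSE)
  res <- aa_stepwise(dm, coh$pheno, "DRB1",
                     classical_alleles = c("DRB1*15:01", "DRB1*15:02"))
  expect_equal(res$positions[1], "DRB1_pos71")
  expect_gt(res$comparison$p_alleles_given_aa$p, 0.05)

  # unequal effects on alleles sharing a residue: the position cannot span
  # the causal partition, so classical alleles retain residual signal
  cfg2 <- simulation_config(
    strata = data.frame(name = "S1", n = 4000, intercept = -0.5),
    effects = c("DRB1*15:01" = 1.0), n_pcs = 0, seed = 107)
  coh2 <- sample_cohort(pool, cfg2)
  dm2 <- encode_cohort(coh2, dict = dict, two_digit = FALSE)
  res2 <- aa_stepwise(dm2, coh2$pheno, "DRB1",
                      classical_alleles = "DRB1*15:01")
  expect_lt(res2$comparison$p_alleles_given_aa$p, 0.05)
})

test_that("variance explained is zero for the empty set and monotone along chains", {
  cfg <- simulation_config(
    strata = data.frame(name = "S1", n = 2000, intercept = -0.5),
    effects = c("DRB1*15:01" = log(2.9), "A*02:01" = log(1.5)), n_pcs = 2, seed = 109)
  coh <- sample_cohort(default_mhc_pool(), cfg)
  dm <- encode_cohort(coh)
  vr <- variance_report(dm, coh$pheno, list(
    none = character(0),
    one = "DRB1*15:01",
    two = c("DRB1*15:01", "A*02:01"),
    three = c("DRB1*15:01", "A*02:01", "rs2516489_T")))
  expect_equal(vr$r2[1], 0)
  expect_true(all(diff(vr$r2) >= -1e-12))
  expect_gt(vr$r2[2], 0.05)
})
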