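# Logistic fitting, omnibus LRTs, effect comparison, interaction,
# stratification, Nagelkerke R2.

# brute-force likelihood oracle for a 1-marker model: two-stage grid search
grid_loglik <- function(y, x = NULL, b0 = seq(-4, 4, 0.02), b1 = seq(-4, 4, 0.02)) {
  ll <- function(eta) sum(y * eta - log(1 + exp(eta)))
  refine <- function(best, width, grid_fun) grid_fun(best - width, best + width)
  if (is.null(x)) {
    f <- function(lo, hi) {
      g <- seq(lo, hi, length.out = 401)
      v <- vapply(g, function(b) ll(rep(b, length(y))), 1)
      g[which.max(v)]
    }
    b <- f(-4, 4); b <- f(b - 0.05, b + 0.05)
    ll(rep(b, length(y)))
  } else {
    best <- c(0, 0); width <- 4
    for (pass in 1:3) {
      g0 <- seq(best[1] - width, best[1] + width, length.out = 81)
      g1 <- seq(best[2] - width, best[2] + width, length.out = 81)
      vals <- outer(g0, g1, Vectorize(function(a, b) ll(a + b * x)))
      ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
      best <- c(g0[ix[1]], g1[ix[2]])
      width <- width / 15
    }
    ll(best[1] + best[2] * x)
  }
}

test_that("null fit on a balanced outcome recovers the closed form", {
  y <- rep(c(0, 1), 60)
  fit <- fit_logistic(matrix(1, 120, 1), y)
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  expect_equal(fit$loglik, 120 * log(0.5), tolerance = 1e-8)
})

test_that("single-marker fit equals the 2x2 contingency log-OR", {
  # exposed: 30 cases / 70 controls; unexposed: 10 cases / 90 controls
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  fit <- fit_logistic(cbind(1, x), y)
  expect_equal(unname(fit$coef[2]), log(27 / 7), tolerance = 1e-7)
  expect_equal(unname(fit$coef[1]), log(10 / 90), tolerance = 1e-7)
})

test_that("stratum dummies recover the common within-stratum OR (Simpson structure)", {
  # two strata with exact within-stratum OR 2 and marginal OR 3.75
  cell <- function(y, x, s, n) data.frame(y = rep(y, n), x = rep(x, n), s = rep(s, n))
  d <- rbind(cell(1, 1, "A", 40), cell(0, 1, "A", 20), cell(1, 0, "A", 20), cell(0, 0, "A", 20),
             cell(1, 1, "B", 10), cell(0, 1, "B", 40), cell(1, 0, "B", 20), cell(0, 0, "B", 160))
  X_adj <- cbind(1, d$x, as.numeric(d$s == "B"))
  X_crude <- cbind(1, d$x)
  expect_equal(unname(fit_logistic(X_adj, d$y)$coef[2]), log(2), tolerance = 1e-7)
  expect_equal(unname(fit_logistic(X_crude, d$y)$coef[2]), log(3.75), tolerance = 1e-7)
})

test_that("deviance matches a grid-search likelihood oracle", {
  set.seed(4)
  n <- 60
  x <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
  fit0 <- fit_logistic(matrix(1, n, 1), y)
  fit1 <- fit_logistic(cbind(1, x), y)
  D_pkg <- lrt(fit0, fit1)$D
  D_grid <- 2 * (grid_loglik(y, x) - grid_loglik(y))
  expect_equal(D_pkg, D_grid, tolerance = 1e-4)
})

test_that("LRT handles identity, textbook quantile and extreme signals", {
  y <- rep(c(0, 1), 50)
  f <- fit_logistic(matrix(1, 100, 1), y)
  same <- lrt(f, f)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  # chi-square quantile: D = qchisq(0.95, 1) gives p = 0.05
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-6)
  # log-space tail survives far below the double underflow limit
  big <- hlafinemap:::new_lrt(1600, 1L)
  expect_lt(big$log10p, -300)
  expect_true(is.finite(big$log10p))
})

test_that("omnibus p is invariant to the reference allele (reparameterization)", {
  coh <- cohort_null(n = 400, seed = 23, pool = pool_four_hap())
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  ph <- coh$pheno
  y <- ph$status
  X0 <- matrix(1, length(y), 1)
  cols <- dm$variants$id[dm$variants$locus == "DRB1"]
  # drop each allele in turn as the reference: identical D
  Ds <- sapply(cols, function(ref) {
    keep <- setdiff(cols, ref)
    hlafinemap:::lrt_add(y, X0, dm$dosages[, keep, drop = FALSE])$D
  })
  expect_lt(max(Ds) - min(Ds), 1e-10)
})

test_that("amino-acid position 71 carries a 3-df omnibus test", {
  coh <- cohort_null(n = 500, seed = 31, pool = default_mhc_pool())
  dm <- encode_cohort(coh, dict = dict_default(), maf = NULL)
  r <- omnibus_aa_position(dm, coh$pheno, "DRB1", 71)
  expect_equal(r$k, 3L)    # 4 residues, one reference
  expect_equal(r$k_all, 3L)
})

test_that("re-testing a conditioned variant is undefined (df 0)", {
  coh <- cohort_null(n = 300, seed = 5)
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  r <- test_variant(dm, coh$pheno, "DRB1*15:01", conditioning = "DRB1*15:01")
  expect_equal(r$k, 0L)
  expect_true(is.na(r$p))
})

test_that("locus test spans the residual alleles given conditioning", {
  coh <- cohort_null(n = 400, seed = 37, pool = pool_four_hap())
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  ph <- coh$pheno
  # 3 DRB1 alleles; unconditioned: group-sum aliasing leaves k = 2
  r0 <- test_locus(dm, ph, "DRB1")
  expect_equal(r0$k, 2L)
  expect_equal(r0$k_all, 3L)
  # conditioning on one allele leaves k <= 2 over the other two
  r1 <- test_locus(dm, ph, "DRB1", conditioning = "DRB1*15:01")
  expect_lte(r1$k, 2L)
  expect_equal(r1$k_all, 2L)
})

test_that("locus omnibus p-values are uniform under the null", {
  # fast direct simulation: multinomial haplotypes at one 4-allele locus
  set.seed(101)
  n <- 150
  reps <- 300
  pvals <- replicate(reps, {
    h1 <- sample(4, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    h2 <- sample(4, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    d <- sapply(1:4, function(a) (h1 == a) + (h2 == a))
    y <- rbinom(n, 1, 0.5)
    hlafinemap:::lrt_add(y, matrix(1, n, 1), d[, -1])$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("effect comparison labels equivalence and explanation correctly", {
  # r^2 = 1: two-haplotype pool, DRB1*15:01 vs DQB1*06:02
  coh <- cohort_null(n = 500, seed = 41)
  coh$pheno$status <- rbinom(500, 1, plogis(-0.5 + 0.8 *
    binarize_classical(coh, "DRB1")$dosages[, "DRB1*15:01"]))
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  cmp <- compare_effects(dm, coh$pheno, "DRB1*15:01", "DQB1*06:02")
  expect_equal(cmp$label, "equivalent")

  # causal A with partial tag B: A explains B at large n
  pool <- build_haplotype_pool(
    data.frame(DRB1 = c("15:01", "15:01", "03:01", "03:01"),
               DQB1 = c("06:02", "05:01", "05:01", "02:01")),
    c(0.3, 0.1, 0.2, 0.4))
  cfg <- simulation_config(strata = data.frame(name = "S1", n = 6000, intercept = -0.5),
                           effects = c("DRB1*15:01" = 0.7), n_pcs = 0, seed = 43)
  coh2 <- sample_cohort(pool, cfg)
  dm2 <- encode_cohort(coh2, maf = NULL, two_digit = FALSE)
  cmp2 <- compare_effects(dm2, coh2$pheno, "DRB1*15:01", "DQB1*06:02")
  expect_equal(cmp2$label, "DRB1*15:01 explains DQB1*06:02")

  # identical columns are rejected
  expect_error(compare_effects(dm, coh$pheno, "DRB1*15:01", "DRB1*15:01"), "identical")
})

test_that("independent causal markers are both retained by the comparison", {
  pool <- build_haplotype_pool(
    data.frame(DRB1 = c("15:01", "15:01", "03:01", "03:01"),
               B = c("37:01", "07:02", "37:01", "07:02")),
    c(0.12, 0.18, 0.28, 0.42))
  cfg <- simulation_config(strata = data.frame(name = "S1", n = 6000, intercept = -0.6),
                           effects = c("DRB1*15:01" = 0.6, "B*37:01" = 0.5),
                           n_pcs = 0, seed = 47)
  coh <- sample_cohort(pool, cfg)
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  cmp <- compare_effects(dm, coh$pheno, "DRB1*15:01", "B*37:01")
  expect_equal(cmp$label, "independent")
})

test_that("interaction test finds a planted product effect and rejects aliased input", {
  pool <- build_haplotype_pool(
    data.frame(DRB1 = c("15:01", "15:01", "03:01", "03:01"),
               B = c("37:01", "07:02", "37:01", "07:02")),
    c(0.2, 0.3, 0.25, 0.25))
  cfg <- simulation_config(strata = data.frame(name = "S1", n = 4000, intercept = -0.5),
                           n_pcs = 0, seed = 53)
  coh <- sample_cohort(pool, cfg)
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  dA <- dm$dosages[, "DRB1*15:01"]; dB <- dm$dosages[, "B*37:01"]
  coh$pheno$status <- rbinom(4000, 1, plogis(-0.5 + 0.2 * dA + 0.1 * dB + 0.6 * dA * dB))
  r <- interaction_test(dm, coh$pheno, "DRB1*15:01", "B*37:01")
  expect_equal(r$k, 1L)
  expect_lt(r$p, 0.05)
  # constant column is aliased
  dmc <- dm; dmc$dosages[, "B*07:02"] <- 1
  expect_error(interaction_test(dmc, coh$pheno, "DRB1*15:01", "B*07:02"), "constant")
})

test_that("carrier stratification recovers within-stratum effects", {
  # index-independent marker: stratum ORs track the marginal OR
  pool <- build_haplotype_pool(
    data.frame(DRB1 = c("15:01", "15:01", "03:01", "03:01"),
               B = c("37:01", "07:02", "37:01", "07:02")),
    c(0.15, 0.25, 0.25, 0.35))
  cfg <- simulation_config(strata = data.frame(name = "S1", n = 6000, intercept = -0.4),
                           effects = c("B*37:01" = 0.45), n_pcs = 0, seed = 59)
  coh <- sample_cohort(pool, cfg)
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  sc <- stratified_scan(dm, coh$pheno, "DRB1*15:01", "B*37:01")
  ors <- sc$OR[match(c("all", "carrier", "noncarrier"), sc$stratum)]
  expect_true(all(ors > 1))
  expect_lt(abs(log(ors[2]) - log(ors[3])), 0.5)
  # empty stratum errors
  dmall <- dm; dmall$dosages[, "DRB1*15:01"] <- 1
  expect_error(stratified_scan(dmall, coh$pheno, "DRB1*15:01", "B*37:01"), "empty stratum")
})

test_that("Nagelkerke R2 matches direct arithmetic and its bounds", {
  expect_equal(nagelkerke_r2(-50, -50, N = 100), 0)
  # independent arithmetic on the closed form
  L0 <- -69.31; L1 <- -59.31; N <- 100
  expected <- (1 - exp(-0.2)) / (1 - exp(2 * L0 / N))
  expect_equal(nagelkerke_r2(L0, L1, N = N), expected, tolerance = 1e-12)
  # saturated fit approaches the upper bound
  expect_equal(nagelkerke_r2(-200, 0, N = 80), 1, tolerance = 1e-6)
  expect_error(nagelkerke_r2(-10, -20, N = 50), "lower likelihood")
})

test_that("deviances add along a conditioning chain", {
  coh <- cohort_null(n = 500, seed = 61, pool = pool_four_hap())
  dm <- encode_cohort(coh, maf = NULL, two_digit = FALSE)
  y <- coh$pheno$status
  X0 <- matrix(1, 500, 1)
  a <- dm$dosages[, "DRB1*15:01", drop = FALSE]
  b <- dm$dosages[, "DQB1*06:02", drop = FALSE]
  D_0A <- hlafinemap:::lrt_add(y, X0, a)$D
  D_A_AB <- hlafinemap:::lrt_add(y, cbind(X0, a), b)$D
  D_0AB <- hlafinemap:::lrt_add(y, X0, cbind(a, b))$D
  expect_equal(D_0AB, D_0A + D_A_AB, tolerance = 1e-6)
})

test_that("eight strata produce seven dummy covariates in the design", {
  ph <- data.frame(subject_id = sprintf("S%03d", 1:160),
                   status = rep(0:1, 80),
                   stratum = rep(table1_strata()$name, each = 20))
  X <- hlafinemap:::base_covariates(ph)
  expect_equal(sum(grepl("^stratum_", colnames(X))), 7L)
})
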