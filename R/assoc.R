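#' Omnibus association test of one variant
#'
#' Jointly tests all p-1 allele markers of a testing group (a SNP, a
#' classical allele, an amino-acid position or a diplotype) against the same
#' model without them, by likelihood-ratio test. The reference allele — the
#' group's most frequent marker among controls — is excluded from the design.
#' Conditional tests are obtained by naming previously selected groups in
#' \code{conditioning}; their p-1 columns are held in the model for both the
#' null and the fitted side.
#'
#' @param dm a \code{dosage_matrix}.
#' @param pheno phenotype/covariate data.frame (\code{status}, \code{stratum},
#'   \code{PC*} columns).
#' @param group testing-group id (a value of \code{dm$variants$group}).
#' @param conditioning character vector of group ids held as covariates.
#' @param .base optional precomputed list(Xbase, fit0) for repeated scans.
#' @return An \code{hla_lrt} with the group id, the number of offered columns
#'   (\code{k_all}) and an \code{unstable} flag (non-convergence/separation).
#'   A group entirely aliased by the conditioning set yields df 0 and p NA.
#' @export
test_variant <- function(dm, pheno, group, conditioning = character(0), .base = NULL) {
  y <- pheno$status
  cols <- group_columns(dm, pheno, group)
  if (is.null(.base)) .base <- conditional_base(dm, pheno, conditioning)
  Xadd <- dm$dosages[, cols, drop = FALSE]
  res <- lrt_add(y, .base$X, Xadd, fit0 = .base$fit0)
  if (res$k == 0L) { res$p <- NA_real_; res$log10p <- NA_real_ }  # fully aliased: undefined
  res$group <- group
  res$k_all <- length(cols)
  res$unstable <- !res$fit1$converged || res$fit1$separated
  res$fit0 <- NULL
  res
}

# Base design (covariates + conditioning columns) and its fit, reusable
# across the variants of one scan step.
conditional_base <- function(dm, pheno, conditioning) {
  X <- base_covariates(pheno)
  if (length(conditioning)) {
    cc <- expand_conditioning(dm, pheno, conditioning)
    X <- cbind(X, dm$dosages[, cc, drop = FALSE])
  }
  list(X = X, fit0 = fit_logistic(X, pheno$status))
}

#' Locus-level (gene) residual test
#'
#' Joint likelihood-ratio test of all the gene's four-digit allele markers
#' that are not already in the conditioning set — the "residual locus
#' effect". Because a locus' markers sum to 2 per subject, one column is
#' always aliased against the intercept at step 0; the reported \code{k} is
#' the post-aliasing rank and \code{k_all} the number of columns offered, so
#' both df conventions are visible.
#'
#' @inheritParams test_variant
#' @param gene HLA gene name, e.g. \code{"DRB1"}.
#' @return An \code{hla_lrt} (df 0 / p NA when every allele is aliased).
#' @export
test_locus <- function(dm, pheno, gene, conditioning = character(0), .base = NULL) {
  v <- dm$variants
  ids <- v$id[v$kind == "HLA4d" & v$locus == gene]
  if (length(ids) == 0L) stopf("no four-digit markers for gene '%s'", gene)
  cond_cols <- if (length(conditioning)) expand_conditioning(dm, pheno, conditioning)
               else character(0)
  ids <- setdiff(ids, cond_cols)
  # alleles of this locus already conditioned on also remove their own column
  cond_groups_here <- v$id[v$id %in% conditioning & v$locus == gene]
  ids <- setdiff(ids, cond_groups_here)
  if (length(ids) == 0L) return(new_lrt(0, 0L, list(group = gene, k_all = 0L)))
  if (is.null(.base)) .base <- conditional_base(dm, pheno, conditioning)
  y <- pheno$status
  res <- lrt_add(y, .base$X, dm$dosages[, ids, drop = FALSE], fit0 = .base$fit0)
  res$group <- gene
  res$k_all <- length(ids)
  res$unstable <- !res$fit1$converged || res$fit1$separated
  res$fit0 <- NULL
  res
}

#' Omnibus test of an amino-acid position
#'
#' Tests all but one residue markers of a translated position, optionally
#' conditional on other variants. A thin wrapper over [test_variant()] using
#' the position's group id.
#'
#' @inheritParams test_variant
#' @param gene gene name; @param position integer position (may be negative
#'   for the leader peptide).
#' @return An \code{hla_lrt}.
#' @export
omnibus_aa_position <- function(dm, pheno, gene, position, conditioning = character(0),
                                .base = NULL) {
  group <- sprintf("%s_pos%d", gene, as.integer(position))
  if (!group %in% dm$variants$group)
    stopf("position %d of %s not present (monomorphic or untranslated)", position, gene)
  test_variant(dm, pheno, group, conditioning, .base = .base)
}

#' Pairwise effect comparison (conditional cross-tests)
#'
#' Fits M_A, M_B and M_AB on identical covariates and reports the two
#' conditional tests: A given B (M_AB vs M_B) and B given A (M_AB vs M_A),
#' judged at the nominal 0.05 level. Labels: \code{"equivalent"} (neither
#' adds), \code{"A explains B"}, \code{"B explains A"}, or
#' \code{"independent"} (both add).
#'
#' @inheritParams test_variant
#' @param A,B testing-group ids.
#' @param alpha nominal level for the labels.
#' @return List with \code{p_A_given_B}, \code{p_B_given_A} (as
#'   \code{hla_lrt}) and \code{label}.
#' @export
compare_effects <- function(dm, pheno, A, B, conditioning = character(0), alpha = 0.05) {
  colsA <- group_columns(dm, pheno, A)
  colsB <- group_columns(dm, pheno, B)
  if (setequal(colsA, colsB)) stopf("A and B are identical marker sets")
  base <- conditional_base(dm, pheno, conditioning)
  y <- pheno$status
  XA <- dm$dosages[, colsA, drop = FALSE]
  XB <- dm$dosages[, colsB, drop = FALSE]
  fitA <- fit_logistic(cbind(base$X, XA), y)
  fitB <- fit_logistic(cbind(base$X, XB), y)
  fitAB <- fit_logistic(cbind(base$X, XA, XB), y)
  a_given_b <- lrt(fitB, fitAB)
  b_given_a <- lrt(fitA, fitAB)
  sig <- function(l) !is.na(l$p) && l$p <= alpha
  label <-
    if (!sig(a_given_b) && !sig(b_given_a)) "equivalent"
    else if (sig(a_given_b) && !sig(b_given_a)) sprintf("%s explains %s", A, B)
    else if (!sig(a_given_b) && sig(b_given_a)) sprintf("%s explains %s", B, A)
    else "independent"
  list(p_A_given_B = a_given_b, p_B_given_A = b_given_a, label = label)
}

#' Interaction (product-term) test for two markers
#'
#' Likelihood-ratio test of the saturated model {A, B, A x B} against the
#' additive model {A, B}, one degree of freedom, on shared covariates and
#' conditioning.
#'
#' @inheritParams test_variant
#' @param A,B single marker column ids (scalar dosages).
#' @return An \code{hla_lrt}.
#' @export
interaction_test <- function(dm, pheno, A, B, conditioning = character(0)) {
  for (id in c(A, B)) if (!id %in% dm$variants$id) stopf("unknown marker '%s'", id)
  a <- dm$dosages[, A]; b <- dm$dosages[, B]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stopf("constant marker column")
  base <- conditional_base(dm, pheno, conditioning)
  Xab <- cbind(a, b); colnames(Xab) <- c(A, B)
  y <- pheno$status
  fit_add <- fit_logistic(cbind(base$X, Xab), y)
  prod_col <- matrix(a * b, dimnames = list(NULL, paste0(A, ":", B)))
  fit_sat <- fit_logistic(cbind(base$X, Xab, prod_col), y)
  if (fit_sat$df == fit_add$df) stopf("product column aliased")
  res <- lrt(fit_add, fit_sat)
  res$group <- paste0(A, ":", B)
  res
}

#' Carrier-stratified univariate scan
#'
#' Splits subjects into carriers (one or two copies) and non-carriers of an
#' index marker and fits the univariate model for each query marker within
#' each stratum, reporting OR with 95\% CI and the 1-df likelihood-ratio
#' p-value. Used to expose Simpson's-paradox structure, where a marginally
#' silent marker shows the same direction of effect in both strata.
#'
#' @inheritParams test_variant
#' @param index_id marker column defining carrier status.
#' @param variant_ids marker columns to test within each stratum.
#' @return data.frame: stratum, variant, n, OR, lo95, hi95, log10p.
#' @export
stratified_scan <- function(dm, pheno, index_id, variant_ids) {
  if (!index_id %in% dm$variants$id) stopf("unknown index marker '%s'", index_id)
  carrier <- dm$dosages[, index_id] > 0
  groups <- list(all = rep(TRUE, length(carrier)), carrier = carrier,
                 noncarrier = !carrier)
  out <- list()
  for (gname in names(groups)) {
    sel <- groups[[gname]]
    if (!any(sel)) stopf("empty stratum '%s'", gname)
    ph <- pheno[sel, , drop = FALSE]
    if (length(unique(ph$status)) < 2L) stopf("stratum '%s' has a single outcome class", gname)
    X0 <- base_covariates(ph)
    fit0 <- fit_logistic(X0, ph$status)
    for (v in variant_ids) {
      x <- dm$dosages[sel, v, drop = FALSE]
      fit1 <- fit_logistic(cbind(X0, x), ph$status)
      l <- lrt(fit0, fit1)
      beta <- fit1$coef[v]; se <- fit1$se[v]
      out[[length(out) + 1L]] <- data.frame(
        stratum = gname, variant = v, n = sum(sel),
        OR = exp(beta), lo95 = exp(beta - 1.96 * se), hi95 = exp(beta + 1.96 * se),
        log10p = l$log10p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Association scan over all testing groups
#'
#' Runs [test_variant()] for every testing group in the matrix (optionally
#' conditional) and returns a ranked table, the per-variant surface behind
#' regional association plots.
#'
#' @inheritParams test_variant
#' @param groups group ids to test; default every group in the matrix.
#' @return data.frame sorted by p: group, kind, k, k_all, D, log10p, p,
#'   unstable.
#' @export
assoc_scan <- function(dm, pheno, conditioning = character(0), groups = NULL) {
  v <- dm$variants
  if (is.null(groups)) groups <- unique(v$group)
  base <- conditional_base(dm, pheno, conditioning)
  res <- lapply(groups, function(g)
    test_variant(dm, pheno, g, conditioning, .base = base))
  out <- data.frame(
    group = groups, kind = v$kind[match(groups, v$group)],
    k = vapply(res, `[[`, 1L, "k"), k_all = vapply(res, `[[`, 1L, "k_all"),
    D = vapply(res, `[[`, 1, "D"), log10p = vapply(res, `[[`, 1, "log10p"),
    p = vapply(res, `[[`, 1, "p"),
    unstable = vapply(res, `[[`, TRUE, "unstable"), stringsAsFactors = FALSE)
  out[order(out$log10p, -out$D, out$group, na.last = TRUE), ]
}
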