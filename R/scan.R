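#' Rank variants by conditional omnibus p-value
#'
#' Tests every candidate testing group given the conditioning set and returns
#' a stable total order: ascending log10 p, then descending deviance, then
#' lexicographic group id. Groups flagged unstable (non-convergence or
#' separation) and groups with no estimable parameters sort last and are
#' never selected by the stepwise engine.
#'
#' @inheritParams test_variant
#' @param groups candidate group ids (default: all groups not conditioned on).
#' @return data.frame as [assoc_scan()], in rank order.
#' @export
rank_variants <- function(dm, pheno, conditioning = character(0), groups = NULL) {
  if (is.null(groups)) groups <- setdiff(unique(dm$variants$group), conditioning)
  if (length(groups) == 0L) stopf("no candidate variants to rank")
  assoc_scan(dm, pheno, conditioning, groups)
}

# ids of markers that are perfect proxies (r^2 = 1) of any column of a group
equivalent_markers <- function(dm, group) {
  ix <- which(dm$variants$group == group)
  others <- setdiff(seq_len(ncol(dm$dosages)), ix)
  hits <- character(0)
  for (j in ix) {
    x <- dm$dosages[, j]
    if (stats::sd(x) == 0) next
    r2 <- suppressWarnings(stats::cor(x, dm$dosages[, others, drop = FALSE]))^2
    hits <- c(hits, dm$variants$id[others][which(r2 > 1 - 1e-12)])
  }
  unique(hits)
}

#' Forward stepwise scan for statistically independent effects
#'
#' At each step every remaining variant is tested conditional on the current
#' set, variants are ranked by omnibus p, and the top variant enters the
#' conditioning set (all p-1 allele columns of a multi-allelic group enter
#' together). Locus-level residual tests are recomputed for each HLA gene at
#' each step. The scan stops only when no variant \emph{and} no gene residual
#' reaches the significance threshold: if no single variant is significant
#' but a gene still is, variants keep being added until the gene residual
#' clears the threshold. Variants with r^2 = 1 to a selected variant are
#' annotated as statistically equivalent rather than re-tested.
#'
#' @inheritParams test_variant
#' @param genes HLA gene names receiving locus residual tests.
#' @param threshold per-step significance threshold (default
#'   [bonferroni_threshold()], 1e-5).
#' @param max_steps safety cap on selections.
#' @param groups candidate group ids (default: all).
#' @param top_m number of ranked candidates recorded per step.
#' @return An object of class \code{hla_scan}: \code{steps} (per-step
#'   records: ranking head, selected group, D/k/log10p, gene residual table,
#'   equivalent markers), \code{selected}, \code{stop_reason},
#'   \code{threshold}.
#' @export
forward_scan <- function(dm, pheno, genes = character(0),
                         threshold = bonferroni_threshold(), max_steps = 25,
                         groups = NULL, top_m = 10) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(groups)) groups <- unique(dm$variants$group)
  conditioning <- character(0)
  steps <- list()
  stop_reason <- "max-steps"
  log10thr <- log10(threshold)

  for (step in seq_len(max_steps)) {
    cand <- setdiff(groups, conditioning)
    if (length(cand) == 0L) { stop_reason <- "variants-exhausted"; break }
    base <- conditional_base(dm, pheno, conditioning)
    ranking <- assoc_scan(dm, pheno, conditioning, cand)
    gene_res <- if (length(genes)) {
      do.call(rbind, lapply(genes, function(g) {
        r <- test_locus(dm, pheno, g, conditioning, .base = base)
        data.frame(gene = g, k = r$k, k_all = r$k_all, D = r$D,
                   log10p = r$log10p, stringsAsFactors = FALSE)
      }))
    } else NULL
    ok <- !ranking$unstable & !is.na(ranking$log10p)
    if (!any(ok)) { stop_reason <- "no-testable-variant"; break }
    best <- ranking[ok, ][1, ]
    variant_sig <- best$log10p <= log10thr
    gene_sig <- !is.null(gene_res) && any(gene_res$log10p <= log10thr, na.rm = TRUE)
    if (!variant_sig && !gene_sig) {
      stop_reason <- "no-variant-and-no-gene-significant"
      steps[[length(steps) + 1L]] <- list(
        step = step, ranking = utils::head(ranking, top_m), selected = NA_character_,
        D = NA_real_, k = NA_integer_, log10p = NA_real_,
        gene_residuals = gene_res, equivalent = character(0))
      break
    }
    conditioning <- c(conditioning, best$group)
    steps[[length(steps) + 1L]] <- list(
      step = step, ranking = utils::head(ranking, top_m), selected = best$group,
      D = best$D, k = best$k, log10p = best$log10p,
      gene_residuals = gene_res, equivalent = equivalent_markers(dm, best$group))
  }

  structure(list(steps = steps, selected = conditioning,
                 stop_reason = stop_reason, threshold = threshold),
            class = "hla_scan")
}

#' @export
print.hla_scan <- function(x, ...) {
  cat(sprintf("Forward stepwise scan: %d effect(s) selected (threshold %.1g, stop: %s)\n",
              length(x$selected), x$threshold, x$stop_reason))
  for (s in x$steps) {
    if (is.na(s$selected)) next
    cat(sprintf("  step %d: %s (df = %d, D = %.1f, log10 p = %.2f)%s\n",
                s$step, s$selected, s$k, s$D, s$log10p,
                if (length(s$equivalent))
                  sprintf("  [equivalent: %s]", paste(s$equivalent, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' @export
summary.hla_scan <- function(object, ...) {
  sel <- Filter(function(s) !is.na(s$selected), object$steps)
  data.frame(
    step = vapply(sel, `[[`, 1L, "step"),
    selected = vapply(sel, `[[`, "", "selected"),
    k = vapply(sel, `[[`, 1L, "k"),
    D = vapply(sel, `[[`, 1, "D"),
    log10p = vapply(sel, `[[`, 1, "log10p"),
    stringsAsFactors = FALSE)
}

#' Stepwise selection of alleles within one locus
#'
#' Starting from an optional seed allele, repeatedly adds the locus'
#' most significant remaining four-digit allele. The stopping rule mirrors
#' the whole-region scan, restricted to one gene: selection continues while
#' either the best remaining allele or the joint residual test of the
#' remaining alleles reaches the threshold, and stops only when both clear
#' it. (A residual-only rule is fragile: a single strongly associated rare
#' allele can be diluted below threshold by the residual test's many
#' degrees of freedom.)
#'
#' @inheritParams test_variant
#' @param locus HLA gene name.
#' @param seed_allele optional allele id (e.g. \code{"DRB1*15:01"}) taken as
#'   the first selection.
#' @param threshold stopping threshold, default 1e-5.
#' @param max_steps cap on selections.
#' @return List: \code{selected} allele ids in order, \code{path} data.frame
#'   (step, selected, log10p of the allele, residual locus log10p before
#'   selection), \code{stop_reason}.
#' @export
within_locus_selection <- function(dm, pheno, locus, seed_allele = NULL,
                                   threshold = bonferroni_threshold(),
                                   max_steps = 25) {
  v <- dm$variants
  alleles <- v$id[v$kind == "HLA4d" & v$locus == locus]
  if (length(alleles) == 0L) stopf("no four-digit markers for locus '%s'", locus)
  conditioning <- character(0)
  if (!is.null(seed_allele)) {
    if (!seed_allele %in% alleles) stopf("seed allele '%s' not in locus %s", seed_allele, locus)
    conditioning <- seed_allele
  }
  log10thr <- log10(threshold)
  path <- list()
  stop_reason <- "max-steps"
  repeat {
    if (length(conditioning) >= max_steps) break
    cand <- setdiff(alleles, conditioning)
    if (length(cand) == 0L) { stop_reason <- "alleles-exhausted"; break }
    res <- test_locus(dm, pheno, locus, conditioning)
    residual_sig <- !is.na(res$log10p) && res$log10p <= log10thr
    ranking <- rank_variants(dm, pheno, conditioning, groups = cand)
    ok <- !ranking$unstable & !is.na(ranking$log10p)
    if (!any(ok)) { stop_reason <- "no-testable-allele"; break }
    best <- ranking[ok, ][1, ]
    best_sig <- best$log10p <= log10thr
    if (!residual_sig && !best_sig) {
      stop_reason <- "no-allele-and-no-residual-significant"; break
    }
    conditioning <- c(conditioning, best$group)
    path[[length(path) + 1L]] <- data.frame(
      step = length(conditioning), selected = best$group, log10p = best$log10p,
      residual_log10p_before = res$log10p, stringsAsFactors = FALSE)
  }
  list(selected = conditioning,
       path = if (length(path)) do.call(rbind, path) else NULL,
       stop_reason = stop_reason)
}

#' Forward stepwise over amino-acid positions, with model comparison
#'
#' Selects amino-acid positions of one gene in a forward stepwise fashion
#' (each step adds all but one residues of the currently most significant
#' position), then compares the selected-positions model against a
#' classical-allele model by the paired conditional-LRT device: each block is
#' tested given the other, on shared covariates.
#'
#' @inheritParams test_variant
#' @param gene gene name.
#' @param threshold per-step threshold, default 1e-5.
#' @param classical_alleles optional classical allele ids (e.g. the stepwise
#'   selection) for the final model comparison.
#' @param max_steps cap on positions selected.
#' @return List: \code{positions} (ordered group ids), \code{path}
#'   data.frame, and when classical alleles were supplied a
#'   \code{comparison} list with \code{p_alleles_given_aa} and
#'   \code{p_aa_given_alleles} (\code{hla_lrt}).
#' @export
aa_stepwise <- function(dm, pheno, gene, threshold = bonferroni_threshold(),
                        classical_alleles = NULL, max_steps = 25) {
  v <- dm$variants
  pos_groups <- unique(v$group[v$kind == "AA" & v$locus == gene])
  if (length(pos_groups) == 0L) stopf("no polymorphic amino-acid positions for '%s'", gene)
  conditioning <- character(0)
  log10thr <- log10(threshold)
  path <- list()
  repeat {
    cand <- setdiff(pos_groups, conditioning)
    if (length(cand) == 0L || length(conditioning) >= max_steps) break
    ranking <- rank_variants(dm, pheno, conditioning, groups = cand)
    ok <- !ranking$unstable & !is.na(ranking$log10p)
    if (!any(ok)) break
    best <- ranking[ok, ][1, ]
    if (best$log10p > log10thr) break
    conditioning <- c(conditioning, best$group)
    path[[length(path) + 1L]] <- data.frame(
      step = length(conditioning), position = best$group, k = best$k,
      D = best$D, log10p = best$log10p, stringsAsFactors = FALSE)
  }
  out <- list(positions = conditioning,
              path = if (length(path)) do.call(rbind, path) else NULL)
  if (!is.null(classical_alleles) && length(conditioning)) {
    y <- pheno$status
    X0 <- base_covariates(pheno)
    aa_cols <- expand_conditioning(dm, pheno, conditioning)
    al_cols <- expand_conditioning(dm, pheno, classical_alleles)
    fit_aa <- fit_logistic(cbind(X0, dm$dosages[, aa_cols, drop = FALSE]), y)
    fit_al <- fit_logistic(cbind(X0, dm$dosages[, al_cols, drop = FALSE]), y)
    fit_both <- fit_logistic(
      cbind(X0, dm$dosages[, union(aa_cols, al_cols), drop = FALSE]), y)
    out$comparison <- list(
      p_alleles_given_aa = lrt(fit_aa, fit_both),
      p_aa_given_alleles = lrt(fit_al, fit_both))
  }
  out
}

#' Variance explained by sets of effects
#'
#' Nagelkerke pseudo-R-squared of each requested model (covariates plus the
#' named testing groups) against the covariate-only null. Along a nested
#' chain of sets the values are monotone non-decreasing.
#'
#' @inheritParams test_variant
#' @param sets named list of character vectors of group ids (an empty vector
#'   gives 0).
#' @return data.frame: model, n_groups, df, r2.
#' @export
variance_report <- function(dm, pheno, sets) {
  stopifnot(is.list(sets))
  if (is.null(names(sets))) names(sets) <- paste0("model", seq_along(sets))
  y <- pheno$status
  X0 <- base_covariates(pheno)
  fit0 <- fit_logistic(X0, y)
  rows <- lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    if (length(ids) == 0L)
      return(data.frame(model = nm, n_groups = 0L, df = 0L, r2 = 0,
                        stringsAsFactors = FALSE))
    cols <- expand_conditioning(dm, pheno, ids)
    fit1 <- fit_logistic(cbind(X0, dm$dosages[, cols, drop = FALSE]), y)
    data.frame(model = nm, n_groups = length(ids), df = fit1$df - fit0$df,
               r2 = nagelkerke_r2(fit0, fit1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
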