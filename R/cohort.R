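#' Simulation configuration for a case-control MHC cohort
#'
#' Defines the study conditions under which [sample_cohort()] draws a phased
#' cohort: per-stratum sample sizes and baseline log-odds, additive per-allele
#' log-odds effects on named markers, and a principal-component covariate
#' model. Effects are additive on the log-odds scale and shared (fixed) across
#' strata, matching the fixed-effect pooled model the association stage fits.
#'
#' @param strata data.frame describing the study strata. Either columns
#'   \code{name}, \code{n}, \code{intercept} (natural sampling: \code{n}
#'   subjects whose case/control split emerges from the stratum baseline), or
#'   columns \code{name}, \code{n_cases}, \code{n_controls} and optionally
#'   \code{intercept} (exact sampling: subjects are drawn until the requested
#'   case and control counts are hit).
#' @param effects named numeric vector of per-allele log-odds, keyed by marker
#'   id: \code{"DRB1*15:01"} (classical allele), \code{"rs2516489_T"} (SNP
#'   allele), or \code{"DRB1*15:01-DQB1*06:02"} (cis diplotype).
#' @param n_pcs number of simulated principal components (standard normal).
#' @param pc_effects log-odds per PC unit; recycled to \code{n_pcs}.
#' @param seed integer seed making the draw reproducible.
#' @return An object of class \code{hla_sim_config}.
#' @export
simulation_config <- function(strata, effects = numeric(0), n_pcs = 5,
                              pc_effects = 0, seed = 1L) {
  strata <- as.data.frame(strata, stringsAsFactors = FALSE)
  exact <- all(c("n_cases", "n_controls") %in% names(strata))
  if (!exact && !all(c("n", "intercept") %in% names(strata)))
    stopf("strata needs either (name, n, intercept) or (name, n_cases, n_controls)")
  if (is.null(strata$name)) strata$name <- paste0("S", seq_len(nrow(strata)))
  if (exact) {
    if (any(strata$n_cases <= 0) || any(strata$n_controls <= 0))
      stopf("per-stratum case and control counts must be positive")
    if (is.null(strata$intercept))
      strata$intercept <- log(strata$n_cases / strata$n_controls)
  } else if (any(strata$n <= 0)) stopf("per-stratum n must be positive")
  if (length(effects) && is.null(names(effects))) stopf("effects must be named by marker id")
  structure(
    list(strata = strata, exact = exact, effects = effects,
         n_pcs = as.integer(n_pcs),
         pc_effects = rep_len(as.numeric(pc_effects), as.integer(n_pcs)),
         seed = as.integer(seed)),
    class = "hla_sim_config")
}

#' The eight GWAS strata of the reference study design
#'
#' Case/control targets for the eight strata used as the package's standard
#' multi-study condition (totals 5,091 cases and 9,595 controls).
#'
#' @return data.frame with columns \code{name}, \code{n_cases},
#'   \code{n_controls}.
#' @export
table1_strata <- function() {
  data.frame(
    name = c("GeneMSA_DU", "GeneMSA_US", "GeneMSA_SW", "IMSGC", "BWH",
             "ANZgene", "Rotterdam", "KaiserPermanente"),
    n_cases    = c(219L, 437L, 239L, 790L, 821L, 1582L, 459L, 544L),
    n_controls = c(225L, 402L, 190L, 1677L, 2705L, 1949L, 1938L, 513L),
    stringsAsFactors = FALSE)
}

# dosage (0/1/2 per subject) of one marker id given two haplotype index vectors
# into the pool's haplotype table
marker_dosage <- function(pool, h1, h2, id) {
  haps <- pool$haplotypes
  carries <- function(id1) {
    if (grepl("-", id1, fixed = TRUE) && grepl("\\*", id1)) {
      parts <- strsplit(id1, "-", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stopf("bad diplotype id '%s'", id1)
      Reduce(`&`, lapply(parts, carries))
    } else if (grepl("*", id1, fixed = TRUE)) {
      la <- strsplit(id1, "*", fixed = TRUE)[[1]]
      if (!la[1] %in% names(haps)) stopf("effect references unknown locus '%s'", la[1])
      haps[[la[1]]] == la[2]
    } else {
      snp <- sub("_[^_]+$", "", id1)
      allele <- sub("^.*_", "", id1)
      if (!snp %in% names(haps)) stopf("effect references unknown variant '%s'", id1)
      haps[[snp]] == allele
    }
  }
  cv <- carries(id)
  as.numeric(cv[h1]) + as.numeric(cv[h2])
}

#' Draw a phased case-control cohort from a haplotype pool
#'
#' Each subject receives two independent haplotype draws from the pool
#' (Hardy-Weinberg within stratum); case status is Bernoulli with
#' \eqn{P(\mathrm{case}) = \mathrm{logit}^{-1}(\beta_{0s} + \sum_m \beta_m d_m
#' + \sum_k \gamma_k \mathrm{PC}_k)} where \eqn{d_m} is the subject's dosage
#' of effect marker \eqn{m} and \eqn{\beta_{0s}} the stratum baseline. In
#' exact mode, draws continue until each stratum holds exactly its requested
#' case and control counts.
#'
#' @param pool an [build_haplotype_pool()] object.
#' @param config an [simulation_config()].
#' @return An object of class \code{hla_cohort}: phased calls (\code{hap1},
#'   \code{hap2} character matrices, subjects x loci), a
#'   phenotype/covariate data.frame (\code{subject_id}, \code{status},
#'   \code{stratum}, \code{PC1..PCk}) and a \code{truth} record of the planted
#'   effects and pool.
#' @export
sample_cohort <- function(pool, config) {
  stopifnot(inherits(pool, "hla_pool"), inherits(config, "hla_sim_config"))
  set.seed(config$seed)
  H <- nrow(pool$haplotypes)
  loci <- names(pool$haplotypes)
  eff <- config$effects

  draw_batch <- function(n, intercept) {
    h1 <- sample.int(H, n, replace = TRUE, prob = pool$frequencies)
    h2 <- sample.int(H, n, replace = TRUE, prob = pool$frequencies)
    eta <- rep(intercept, n)
    for (id in names(eff)) eta <- eta + eff[[id]] * marker_dosage(pool, h1, h2, id)
    pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
    if (config$n_pcs > 0) eta <- eta + drop(pcs %*% config$pc_effects)
    y <- stats::rbinom(n, 1L, logistic(eta))
    list(h1 = h1, h2 = h2, y = y, pcs = pcs)
  }

  out <- list()
  for (s in seq_len(nrow(config$strata))) {
    st <- config$strata[s, ]
    if (!config$exact) {
      b <- draw_batch(st$n, st$intercept)
    } else {
      want <- c(st$n_cases, st$n_controls)
      acc <- list(h1 = integer(0), h2 = integer(0), y = integer(0),
                  pcs = matrix(0, 0, config$n_pcs))
      while (sum(acc$y == 1L) < want[1] || sum(acc$y == 0L) < want[2]) {
        b <- draw_batch(max(2L * sum(want), 200L), st$intercept)
        keep1 <- which(b$y == 1L)[seq_len(min(want[1] - sum(acc$y == 1L), sum(b$y == 1L)))]
        keep0 <- which(b$y == 0L)[seq_len(min(want[2] - sum(acc$y == 0L), sum(b$y == 0L)))]
        keep <- sort(c(keep1, keep0))
        acc <- list(h1 = c(acc$h1, b$h1[keep]), h2 = c(acc$h2, b$h2[keep]),
                    y = c(acc$y, b$y[keep]), pcs = rbind(acc$pcs, b$pcs[keep, , drop = FALSE]))
      }
      b <- acc
    }
    out[[s]] <- b
  }

  h1 <- unlist(lapply(out, `[[`, "h1"))
  h2 <- unlist(lapply(out, `[[`, "h2"))
  y <- unlist(lapply(out, `[[`, "y"))
  pcs <- do.call(rbind, lapply(out, `[[`, "pcs"))
  stratum <- rep(config$strata$name, vapply(out, function(b) length(b$y), 1L))
  n <- length(y)

  hap1 <- as.matrix(pool$haplotypes)[h1, , drop = FALSE]
  hap2 <- as.matrix(pool$haplotypes)[h2, , drop = FALSE]
  dimnames(hap1) <- dimnames(hap2) <- list(NULL, loci)
  pheno <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                      status = y, stratum = stratum, stringsAsFactors = FALSE)
  if (config$n_pcs > 0) {
    colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))
    pheno <- cbind(pheno, as.data.frame(pcs))
  }
  rownames(hap1) <- rownames(hap2) <- pheno$subject_id

  structure(
    list(hap1 = hap1, hap2 = hap2, pheno = pheno, loci = pool$loci,
         truth = list(effects = eff, pool = pool, config = config)),
    class = "hla_cohort")
}

#' @export
print.hla_cohort <- function(x, ...) {
  cat(sprintf("Phased cohort: %d subjects (%d cases / %d controls), %d strata, %d loci\n",
              nrow(x$pheno), sum(x$pheno$status == 1), sum(x$pheno$status == 0),
              length(unique(x$pheno$stratum)), ncol(x$hap1)))
  invisible(x)
}

#' Simulate expression traits with planted cis effects
#'
#' Per gene, expression is \eqn{\alpha + \gamma \cdot d + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)}, where \eqn{d} is the subject dosage of
#' the gene's effect marker (0 for genes with no planted effect). Feeds the
#' permutation-calibrated cis-eQTL screen with known truth.
#'
#' @param cohort an \code{hla_cohort}.
#' @param genes data.frame with columns \code{gene}, \code{tss} and optionally
#'   \code{alpha}, \code{snp} (marker id or \code{NA}), \code{gamma},
#'   \code{noise_sd}.
#' @param seed integer seed.
#' @return List with \code{expr} (genes x subjects matrix) and the completed
#'   \code{genes} annotation.
#' @export
simulate_expression <- function(cohort, genes, seed = 1L) {
  stopifnot(inherits(cohort, "hla_cohort"))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$alpha)) genes$alpha <- 0
  if (is.null(genes$snp)) genes$snp <- NA_character_
  if (is.null(genes$gamma)) genes$gamma <- 0
  if (is.null(genes$noise_sd)) genes$noise_sd <- 1
  if (any(genes$noise_sd < 0)) stopf("negative noise sd")
  set.seed(seed)
  n <- nrow(cohort$pheno)
  expr <- matrix(NA_real_, nrow(genes), n,
                 dimnames = list(genes$gene, cohort$pheno$subject_id))
  for (g in seq_len(nrow(genes))) {
    mu <- rep(genes$alpha[g], n)
    if (!is.na(genes$snp[g]) && genes$gamma[g] != 0) {
      d <- cohort_marker_dosage(cohort, genes$snp[g])
      mu <- mu + genes$gamma[g] * d
    }
    expr[g, ] <- mu + stats::rnorm(n, 0, genes$noise_sd[g])
  }
  list(expr = expr, genes = genes)
}

# dosage of a marker id computed directly from a cohort's phased calls
cohort_marker_dosage <- function(cohort, id) {
  carries_hap <- function(hapmat, id1) {
    if (grepl("-", id1, fixed = TRUE) && grepl("\\*", id1)) {
      parts <- strsplit(id1, "-", fixed = TRUE)[[1]]
      Reduce(`&`, lapply(parts, function(p) carries_hap(hapmat, p)))
    } else if (grepl("*", id1, fixed = TRUE)) {
      la <- strsplit(id1, "*", fixed = TRUE)[[1]]
      if (!la[1] %in% colnames(hapmat)) stopf("unknown locus '%s'", la[1])
      hapmat[, la[1]] == la[2]
    } else {
      snp <- sub("_[^_]+$", "", id1)
      allele <- sub("^.*_", "", id1)
      if (!snp %in% colnames(hapmat)) stopf("unknown variant '%s'", id1)
      hapmat[, snp] == allele
    }
  }
  as.numeric(carries_hap(cohort$hap1, id)) + as.numeric(carries_hap(cohort$hap2, id))
}
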