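# Permutation-calibrated cis-eQTL screen: Spearman rank correlation of SNP
# dosage with adjusted expression, per-gene null from permuted expression.

#' Enumerate cis SNP-gene pairs
#'
#' A pair is cis when the SNP lies within \code{window} bp of the gene's
#' transcription start site (inclusive boundary, strand ignored). Genes on
#' the \code{always_include} list (e.g. classical HLA class I/II genes) are
#' paired with every SNP regardless of distance.
#'
#' @param snps data.frame with columns \code{id}, \code{position}.
#' @param genes data.frame with columns \code{gene}, \code{tss}.
#' @param window cis window in bp (default 2 Mb).
#' @param always_include gene names exempt from the distance rule.
#' @return data.frame: \code{snp}, \code{gene}, \code{distance}.
#' @export
cis_pairs <- function(snps, genes, window = 2e6, always_include = character(0)) {
  stopifnot(all(c("id", "position") %in% names(snps)),
            all(c("gene", "tss") %in% names(genes)))
  if (anyNA(genes$tss)) stopf("missing TSS for gene(s): %s",
                              paste(genes$gene[is.na(genes$tss)], collapse = ", "))
  out <- list()
  for (g in seq_len(nrow(genes))) {
    d <- abs(snps$position - genes$tss[g])
    keep <- d <= window | genes$gene[g] %in% always_include
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        snp = snps$id[keep], gene = genes$gene[g], distance = d[keep],
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(data.frame(snp = character(0), gene = character(0),
                                           distance = numeric(0)))
  do.call(rbind, out)
}

#' Spearman rank correlation with large-sample p-value
#'
#' Mid-ranks are used for tied dosages; the two-sided p-value comes from the
#' t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} df.
#'
#' @param x dosage vector; @param y expression residual vector.
#' @return List: \code{rho}, \code{p}, \code{n}.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch")
  if (length(x) < 10L) stopf("need at least 10 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_p(rho, length(x))
  list(rho = rho, p = p, n = length(x))
}

spearman_p <- function(rho, n) {
  rho <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

# rho of each column of the rank-transformed dosage matrix with a ranked
# expression vector (both pre-ranked)
rho_vec <- function(Rd, ry) drop(stats::cor(Rd, ry))

#' Per-gene permutation calibration of the minimum p-value
#'
#' Builds the null distribution of the smallest nominal Spearman p across a
#' gene's cis SNPs by permuting the expression vector \code{n_perm} times,
#' and sets the gene's significance threshold at the 5\% tail of that
#' distribution. A SNP-gene pair is called significant when its nominal p is
#' smaller (more extreme) than the threshold. Because the dosage matrix is
#' held fixed, the null preserves the LD among cis SNPs, so the threshold
#' adapts to the effective number of independent tests.
#'
#' @param dosages numeric matrix (subjects x cis SNPs of one gene).
#' @param expression numeric expression-residual vector.
#' @param n_perm number of permutations (>= 100; default 10,000).
#' @param seed integer seed.
#' @param tail tail probability of the min-p null (default 0.05).
#' @return List: \code{threshold}, \code{nominal} (data.frame snp, rho, p,
#'   significant), \code{null_min_p} (length \code{n_perm}).
#' @export
permutation_calibration <- function(dosages, expression, n_perm = 10000,
                                    seed = 1L, tail = 0.05) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) == 0L) stopf("no cis SNPs")
  if (n_perm < 100) stopf("n_perm must be at least 100")
  n <- nrow(dosages)
  Rd <- apply(dosages, 2, rank)
  ry <- rank(expression)
  rho <- rho_vec(Rd, ry)
  p_obs <- spearman_p(rho, n)
  set.seed(seed)
  null_min <- vapply(seq_len(n_perm), function(i) {
    rp <- ry[sample.int(n)]
    min(spearman_p(rho_vec(Rd, rp), n))
  }, 1)
  threshold <- unname(stats::quantile(null_min, tail))
  data_nom <- data.frame(snp = colnames(dosages) %||% paste0("snp", seq_along(rho)),
                         rho = rho, p = p_obs,
                         significant = p_obs < threshold,
                         stringsAsFactors = FALSE)
  list(threshold = threshold, nominal = data_nom, null_min_p = null_min)
}

#' Run the full cis-eQTL screen
#'
#' For each gene: enumerate cis SNPs within the window, compute Spearman
#' correlations of each SNP's minor-allele dosage with the gene's expression
#' residuals, and calibrate significance against the per-gene permutation
#' null of the minimum p-value. With \code{best_snp_only} the permutation
#' call is made only for the gene's most significant SNP.
#'
#' @param dm \code{dosage_matrix} containing SNP markers with positions.
#' @param expr genes x subjects matrix of expression residuals.
#' @param genes data.frame with \code{gene}, \code{tss}.
#' @param window cis window in bp.
#' @param n_perm permutations per gene.
#' @param seed integer seed (a distinct child seed is drawn per gene).
#' @param always_include genes tested against every SNP regardless of
#'   distance.
#' @param best_snp_only restrict the significance call to each gene's top
#'   SNP.
#' @return Object of class \code{hla_eqtl}: \code{results} data.frame (snp,
#'   gene, rho, p, threshold, significant) and \code{thresholds} per gene.
#' @export
run_cis_eqtl <- function(dm, expr, genes, window = 2e6, n_perm = 10000,
                         seed = 1L, always_include = character(0),
                         best_snp_only = FALSE) {
  v <- dm$variants
  snp_ix <- which(v$kind == "SNP" & !is.na(v$position))
  if (length(snp_ix) == 0L) stopf("no positioned SNP markers in the matrix")
  # one dosage column per SNP: the minor allele of each SNP group
  per_snp <- split(snp_ix, v$group[snp_ix])
  snp_cols <- vapply(per_snp, function(ix) ix[which.min(v$frequency[ix])], 1L)
  snp_tab <- data.frame(id = names(per_snp),
                        position = v$position[snp_cols],
                        col = snp_cols, stringsAsFactors = FALSE)
  pairs <- cis_pairs(snp_tab, genes, window, always_include)
  res <- list(); thresholds <- numeric(0)
  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene[gi]
    psel <- pairs[pairs$gene == g, , drop = FALSE]
    if (nrow(psel) == 0L) next
    cols <- snp_tab$col[match(psel$snp, snp_tab$id)]
    D <- dm$dosages[, cols, drop = FALSE]
    colnames(D) <- psel$snp
    pc <- permutation_calibration(D, expr[g, ], n_perm = n_perm,
                                  seed = child_seed(seed, gi))
    nom <- pc$nominal
    if (best_snp_only) {
      best <- which.min(nom$p)
      nom$significant <- FALSE
      nom$significant[best] <- nom$p[best] < pc$threshold
    }
    nom$gene <- g
    nom$threshold <- pc$threshold
    thresholds[g] <- pc$threshold
    res[[length(res) + 1L]] <- nom[, c("snp", "gene", "rho", "p", "threshold", "significant")]
  }
  structure(list(results = do.call(rbind, res), thresholds = thresholds),
            class = "hla_eqtl")
}

#' @export
print.hla_eqtl <- function(x, ...) {
  r <- x$results
  cat(sprintf("cis-eQTL screen: %d pairs over %d gene(s); %d significant\n",
              nrow(r), length(unique(r$gene)), sum(r$significant)))
  if (any(r$significant)) print(r[r$significant, ], row.names = FALSE)
  invisible(x)
}

#' Residualize expression on covariates
#'
#' Simple least-squares residualizer used to adjust synthetic expression for
#' covariates before the Spearman screen. Real expression data are expected
#' to arrive already adjusted.
#'
#' @param expr genes x subjects matrix.
#' @param covariates data.frame or matrix of per-subject covariates.
#' @return Matrix of residuals, same shape as \code{expr}.
#' @export
residualize_expression <- function(expr, covariates) {
  C <- cbind(1, as.matrix(covariates))
  t(partial_out(t(expr), C))
}
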