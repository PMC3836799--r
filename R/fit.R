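# Logistic model core: design construction, rank-aware ML fitting, LRTs.
# Every test in the package reduces to lrt_add() on designs built here.

# Build the covariate block shared by all models: intercept, PCs, and
# (#strata - 1) dummy variables. Deterministic column order.
base_covariates <- function(pheno) {
  n <- nrow(pheno)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  pc_cols <- grep("^PC[0-9]+$", names(pheno), value = TRUE)
  if (length(pc_cols))
    X <- cbind(X, as.matrix(pheno[pc_cols]))
  strata <- unique(pheno$stratum)
  if (length(strata) > 1L) {
    f <- factor(pheno$stratum, levels = strata)
    D <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(D) <- paste0("stratum_", strata[-1])
    X <- cbind(X, D)
  }
  X
}

# Columns of a testing group, minus the reference allele. The reference is
# the group's most frequent marker among controls (ties broken by id); it is
# dropped only for groups of >= 2 columns (a lone presence/absence marker has
# "absence" as its implicit reference).
group_columns <- function(dm, pheno, group, drop_reference = TRUE) {
  ix <- which(dm$variants$group == group)
  if (length(ix) == 0L) stopf("unknown testing group '%s'", group)
  if (length(ix) == 1L || !drop_reference) return(dm$variants$id[ix])
  ctrl <- pheno$status == 0
  f <- colMeans(dm$dosages[ctrl, ix, drop = FALSE]) / 2
  ord <- order(-f, dm$variants$id[ix])
  dm$variants$id[ix[ord[-1]]]
}

# Expand a conditioning set of group ids into design columns (all p-1
# columns per multi-allelic group).
expand_conditioning <- function(dm, pheno, groups) {
  unique(unlist(lapply(groups, function(g) {
    if (g %in% dm$variants$group) group_columns(dm, pheno, g)
    else if (g %in% dm$variants$id) g
    else stopf("conditioning id '%s' not found", g)
  })))
}

#' Fit a logistic regression by maximum likelihood
#'
#' Rank-revealing fit of a binary outcome on an arbitrary design: aliased
#' (collinear) columns are detected by pivoted QR and dropped before the
#' iteratively reweighted least-squares fit, so the effective degrees of
#' freedom count only estimable parameters. Complete separation is flagged
#' rather than reported as a spurious finite estimate.
#'
#' @param X numeric design matrix (including the intercept column).
#' @param y 0/1 outcome vector.
#' @param se compute standard errors (skipped inside pure likelihood-ratio
#'   scans, where only the log-likelihood is needed).
#' @return An object of class \code{hla_fit}: \code{coef}, \code{se},
#'   \code{loglik}, \code{df} (rank), \code{n}, \code{converged},
#'   \code{separated}, \code{aliased} (dropped column names).
#' @export
fit_logistic <- function(X, y, se = TRUE) {
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stopf("outcome must be binary 0/1")
  if (nrow(X) != length(y)) stopf("design and outcome sizes differ")
  cn <- colnames(X) %||% rep("", ncol(X))
  blank <- !nzchar(cn)
  cn[blank] <- paste0("x", which(blank))
  colnames(X) <- make.unique(cn)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  cf <- fit$coefficients
  aliased <- names(cf)[is.na(cf)]
  cf <- cf[!is.na(cf)]
  mu <- fit$fitted.values
  separated <- any(abs(cf) > 15) && (min(mu) < 1e-8 || max(mu) > 1 - 1e-8)
  ses <- NULL
  if (se) {
    # observed-information standard errors on the estimable columns
    Xr <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    w <- mu * (1 - mu)
    ses <- rep(NA_real_, ncol(Xr))
    XtWX <- crossprod(Xr, Xr * w)
    cv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (!is.null(cv)) ses <- sqrt(diag(cv))
    names(ses) <- colnames(Xr)
    ses <- ses[names(cf)]
  }
  structure(
    list(coef = cf, se = ses,
         loglik = -fit$deviance / 2, df = fit$rank, n = length(y),
         converged = fit$converged, separated = separated, aliased = aliased),
    class = "hla_fit")
}

#' @export
print.hla_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, df = %d, logLik = %.3f%s%s\n",
              x$n, x$df, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$separated) " [SEPARATED]" else ""))
  if (length(x$aliased)) cat("  aliased:", paste(x$aliased, collapse = ", "), "\n")
  tab <- cbind(coef = x$coef, OR = exp(x$coef),
               se = x$se %||% rep(NA_real_, length(x$coef)))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.hla_fit <- function(object, ...) object$coef

#' @export
logLik.hla_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}

#' Likelihood-ratio test between nested fits
#'
#' The deviance is \eqn{D = 2(L_1 - L_0)} on the log-likelihood scale and is
#' referred to a chi-square distribution with \eqn{k} degrees of freedom,
#' \eqn{k} being the difference in estimable parameters after aliasing. The
#' p-value is computed and stored in log10 space so that extreme signals
#' (e.g. p of order 1e-234) do not underflow.
#'
#' @param fit0,fit1 nested \code{hla_fit} objects on the same subjects.
#' @return An object of class \code{hla_lrt}: \code{D}, \code{k},
#'   \code{log10p}, \code{p}.
#' @export
lrt <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "hla_fit"), inherits(fit1, "hla_fit"))
  if (fit0$n != fit1$n) stopf("fits are on different subject sets")
  if (fit1$df < fit0$df) stopf("fit1 must nest fit0 (df %d < %d)", fit1$df, fit0$df)
  D <- 2 * (fit1$loglik - fit0$loglik)
  if (D < -1e-6) stopf("negative deviance (%.3g): models not nested?", D)
  D <- max(D, 0)
  k <- fit1$df - fit0$df
  res <- new_lrt(D, k)
  if (k == 0L) { res$p <- 1; res$log10p <- 0 }  # identical parameter spaces
  res
}

new_lrt <- function(D, k, extra = list()) {
  if (k == 0L) {
    log10p <- NA_real_
  } else {
    log10p <- stats::pchisq(D, k, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  structure(c(list(D = D, k = as.integer(k), log10p = log10p,
                   p = if (is.na(log10p)) NA_real_ else 10^log10p), extra),
            class = "hla_lrt")
}

#' @export
print.hla_lrt <- function(x, ...) {
  if (is.na(x$log10p)) {
    cat(sprintf("LRT: D = %.3f, df = 0 (test undefined: no estimable parameters)\n", x$D))
  } else {
    cat(sprintf("LRT: D = %.3f, df = %d, p = %.2g (log10 p = %.2f)\n",
                x$D, x$k, x$p, x$log10p))
  }
  invisible(x)
}

# Core omnibus device: LRT for adding columns Xadd to base design Xbase.
# fit0 may be passed to avoid refitting the base model.
lrt_add <- function(y, Xbase, Xadd, fit0 = NULL) {
  if (is.null(fit0)) fit0 <- fit_logistic(Xbase, y, se = FALSE)
  fit1 <- fit_logistic(cbind(Xbase, Xadd), y, se = FALSE)
  res <- lrt(fit0, fit1)
  res$fit0 <- fit0
  res$fit1 <- fit1
  res
}

#' Nagelkerke's pseudo-R-squared
#'
#' Variance explained for a binary trait:
#' \deqn{R^2 = \frac{1 - \exp\{\tfrac{2}{N}(L_0 - L_1)\}}{1 - \exp\{\tfrac{2}{N} L_0\}}}
#' with \eqn{L_0}, \eqn{L_1} the maximized log-likelihoods of the null and
#' fitted model and \eqn{N} the number of subjects.
#'
#' @param fit0,fit1 nested \code{hla_fit}s, or raw log-likelihood values.
#' @param N number of subjects (taken from the fits when omitted).
#' @return Proportion in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit0, fit1, N = NULL) {
  L0 <- if (inherits(fit0, "hla_fit")) fit0$loglik else as.numeric(fit0)
  L1 <- if (inherits(fit1, "hla_fit")) fit1$loglik else as.numeric(fit1)
  if (is.null(N)) {
    stopifnot(inherits(fit0, "hla_fit"), inherits(fit1, "hla_fit"), fit0$n == fit1$n)
    N <- fit0$n
  }
  if (L1 < L0 - 1e-8) stopf("fitted model has lower likelihood than null")
  num <- 1 - exp((2 / N) * (L0 - max(L0, L1)))
  den <- 1 - exp((2 / N) * L0)
  if (den <= 0) return(0)
  min(max(num / den, 0), 1)
}
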