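# Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

logistic <- function(x) 1 / (1 + exp(-x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Bonferroni significance threshold
#'
#' The study-wide significance level used throughout the stepwise analysis:
#' a type-1 error rate alpha divided by the assumed number of independent
#' tests across the MHC (5,000 by default, giving 1e-5).
#'
#' @param alpha study-wide type-1 error rate.
#' @param n_tests assumed number of independent tests.
#' @return Numeric per-test threshold.
#' @examples
#' bonferroni_threshold()        # 1e-5
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 5000) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

# squared Pearson correlation between two dosage columns; NA if either constant
dosage_r2 <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# derive a child seed from a base seed and an index, kept below 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}
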