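#' Variance explained from a p-value and sample size
#'
#' Converts an association p-value into the implied coefficient of
#' determination: `t2` is the upper-tail chi-square(1) quantile at `p` and
#' `r2 = t2 / (t2 + n - 2)`. Strictly decreasing in `p` at fixed `n`.
#'
#' @param pvalue Association p-value(s) in (0, 1].
#' @param n Sample size (> 2).
#' @return Variance explained, in \[0, 1).
#' @export
#' @examples
#' r2_from_pn(5e-8, 521612) # ~5.7e-5
r2_from_pn <- function(pvalue, n) {
  if (any(!is.finite(pvalue)) || any(pvalue <= 0) || any(pvalue > 1))
    stop("pvalue must lie in (0, 1]", call. = FALSE)
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  t2 <- qchisq(pvalue, df = 1, lower.tail = FALSE)
  t2 / (t2 + n - 2)
}

#' Steiger directionality test
#'
#' Compares the variance a SNP explains in the exposure versus the outcome
#' via Fisher z-transforms of the implied correlations (`r = sqrt(r2)`,
#' positive root): `z = (atanh(r_exp) - atanh(r_out)) /
#' sqrt(1/(n_exp - 3) + 1/(n_out - 3))`, two-sided normal p. Positive `z`
#' supports the exposure -> outcome direction. Antisymmetric under swapping
#' the two sides.
#'
#' @param r2_exp,r2_out Variance explained in exposure / outcome, in \[0, 1).
#' @param n_exp,n_out Sample sizes (> 3).
#' @return List with `z` and `pvalue`.
#' @export
steiger_test <- function(r2_exp, n_exp, r2_out, n_out) {
  if (any(n_exp <= 3) || any(n_out <= 3))
    stop("sample sizes must exceed 3", call. = FALSE)
  if (any(r2_exp < 0) || any(r2_exp >= 1) || any(r2_out < 0) ||
      any(r2_out >= 1))
    stop("r2 values must lie in [0, 1)", call. = FALSE)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(z = z, pvalue = two_sided_normal_p(z))
}

#' Steiger directionality filter
#'
#' Retains instruments that explain more variance in the exposure than in
#' the outcome (`r2_exp > r2_out`), computed from the per-SNP association
#' p-values and the dataset-level sample sizes (per-SNP sizes are not
#' available at summary level). All per-SNP results are logged.
#'
#' @param instruments `harmonized_instruments` data frame with `pval_exp`
#'   and `pval_out` columns.
#' @param n_exp,n_out Exposure / outcome GWAS sample sizes.
#' @return List with `kept` (instruments passing), `flagged` (rows of
#'   `results` for instruments failing), and `results` (data frame
#'   `snp_id`, `r2_exp`, `r2_out`, `z`, `pvalue`, `kept`).
#' @export
steiger_filter <- function(instruments, n_exp, n_out) {
  stopifnot(is.data.frame(instruments))
  if (!nrow(instruments)) {
    empty <- data.frame(snp_id = character(), r2_exp = numeric(),
                        r2_out = numeric(), z = numeric(),
                        pvalue = numeric(), kept = logical(),
                        stringsAsFactors = FALSE)
    return(list(kept = instruments, flagged = empty, results = empty))
  }
  if (!all(c("pval_exp", "pval_out") %in% names(instruments)))
    stop("instruments need pval_exp and pval_out columns", call. = FALSE)
  r2_exp <- r2_from_pn(instruments$pval_exp, n_exp)
  r2_out <- r2_from_pn(instruments$pval_out, n_out)
  st <- steiger_test(r2_exp, n_exp, r2_out, n_out)
  keep <- r2_exp > r2_out
  results <- data.frame(snp_id = instruments$snp_id, r2_exp = r2_exp,
                        r2_out = r2_out, z = st$z, pvalue = st$pvalue,
                        kept = keep, stringsAsFactors = FALSE)
  list(kept = instruments[keep, , drop = FALSE],
       flagged = results[!keep, , drop = FALSE],
       results = results)
}
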