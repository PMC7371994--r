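new_mr_estimate <- function(method, beta, se, pvalue, n_snps,
                            variance_model = "default", scale_factor = 1) {
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 or_value = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 n_snps = as.integer(n_snps),
                 variance_model = variance_model,
                 scale_factor = scale_factor),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s (%d SNPs): beta = %.4f, se = %.4f, p = %.4g, OR = %.4f [%.4f, %.4f]\n",
    x$method, x$n_snps, x$beta, x$se, x$pvalue, x$or_value, x$ci_lower,
    x$ci_upper))
  invisible(x)
}

new_heterogeneity <- function(q, df) {
  structure(list(q = q, df = as.integer(df),
                 pvalue = pchisq(q, df, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %.4f\n", x$q, x$df,
              x$pvalue))
  invisible(x)
}

two_sided_normal_p <- function(z) 2 * pnorm(-abs(z))

check_instruments <- function(instruments, min_n = 1L) {
  stopifnot(is.data.frame(instruments))
  need <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(need, names(instruments))
  if (length(missing))
    stop("instruments lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(instruments) < min_n)
    stop("need at least ", min_n, " instrument(s), got ", nrow(instruments),
         call. = FALSE)
  invisible(instruments)
}

#' Single-instrument Wald ratio
#'
#' Per-SNP causal estimate: `beta_out / beta_exp`, with first-order
#' delta-method standard error `se_out / |beta_exp|` and a two-sided normal
#' p-value. Exposure-side sampling error is ignored (the usual NOME
#' convention for summary-level MR).
#'
#' @param inst A single harmonized instrument (one-row data frame or list
#'   with `beta_exp`, `beta_out`, `se_out`).
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(inst) {
  if (is.data.frame(inst)) {
    check_instruments(inst, 1L)
    stopifnot(nrow(inst) == 1L)
    inst <- as.list(inst)
  }
  if (!is.finite(inst$beta_exp) || inst$beta_exp == 0)
    stop("wald_ratio requires a nonzero exposure effect", call. = FALSE)
  beta <- inst$beta_out / inst$beta_exp
  se <- inst$se_out / abs(inst$beta_exp)
  new_mr_estimate("wald_ratio", beta, se, two_sided_normal_p(beta / se),
                  n_snps = 1L, variance_model = "fixed")
}

# IVW weights: first-order inverse ratio variance (beta_exp / se_out)^2
ivw_weights <- function(instruments) {
  (instruments$beta_exp / instruments$se_out)^2
}

#' Inverse-variance weighted causal estimate with Cochran's Q
#'
#' Pools the per-SNP Wald ratios `theta_j = beta_out_j / beta_exp_j` with
#' weights `w_j = (beta_exp_j / se_out_j)^2` (equivalently, zero-intercept
#' weighted least squares of outcome on exposure betas with weights
#' `1 / se_out^2`). Heterogeneity is `Q = sum w_j (theta_j - theta_hat)^2`
#' on `J - 1` degrees of freedom.
#'
#' Variance models: `"fixed"` uses `(sum w_j)^(-1/2)`; `"random"` is the
#' multiplicative random-effects model, inflating the fixed SE by
#' `max(1, sqrt(Q / (J - 1)))` (under-dispersion floored at 1); `"default"`
#' applies `"fixed"` below four instruments and `"random"` from four up —
#' the rule that reproduces the default behaviour of the standard MR
#' software on every packaged analysis.
#'
#' @param instruments `harmonized_instruments` data frame (J >= 1 rows, all
#'   `beta_exp` nonzero).
#' @param variance_model `"default"`, `"fixed"` or `"random"`.
#' @return List with `estimate` (an `mr_estimate`) and `heterogeneity`
#'   (a `heterogeneity_result`, `NULL` when J < 2).
#' @export
#' @examples
#' sel <- select_instruments(load_fixture("AS", "exposure"),
#'                           load_fixture("AS", "outcome"))
#' mr_ivw(sel$kept)
mr_ivw <- function(instruments,
                   variance_model = c("default", "fixed", "random")) {
  variance_model <- match.arg(variance_model)
  check_instruments(instruments, 1L)
  if (any(instruments$beta_exp == 0))
    stop("all exposure effects must be nonzero", call. = FALSE)
  J <- nrow(instruments)
  theta <- instruments$beta_out / instruments$beta_exp
  w <- ivw_weights(instruments)
  est <- sum(w * theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (theta - est)^2)
  het <- if (J >= 2) new_heterogeneity(q, J - 1) else NULL
  resolved <- switch(variance_model,
                     fixed = "fixed", random = "random",
                     default = if (J >= 4) "random" else "fixed")
  scale <- if (resolved == "random" && J >= 2)
    max(1, sqrt(q / (J - 1))) else 1
  se <- se_fixed * scale
  list(estimate = new_mr_estimate("ivw", est, se,
                                  two_sided_normal_p(est / se), J,
                                  variance_model = resolved,
                                  scale_factor = scale),
       heterogeneity = het)
}

# deterministic percentile-interpolation weighted median; ties in theta
# broken by a stable sort on ids
weighted_median_point <- function(theta, w, ids = seq_along(theta)) {
  o <- order(theta, ids)
  theta <- theta[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (any(dup <- duplicated(p))) p[dup] <- p[dup] + 1e-12 # degenerate ties
  approx(p, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

ratio_weight_fun <- function(instruments, ratio_weights) {
  switch(ratio_weights,
         first_order = (instruments$beta_exp / instruments$se_out)^2,
         delta = 1 / (instruments$se_out^2 / instruments$beta_exp^2 +
                        instruments$beta_out^2 * instruments$se_exp^2 /
                        instruments$beta_exp^4))
}

#' Weighted-median causal estimate with parametric-bootstrap SE
#'
#' The 50th-percentile Wald ratio under inverse-variance weighting,
#' consistent when valid instruments carry more than half the total weight.
#' Ratios are sorted ascending with normalized weights `w'_j`; cumulative
#' percentiles are `p_j = (S_j - w'_j/2) / S_J`; the estimate interpolates
#' the ratio linearly at `p = 1/2` (an exact match returns that ratio). The
#' point estimate is deterministic; the SE is the standard deviation of the
#' estimate over `n_boot` parametric resamples drawing both beta vectors
#' from normals centred on the observations, so SE and p depend on `seed`.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed RNG seed (required, for reproducibility).
#' @param ratio_weights `"first_order"` weights `(beta_exp/se_out)^2`, or
#'   `"delta"` for full delta-method ratio variances
#'   `1/(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)` as used by
#'   some MR software.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed,
                               ratio_weights = c("first_order", "delta")) {
  ratio_weights <- match.arg(ratio_weights)
  check_instruments(instruments, 3L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_boot >= 1)
  J <- nrow(instruments)
  theta <- instruments$beta_out / instruments$beta_exp
  w <- ratio_weight_fun(instruments, ratio_weights)
  est <- weighted_median_point(theta, w, instruments$snp_id)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(J, instruments$beta_exp, instruments$se_exp)
      by <- rnorm(J, instruments$beta_out, instruments$se_out)
      sim <- instruments
      sim$beta_exp <- bx; sim$beta_out <- by
      weighted_median_point(by / bx, ratio_weight_fun(sim, ratio_weights),
                            instruments$snp_id)
    }, numeric(1))
  })
  se <- sd(boot)
  p <- if (se > 0) two_sided_normal_p(est / se)
       else if (est == 0) 1 else .Machine$double.xmin
  new_mr_estimate("weighted_median", est, se, p, J)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas \emph{with}
#' intercept, weights `1/se_out^2`, after reorienting every instrument so
#' exposure betas are non-negative (Egger regression is not
#' orientation-invariant). The slope is the pleiotropy-adjusted causal
#' estimate under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy. Residual heterogeneity Q' is reported on `J - 2`
#' degrees of freedom and both coefficient SEs are inflated by
#' `max(1, sqrt(Q'/(J-2)))`. P-values use normal tails by default; set
#' `t_dist = TRUE` for t(J-2) tails (the convention of some MR software).
#'
#' @inheritParams mr_ivw
#' @param t_dist Use a t(J-2) reference distribution for the p-values.
#' @return List with `slope` and `intercept` (`mr_estimate`s) and
#'   `heterogeneity` (a `heterogeneity_result` for Q' on J-2 df).
#' @export
mr_egger <- function(instruments, t_dist = FALSE) {
  check_instruments(instruments, 3L)
  J <- nrow(instruments)
  flip <- ifelse(instruments$beta_exp < 0, -1, 1)
  x <- instruments$beta_exp * flip
  y <- instruments$beta_out * flip
  w <- 1 / instruments$se_out^2
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (!is.finite(det) || det <= .Machine$double.eps * sw * swxx)
    stop("rank-deficient design: exposure betas (after orientation) are ",
         "all equal", call. = FALSE)
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- y - intercept - slope * x
  qprime <- sum(w * resid^2)
  df <- J - 2L
  scale <- max(1, sqrt(qprime / df))
  se_slope <- sqrt(sw / det) * scale
  se_int <- sqrt(swxx / det) * scale
  pval <- function(b, s) {
    if (t_dist) 2 * pt(-abs(b / s), df) else two_sided_normal_p(b / s)
  }
  list(slope = new_mr_estimate("egger_slope", slope, se_slope,
                               pval(slope, se_slope), J,
                               scale_factor = scale),
       intercept = new_mr_estimate("egger_intercept", intercept, se_int,
                                   pval(intercept, se_int), J,
                                   scale_factor = scale),
       heterogeneity = new_heterogeneity(qprime, df))
}

#' Tidy one-row summary of an `mr_estimate`
#' @param est An `mr_estimate` (or `NULL`).
#' @param het Optional `heterogeneity_result` to append as q/q_df/q_pvalue.
#' @return One-row data frame.
#' @export
tidy_estimate <- function(est, het = NULL) {
  if (is.null(est)) return(NULL)
  data.frame(method = est$method, n_snps = est$n_snps, beta = est$beta,
             se = est$se, pvalue = est$pvalue, or = est$or_value,
             ci_lower = est$ci_lower, ci_upper = est$ci_upper,
             q = if (is.null(het)) NA_real_ else het$q,
             q_df = if (is.null(het)) NA_integer_ else het$df,
             q_pvalue = if (is.null(het)) NA_real_ else het$pvalue,
             stringsAsFactors = FALSE)
}
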