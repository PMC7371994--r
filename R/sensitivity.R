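#' Leave-one-out sensitivity analysis
#'
#' Excludes each instrument in turn and re-runs the three estimators on the
#' remaining J-1. Requires J >= 4 so every reduced set still supports Egger
#' regression. The weighted-median bootstrap is reseeded deterministically
#' per row (`seed + row index`), so re-running with the same seed reproduces
#' the WMR columns bit-for-bit.
#'
#' @inheritParams mr_ivw
#' @inheritParams mr_weighted_median
#' @return Data frame with one row per excluded instrument: `excluded_snp`,
#'   `ivw_beta`, `ivw_p`, `wmr_beta`, `wmr_p`, `egger_beta`, `egger_p`,
#'   `intercept_beta`, `intercept_p`.
#' @export
leave_one_out <- function(instruments, variance_model = "default",
                          n_boot = 1000, seed,
                          ratio_weights = "first_order") {
  check_instruments(instruments, 4L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rows <- lapply(seq_len(nrow(instruments)), function(i) {
    sub <- instruments[-i, , drop = FALSE]
    ivw <- mr_ivw(sub, variance_model)$estimate
    wmr <- mr_weighted_median(sub, n_boot = n_boot, seed = seed + i,
                              ratio_weights = ratio_weights)
    eg <- mr_egger(sub)
    data.frame(excluded_snp = instruments$snp_id[i],
               ivw_beta = ivw$beta, ivw_p = ivw$pvalue,
               wmr_beta = wmr$beta, wmr_p = wmr$pvalue,
               egger_beta = eg$slope$beta, egger_p = eg$slope$pvalue,
               intercept_beta = eg$intercept$beta,
               intercept_p = eg$intercept$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-SNP single-instrument MR scan
#'
#' One [wald_ratio()] per instrument, in input order.
#'
#' @inheritParams mr_ivw
#' @return Data frame: `snp_id`, `beta`, `se`, `pvalue`, `or`, `ci_lower`,
#'   `ci_upper`.
#' @export
single_snp_scan <- function(instruments) {
  check_instruments(instruments, 1L)
  rows <- lapply(seq_len(nrow(instruments)), function(i) {
    est <- wald_ratio(instruments[i, ])
    data.frame(snp_id = instruments$snp_id[i], beta = est$beta,
               se = est$se, pvalue = est$pvalue, or = est$or_value,
               ci_lower = est$ci_lower, ci_upper = est$ci_upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance cutoff
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 11) # 0.004545
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(n_tests) || n_tests < 1 || n_tests != round(n_tests))
    stop("n_tests must be a positive integer", call. = FALSE)
  alpha / n_tests
}

#' Staged pleiotropy screen over a SNP x trait p-value matrix
#'
#' Flags every (SNP, trait) pair whose association p-value falls below the
#' Bonferroni-corrected cutoff `alpha / n_instruments`. Absent entries (NA)
#' are never flagged — a missing database lookup is not evidence of
#' pleiotropy.
#'
#' @param pmatrix Data frame with a `snp_id` column and one numeric p-value
#'   column per candidate trait (as returned by
#'   `load_fixture("pleiotropy_matrix")`), or a numeric matrix with rsID
#'   rownames.
#' @param alpha Family-wise level (default 0.05).
#' @param n_instruments Number of instruments in the MR analysis the screen
#'   protects (defaults to the number of SNP rows).
#' @return A `pleiotropy_screen` list: `threshold`, `flags` (data frame
#'   `snp_id`, `trait`, `pvalue`), `n_tested`, `alpha`, `n_instruments`.
#' @export
screen_pleiotropy <- function(pmatrix, alpha = 0.05,
                              n_instruments = NULL) {
  if (is.matrix(pmatrix))
    pmatrix <- data.frame(snp_id = rownames(pmatrix), pmatrix,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(is.data.frame(pmatrix))
  if (!nrow(pmatrix) || ncol(pmatrix) < 2) {
    flags <- data.frame(snp_id = character(), trait = character(),
                        pvalue = numeric(), stringsAsFactors = FALSE)
    n_instruments <- n_instruments %||% max(1L, nrow(pmatrix))
    return(structure(list(threshold = bonferroni_threshold(alpha,
                                                           n_instruments),
                          flags = flags, n_tested = 0L, alpha = alpha,
                          n_instruments = n_instruments),
                     class = "pleiotropy_screen"))
  }
  if (!("snp_id" %in% names(pmatrix)))
    names(pmatrix)[1] <- "snp_id"
  traits <- setdiff(names(pmatrix), "snp_id")
  n_instruments <- n_instruments %||% nrow(pmatrix)
  threshold <- bonferroni_threshold(alpha, n_instruments)
  flags <- list(); n_tested <- 0L
  for (tr in traits) {
    p <- as.numeric(pmatrix[[tr]])
    ok <- !is.na(p)
    if (any(p[ok] <= 0 | p[ok] > 1))
      stop("p-values must lie in (0, 1]", call. = FALSE)
    n_tested <- n_tested + sum(ok)
    hit <- ok & p < threshold
    if (any(hit))
      flags[[length(flags) + 1L]] <-
        data.frame(snp_id = pmatrix$snp_id[hit], trait = tr,
                   pvalue = p[hit], stringsAsFactors = FALSE)
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(snp_id = character(), trait = character(),
               pvalue = numeric(), stringsAsFactors = FALSE)
  structure(list(threshold = threshold, flags = flags,
                 n_tested = n_tested, alpha = alpha,
                 n_instruments = n_instruments),
            class = "pleiotropy_screen")
}

#' @export
print.pleiotropy_screen <- function(x, ...) {
  cat(sprintf("pleiotropy screen: %d lookups, cutoff %.6g, %d flagged\n",
              x$n_tested, x$threshold, nrow(x$flags)))
  if (nrow(x$flags)) print.data.frame(x$flags)
  invisible(x)
}
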