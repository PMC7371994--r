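#' Configuration for one MR analysis
#'
#' @param exposure_source,outcome_source A [summary_dataset()], a packaged
#'   fixture key (`"AS"`, `"AIS"`, `"LAS"`, `"CES"`), or a file path read
#'   with [read_summary_table()] under the default schema.
#' @param rules A [selection_rules()] object.
#' @param variance_model IVW variance model (`"default"`, `"fixed"`,
#'   `"random"`).
#' @param steiger_mode Apply the Steiger directionality filter after
#'   selection (requires `n_exp` and `n_out`).
#' @param n_exp,n_out GWAS sample sizes for Steiger filtering; default to
#'   the packaged cohort totals (521,612 stroke; 54,162 AD).
#' @param n_boot,seed Weighted-median bootstrap replicates and RNG seed.
#' @param egger_t_dist Use t(J-2) tails for MR-Egger p-values.
#' @param ratio_weights Weighted-median ratio-weight convention (see
#'   [mr_weighted_median()]).
#' @param label Analysis label used in the report (defaults to the exposure
#'   trait label).
#' @param output_dir If non-`NULL`, report tables and a run log are written
#'   there as TSV/JSON.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(exposure_source, outcome_source,
                            rules = selection_rules(),
                            variance_model = "default",
                            steiger_mode = FALSE, n_exp = 521612,
                            n_out = 54162, n_boot = 1000, seed = 1,
                            egger_t_dist = FALSE,
                            ratio_weights = "first_order", label = NULL,
                            output_dir = NULL) {
  stopifnot(inherits(rules, "selection_rules"))
  if (isTRUE(steiger_mode) && (is.null(n_exp) || is.null(n_out)))
    stop("steiger_mode requires n_exp and n_out", call. = FALSE)
  structure(list(exposure_source = exposure_source,
                 outcome_source = outcome_source, rules = rules,
                 variance_model = variance_model,
                 steiger_mode = isTRUE(steiger_mode),
                 n_exp = n_exp, n_out = n_out, n_boot = n_boot,
                 seed = seed, egger_t_dist = isTRUE(egger_t_dist),
                 ratio_weights = ratio_weights, label = label,
                 output_dir = output_dir),
            class = "analysis_config")
}

resolve_source <- function(src, role) {
  if (inherits(src, "summary_dataset")) return(src)
  if (is.character(src) && length(src) == 1L) {
    if (src %in% .fixture_keys) return(load_fixture(src, role))
    if (file.exists(src))
      return(read_summary_table(src, trait_label = basename(src)))
    stop("cannot resolve ", role, " source: ", src, call. = FALSE)
  }
  stop("invalid ", role, " source", call. = FALSE)
}

#' Run one configured MR analysis end to end
#'
#' Chains instrument selection, optional Steiger filtering, the three
#' estimators with heterogeneity, the leave-one-out table (J >= 4), and the
#' single-SNP scan. Every decision (drops, flips, proxies, variance model,
#' seeds) is recorded in the run log; with `output_dir` set, all tables are
#' written as TSV plus a JSON results file and the plain-text log.
#'
#' @param config An [analysis_config()].
#' @return An `mr_report` list: `label`, `instruments`, `dropped`,
#'   `steiger`, `results` (tidy data frame: method, n_snps, beta, se,
#'   pvalue, or, ci_lower, ci_upper, q, q_df, q_pvalue), `loo`,
#'   `single_snp`, `log`, `config`.
#' @export
#' @examples
#' rep <- run_analysis(analysis_config("AS", "AS", seed = 7, n_boot = 200))
#' subset(rep$results, method == "ivw")
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  exposure <- resolve_source(config$exposure_source, "exposure")
  outcome <- resolve_source(config$outcome_source, "outcome")
  label <- config$label %||% trait_label(exposure)
  say("analysis %s: exposure '%s' (%d SNPs), outcome '%s' (%d SNPs)",
      label, trait_label(exposure), nrow(exposure), trait_label(outcome),
      nrow(outcome))

  sel <- select_instruments(exposure, outcome, config$rules)
  for (i in seq_len(nrow(sel$dropped)))
    say("dropped %s: %s", sel$dropped$snp_id[i], sel$dropped$reason[i])
  inst <- sel$kept
  for (i in which(inst$flipped))
    say("flipped outcome orientation for %s", inst$snp_id[i])
  for (i in which(!is.na(inst$proxy_of)))
    say("proxy %s used for %s", inst$proxy_of[i], inst$snp_id[i])

  steiger <- NULL
  if (config$steiger_mode) {
    st <- steiger_filter(inst, config$n_exp, config$n_out)
    steiger <- st$results
    say("steiger filter (n_exp %s, n_out %s, total-n convention): %d of %d kept",
        format(config$n_exp), format(config$n_out), nrow(st$kept),
        nrow(inst))
    inst <- st$kept
    if (!nrow(inst))
      stop_strokemr("no_instruments: Steiger filter removed all instruments",
                    "strokemr_no_instruments")
  }
  J <- nrow(inst)
  say("estimating on %d instruments (variance_model %s, seed %s, n_boot %s)",
      J, config$variance_model, format(config$seed),
      format(config$n_boot))

  ivw <- mr_ivw(inst, config$variance_model)
  say("ivw variance model resolved to '%s' (scale factor %.4f)",
      ivw$estimate$variance_model, ivw$estimate$scale_factor)
  wmr <- if (J >= 3)
    mr_weighted_median(inst, n_boot = config$n_boot, seed = config$seed,
                       ratio_weights = config$ratio_weights) else NULL
  egger <- if (J >= 3) mr_egger(inst, t_dist = config$egger_t_dist) else NULL

  results <- rbind(tidy_estimate(ivw$estimate, ivw$heterogeneity),
                   tidy_estimate(wmr),
                   if (!is.null(egger))
                     tidy_estimate(egger$slope, egger$heterogeneity),
                   if (!is.null(egger)) tidy_estimate(egger$intercept))
  results <- cbind(analysis = label, results, stringsAsFactors = FALSE)
  results$method[results$method == "egger_slope"] <- "egger"

  loo <- if (J >= 4)
    leave_one_out(inst, config$variance_model, n_boot = config$n_boot,
                  seed = config$seed, ratio_weights = config$ratio_weights)
  else NULL
  scan <- single_snp_scan(inst)

  report <- structure(list(label = label, instruments = inst,
                           dropped = sel$dropped, steiger = steiger,
                           results = results, loo = loo,
                           single_snp = scan, log = log_lines,
                           config = config),
                      class = "mr_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, paste0(report$label, "_", f))
  tsv <- function(x, f)
    if (!is.null(x)) write.table(x, p(f), sep = "\t", quote = FALSE,
                                 row.names = FALSE)
  tsv(report$results, "results.tsv")
  tsv(report$dropped, "drops.tsv")
  tsv(report$steiger, "steiger.tsv")
  tsv(report$loo, "leave_one_out.tsv")
  tsv(report$single_snp, "single_snp.tsv")
  tsv(report$instruments, "instruments.tsv")
  jsonlite::write_json(report$results, p("results.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(report$log, p("run.log"))
  invisible(dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("MR analysis '%s': %d instrument(s), %d dropped\n", x$label,
              nrow(x$instruments), nrow(x$dropped)))
  out <- x$results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 4)
  print.data.frame(out, row.names = FALSE)
  invisible(x)
}

fixture_rules <- function(key, steiger) {
  selection_rules(
    drop_palindromic = steiger,
    proxy_map = if (key == "AIS") c(rs6825454 = "rs56010410")
                else character())
}

#' Run the packaged stroke -> AD analysis suite
#'
#' Runs the four primary analyses (AS, AIS, LAS, CES against AD) and their
#' Steiger-mode variants, then compares every deterministic quantity
#' (betas, IVW p-values, Q) against the published values stored in the
#' packaged `expected_results.tsv`, at the precision each was printed.
#' The Steiger arms use the conventions of the software that produced them:
#' multiplicative random-effects IVW at any J, t(J-2) Egger tails, and
#' delta-method weighted-median weights.
#'
#' @param seed RNG seed for the weighted-median bootstraps.
#' @param n_boot Bootstrap replicates per weighted-median fit.
#' @param output_dir Optional directory for per-analysis report files.
#' @return List with `reports` (named list of `mr_report`s) and
#'   `comparison` (data frame: analysis, method, field, expected, value,
#'   pass).
#' @export
run_all_fixture_analyses <- function(seed = 1, n_boot = 1000,
                                     output_dir = NULL) {
  reports <- list()
  for (key in .fixture_keys) {
    reports[[key]] <- run_analysis(analysis_config(
      key, key, rules = fixture_rules(key, steiger = FALSE),
      seed = seed, n_boot = n_boot, label = key,
      output_dir = output_dir))
    skey <- paste0(key, "_steiger")
    reports[[skey]] <- run_analysis(analysis_config(
      key, key, rules = fixture_rules(key, steiger = TRUE),
      variance_model = "random", steiger_mode = TRUE,
      egger_t_dist = TRUE, ratio_weights = "delta",
      seed = seed, n_boot = n_boot, label = skey,
      output_dir = output_dir))
  }
  expected <- read.delim(fixture_path("expected_results.tsv"),
                         stringsAsFactors = FALSE)
  expected$value <- NA_real_
  for (i in seq_len(nrow(expected))) {
    res <- reports[[expected$analysis[i]]]$results
    row <- res[res$method == expected$method[i], ]
    if (nrow(row) == 1L)
      expected$value[i] <- row[[expected$field[i]]]
  }
  tol <- 0.5 * 10^(-expected$digits) + 1e-9
  expected$pass <- !is.na(expected$value) &
    abs(expected$value - expected$expected) <= tol
  list(reports = reports, comparison = expected)
}
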