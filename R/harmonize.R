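.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has alleles that are each other's
#' reverse complement: the unordered pair \{A,T\} or \{C,G\}.
#'
#' @param effect_allele,other_allele Single-nucleotide alleles (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' is_palindromic("T", "A") # TRUE
#' is_palindromic("C", "T") # FALSE
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele); oa <- toupper(other_allele)
  if (any(!(ea %in% .nucleotides)) || any(!(oa %in% .nucleotides)))
    stop("alleles must be single nucleotides (A/C/G/T)", call. = FALSE)
  unname(.complement[ea] == oa)
}

#' Instrument-selection rules
#'
#' Bundles the thresholds and per-SNP decisions applied by
#' [select_instruments()]. Defaults are the conventional genome-wide
#' significance threshold for the exposure (p < 5e-8, strict), exclusion of
#' instruments nominally associated with the outcome (p < 0.05), and an
#' effect-allele-frequency ambiguity window of \[0.42, 0.58\] for palindromic
#' SNPs. Palindromic handling is off by default (the primary analysis arm)
#' and should be switched on for Steiger-mode runs.
#'
#' @param exposure_p_max Keep exposure SNPs with p strictly below this.
#' @param outcome_p_min Drop instruments whose outcome-association p falls
#'   below this.
#' @param drop_palindromic Drop palindromic SNPs with ambiguous or missing
#'   frequency (either dataset), or listed in `palindromic_exclusions`.
#' @param palindromic_eaf_window Frequency interval around 0.5 treated as
#'   ambiguous; must be symmetric about 0.5.
#' @param explicit_exclusions Character vector of rsIDs to drop; may be named
#'   with reason strings (default reason `"explicit_exclusion"`).
#' @param palindromic_exclusions rsIDs always treated as ambiguous
#'   palindromic when `drop_palindromic` is on.
#' @param proxy_map Named character vector mapping an exposure rsID to the
#'   proxy rsID carrying its outcome record (e.g.
#'   `c(rs6825454 = "rs56010410")`). Proxy statistics are taken verbatim; no
#'   LD computation is performed.
#' @return A `selection_rules` object.
#' @export
selection_rules <- function(exposure_p_max = 5e-8, outcome_p_min = 0.05,
                            drop_palindromic = FALSE,
                            palindromic_eaf_window = c(0.42, 0.58),
                            explicit_exclusions = character(),
                            palindromic_exclusions = character(),
                            proxy_map = character()) {
  stopifnot(is.numeric(exposure_p_max), is.numeric(outcome_p_min))
  if (!(exposure_p_max > 0 && exposure_p_max < outcome_p_min &&
        outcome_p_min <= 1))
    stop("require 0 < exposure_p_max < outcome_p_min <= 1", call. = FALSE)
  w <- sort(as.numeric(palindromic_eaf_window))
  if (length(w) != 2L || w[1] < 0 || w[2] > 1 ||
      abs((w[1] + w[2]) - 1) > 1e-9)
    stop("palindromic_eaf_window must lie in [0,1], symmetric about 0.5",
         call. = FALSE)
  excl <- as.character(explicit_exclusions)
  reasons <- names(explicit_exclusions)
  if (is.null(reasons)) reasons <- rep("explicit_exclusion", length(excl))
  reasons[reasons == ""] <- "explicit_exclusion"
  # explicit_exclusions supplied as c(rsid = "reason")
  if (length(excl) && all(grepl("^rs", reasons)) && !all(grepl("^rs", excl))) {
    tmp <- reasons; reasons <- excl; excl <- tmp
  }
  structure(list(exposure_p_max = exposure_p_max,
                 outcome_p_min = outcome_p_min,
                 drop_palindromic = isTRUE(drop_palindromic),
                 palindromic_eaf_window = w,
                 explicit_exclusions = setNames(reasons, excl),
                 palindromic_exclusions = as.character(palindromic_exclusions),
                 proxy_map = proxy_map),
            class = "selection_rules")
}

harmonized_row <- function(snp_id, exposure, outcome, flipped, palindromic,
                           proxy_of = NA_character_) {
  data.frame(snp_id = snp_id,
             beta_exp = exposure$beta, se_exp = exposure$se,
             pval_exp = exposure$pvalue,
             eaf_exp = exposure$eaf %||% NA_real_,
             beta_out = outcome$beta, se_out = outcome$se,
             pval_out = outcome$pvalue,
             eaf_out = outcome$eaf %||% NA_real_,
             flipped = flipped, palindromic = palindromic,
             proxy_of = proxy_of, stringsAsFactors = FALSE)
}

as_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- as.list(x)
  }
  x$effect_allele <- toupper(x$effect_allele)
  x$other_allele <- toupper(x$other_allele)
  x
}

#' Align one outcome record to the exposure's effect allele
#'
#' Resolves allele orientation between the exposure and outcome records of a
#' single SNP. Matching orientation passes effects through; swapped alleles
#' negate the outcome beta and reflect its frequency (`eaf_out` becomes
#' `1 - eaf_out`); strand-complemented pairs are complemented first
#' (non-palindromic pairs only, since complementing a palindromic pair is
#' unidentifiable). Incompatible pairs raise an error of class
#' `"strokemr_allele_mismatch"`.
#'
#' With `proxy = TRUE` the outcome record belongs to an LD proxy of the
#' exposure SNP: its statistics are taken verbatim with orientation trusted
#' (alleles of different variants cannot be compared), the instrument keeps
#' the exposure rsID, and the proxy's rsID is recorded in `proxy_of`.
#'
#' @param exposure,outcome Single SNP records: one-row data frames or lists
#'   with `snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`.
#' @param proxy `TRUE` when `outcome` is an LD-proxy record.
#' @return One-row data frame of class `harmonized_instruments`.
#' @export
align_alleles <- function(exposure, outcome, proxy = FALSE) {
  e <- as_record(exposure); o <- as_record(outcome)
  pal <- is_palindromic(e$effect_allele, e$other_allele)
  if (isTRUE(proxy)) {
    row <- harmonized_row(e$snp_id, e, o, flipped = FALSE, palindromic = pal,
                          proxy_of = o$snp_id)
  } else {
    if (!identical(e$snp_id, o$snp_id))
      stop("snp_id mismatch: ", e$snp_id, " vs ", o$snp_id, call. = FALSE)
    same <- o$effect_allele == e$effect_allele &
      o$other_allele == e$other_allele
    swap <- o$effect_allele == e$other_allele &
      o$other_allele == e$effect_allele
    comp_same <- comp_swap <- FALSE
    if (!same && !swap && !pal &&
        !is_palindromic(o$effect_allele, o$other_allele)) {
      cea <- unname(.complement[o$effect_allele])
      coa <- unname(.complement[o$other_allele])
      comp_same <- cea == e$effect_allele & coa == e$other_allele
      comp_swap <- cea == e$other_allele & coa == e$effect_allele
    }
    if (same || comp_same) {
      row <- harmonized_row(e$snp_id, e, o, flipped = FALSE,
                            palindromic = pal)
    } else if (swap || comp_swap) {
      o$beta <- -o$beta
      if (!is.null(o$eaf) && !is.na(o$eaf)) o$eaf <- 1 - o$eaf
      row <- harmonized_row(e$snp_id, e, o, flipped = TRUE,
                            palindromic = pal)
    } else {
      stop_strokemr(paste0("allele_mismatch: ", e$snp_id, " (",
                           e$effect_allele, "/", e$other_allele, " vs ",
                           o$effect_allele, "/", o$other_allele, ")"),
                    "strokemr_allele_mismatch")
    }
  }
  class(row) <- c("harmonized_instruments", "data.frame")
  row
}

#' Harmonize every SNP shared by two summary datasets
#'
#' Applies [align_alleles()] across the intersection of rsIDs, preserving
#' the exposure dataset's row order. No selection thresholds are applied;
#' use [select_instruments()] for the full pipeline.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @return List with `instruments` (`harmonized_instruments` data frame) and
#'   `dropped` (data frame of `snp_id`, `reason` for allele mismatches and
#'   SNPs absent from the outcome).
#' @export
harmonize_pair <- function(exposure, outcome) {
  idx <- match(exposure$snp_id, outcome$snp_id)
  present <- !is.na(idx)
  e <- as.data.frame(exposure)[present, , drop = FALSE]
  o <- as.data.frame(outcome)[idx[present], , drop = FALSE]
  pal_e <- .complement[e$effect_allele] == e$other_allele
  pal_o <- .complement[o$effect_allele] == o$other_allele
  same <- o$effect_allele == e$effect_allele &
    o$other_allele == e$other_allele
  swap <- o$effect_allele == e$other_allele &
    o$other_allele == e$effect_allele
  compable <- !same & !swap & !pal_e & !pal_o
  cea <- unname(.complement[o$effect_allele])
  coa <- unname(.complement[o$other_allele])
  comp_same <- compable & cea == e$effect_allele & coa == e$other_allele
  comp_swap <- compable & cea == e$other_allele & coa == e$effect_allele
  ok <- same | swap | comp_same | comp_swap
  flip <- (swap | comp_swap)[ok]
  instruments <- data.frame(
    snp_id = e$snp_id[ok],
    beta_exp = e$beta[ok], se_exp = e$se[ok], pval_exp = e$pvalue[ok],
    eaf_exp = e$eaf[ok],
    beta_out = ifelse(flip, -o$beta[ok], o$beta[ok]),
    se_out = o$se[ok], pval_out = o$pvalue[ok],
    eaf_out = ifelse(flip & !is.na(o$eaf[ok]), 1 - o$eaf[ok], o$eaf[ok]),
    flipped = flip, palindromic = unname(pal_e[ok]),
    proxy_of = NA_character_, stringsAsFactors = FALSE)
  class(instruments) <- c("harmonized_instruments", "data.frame")
  rownames(instruments) <- NULL
  miss <- exposure$snp_id[!present]
  mism <- e$snp_id[!ok]
  dropped <- data.frame(
    snp_id = c(miss, mism),
    reason = c(rep("missing_in_outcome", length(miss)),
               rep("allele_mismatch", length(mism))),
    stringsAsFactors = FALSE)
  list(instruments = instruments, dropped = dropped)
}

#' Select and harmonize MR instruments
#'
#' The fixed selection pipeline, every drop logged with its rule name:
#' \enumerate{
#'   \item drop exposure SNPs not reaching `exposure_p_max` (strict `<`);
#'   \item substitute outcome-side proxies per `proxy_map`;
#'   \item drop SNPs absent from the outcome dataset (`missing_in_outcome`);
#'   \item drop SNPs nominally associated with the outcome
#'     (`outcome_associated`);
#'   \item drop explicit exclusions;
#'   \item if `drop_palindromic`, drop palindromic SNPs whose frequency is
#'     ambiguous or missing in either dataset, or which are listed in
#'     `palindromic_exclusions`;
#'   \item harmonize the survivors via [align_alleles()].
#' }
#' The kept set is independent of input row order.
#'
#' @param exposure,outcome [summary_dataset()] objects.
#' @param rules A [selection_rules()] object.
#' @return List with `kept` (`harmonized_instruments` data frame) and
#'   `dropped` (data frame `snp_id`, `reason`; includes step-1 drops, so the
#'   two partition the exposure candidate set). Errors with class
#'   `"strokemr_no_instruments"` if nothing survives.
#' @export
#' @examples
#' sel <- select_instruments(load_fixture("AS", "exposure"),
#'                           load_fixture("AS", "outcome"))
#' nrow(sel$kept) # 11
select_instruments <- function(exposure, outcome,
                               rules = selection_rules()) {
  stopifnot(inherits(rules, "selection_rules"))
  drops <- list()
  note <- function(id, reason)
    drops[[length(drops) + 1L]] <<-
      data.frame(snp_id = id, reason = reason, stringsAsFactors = FALSE)

  out_idx <- setNames(seq_len(nrow(outcome)), outcome$snp_id)
  window <- rules$palindromic_eaf_window
  kept <- list()
  for (i in seq_len(nrow(exposure))) {
    id <- exposure$snp_id[i]
    # (1) exposure significance, strict inequality
    if (!(exposure$pvalue[i] < rules$exposure_p_max)) {
      note(id, "exposure_not_significant"); next
    }
    # (2) proxy substitution for SNPs absent from the outcome
    proxy_of <- NULL; out_id <- id
    if (is.na(out_idx[id]) && id %in% names(rules$proxy_map)) {
      candidate <- unname(rules$proxy_map[[id]])
      if (!is.na(out_idx[candidate])) {
        out_id <- candidate; proxy_of <- id
      }
    }
    # (3) missing in outcome
    if (is.na(out_idx[out_id])) { note(id, "missing_in_outcome"); next }
    orec <- outcome[out_idx[out_id], ]
    # (4) outcome association
    if (orec$pvalue < rules$outcome_p_min) {
      note(id, "outcome_associated"); next
    }
    # (5) explicit exclusions
    if (id %in% names(rules$explicit_exclusions)) {
      note(id, unname(rules$explicit_exclusions[[id]])); next
    }
    # (6) ambiguous palindromic SNPs
    if (rules$drop_palindromic &&
        is_palindromic(exposure$effect_allele[i],
                       exposure$other_allele[i])) {
      eafs <- c(exposure$eaf[i], orec$eaf)
      ambiguous <- any(is.na(eafs)) ||
        any(eafs >= window[1] & eafs <= window[2]) ||
        id %in% rules$palindromic_exclusions
      if (ambiguous) { note(id, "palindromic_ambiguous"); next }
    }
    # (7) harmonize
    row <- tryCatch(
      align_alleles(exposure[i, ], orec, proxy = !is.null(proxy_of)),
      strokemr_allele_mismatch = function(e) NULL)
    if (is.null(row)) { note(id, "allele_mismatch"); next }
    kept[[length(kept) + 1L]] <- row
  }
  if (!length(kept))
    stop_strokemr("no_instruments: selection left an empty instrument set",
                  "strokemr_no_instruments")
  instruments <- do.call(rbind, kept)
  class(instruments) <- c("harmonized_instruments", "data.frame")
  rownames(instruments) <- NULL
  list(kept = instruments,
       dropped = if (length(drops)) do.call(rbind, drops) else
         data.frame(snp_id = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Write a drop log as TSV
#' @param dropped Data frame with `snp_id` and `reason`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drop_log <- function(dropped, path) {
  write.table(dropped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
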