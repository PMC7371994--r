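#' Default column-name mapping for summary-statistic tables
#'
#' Maps the canonical field names used throughout the package to the column
#' names expected in a delimited file. Override individual entries to read
#' other GWAS summary formats.
#'
#' @return Named character vector: canonical field -> file column name.
#' @export
#' @examples
#' default_schema()
default_schema <- function() {
  c(snp_id = "snp", chrom = "chr", nearby_gene = "gene",
    effect_allele = "ea", other_allele = "nea", eaf = "eaf",
    beta = "beta", se = "se", pvalue = "pval")
}

.canonical_fields <- c("snp_id", "chrom", "nearby_gene", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pvalue")
.required_fields <- c("snp_id", "effect_allele", "other_allele",
                      "beta", "se", "pvalue")
.nucleotides <- c("A", "C", "G", "T")

#' Construct a validated summary-statistics dataset
#'
#' A `summary_dataset` is a data frame with one row per SNP (columns
#' `snp_id`, `chrom`, `nearby_gene`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`) carrying the trait label and sample sizes as
#' attributes. `beta` is the additive per-allele log-odds effect.
#'
#' Invariants enforced: unique `snp_id`; alleles are single nucleotides and
#' differ within a row; `se > 0`; `eaf`, when present, in \[0, 1\]; `pvalue`
#' in (0, 1\]; and `n_cases + n_controls == n_total` when all three are given.
#' A loose warn-only check compares each printed p-value with the two-sided
#' normal tail implied by `beta/se` (meta-analysis p-values routinely differ
#' from the plain Wald p by an order of magnitude or two, so the check only
#' warns past 3 decades on the log10 scale).
#'
#' @param records Data frame containing at least the required canonical
#'   columns (`snp_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pvalue`); optional columns are filled with `NA`.
#' @param trait_label Short trait name, e.g. `"AS"` or `"AD"`.
#' @param n_total,n_cases,n_controls Optional integer sample sizes.
#' @return A `summary_dataset` object.
#' @export
summary_dataset <- function(records, trait_label,
                            n_total = NULL, n_cases = NULL, n_controls = NULL) {
  stopifnot(is.data.frame(records), is.character(trait_label),
            length(trait_label) == 1L)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_req <- setdiff(.required_fields, names(records))
  if (length(missing_req))
    stop("missing required columns: ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  for (f in setdiff(.canonical_fields, names(records)))
    records[[f]] <- rep(if (f %in% c("eaf")) NA_real_ else NA_character_,
                        nrow(records))
  records <- records[, .canonical_fields]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (f in c("eaf", "beta", "se", "pvalue"))
    records[[f]] <- as.numeric(records[[f]])

  if (nrow(records)) {
    dup <- records$snp_id[duplicated(records$snp_id)]
    if (length(dup))
      stop("duplicate snp_id: ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    bad <- !(records$effect_allele %in% .nucleotides) |
      !(records$other_allele %in% .nucleotides)
    if (any(bad))
      stop("non-nucleotide alleles for: ",
           paste(records$snp_id[bad], collapse = ", "), call. = FALSE)
    if (any(records$effect_allele == records$other_allele))
      stop("effect_allele equals other_allele for: ",
           paste(records$snp_id[records$effect_allele ==
                                  records$other_allele], collapse = ", "),
           call. = FALSE)
    if (any(!is.finite(records$se)) || any(records$se <= 0))
      stop("se must be finite and > 0", call. = FALSE)
    eaf_ok <- is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)
    if (!all(eaf_ok)) stop("eaf outside [0, 1]", call. = FALSE)
    p_ok <- is.finite(records$pvalue) & records$pvalue > 0 &
      records$pvalue <= 1
    if (!all(p_ok)) stop("pvalue outside (0, 1]", call. = FALSE)
    # warn-only beta/se vs p consistency, log10 scale
    log10p_implied <- (pnorm(-abs(records$beta / records$se),
                             log.p = TRUE) + log(2)) / log(10)
    off <- abs(log10p_implied - log10(records$pvalue)) > 3 &
      records$pvalue > 1e-290   # floored/underflowed p-values exempt
    if (any(off))
      warning("pvalue inconsistent with beta/se (> 3 decades) for: ",
              paste(records$snp_id[off], collapse = ", "), call. = FALSE)
  }
  if (!is.null(n_total) && !is.null(n_cases) && !is.null(n_controls) &&
      n_cases + n_controls != n_total)
    stop("n_cases + n_controls != n_total", call. = FALSE)

  structure(records, class = c("summary_dataset", "data.frame"),
            trait_label = trait_label,
            n_total = if (is.null(n_total)) NULL else as.integer(n_total),
            n_cases = if (is.null(n_cases)) NULL else as.integer(n_cases),
            n_controls = if (is.null(n_controls)) NULL
                         else as.integer(n_controls))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("summary_dataset '%s': %d SNP(s)", attr(x, "trait_label"),
              nrow(x)))
  if (!is.null(attr(x, "n_total")))
    cat(sprintf(", n = %d", attr(x, "n_total")))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Trait label and sample sizes of a summary dataset
#' @param x A `summary_dataset`.
#' @return `trait_label()`: the label; `sample_sizes()`: named list with
#'   `n_total`, `n_cases`, `n_controls` (`NULL` when unknown).
#' @export
trait_label <- function(x) attr(x, "trait_label")

#' @rdname trait_label
#' @export
sample_sizes <- function(x) {
  list(n_total = attr(x, "n_total"), n_cases = attr(x, "n_cases"),
       n_controls = attr(x, "n_controls"))
}

#' Convert an odds ratio to a log-odds beta
#'
#' @param or_value Odds ratio(s), strictly positive.
#' @return `log(or_value)`.
#' @export
#' @examples
#' beta_from_or(0.9618) # -0.039
beta_from_or <- function(or_value) {
  if (!is.numeric(or_value) || any(!is.finite(or_value)) ||
      any(or_value <= 0))
    stop("or_value must be positive and finite", call. = FALSE)
  log(or_value)
}

#' Standard error of a log-odds beta from an OR confidence interval
#'
#' SE = (ln(CI_upper) - ln(CI_lower)) / (2 * 1.96), the normal-theory
#' back-calculation from a 95% interval on the odds-ratio scale. Depends only
#' on the ratio of the bounds.
#'
#' @param ci_lower,ci_upper Positive OR interval bounds, `ci_lower <= ci_upper`.
#' @return Standard error (0 for a degenerate interval).
#' @export
#' @examples
#' se_from_ci(1.2, 1.5) # 0.05693
se_from_ci <- function(ci_lower, ci_upper) {
  if (!is.numeric(ci_lower) || !is.numeric(ci_upper) ||
      any(!is.finite(ci_lower)) || any(!is.finite(ci_upper)) ||
      any(ci_lower <= 0) || any(ci_upper < ci_lower))
    stop("require 0 < ci_lower <= ci_upper", call. = FALSE)
  (log(ci_upper) - log(ci_lower)) / (2 * 1.96)
}

# Parse numbers that may carry en-dash/minus glyphs or mixed-case exponents
# ("3.619E-10", "6.44E–8").
parse_number <- function(x) {
  x <- gsub("–|−|—", "-", as.character(x))
  suppressWarnings(as.numeric(x))
}

#' Read a delimited GWAS summary-statistics table
#'
#' One `SnpAssociation` row per file row, in file order. Rows whose required
#' fields do not parse are rejected with a warning naming the offending row
#' numbers. Scientific-notation p-values are parsed case-insensitively and
#' Unicode dash glyphs are normalized.
#'
#' @param path File path.
#' @param trait_label Trait name stored on the result.
#' @param schema Column mapping as from [default_schema()]; partial overrides
#'   are merged over the default.
#' @param delim Field delimiter (tab by default).
#' @inheritParams summary_dataset
#' @return A [summary_dataset()].
#' @export
read_summary_table <- function(path, trait_label, schema = default_schema(),
                               delim = "\t", n_total = NULL, n_cases = NULL,
                               n_controls = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- c(schema, default_schema()[setdiff(names(default_schema()),
                                               names(schema))])
  raw <- read.delim(path, sep = delim, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  req_cols <- schema[.required_fields]
  missing_cols <- req_cols[!(req_cols %in% names(raw))]
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    snp_id = trimws(raw[[schema[["snp_id"]]]]))
  for (f in setdiff(.canonical_fields, "snp_id")) {
    col <- schema[[f]]
    if (!is.null(col) && col %in% names(raw)) {
      v <- trimws(raw[[col]])
      v[v %in% c("", "NA", "na", ".")] <- NA
      out[[f]] <- if (f %in% c("eaf", "beta", "se", "pvalue"))
        parse_number(v) else v
    }
  }
  if (nrow(out)) {
    bad <- out$snp_id %in% c("", NA) |
      is.na(out$beta) | is.na(out$se) | is.na(out$pvalue) |
      is.na(out$effect_allele) | is.na(out$other_allele)
    if (any(bad)) {
      warning("rejected ", sum(bad), " row(s) with unparseable required ",
              "fields: rows ", paste(which(bad), collapse = ", "),
              call. = FALSE)
      out <- out[!bad, , drop = FALSE]
    }
  }
  dup <- out$snp_id[duplicated(out$snp_id)]
  if (length(dup))
    stop("duplicate snp_id in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  summary_dataset(out, trait_label, n_total = n_total, n_cases = n_cases,
                  n_controls = n_controls)
}

#' Write a summary dataset as a delimited table
#'
#' Inverse of [read_summary_table()] under the same schema: field values
#' round-trip at printed precision.
#'
#' @param x A `summary_dataset`.
#' @param path Output file path.
#' @param schema Column mapping (canonical -> file column names).
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path, schema = default_schema(),
                                delim = "\t") {
  stopifnot(inherits(x, "summary_dataset"))
  out <- as.data.frame(x)[, .canonical_fields]
  names(out) <- schema[.canonical_fields]
  write.table(out, path, sep = delim, quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

.fixture_keys <- c("AS", "AIS", "LAS", "CES")
.exposure_n <- list(n_total = 521612L, n_cases = 67162L, n_controls = 454450L)
.outcome_n <- list(n_total = 54162L, n_cases = 17008L, n_controls = 37154L)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "strokemr")
  if (p == "") stop("fixture file not installed: ", file, call. = FALSE)
  p
}

#' Load a packaged instrument table
#'
#' Digit-for-digit transcriptions of the published stroke->AD instrument
#' tables: exposure (stroke GWAS) and outcome (AD GWAS) summary statistics
#' for the four phenotypes, plus the SNP x trait p-value matrix used by the
#' pleiotropy screen. SNPs the source marks `NA` on the outcome side are
#' absent from the outcome dataset; where a proxy SNP supplied the outcome
#' record, the outcome dataset carries the proxy's rsID (see
#' [selection_rules()] `proxy_map`).
#'
#' @param name `"AS"`, `"AIS"`, `"LAS"`, `"CES"`, or `"pleiotropy_matrix"`.
#' @param role `"exposure"` (stroke GWAS columns) or `"outcome"` (AD GWAS
#'   columns); ignored for the pleiotropy matrix.
#' @return A [summary_dataset()], or for `"pleiotropy_matrix"` a data frame
#'   of p-values with a `snp_id` column (NA = association not available).
#' @export
#' @examples
#' load_fixture("AS", "exposure")
load_fixture <- function(name, role = c("exposure", "outcome")) {
  if (identical(name, "pleiotropy_matrix")) {
    raw <- read.delim(fixture_path("pleiotropy_pvalues.tsv"),
                      stringsAsFactors = FALSE, check.names = FALSE)
    raw[-1] <- lapply(raw[-1], parse_number)
    return(raw)
  }
  if (!(name %in% .fixture_keys))
    stop("unknown fixture key: ", name, call. = FALSE)
  role <- match.arg(role)
  raw <- read.delim(fixture_path(paste0("gwas_", tolower(name), "_ad.tsv")),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  num <- function(col) parse_number(raw[[col]])
  if (role == "exposure") {
    rec <- data.frame(snp_id = raw$snp, chrom = raw$chr,
                      nearby_gene = raw$gene, effect_allele = raw$ea,
                      other_allele = raw$nea, eaf = num("eaf"),
                      beta = num("beta_exp"), se = num("se_exp"),
                      pvalue = num("pval_exp"), stringsAsFactors = FALSE)
    summary_dataset(rec, name, n_total = .exposure_n$n_total,
                    n_cases = .exposure_n$n_cases,
                    n_controls = .exposure_n$n_controls)
  } else {
    keep <- !is.na(parse_number(raw$beta_out))
    raw <- raw[keep, , drop = FALSE]
    proxy <- trimws(raw$proxy_out)
    snp <- ifelse(is.na(proxy) | proxy == "" | proxy == "NA",
                  raw$snp, proxy)
    rec <- data.frame(snp_id = snp, chrom = raw$chr,
                      nearby_gene = raw$gene, effect_allele = raw$ea,
                      other_allele = raw$nea, eaf = NA_real_,
                      beta = num("beta_out"), se = num("se_out"),
                      pvalue = num("pval_out"), stringsAsFactors = FALSE)
    summary_dataset(rec, "AD", n_total = .outcome_n$n_total,
                    n_cases = .outcome_n$n_cases,
                    n_controls = .outcome_n$n_controls)
  }
}
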