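#' Scenario configuration for the synthetic summary-statistic generator
#'
#' Describes a two-sample MR world with known ground truth. Defaults mirror
#' the scale of the packaged stroke/AD analyses: per-SNP exposure effects of
#' a few hundredths of a log-odds unit with genome-wide-significant
#' precision (se_exp ~ 0.008-0.016 at n ~ 5e5) and an outcome GWAS roughly
#' a tenth the size (se_out ~ 0.015-0.035).
#'
#' @param n_snps Number of instruments J (>= 1).
#' @param theta True causal effect (log-odds of outcome per log-odds
#'   exposure liability).
#' @param gamma_mean,gamma_sd Normal distribution of true per-SNP exposure
#'   effects, truncated away from zero at `gamma_min` to keep Wald ratios
#'   defined.
#' @param gamma_min Truncation threshold for |gamma| (default 0.02).
#' @param se_exp_range,se_out_range Uniform ranges for per-SNP standard
#'   errors.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct effects),
#'   `"directional"` (mean `alpha_mean`), or `"invalid_majority"`
#'   (directional with `prop_invalid > 0.5`).
#' @param alpha_mean,alpha_sd Pleiotropy distribution parameters (the mean
#'   is forced to zero under `"balanced"`).
#' @param prop_invalid Fraction of SNPs receiving a direct effect.
#' @param exposure_noise If `TRUE`, observed exposure betas are drawn
#'   `Normal(gamma_j, se_exp_j)`; the default `FALSE` reports `gamma_j`
#'   exactly (the no-measurement-error convention matched by the
#'   estimators).
#' @param n_exp,n_out Nominal GWAS sample sizes carried on the generated
#'   datasets (used by Steiger filtering).
#' @param seed RNG seed (required; Mersenne-Twister).
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(n_snps, theta = 0, gamma_mean = 0.06,
                            gamma_sd = 0.015, gamma_min = 0.02,
                            se_exp_range = c(0.008, 0.016),
                            se_out_range = c(0.015, 0.035),
                            pleiotropy_mode = c("none", "balanced",
                                                "directional",
                                                "invalid_majority"),
                            alpha_mean = 0, alpha_sd = 0.01,
                            prop_invalid = 0, exposure_noise = FALSE,
                            n_exp = 521612, n_out = 54162, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_snps >= 1, gamma_min > 0,
            length(se_exp_range) == 2L, length(se_out_range) == 2L)
  if (any(se_exp_range <= 0) || any(se_out_range <= 0) ||
      diff(se_exp_range) < 0 || diff(se_out_range) < 0)
    stop("SE ranges must be positive and ordered", call. = FALSE)
  if (prop_invalid < 0 || prop_invalid > 1)
    stop("prop_invalid must lie in [0, 1]", call. = FALSE)
  if (pleiotropy_mode == "invalid_majority" && prop_invalid <= 0.5)
    stop("invalid_majority requires prop_invalid > 0.5", call. = FALSE)
  if (pleiotropy_mode == "balanced") alpha_mean <- 0
  if (pleiotropy_mode == "none") prop_invalid <- 0
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 gamma_min = gamma_min, se_exp_range = se_exp_range,
                 se_out_range = se_out_range,
                 pleiotropy_mode = pleiotropy_mode,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 prop_invalid = prop_invalid,
                 exposure_noise = isTRUE(exposure_noise),
                 n_exp = as.integer(n_exp), n_out = as.integer(n_out),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# non-palindromic allele pairs only, so harmonization is unambiguous
.sim_allele_pairs <- matrix(c("A", "G", "G", "A", "A", "C", "C", "A",
                              "C", "T", "T", "C", "G", "T", "T", "G"),
                            ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome summary-statistic dataset
#'
#' For each SNP j: a true exposure effect `gamma_j ~ Normal(gamma_mean,
#' gamma_sd)` truncated at `|gamma| >= gamma_min`; a direct (pleiotropic)
#' outcome effect `alpha_j` (zero for valid SNPs); observed
#' `beta_out_j ~ Normal(theta * gamma_j + alpha_j, se_out_j)` and
#' `beta_exp_j` either `gamma_j` exactly or `Normal(gamma_j, se_exp_j)`
#' (see `exposure_noise`). P-values are two-sided normal. Alleles are
#' assigned non-palindromic and pre-aligned. Identical configs (including
#' seed) produce byte-identical output; the RNG (Mersenne-Twister) and seed
#' are recorded as attributes.
#'
#' @param config A [scenario_config()].
#' @return List of class `mr_simulation`: `exposure` and `outcome`
#'   ([summary_dataset()]s), `truth` (data frame `snp_id`, `gamma`,
#'   `alpha`), and `theta`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  J <- config$n_snps
  out <- with_seed(config$seed, {
    gamma <- rnorm(J, config$gamma_mean, config$gamma_sd)
    while (any(small <- abs(gamma) < config$gamma_min))
      gamma[small] <- rnorm(sum(small), config$gamma_mean, config$gamma_sd)
    alpha <- numeric(J)
    n_invalid <- round(config$prop_invalid * J)
    if (config$pleiotropy_mode != "none" && n_invalid > 0) {
      idx <- sample.int(J, n_invalid)
      alpha[idx] <- rnorm(n_invalid, config$alpha_mean, config$alpha_sd)
    }
    se_exp <- runif(J, config$se_exp_range[1], config$se_exp_range[2])
    se_out <- runif(J, config$se_out_range[1], config$se_out_range[2])
    beta_exp <- if (config$exposure_noise) rnorm(J, gamma, se_exp) else gamma
    beta_out <- rnorm(J, config$theta * gamma + alpha, se_out)
    pair_idx <- sample.int(nrow(.sim_allele_pairs), J, replace = TRUE)
    eaf <- runif(J, 0.05, 0.95)
    list(gamma = gamma, alpha = alpha, se_exp = se_exp, se_out = se_out,
         beta_exp = beta_exp, beta_out = beta_out, pair_idx = pair_idx,
         eaf = eaf)
  })
  snp_id <- sprintf("snp%04d", seq_len(J))
  pvals <- function(b, s) pmax(two_sided_normal_p(b / s), 1e-300)
  base <- data.frame(snp_id = snp_id, chrom = NA_character_,
                     nearby_gene = NA_character_,
                     effect_allele = .sim_allele_pairs[out$pair_idx, 1],
                     other_allele = .sim_allele_pairs[out$pair_idx, 2],
                     eaf = out$eaf, stringsAsFactors = FALSE)
  exposure <- summary_dataset(
    cbind(base, data.frame(beta = out$beta_exp, se = out$se_exp,
                           pvalue = pvals(out$beta_exp, out$se_exp))),
    "sim_exposure", n_total = config$n_exp)
  outcome <- summary_dataset(
    cbind(base, data.frame(beta = out$beta_out, se = out$se_out,
                           pvalue = pvals(out$beta_out, out$se_out))),
    "sim_outcome", n_total = config$n_out)
  structure(list(exposure = exposure, outcome = outcome,
                 truth = data.frame(snp_id = snp_id, gamma = out$gamma,
                                    alpha = out$alpha,
                                    stringsAsFactors = FALSE),
                 theta = config$theta),
            class = "mr_simulation",
            rng = "Mersenne-Twister", seed = config$seed)
}

#' Monte-Carlo calibration of the MR estimators
#'
#' Repeatedly simulates a scenario, harmonizes each replicate through the
#' standard pipeline, runs the requested estimators, and tabulates empirical
#' rejection rate at level `alpha`, mean bias, and empirical SE per method.
#' Replicate r uses seed `config$seed + r`. For `"egger_intercept"` the
#' reference truth is the mean direct effect `alpha_mean * prop_invalid`;
#' all other methods are compared against `theta`.
#'
#' @param config A [scenario_config()].
#' @param n_reps Number of replicates (>= 100).
#' @param alpha Nominal test level.
#' @param methods Subset of `"ivw"`, `"weighted_median"`, `"egger_slope"`,
#'   `"egger_intercept"`.
#' @param n_boot Bootstrap replicates for the weighted-median SE within each
#'   replicate (kept small by default; only the SE/p depend on it).
#' @return List with `summary` (per-method data frame: `method`,
#'   `rejection_rate`, `mean_bias`, `empirical_se`, `truth`) and
#'   `replicates` (long per-replicate table).
#' @export
evaluate_calibration <- function(config, n_reps, alpha = 0.05,
                                 methods = c("ivw", "weighted_median",
                                             "egger_slope",
                                             "egger_intercept"),
                                 n_boot = 100) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_reps < 100) stop("n_reps must be at least 100", call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  truth_of <- function(m)
    if (m == "egger_intercept") config$alpha_mean * config$prop_invalid
    else config$theta
  rows <- vector("list", n_reps * length(methods)); k <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_pair(cfg)
    inst <- harmonize_pair(sim$exposure, sim$outcome)$instruments
    for (m in methods) {
      est <- switch(m,
        ivw = mr_ivw(inst)$estimate,
        weighted_median = mr_weighted_median(inst, n_boot = n_boot,
                                             seed = cfg$seed),
        egger_slope = mr_egger(inst)$slope,
        egger_intercept = mr_egger(inst)$intercept)
      k <- k + 1L
      rows[[k]] <- data.frame(rep = r, method = m, estimate = est$beta,
                              se = est$se, pvalue = est$pvalue,
                              reject = est$pvalue < alpha,
                              bias = est$beta - truth_of(m),
                              stringsAsFactors = FALSE)
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(methods, function(m) {
    d <- replicates[replicates$method == m, ]
    data.frame(method = m, rejection_rate = mean(d$reject),
               mean_bias = mean(d$bias), empirical_se = sd(d$estimate),
               truth = truth_of(m), stringsAsFactors = FALSE)
  }))
  list(summary = summary, replicates = replicates, alpha = alpha,
       n_reps = n_reps)
}
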