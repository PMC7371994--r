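rec <- function(id, ea, nea, beta, se = 0.02, p = 0.5, eaf = NA_real_) {
  list(snp_id = id, effect_allele = ea, other_allele = nea, eaf = eaf,
       beta = beta, se = se, pvalue = p)
}

test_that("is_palindromic identifies ambiguous-strand pairs", {
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_equal(is_palindromic(c("A", "G"), c("T", "A")), c(TRUE, FALSE))
  expect_error(is_palindromic("N", "A"), "nucleotides")
})

test_that("align_alleles resolves orientation, strand, and mismatches", {
  # same orientation: pass-through (Table 1 rs880315 values)
  h <- align_alleles(rec("rs880315", "C", "T", 0.0527, 0.0084),
                     rec("rs880315", "C", "T", -0.0083, 0.0171))
  expect_false(h$flipped)
  expect_equal(h$beta_out, -0.0083)

  # swapped alleles: sign flip and eaf reflection
  h <- align_alleles(rec("s", "C", "T", 0.05),
                     rec("s", "T", "C", 0.02, eaf = 0.3))
  expect_true(h$flipped)
  expect_equal(h$beta_out, -0.02)
  expect_equal(h$eaf_out, 0.7)

  # strand complement, same orientation
  h <- align_alleles(rec("s", "C", "T", 0.05), rec("s", "G", "A", 0.02))
  expect_false(h$flipped)
  expect_equal(h$beta_out, 0.02)

  # strand complement, swapped
  h <- align_alleles(rec("s", "C", "T", 0.05), rec("s", "A", "G", 0.02))
  expect_true(h$flipped)
  expect_equal(h$beta_out, -0.02)

  expect_error(align_alleles(rec("s", "C", "T", 0.05),
                             rec("s", "A", "C", 0.02)),
               class = "strokemr_allele_mismatch")

  # involution: re-aligning an already-aligned pair changes nothing
  h1 <- align_alleles(rec("s", "C", "T", 0.05), rec("s", "T", "C", 0.02))
  h2 <- align_alleles(rec("s", "C", "T", 0.05),
                      rec("s", "C", "T", h1$beta_out))
  expect_false(h2$flipped)
  expect_equal(h2$beta_out, h1$beta_out)

  # proxy records pass through verbatim and keep both rsIDs
  h <- align_alleles(rec("rs6825454", "C", "T", 0.0583),
                     rec("rs56010410", "C", "T", 0.0047), proxy = TRUE)
  expect_identical(h$snp_id, "rs6825454")
  expect_identical(h$proxy_of, "rs56010410")
})

test_that("selection_rules validates thresholds and window", {
  expect_error(selection_rules(exposure_p_max = 0.1, outcome_p_min = 0.05),
               "exposure_p_max")
  expect_error(selection_rules(palindromic_eaf_window = c(0.3, 0.6)),
               "symmetric")
  r <- selection_rules(explicit_exclusions = c(rs42039 = "confounder"))
  expect_identical(unname(r$explicit_exclusions["rs42039"]), "confounder")
})

test_that("select_instruments reproduces the four published arms", {
  sel <- select_instruments(load_fixture("AS", "exposure"),
                            load_fixture("AS", "outcome"))
  expect_equal(nrow(sel$kept), 11L)
  expect_equal(nrow(sel$dropped), 0L)
  expect_false(any(sel$kept$flipped))

  sel <- select_instruments(
    load_fixture("AIS", "exposure"), load_fixture("AIS", "outcome"),
    selection_rules(proxy_map = c(rs6825454 = "rs56010410")))
  expect_equal(nrow(sel$kept), 9L)
  expect_identical(
    sel$dropped$reason[sel$dropped$snp_id == "rs34311906"],
    "missing_in_outcome")
  expect_identical(sel$dropped$reason[sel$dropped$snp_id == "rs42039"],
                   "outcome_associated")
  expect_identical(
    sel$kept$proxy_of[sel$kept$snp_id == "rs6825454"], "rs56010410")

  sel <- select_instruments(load_fixture("LAS", "exposure"),
                            load_fixture("LAS", "outcome"))
  expect_setequal(sel$kept$snp_id,
                  c("rs10820405", "rs12124533", "rs2107595"))
  expect_identical(sel$dropped$reason[sel$dropped$snp_id == "rs7610618"],
                   "missing_in_outcome")
  expect_identical(
    sel$dropped$reason[sel$dropped$snp_id == "rs17612742"],
    "outcome_associated")

  sel <- select_instruments(load_fixture("CES", "exposure"),
                            load_fixture("CES", "outcome"))
  expect_equal(nrow(sel$kept), 3L)
})

test_that("exposure threshold is strict and logged", {
  exp_d <- summary_dataset(data.frame(
    snp_id = c("rs_strong", "rs12476527"), effect_allele = "A",
    other_allele = "G", beta = c(0.06, 0.055),
    se = c(0.01, 0.0102), pvalue = c(1e-9, 6.44e-8),
    stringsAsFactors = FALSE), "X")
  out_d <- summary_dataset(data.frame(
    snp_id = c("rs_strong", "rs12476527"), effect_allele = "A",
    other_allele = "G", beta = c(0.01, 0.01), se = 0.02,
    pvalue = 0.6, stringsAsFactors = FALSE), "Y")
  sel <- select_instruments(exp_d, out_d)
  expect_identical(sel$kept$snp_id, "rs_strong")
  expect_identical(sel$dropped$reason, "exposure_not_significant")
  # boundary value 5e-8 is excluded too
  exp_d$pvalue[2] <- 5e-8
  sel <- select_instruments(exp_d, out_d)
  expect_identical(sel$dropped$snp_id, "rs12476527")
})

test_that("palindromic handling follows the ambiguity rules", {
  mk <- function(eaf_exp, eaf_out, trait = c("X", "Y")) {
    e <- summary_dataset(data.frame(
      snp_id = "rs_p", effect_allele = "A", other_allele = "T",
      eaf = eaf_exp, beta = 0.06, se = 0.01, pvalue = 1e-9,
      stringsAsFactors = FALSE), trait[1])
    o <- summary_dataset(data.frame(
      snp_id = "rs_p", effect_allele = "A", other_allele = "T",
      eaf = eaf_out, beta = 0.01, se = 0.02, pvalue = 0.6,
      stringsAsFactors = FALSE), trait[2])
    list(e = e, o = o)
  }
  rules_on <- selection_rules(drop_palindromic = TRUE)
  # intermediate frequency -> ambiguous
  d <- mk(0.5, 0.5)
  expect_error(select_instruments(d$e, d$o, rules_on),
               class = "strokemr_no_instruments")
  # missing outcome-side frequency -> ambiguous
  d <- mk(0.3, NA_real_)
  expect_error(select_instruments(d$e, d$o, rules_on),
               class = "strokemr_no_instruments")
  # clear frequency on both sides -> kept
  d <- mk(0.3, 0.3)
  expect_equal(nrow(select_instruments(d$e, d$o, rules_on)$kept), 1L)
  # explicit palindromic exclusion overrides a clear frequency
  sel_rules <- selection_rules(drop_palindromic = TRUE,
                               palindromic_exclusions = "rs_p")
  expect_error(select_instruments(d$e, d$o, sel_rules),
               class = "strokemr_no_instruments")
  # palindromic handling off: kept regardless
  expect_equal(nrow(select_instruments(d$e, d$o)$kept), 1L)
})

test_that("kept and dropped partition the candidates, order-independent", {
  exposure <- load_fixture("AIS", "exposure")
  outcome <- load_fixture("AIS", "outcome")
  rules <- selection_rules(proxy_map = c(rs6825454 = "rs56010410"))
  sel <- select_instruments(exposure, outcome, rules)
  ids <- c(sel$kept$snp_id, sel$dropped$snp_id)
  expect_setequal(ids, exposure$snp_id)
  expect_false(any(duplicated(ids)))

  for (s in 1:3) {
    set.seed(s)
    perm <- exposure[sample(nrow(exposure)), ]
    class(perm) <- class(exposure)
    attributes(perm)[c("trait_label")] <- attributes(exposure)["trait_label"]
    sel2 <- select_instruments(perm, outcome, rules)
    expect_setequal(sel2$kept$snp_id, sel$kept$snp_id)
  }
})

test_that("harmonize_pair aligns intersections and logs the rest", {
  sim <- simulate_pair(scenario_config(n_snps = 8, theta = 0.1, seed = 42))
  h <- harmonize_pair(sim$exposure, sim$outcome)
  expect_equal(nrow(h$instruments), 8L)
  expect_equal(nrow(h$dropped), 0L)
  expect_equal(h$instruments$beta_exp, sim$exposure$beta)
  # drop one outcome record: reported missing
  out2 <- sim$outcome[-3, ]
  h2 <- harmonize_pair(sim$exposure, out2)
  expect_identical(h2$dropped$snp_id, sim$exposure$snp_id[3])
  expect_identical(h2$dropped$reason, "missing_in_outcome")
})
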