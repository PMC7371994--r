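test_that("wald_ratio implements the delta-method ratio", {
  las <- fixture_instruments("LAS")
  est <- wald_ratio(las[las$snp_id == "rs10820405", ])
  expect_equal(round(est$beta, 3), -0.047)
  expect_equal(round(est$pvalue, 3), 0.664)

  est <- wald_ratio(list(beta_exp = 0.5, beta_out = 0, se_out = 0.05))
  expect_equal(est$beta, 0)
  expect_equal(est$pvalue, 1)

  est <- wald_ratio(list(beta_exp = 0.5, beta_out = 0.1, se_out = 0.05))
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)

  expect_error(wald_ratio(list(beta_exp = 0, beta_out = 0.1,
                               se_out = 0.05)), "nonzero")
})

test_that("mr_ivw reproduces the published pooled estimates", {
  as_inst <- fixture_instruments("AS")
  res <- mr_ivw(as_inst)
  expect_equal(round(res$estimate$beta, 3), -0.039)
  expect_equal(round(res$estimate$pvalue, 3), 0.750)
  expect_equal(round(res$estimate$or_value, 3), 0.962)
  expect_equal(round(res$heterogeneity$q, 4), 15.8637)
  expect_identical(res$heterogeneity$df, 10L)
  expect_equal(round(res$heterogeneity$pvalue, 4), 0.1036)
  expect_identical(res$estimate$variance_model, "random")

  las <- fixture_instruments("LAS")
  res <- mr_ivw(las)                       # J = 3 -> fixed under "default"
  expect_equal(round(res$estimate$beta, 3), 0.037)
  expect_equal(round(res$estimate$pvalue, 3), 0.568)
  expect_identical(res$estimate$variance_model, "fixed")

  single <- as_inst[1, ]
  expect_equal(mr_ivw(single)$estimate$beta, wald_ratio(single)$beta)
  expect_equal(mr_ivw(single)$estimate$se, wald_ratio(single)$se)
  expect_error(mr_ivw(make_instruments(0, 0.1, 0.05)), "nonzero")
})

test_that("IVW and Egger match an independent WLS oracle to 1e-10", {
  for (s in 1:5) {
    inst <- random_instruments(J = sample(3:6, 1), seed = 100 + s)
    o <- oracle_ivw_fixed(inst)
    res <- mr_ivw(inst, "fixed")
    expect_equal(res$estimate$beta, unname(o["beta"]), tolerance = 1e-10)
    expect_equal(res$estimate$se, unname(o["se"]), tolerance = 1e-10)

    oe <- oracle_egger(inst)
    eg <- mr_egger(inst)
    scale <- eg$slope$scale_factor
    expect_equal(eg$slope$beta, unname(oe["slope"]), tolerance = 1e-10)
    expect_equal(eg$intercept$beta, unname(oe["intercept"]),
                 tolerance = 1e-10)
    expect_equal(eg$slope$se, unname(oe["se_slope"]) * scale,
                 tolerance = 1e-10)
    expect_equal(eg$intercept$se, unname(oe["se_int"]) * scale,
                 tolerance = 1e-10)
  }
})

test_that("IVW is orientation-invariant and Q is scale-free", {
  inst <- fixture_instruments("AS")
  base <- mr_ivw(inst)
  for (s in 1:3) {
    set.seed(200 + s)
    flip <- sample(c(-1, 1), nrow(inst), replace = TRUE)
    inst2 <- inst
    inst2$beta_exp <- inst$beta_exp * flip
    inst2$beta_out <- inst$beta_out * flip
    res <- mr_ivw(inst2)
    expect_equal(res$estimate$beta, base$estimate$beta, tolerance = 1e-12)
    expect_equal(res$heterogeneity$q, base$heterogeneity$q,
                 tolerance = 1e-12)
  }
  for (c_ in c(0.5, 2, 10)) {
    inst3 <- inst
    inst3$se_out <- inst$se_out * c_
    expect_equal(mr_ivw(inst3)$heterogeneity$q,
                 base$heterogeneity$q / c_^2)
  }
  # Q = 0 iff all ratios equal
  flat <- make_instruments(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2),
                           c(0.01, 0.02, 0.03))
  expect_equal(mr_ivw(flat)$heterogeneity$q, 0, tolerance = 1e-24)
})

test_that("random-effects SE floors at the fixed-effects SE", {
  # overdispersed: Q > df
  inst <- fixture_instruments("AS")
  f <- mr_ivw(inst, "fixed"); r <- mr_ivw(inst, "random")
  expect_gt(r$estimate$se, f$estimate$se)
  expect_equal(r$estimate$se,
               f$estimate$se * sqrt(r$heterogeneity$q /
                                      r$heterogeneity$df))
  # underdispersed: Q < df -> floor binds, SEs equal
  ais <- fixture_instruments("AIS")
  f <- mr_ivw(ais, "fixed"); r <- mr_ivw(ais, "random")
  expect_lt(r$heterogeneity$q, r$heterogeneity$df)
  expect_equal(r$estimate$se, f$estimate$se)
})

test_that("weighted median interpolates the 50th percentile ratio", {
  inst <- make_instruments(c(1, 1, 1), c(1, 2, 10), c(1, 1, 1))
  est <- mr_weighted_median(inst, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2)

  as_inst <- fixture_instruments("AS")
  est <- mr_weighted_median(as_inst, n_boot = 200, seed = 1)
  expect_equal(round(est$beta, 3), -0.156)

  # degenerate: identical ratios, vanishing noise
  flat <- make_instruments(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2),
                           rep(1e-8, 3), se_exp = rep(1e-8, 3))
  est <- mr_weighted_median(flat, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.5)
  expect_lt(est$se, 1e-5)

  expect_error(mr_weighted_median(as_inst[1:2, ], n_boot = 10, seed = 1),
               "at least 3")
  expect_error(mr_weighted_median(as_inst, n_boot = 10), "seed")
})

test_that("weighted median: bracketing, equal-weight medians, determinism", {
  for (s in 1:5) {
    inst <- random_instruments(J = sample(3:9, 1), seed = 300 + s)
    theta <- inst$beta_out / inst$beta_exp
    est <- mr_weighted_median(inst, n_boot = 20, seed = s)
    expect_gte(est$beta, min(theta))
    expect_lte(est$beta, max(theta))
  }
  # equal weights, odd J -> the middle ratio
  inst <- make_instruments(rep(0.2, 5), 0.2 * c(-0.3, 0.1, 0.25, 0.6, 1.1),
                           rep(0.02, 5))
  est <- mr_weighted_median(inst, n_boot = 20, seed = 1)
  expect_equal(est$beta, 0.25)

  as_inst <- fixture_instruments("AS")
  a <- mr_weighted_median(as_inst, n_boot = 100, seed = 99)
  b <- mr_weighted_median(as_inst, n_boot = 100, seed = 99)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(as_inst, n_boot = 100, seed = 7)
  expect_identical(a$beta, c_$beta)   # point estimate seed-free
  expect_false(identical(a$se, c_$se))
})

test_that("mr_egger recovers slope, intercept and residual Q", {
  as_inst <- fixture_instruments("AS")
  eg <- mr_egger(as_inst)
  expect_equal(round(eg$slope$beta, 3), -1.312)
  expect_equal(round(eg$intercept$beta, 3), 0.071)
  expect_equal(round(eg$slope$pvalue, 3), 0.098)
  expect_equal(round(eg$intercept$pvalue, 3), 0.105)
  expect_identical(eg$heterogeneity$df, 9L)

  ces <- fixture_instruments("CES")
  eg <- mr_egger(ces)
  expect_equal(round(eg$slope$beta, 3), -0.062)
  expect_equal(round(eg$intercept$beta, 3), -0.001)

  # exact line: slope/intercept recovered, zero residual heterogeneity
  x <- c(0.05, 0.1, 0.2, 0.3)
  inst <- make_instruments(x, 0.04 + 0.7 * x, c(0.01, 0.03, 0.02, 0.015))
  eg <- mr_egger(inst)
  expect_equal(eg$slope$beta, 0.7, tolerance = 1e-12)
  expect_equal(eg$intercept$beta, 0.04, tolerance = 1e-12)
  expect_equal(eg$heterogeneity$q, 0, tolerance = 1e-20)

  expect_error(mr_egger(make_instruments(rep(0.1, 4), rnorm(4), rep(0.02, 4))),
               "rank")
  expect_error(mr_egger(as_inst[1:2, ]), "at least 3")
})

test_that("estimate objects keep OR and CI consistent with beta/se", {
  for (est in list(mr_ivw(fixture_instruments("AS"))$estimate,
                   mr_egger(fixture_instruments("CES"))$slope)) {
    expect_equal(est$or_value, exp(est$beta), tolerance = 1e-12)
    expect_lt(est$ci_lower, est$or_value)
    expect_gt(est$ci_upper, est$or_value)
    expect_equal(est$ci_upper, exp(est$beta + 1.96 * est$se))
  }
})
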