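# small builders used across the suite

make_instruments <- function(beta_exp, beta_out, se_out,
                             se_exp = rep(0.01, length(beta_exp)),
                             ids = sprintf("s%02d", seq_along(beta_exp)),
                             pval_exp = NULL, pval_out = NULL) {
  df <- data.frame(
    snp_id = ids, beta_exp = beta_exp, se_exp = se_exp,
    pval_exp = pval_exp %||% 2 * pnorm(-abs(beta_exp / se_exp)),
    eaf_exp = NA_real_, beta_out = beta_out, se_out = se_out,
    pval_out = pval_out %||% 2 * pnorm(-abs(beta_out / se_out)),
    eaf_out = NA_real_, flipped = FALSE, palindromic = FALSE,
    proxy_of = NA_character_, stringsAsFactors = FALSE)
  class(df) <- c("harmonized_instruments", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_instruments <- function(key, steiger = FALSE) {
  rules <- selection_rules(
    drop_palindromic = steiger,
    proxy_map = if (key == "AIS") c(rs6825454 = "rs56010410")
                else character())
  sel <- select_instruments(load_fixture(key, "exposure"),
                            load_fixture(key, "outcome"), rules)
  if (steiger)
    steiger_filter(sel$kept, 521612, 54162)$kept
  else sel$kept
}

random_instruments <- function(J, seed) {
  set.seed(seed)
  make_instruments(beta_exp = runif(J, 0.03, 0.2) * sample(c(-1, 1), J, TRUE),
                   beta_out = rnorm(J, 0, 0.03),
                   se_out = runif(J, 0.01, 0.04),
                   se_exp = runif(J, 0.005, 0.02))
}

# independent WLS oracles built on lm(), distinct from the closed-form
# implementation path
oracle_ivw_fixed <- function(inst) {
  f <- lm(beta_out ~ beta_exp - 1, data = inst, weights = 1 / se_out^2)
  s <- summary(f)
  c(beta = unname(coef(f)[1]), se = unname(s$coefficients[1, 2] / s$sigma))
}

oracle_egger <- function(inst) {
  sgn <- ifelse(inst$beta_exp < 0, -1, 1)
  d <- data.frame(x = inst$beta_exp * sgn, y = inst$beta_out * sgn,
                  w = 1 / inst$se_out^2)
  f <- lm(y ~ x, data = d, weights = d$w)
  s <- summary(f)
  c(intercept = unname(coef(f)[1]), slope = unname(coef(f)[2]),
    se_int = unname(s$coefficients[1, 2] / s$sigma),
    se_slope = unname(s$coefficients[2, 2] / s$sigma))
}

write_tiny_table <- function(path, n = 3, dup = FALSE) {
  lines <- c("snp\tchr\tea\tnea\teaf\tbeta\tse\tpval",
             sprintf("rs%d\t1\tA\tG\t0.%d\t0.06%d\t0.01\t2e-9",
                     seq_len(n), seq_len(n), seq_len(n)))
  if (dup) lines <- c(lines, lines[2])
  writeLines(lines, path)
  path
}
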