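# Shared builders for tests. Everything is constructed in code; no stored
# fixtures.

# Minimal summary-statistics data.frame with sensible defaults.
make_stats <- function(snp, effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.02,
                       pval = NULL, n = 18340, chrom = "1",
                       pos = seq_along(snp) * 2e7) {
  k <- length(snp)
  df <- data.frame(
    snp = snp,
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k),
    beta = rep_len(beta, k),
    se = rep_len(se, k),
    n = rep_len(n, k),
    chrom = rep_len(chrom, k),
    pos = rep_len(pos, k),
    stringsAsFactors = FALSE)
  df$pval <- if (is.null(pval)) 2 * pnorm(-abs(df$beta / df$se)) else rep_len(pval, k)
  df
}

# Harmonized-instrument data.frame built directly from Wald ratios, for
# estimator tests. With beta_exposure = 1 the outcome betas equal the ratios
# and se_outcome equals ratio_se, so ratio-space and regression-space views
# coincide.
make_harm <- function(ratio, ratio_se, beta_exposure = rep(1, length(ratio)),
                      se_exposure = rep(1e-6, length(ratio))) {
  k <- length(ratio)
  beta_outcome <- ratio * beta_exposure
  se_outcome <- ratio_se * abs(beta_exposure)
  data.frame(
    snp = sprintf("rs%03d", seq_len(k)),
    effect_allele = "A", other_allele = "G",
    eaf_exposure = 0.3,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    pval_exposure = 1e-8, n_exposure = 18340,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf_outcome = 0.3, chrom = "1", pos = seq_len(k) * 2e7,
    ratio = ratio, ratio_se = ratio_se,
    f_stat = 100,
    stringsAsFactors = FALSE)
}

# Harmonize a generated scenario without selection loss: all SNPs pass
# (non-palindromic scenarios), giving exactly truth$k instruments.
harmonize_sim <- function(sim) harmonize(sim$exposure, sim$outcome)$instruments

# Independent weighted-least-squares oracle via base lm.
wls_slope_no_intercept <- function(bx, by, w) {
  unname(coef(lm(by ~ bx - 1, weights = w))["bx"])
}

write_stats_file <- function(df, path, sep = "\t",
                             names_map = c(snp = "SNP")) {
  out <- df
  for (canon in names(names_map)) {
    names(out)[names(out) == canon] <- names_map[[canon]]
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
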