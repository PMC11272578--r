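# Synthetic two-sample GWAS summary statistics with known causal structure,
# emulating the shape of a 16S-taxon exposure GWAS (quantitative, n ~ 18k)
# against a rare binary outcome from a large biobank (240 cases / 456,108
# controls).

#' Parameters of a synthetic two-sample GWAS scenario
#'
#' Describes the generative model from which [generate_summary_stats()]
#' draws: `k` independent biallelic SNPs with minor-allele frequencies
#' uniform on `maf_range`; true SNP-exposure effects
#' `gamma_j ~ Normal(0, gamma_sd^2)` on a standardized exposure scale;
#' per-SNP direct (pleiotropic) outcome effects `alpha_j` per regime; and a
#' true causal effect `theta` on the log-odds scale, so the true SNP-outcome
#' effect is `theta * gamma_j + alpha_j`.
#'
#' Sampling noise follows the standard GWAS approximation
#' `se = (2 * maf * (1 - maf) * n)^(-1/2)`. For the binary outcome the `n`
#' entering that formula is the effective sample size
#' `4 / (1/n_cases + 1/n_controls)`, which is what governs the sampling
#' variance of a log-odds-ratio estimate under heavy case-control imbalance;
#' the written outcome table still reports total `n`.
#'
#' Pleiotropy regimes: `"none"` (`alpha = 0`); `"balanced"`
#' (`alpha ~ Normal(0, sigma_alpha^2)`); `"directional"`
#' (`alpha = sign(gamma) * Normal(mu_alpha, sigma_alpha^2)` — a constant
#' mean direct effect in the exposure-increasing orientation of each
#' instrument, the frame in which MR-Egger fits; `alpha` remains independent
#' of instrument strength `|gamma|`, so the InSIDE condition holds and the
#' Egger slope stays consistent while IVW is biased).
#'
#' Injected outliers replace `alpha_j` by `outlier_offset_se` times that
#' SNP's outcome SE. Outlier SNPs are never drawn palindromic, so they
#' survive harmonization and remain visible to outlier diagnostics.
#'
#' @param theta true causal effect (log-odds per SD of exposure).
#' @param k number of SNPs.
#' @param n_exposure exposure GWAS sample size.
#' @param n_cases,n_controls outcome case/control counts.
#' @param maf_range range of minor-allele frequencies.
#' @param gamma_sd SD of true SNP-exposure effects.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param mu_alpha,sigma_alpha mean/SD of pleiotropic effects (regimes
#'   above).
#' @param outlier_idx integer indices of SNPs to inject as outliers.
#' @param outlier_offset_se outlier direct effect, in multiples of the SNP's
#'   outcome SE.
#' @param palindrome_fraction fraction of SNPs drawn with strand-ambiguous
#'   (A/T or C/G) alleles, exercising the harmonization drop path.
#' @param seed RNG seed; the whole draw is a deterministic function of it.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(theta = 0, k = 30, n_exposure = 18340,
                            n_cases = 240, n_controls = 456108,
                            maf_range = c(0.05, 0.5), gamma_sd = 0.08,
                            pleiotropy = c("none", "balanced", "directional"),
                            mu_alpha = 0.1, sigma_alpha = 0.05,
                            outlier_idx = integer(), outlier_offset_se = 10,
                            palindrome_fraction = 0.1, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  assert_that(is_count(k), "k must be a positive integer")
  assert_that(gamma_sd >= 0 && sigma_alpha >= 0, "scale parameters must be >= 0")
  assert_that(length(maf_range) == 2L && maf_range[1] > 0 &&
                maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "maf_range must lie within (0, 0.5]")
  assert_that(palindrome_fraction >= 0 && palindrome_fraction <= 1,
              "palindrome_fraction must lie in [0, 1]")
  assert_that(all(outlier_idx >= 1 & outlier_idx <= k),
              "outlier_idx out of range")
  structure(list(theta = theta, k = as.integer(k),
                 n_exposure = n_exposure, n_cases = n_cases,
                 n_controls = n_controls,
                 n_outcome = n_cases + n_controls,
                 maf_range = maf_range, gamma_sd = gamma_sd,
                 pleiotropy = pleiotropy, mu_alpha = mu_alpha,
                 sigma_alpha = sigma_alpha,
                 outlier_idx = as.integer(outlier_idx),
                 outlier_offset_se = outlier_offset_se,
                 palindrome_fraction = palindrome_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Effective sample size of a case-control log-odds GWAS.
effective_n <- function(n_cases, n_controls) 4 / (1 / n_cases + 1 / n_controls)

#' Generate synthetic exposure and outcome summary statistics
#'
#' Draws one realisation of the scenario described by a [synthetic_truth()]:
#' exposure and outcome per-SNP association tables in the canonical
#' summary-statistics layout, plus the truth record augmented with the
#' realised rsIDs, true effects and injected-outlier identities for use in
#' recovery tests. SNPs are mutually unlinked and placed far apart in the
#' genome (25 Mb spacing), so clumping at any sensible window is the
#' identity. Outcome records have their allele orientation swapped for a
#' random half of SNPs (with beta sign and frequency adjusted), exercising
#' the harmonization alignment path.
#'
#' @param truth a [synthetic_truth()].
#' @return list with `exposure` and `outcome` summary-statistics data.frames
#'   and `truth` (the input plus `snp`, `gamma`, `alpha`, `maf`,
#'   `outlier_ids`, `outlier_offsets`).
#' @export
generate_summary_stats <- function(truth) {
  assert_that(inherits(truth, "synthetic_truth"),
              "truth must be a synthetic_truth object")
  k <- truth$k
  with_seed(truth$seed, {
    rsid <- sprintf("rs%08d", sample.int(89999999L, k) + 10000000L)
    chrom <- as.character(rep_len(1:22, k))
    pos <- 1e6 + 25e6 * (ceiling(seq_len(k) / 22) - 1) + 1000 * seq_len(k)

    maf <- stats::runif(k, truth$maf_range[1], truth$maf_range[2])
    gamma <- stats::rnorm(k, 0, truth$gamma_sd)
    se_x <- (2 * maf * (1 - maf) * truth$n_exposure)^-0.5
    bx <- stats::rnorm(k, gamma, se_x)

    n_eff <- effective_n(truth$n_cases, truth$n_controls)
    se_y <- (2 * maf * (1 - maf) * n_eff)^-0.5
    alpha <- switch(truth$pleiotropy,
      none = rep(0, k),
      balanced = stats::rnorm(k, 0, truth$sigma_alpha),
      directional = sign(gamma) * stats::rnorm(k, truth$mu_alpha,
                                               truth$sigma_alpha))
    offsets <- truth$outlier_offset_se * se_y[truth$outlier_idx]
    alpha[truth$outlier_idx] <- offsets
    by <- stats::rnorm(k, truth$theta * gamma + alpha, se_y)

    a1 <- sample(VALID_ALLELES, k, replace = TRUE)
    a2 <- unname(vapply(a1, function(a) {
      sample(setdiff(VALID_ALLELES, c(a, unname(complement_allele(a)))), 1L)
    }, character(1)))
    n_pal <- round(truth$palindrome_fraction * k)
    pal_pool <- setdiff(seq_len(k), truth$outlier_idx)
    pal_idx <- if (n_pal > 0) sample(pal_pool, min(n_pal, length(pal_pool)))
               else integer()
    a2[pal_idx] <- unname(complement_allele(a1[pal_idx]))

    exposure <- data.frame(
      snp = rsid, effect_allele = a1, other_allele = a2, eaf = maf,
      beta = bx, se = se_x, pval = pmax(z_pvalue(bx, se_x), 1e-320),
      n = truth$n_exposure, chrom = chrom, pos = pos,
      stringsAsFactors = FALSE)

    swap <- stats::runif(k) < 0.5
    outcome <- data.frame(
      snp = rsid,
      effect_allele = ifelse(swap, a2, a1),
      other_allele = ifelse(swap, a1, a2),
      eaf = ifelse(swap, 1 - maf, maf),
      beta = ifelse(swap, -by, by),
      se = se_y, pval = pmax(z_pvalue(by, se_y), 1e-320),
      n = truth$n_outcome, chrom = chrom, pos = pos,
      stringsAsFactors = FALSE)

    truth_out <- truth
    truth_out$snp <- rsid
    truth_out$maf <- maf
    truth_out$gamma <- gamma
    truth_out$alpha <- alpha
    truth_out$outlier_ids <- rsid[truth$outlier_idx]
    truth_out$outlier_offsets <- offsets
    list(exposure = exposure, outcome = outcome, truth = truth_out)
  })
}

FIXTURE_SCENARIOS <- list(
  null = list(theta = 0, k = 10, seed = 20240712L),
  causal = list(theta = log(2.20), k = 12, seed = 20240713L),
  directional_pleiotropy = list(theta = 0.5, k = 10,
                                pleiotropy = "directional",
                                mu_alpha = 0.1, sigma_alpha = 0.05,
                                seed = 20240714L),
  one_outlier = list(theta = 0.5, k = 10, outlier_idx = 5L,
                     outlier_offset_se = 10, palindrome_fraction = 0,
                     seed = 20240715L),
  palindrome_mix = list(theta = 0.5, k = 10, palindrome_fraction = 0.4,
                        seed = 20240716L)
)

#' Write a named fixture scenario to disk
#'
#' Materialises one of the built-in scenarios (`"null"`, `"causal"`,
#' `"directional_pleiotropy"`, `"one_outlier"`, `"palindrome_mix"`) as a
#' file bundle: `exposure.tsv`, `outcome.tsv`, `truth.yaml` and an empty
#' `ld.tsv` (the generated SNPs are unlinked). Each scenario has a fixed
#' seed, so regeneration is byte-identical.
#'
#' @param name scenario label.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file `paths` and the realised `truth`.
#' @export
make_fixture <- function(name, dir = tempfile("fixture_")) {
  if (!name %in% names(FIXTURE_SCENARIOS)) {
    stop_mrpipe(sprintf("unknown fixture scenario '%s' (known: %s)", name,
                        paste(names(FIXTURE_SCENARIOS), collapse = ", ")),
                "mrpipe_config_error")
  }
  truth <- do.call(synthetic_truth, FIXTURE_SCENARIOS[[name]])
  sim <- generate_summary_stats(truth)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    exposure = file.path(dir, "exposure.tsv"),
    outcome = file.path(dir, "outcome.tsv"),
    truth = file.path(dir, "truth.yaml"),
    ld = file.path(dir, "ld.tsv")
  )
  exposure <- sim$exposure
  outcome <- sim$outcome
  names(exposure)[names(exposure) == "snp"] <- "SNP"
  names(outcome)[names(outcome) == "snp"] <- "SNP"
  write_tsv_(exposure, paths$exposure)
  write_tsv_(outcome, paths$outcome)
  writeLines("snp_a\tsnp_b\tr2", paths$ld)
  truth_list <- unclass(sim$truth)
  truth_list$scenario <- name
  yaml::write_yaml(truth_list, paths$truth, precision = 15L)
  invisible(list(paths = paths, truth = sim$truth))
}
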