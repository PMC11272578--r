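# Heterogeneity, pleiotropy, outlier and influence diagnostics for a
# harmonized instrument set.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (ratio_j - beta_IVW_fixed)^2` with `w_j = 1/ratio_se_j^2`,
#' compared to a chi-square with k - 1 degrees of freedom. Large Q indicates
#' the per-SNP causal estimates disagree beyond their sampling error —
#' heterogeneity from pleiotropy, invalid instruments or model
#' misspecification.
#'
#' @param instruments an `instrument_set` or harmonized data.frame (k >= 2).
#' @return list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(instruments) {
  dat <- as_instruments(instruments)
  k <- nrow(dat)
  if (k < 2L) stop_insufficient("Cochran's Q", k, 2L)
  w <- dat$ratio_se^-2
  beta <- sum(w * dat$ratio) / sum(w)
  q <- sum(w * (dat$ratio - beta)^2)
  list(q = q, df = k - 1L,
       pval = stats::pchisq(q, df = k - 1L, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the MR-Egger regression intercept with its SE and two-sided
#' t-test p-value (k - 2 df). An intercept p below `alpha` flags directional
#' horizontal pleiotropy.
#'
#' @param instruments an `instrument_set` or harmonized data.frame (k >= 3).
#' @param alpha flag threshold.
#' @return list with `intercept`, `se`, `pval`, `pleiotropy_present`.
#' @export
egger_intercept_test <- function(instruments, alpha = 0.05) {
  fit <- mr_egger(instruments)
  list(intercept = fit$intercept, se = fit$intercept_se,
       pval = fit$intercept_pval,
       pleiotropy_present = fit$intercept_pval < alpha)
}

# Leave-one-out IVW slopes of beta_outcome on beta_exposure with outcome-SE
# weights, computed in O(k) from the full-set sums.
loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global outlier test and correction
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. The observed
#' global RSS is `sum_j w_j (beta_outcome_j - theta_hat_(-j) *
#' beta_exposure_j)^2`, with `theta_hat_(-j)` the leave-one-out IVW slope
#' and `w_j = 1/se_outcome_j^2`. Its null distribution is built by
#' simulation: `n_sim` times, exposure betas are redrawn from
#' `Normal(beta_exposure_j, se_exposure_j)` and outcome betas from
#' `Normal(theta_hat_(-j) * beta_exposure_j, se_outcome_j)`, and the RSS is
#' recomputed on the simulated pairs. The global p uses the add-one
#' estimator `(1 + #\{RSS_sim >= RSS_obs\}) / (n_sim + 1)` so it is never
#' exactly zero. Per-SNP outlier p-values compare each SNP's observed RSS
#' contribution to its simulated contributions, Bonferroni-corrected by k;
#' when outliers are found the corrected estimate is IVW on the remaining
#' SNPs. A distortion test (is the corrected estimate farther from the
#' all-SNP estimate than random removal of as many SNPs would move it?) is
#' available but off by default.
#'
#' @param instruments an `instrument_set` or harmonized data.frame (k >= 4).
#' @param n_sim simulated null replicates (values below 100 warn).
#' @param outlier_alpha significance level for the Bonferroni-corrected
#'   per-SNP outlier tests.
#' @param seed RNG seed for the simulations.
#' @param distortion_test also run the distortion test?
#' @return list with `global_pval`, `outliers` (character rsIDs),
#'   `outlier_pvals` (named, Bonferroni-corrected), `corrected` (one-row
#'   MrEstimate, or NULL when no outliers), and `distortion_pval` (NA unless
#'   requested and outliers found).
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                      seed = NULL, distortion_test = FALSE) {
  dat <- as_instruments(instruments)
  k <- nrow(dat)
  if (k < 4L) stop_insufficient("MR-PRESSO", k, 4L)
  if (n_sim < 100) warning("MR-PRESSO with n_sim < 100 is unreliable")
  assert_that(all(dat$se_exposure > 0), "se_exposure must be > 0")

  bx <- dat$beta_exposure; by <- dat$beta_outcome
  w <- dat$se_outcome^-2
  theta_loo <- loo_slopes(bx, by, w)
  obs_contrib <- w * (by - theta_loo * bx)^2
  rss_obs <- sum(obs_contrib)

  sims <- with_seed(seed, {
    bx_sim <- matrix(stats::rnorm(n_sim * k, mean = rep(bx, each = n_sim),
                                  sd = rep(dat$se_exposure, each = n_sim)),
                     nrow = n_sim)
    by_sim <- matrix(stats::rnorm(n_sim * k,
                                  mean = rep(theta_loo * bx, each = n_sim),
                                  sd = rep(dat$se_outcome, each = n_sim)),
                     nrow = n_sim)
    list(bx = bx_sim, by = by_sim)
  })
  wmat <- matrix(w, nrow = n_sim, ncol = k, byrow = TRUE)
  sxy <- (sims$bx * sims$by) %*% w          # n_sim x 1
  sxx <- (sims$bx^2) %*% w
  theta_sim <- (as.vector(sxy) - wmat * sims$bx * sims$by) /
    (as.vector(sxx) - wmat * sims$bx^2)     # n_sim x k leave-one-out slopes
  contrib_sim <- wmat * (sims$by - theta_sim * sims$bx)^2
  rss_sim <- rowSums(contrib_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + colSums(contrib_sim >= matrix(obs_contrib, nrow = n_sim,
                                              ncol = k, byrow = TRUE))) /
    (n_sim + 1)
  p_bonf <- pmin(1, p_snp * k)
  names(p_bonf) <- dat$snp
  out_idx <- which(p_bonf < outlier_alpha)
  outliers <- dat$snp[out_idx]

  corrected <- NULL
  distortion_pval <- NA_real_
  if (length(out_idx)) {
    remaining <- dat[-out_idx, , drop = FALSE]
    if (nrow(remaining) >= 1L) corrected <- mr_ivw(remaining, "auto")
    if (distortion_test && !is.null(corrected)) {
      beta_all <- mr_ivw(dat, "fixed")$beta
      shift_obs <- abs(corrected$beta - beta_all)
      shifts <- with_seed(if (is.null(seed)) NULL else seed + 1L,
        replicate(n_sim, {
          drop <- sample.int(k, length(out_idx))
          abs(mr_ivw(dat[-drop, , drop = FALSE], "fixed")$beta - beta_all)
        }))
      distortion_pval <- (1 + sum(shifts >= shift_obs)) / (n_sim + 1)
    }
  }
  list(global_pval = global_pval, outliers = outliers,
       outlier_pvals = p_bonf, corrected = corrected,
       distortion_pval = distortion_pval)
}

#' Leave-one-out influence analysis
#'
#' Recomputes the fixed-effects IVW estimate with each instrument removed in
#' turn. A single SNP whose removal moves the estimate materially (or flips
#' the sign region of its CI) indicates that the overall result hinges on
#' that one variant.
#'
#' @param instruments an `instrument_set` or harmonized data.frame (k >= 2).
#' @return list with `table` (data.frame `snp_dropped`, `beta`, `se`,
#'   `ci_low`, `ci_high`, one row per instrument), `full` (one-row MrEstimate
#'   for the complete set, fixed effects) and `stable` (TRUE iff every
#'   leave-one-out CI overlaps the sign of the full-set estimate).
#' @export
leave_one_out <- function(instruments) {
  dat <- as_instruments(instruments)
  k <- nrow(dat)
  if (k < 2L) stop_insufficient("leave-one-out", k, 2L)
  w <- dat$ratio_se^-2
  sw <- sum(w); swr <- sum(w * dat$ratio)
  beta_j <- (swr - w * dat$ratio) / (sw - w)
  se_j <- (sw - w)^-0.5
  zq <- stats::qnorm(0.975)
  tab <- data.frame(snp_dropped = dat$snp, beta = beta_j, se = se_j,
                    ci_low = beta_j - zq * se_j, ci_high = beta_j + zq * se_j,
                    stringsAsFactors = FALSE)
  full <- mr_ivw(dat, "fixed")
  stable <- if (full$beta >= 0) all(tab$ci_high > 0) else all(tab$ci_low < 0)
  list(table = tab, full = full, stable = stable)
}

#' Full sensitivity report for one instrument set
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, MR-PRESSO and the
#' leave-one-out analysis, tolerating instrument counts too small for
#' individual diagnostics (those entries are NA/NULL with a note).
#'
#' @param instruments an `instrument_set` or harmonized data.frame.
#' @param n_sim MR-PRESSO simulation count.
#' @param alpha flag threshold for heterogeneity/pleiotropy.
#' @param seed RNG seed for MR-PRESSO.
#' @return object of class `sensitivity_report`: list with `q_stat`, `q_df`,
#'   `q_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, `presso_global_pval`, `presso_outliers`,
#'   `presso_corrected`, `loo` (see [leave_one_out()]),
#'   `heterogeneity_present`, `pleiotropy_present`, `notes`.
#' @export
sensitivity_report <- function(instruments, n_sim = 1000, alpha = 0.05,
                               seed = NULL) {
  dat <- as_instruments(instruments)
  notes <- character()
  maybe <- function(fun, label) {
    tryCatch(fun(), mrpipe_insufficient_instruments = function(e) {
      notes <<- c(notes, sprintf("%s: insufficient instruments", label))
      NULL
    })
  }
  q <- maybe(function() cochran_q(dat), "cochran_q")
  eg <- maybe(function() egger_intercept_test(dat, alpha), "egger_intercept")
  pr <- maybe(function() mr_presso(dat, n_sim = n_sim, seed = seed),
              "mr_presso")
  loo <- maybe(function() leave_one_out(dat), "leave_one_out")
  structure(list(
    k = nrow(dat),
    q_stat = q$q %||% NA_real_, q_df = q$df %||% NA_integer_,
    q_pval = q$pval %||% NA_real_,
    egger_intercept = eg$intercept %||% NA_real_,
    egger_intercept_se = eg$se %||% NA_real_,
    egger_intercept_pval = eg$pval %||% NA_real_,
    presso_global_pval = pr$global_pval %||% NA_real_,
    presso_outliers = pr$outliers %||% character(),
    presso_corrected = pr$corrected,
    loo = loo,
    heterogeneity_present = if (is.null(q)) NA else q$pval < alpha,
    pleiotropy_present = if (is.null(eg)) NA else eg$pleiotropy_present,
    notes = notes
  ), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report (k = %d)\n", x$k))
  cat(sprintf("  Cochran's Q: %.3f (df %s), p = %.3g\n",
              x$q_stat, x$q_df, x$q_pval))
  cat(sprintf("  Egger intercept: %.4f (p = %.3g)\n",
              x$egger_intercept, x$egger_intercept_pval))
  cat(sprintf("  MR-PRESSO global p: %.3g; outliers: %s\n",
              x$presso_global_pval,
              if (length(x$presso_outliers)) paste(x$presso_outliers,
                                                   collapse = ", ") else "none"))
  if (!is.null(x$loo)) {
    cat(sprintf("  Leave-one-out stable: %s\n", x$loo$stable))
  }
  if (length(x$notes)) cat("  Notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
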