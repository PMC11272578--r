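# The five causal-effect estimators: IVW, MR-Egger, weighted median,
# simple mode and weighted mode. All operate on a harmonized instrument set
# and report on the log-odds scale with odds-ratio columns.

METHOD_ORDER <- c("IVW", "MR-Egger", "WeightedMedian", "SimpleMode", "WeightedMode")

# Accept either an instrument_set or a bare harmonized data.frame.
as_instruments <- function(x) {
  df <- if (inherits(x, "instrument_set")) x$instruments else x
  assert_that(is.data.frame(df) &&
                all(c("beta_exposure", "beta_outcome", "se_outcome",
                      "ratio", "ratio_se") %in% names(df)),
              "expected an instrument_set or harmonized instruments data.frame")
  assert_that(all(df$beta_exposure != 0), "beta_exposure must be nonzero")
  assert_that(all(df$ratio_se > 0), "ratio_se must be > 0")
  df
}

# One-row MrEstimate data.frame. CI multiplier is normal 1.96 unless a t
# quantile is supplied (MR-Egger).
mr_estimate <- function(method, beta, se, pval, k, model_note = "",
                        ci_mult = stats::qnorm(0.975)) {
  ci_low <- beta - ci_mult * se
  ci_high <- beta + ci_mult * se
  data.frame(method = method, beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high,
             or_value = exp(beta), or_ci_low = exp(ci_low),
             or_ci_high = exp(ci_high),
             pval = pval, k = k, model_note = model_note,
             stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#'
#' Per-SNP causal estimate: the outcome effect divided by the exposure
#' effect, with first-order (delta-method) standard error
#' `se_outcome / |beta_exposure|`.
#'
#' @param beta_exposure,beta_outcome per-allele effect estimates on a shared
#'   effect allele.
#' @param se_outcome standard error of the outcome effect.
#' @return list with `ratio` and `ratio_se`.
#' @examples
#' wald_ratio(0.1, 0.05, 0.02)  # ratio 0.5, se 0.2
#' @export
wald_ratio <- function(beta_exposure, beta_outcome, se_outcome) {
  assert_that(all(beta_exposure != 0),
              "Wald ratio undefined for zero exposure effect")
  assert_that(all(se_outcome > 0), "se_outcome must be > 0")
  list(ratio = beta_outcome / beta_exposure,
       ratio_se = se_outcome / abs(beta_exposure))
}

#' Inverse-variance-weighted (IVW) estimate
#'
#' Meta-analyses the per-SNP Wald ratios with weights `1 / ratio_se^2`.
#' Equivalent to the slope of a weighted no-intercept regression of outcome
#' betas on exposure betas with weights `1 / se_outcome^2`. The fixed-effects
#' SE is `(sum w)^(-1/2)`; the multiplicative random-effects SE scales it by
#' `max(1, sqrt(Q / (k - 1)))` where Q is Cochran's heterogeneity statistic.
#' In `"auto"` mode (the primary analysis configuration) random effects are
#' used iff the Q test has p < 0.05, mirroring the convention of switching
#' model only under detected heterogeneity.
#'
#' @param instruments an `instrument_set` or harmonized data.frame.
#' @param effects_model `"auto"`, `"fixed"` or `"random"`.
#' @return one-row MrEstimate data.frame (see [mr_all()] for columns);
#'   `model_note` records the model actually used (`"single_snp"` when
#'   k = 1 forces fixed effects).
#' @export
mr_ivw <- function(instruments, effects_model = c("auto", "fixed", "random")) {
  effects_model <- match.arg(effects_model)
  dat <- as_instruments(instruments)
  k <- nrow(dat)
  if (k < 1L) stop_insufficient("IVW", k, 1L)
  w <- dat$ratio_se^-2
  beta <- sum(w * dat$ratio) / sum(w)
  se_fixed <- sum(w)^-0.5
  if (k == 1L) {
    note <- if (effects_model == "auto") "single_snp" else effects_model
    return(mr_estimate("IVW", beta, se_fixed,
                       z_pvalue(beta, se_fixed), k, note))
  }
  q <- sum(w * (dat$ratio - beta)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  model <- switch(effects_model,
                  fixed = "fixed",
                  random = "random",
                  auto = if (q_p < 0.05) "random" else "fixed")
  se <- if (model == "random") se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
  mr_estimate("IVW", beta, se, z_pvalue(beta, se), k, model)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas *with* an
#' intercept, weights `1 / se_outcome^2`, after flipping each instrument so
#' its exposure beta is non-negative (the estimator is defined in the
#' exposure-increasing orientation). The slope is the causal estimate; a
#' nonzero intercept indicates directional horizontal pleiotropy. Standard
#' errors carry a residual-dispersion factor floored at 1, and inference
#' uses the t distribution with k - 2 degrees of freedom.
#'
#' @param instruments an `instrument_set` or harmonized data.frame (k >= 3).
#' @return list with `estimate` (one-row MrEstimate for the slope),
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(instruments) {
  dat <- as_instruments(instruments)
  k <- nrow(dat)
  if (k < 3L) stop_insufficient("MR-Egger", k, 3L)
  flip <- sign(dat$beta_exposure)
  x <- flip * dat$beta_exposure
  y <- flip * dat$beta_outcome
  w <- dat$se_outcome^-2
  # weighted normal equations; dispersion floored at 1 so SEs are never
  # smaller than the fixed-effect (known-variance) ones
  X <- cbind(intercept = 1, x = x)
  xtwx_inv <- solve(crossprod(X * sqrt(w)))
  coefs <- drop(xtwx_inv %*% crossprod(X, w * y))
  res <- y - drop(X %*% coefs)
  disp <- sqrt(sum(w * res^2) / (k - 2))
  se_unscaled <- sqrt(diag(xtwx_inv))
  se_adj <- se_unscaled * max(1, disp)
  slope <- coefs[["x"]]
  slope_se <- se_adj[["x"]]
  int <- coefs[["intercept"]]
  int_se <- se_adj[["intercept"]]
  tq <- function(b, se) 2 * stats::pt(-abs(b / se), df = k - 2)
  est <- mr_estimate("MR-Egger", slope, slope_se, tq(slope, slope_se), k,
                     ci_mult = stats::qt(0.975, df = k - 2))
  list(estimate = est, intercept = int, intercept_se = int_se,
       intercept_pval = tq(int, int_se))
}

# Weighted-median point estimate: cumulative standardized weights with
# linear interpolation at 0.5.
weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; ws <- w[ord]
  s <- (cumsum(ws) - ws / 2) / sum(ws)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(s)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# Parametric-bootstrap SE: redraw each ratio from Normal(ratio_j, ratio_se_j)
# and recompute the point estimate with unchanged weights.
bootstrap_se <- function(ratio, ratio_se, point_fun, n_boot, seed) {
  k <- length(ratio)
  with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * k, mean = rep(ratio, each = n_boot),
                                 sd = rep(ratio_se, each = n_boot)),
                    nrow = n_boot)
    stats::sd(apply(draws, 1L, point_fun))
  })
}

#' Weighted-median estimate
#'
#' Orders the per-SNP Wald ratios and takes the inverse-variance-weighted
#' median: with standardized cumulative weights
#' `s_j = (sum_{i<=j} w_i - w_j/2) / sum w`, the estimate is the ratio
#' linearly interpolated at `s = 0.5`. Consistent when at least half the
#' weight comes from valid instruments. The SE is a parametric bootstrap:
#' each ratio is redrawn from `Normal(ratio_j, ratio_se_j)` and the median
#' recomputed.
#'
#' @param instruments an `instrument_set` or harmonized data.frame (k >= 3).
#' @param n_boot bootstrap replicates for the SE.
#' @param seed RNG seed for the bootstrap (NULL uses the current stream).
#' @return one-row MrEstimate data.frame.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = NULL) {
  dat <- as_instruments(instruments)
  k <- nrow(dat)
  if (k < 3L) stop_insufficient("WeightedMedian", k, 3L)
  w <- dat$ratio_se^-2
  beta <- weighted_median_point(dat$ratio, w)
  se <- bootstrap_se(dat$ratio, dat$ratio_se,
                     function(r) weighted_median_point(r, w), n_boot, seed)
  mr_estimate("WeightedMedian", beta, se, z_pvalue(beta, se), k)
}

# Modified-Silverman bandwidth over Wald ratios.
mode_bandwidth <- function(ratio, phi) {
  k <- length(ratio)
  spread <- min(stats::sd(ratio), stats::IQR(ratio) / 1.349)
  phi * 0.9 * spread * k^(-1 / 5)
}

# Weighted Gaussian-KDE argmax on a fixed grid.
mode_point <- function(ratio, w, phi, grid_n = 512L) {
  h <- mode_bandwidth(ratio, phi)
  if (!is.finite(h) || h <= 0) return(ratio[which.max(w)])  # degenerate spread
  d <- stats::density(ratio, weights = w / sum(w), bw = h, kernel = "gaussian",
                      from = min(ratio) - 3 * h, to = max(ratio) + 3 * h,
                      n = grid_n)
  d$x[which.max(d$y)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Forms a Gaussian kernel density over the per-SNP Wald ratios — bandwidth
#' `phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)` (modified Silverman rule) —
#' and takes the density argmax on a 512-point grid spanning
#' `[min - 3h, max + 3h]`. The simple mode weights every ratio equally; the
#' weighted mode uses inverse-variance weights. Consistent when the largest
#' group of instruments sharing the same underlying ratio is valid (the
#' ZEMPA assumption). SE by the same parametric bootstrap as the weighted
#' median.
#'
#' @param instruments an `instrument_set` or harmonized data.frame (k >= 3).
#' @param weighted use inverse-variance weights? (FALSE = simple mode)
#' @param phi bandwidth inflation factor (1 = the modified Silverman rule).
#' @param n_boot,seed bootstrap replicates and RNG seed for the SE.
#' @param grid_n number of density grid points.
#' @return one-row MrEstimate data.frame.
#' @export
mr_mode <- function(instruments, weighted = FALSE, phi = 1, n_boot = 1000,
                    seed = NULL, grid_n = 512L) {
  dat <- as_instruments(instruments)
  k <- nrow(dat)
  method <- if (weighted) "WeightedMode" else "SimpleMode"
  if (k < 3L) stop_insufficient(method, k, 3L)
  w <- if (weighted) dat$ratio_se^-2 else rep(1, k)
  beta <- mode_point(dat$ratio, w, phi, grid_n)
  se <- bootstrap_se(dat$ratio, dat$ratio_se,
                     function(r) mode_point(r, w, phi, grid_n), n_boot, seed)
  mr_estimate(method, beta, se, z_pvalue(beta, se), k)
}

#' Run all five MR estimators
#'
#' Applies IVW (the primary method), MR-Egger, weighted median, simple mode
#' and weighted mode to one harmonized instrument set. Methods whose
#' instrument-count requirement is not met return a row of NAs with
#' `model_note = "insufficient_instruments"` instead of failing.
#'
#' @param instruments an `instrument_set` or harmonized data.frame.
#' @param effects_model IVW effects model (see [mr_ivw()]).
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param phi mode bandwidth factor.
#' @param seed RNG seed for the bootstraps.
#' @return data.frame with one row per method (fixed order IVW, MR-Egger,
#'   WeightedMedian, SimpleMode, WeightedMode) and columns `method`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `or_value`, `or_ci_low`, `or_ci_high`,
#'   `pval`, `k`, `model_note`.
#' @export
mr_all <- function(instruments, effects_model = "auto", n_boot = 1000,
                   phi = 1, seed = NULL) {
  run <- function(method, fun) {
    tryCatch(fun(), mrpipe_insufficient_instruments = function(e) {
      est <- mr_estimate(method, NA_real_, NA_real_, NA_real_,
                         if (inherits(instruments, "instrument_set"))
                           instruments$k else nrow(instruments),
                         "insufficient_instruments")
      est
    })
  }
  rows <- list(
    run("IVW", function() mr_ivw(instruments, effects_model)),
    run("MR-Egger", function() mr_egger(instruments)$estimate),
    run("WeightedMedian",
        function() mr_weighted_median(instruments, n_boot, seed)),
    run("SimpleMode",
        function() mr_mode(instruments, weighted = FALSE, phi, n_boot, seed)),
    run("WeightedMode",
        function() mr_mode(instruments, weighted = TRUE, phi, n_boot, seed))
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
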