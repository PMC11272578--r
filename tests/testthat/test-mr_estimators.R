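test_that("Wald ratios follow the first-order formula", {
  expect_equal(wald_ratio(0.1, 0.05, 0.02), list(ratio = 0.5, ratio_se = 0.2))
  expect_equal(wald_ratio(0.1, 0, 0.02)$ratio, 0)
  expect_equal(wald_ratio(-0.1, 0.05, 0.02),
               list(ratio = -0.5, ratio_se = 0.2))
  expect_error(wald_ratio(0, 0.05, 0.02), class = "mrpipe_validation_error")
})

test_that("IVW reduces to the Wald ratio for a single instrument", {
  dat <- make_harm(ratio = 0.5, ratio_se = 0.2)
  est <- mr_ivw(dat, "auto")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_equal(est$model_note, "single_snp")
  expect_equal(est$or_value, exp(0.5))
})

test_that("IVW matches the hand-computed two-instrument example", {
  dat <- make_harm(ratio = c(0.5, 1.0), ratio_se = c(0.2, 0.1))
  est <- mr_ivw(dat, "fixed")
  expect_equal(est$beta, 0.9)                  # (25*0.5 + 100*1)/125
  expect_equal(est$se, 1 / sqrt(125))          # ~0.0894
  expect_equal(est$ci_low, 0.9 - qnorm(0.975) / sqrt(125))
  expect_equal(est$pval, 2 * pnorm(-0.9 * sqrt(125)))
})

test_that("identical ratios give zero heterogeneity and the fixed model", {
  dat <- make_harm(ratio = rep(0.37, 5), ratio_se = runif(5, 0.05, 0.2))
  est <- mr_ivw(dat, "auto")
  expect_equal(est$beta, 0.37)
  expect_equal(est$model_note, "fixed")
  expect_equal(cochran_q(dat)$q, 0)
})

test_that("IVW equals the no-intercept WLS slope on random instances", {
  set.seed(31)
  for (i in 1:100) {
    k <- sample(3:25, 1)
    bx <- rnorm(k, 0, 0.1); bx[abs(bx) < 1e-3] <- 0.05
    by <- rnorm(k, 0.3 * bx, 0.05)
    se_y <- runif(k, 0.01, 0.3)
    dat <- make_harm(ratio = by / bx, ratio_se = se_y / abs(bx),
                     beta_exposure = bx)
    oracle <- wls_slope_no_intercept(bx, by, 1 / se_y^2)
    expect_equal(mr_ivw(dat, "fixed")$beta, oracle, tolerance = 1e-10)
  }
})

test_that("random-effects IVW inflates the SE only under heterogeneity", {
  dat <- make_harm(ratio = c(0.1, 0.9, 0.2, 1.5), ratio_se = rep(0.05, 4))
  fixed <- mr_ivw(dat, "fixed")
  auto <- mr_ivw(dat, "auto")
  q <- cochran_q(dat)
  expect_lt(q$pval, 0.05)
  expect_equal(auto$model_note, "random")
  expect_equal(auto$se, fixed$se * sqrt(q$q / q$df))
  expect_equal(auto$beta, fixed$beta)  # point estimate unchanged
})

test_that("MR-Egger recovers exact linear and affine relations", {
  bx <- c(0.05, 0.08, 0.12, 0.2, 0.3)
  se_y <- c(0.01, 0.02, 0.015, 0.03, 0.02)
  lin <- make_harm(ratio = rep(0.3, 5), ratio_se = se_y / bx,
                   beta_exposure = bx)
  fit <- mr_egger(lin)
  expect_equal(fit$estimate$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)

  by <- 0.05 + 0.3 * bx
  aff <- make_harm(ratio = by / bx, ratio_se = se_y / bx, beta_exposure = bx)
  fit2 <- mr_egger(aff)
  expect_equal(fit2$estimate$beta, 0.3, tolerance = 1e-8)
  expect_equal(fit2$intercept, 0.05, tolerance = 1e-8)
  expect_true(is.finite(fit2$estimate$se) && fit2$estimate$se > 0)
})

test_that("MR-Egger equals with-intercept WLS (lm oracle) on random instances", {
  set.seed(47)
  for (i in 1:100) {
    k <- sample(4:20, 1)
    bx <- abs(rnorm(k, 0.1, 0.05)) + 0.01   # already oriented positive
    by <- rnorm(k, 0.02 + 0.4 * bx, 0.03)
    se_y <- runif(k, 0.02, 0.2)
    dat <- make_harm(ratio = by / bx, ratio_se = se_y / bx,
                     beta_exposure = bx)
    fit <- mr_egger(dat)
    lmfit <- summary(lm(by ~ bx, weights = 1 / se_y^2))
    expect_equal(fit$estimate$beta, lmfit$coefficients["bx", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(fit$intercept, lmfit$coefficients["(Intercept)", "Estimate"],
                 tolerance = 1e-10)
    # with dispersion above 1 the SEs match lm's model-based SEs exactly
    if (lmfit$sigma > 1) {
      expect_equal(fit$estimate$se, lmfit$coefficients["bx", "Std. Error"],
                   tolerance = 1e-10)
    } else {
      expect_equal(fit$estimate$se,
                   lmfit$coefficients["bx", "Std. Error"] / lmfit$sigma,
                   tolerance = 1e-10)
    }
  }
})

test_that("MR-Egger orientation makes it invariant to instrument sign flips", {
  set.seed(3)
  bx <- rnorm(12, 0, 0.1); bx[abs(bx) < 0.01] <- 0.05
  by <- rnorm(12, 0.3 * bx, 0.05)
  dat <- make_harm(ratio = by / bx, ratio_se = 0.05 / abs(bx),
                   beta_exposure = bx)
  flipped <- dat
  flipped$beta_exposure <- -dat$beta_exposure
  flipped$beta_outcome <- -dat$beta_outcome
  f1 <- mr_egger(dat); f2 <- mr_egger(flipped)
  expect_equal(f1$estimate$beta, f2$estimate$beta)
  expect_equal(f1$intercept, f2$intercept)
})

test_that("directional pleiotropy shows up as the mean Egger intercept", {
  run_mc <- function(n_rep, gamma_sd, seed0) {
    vapply(seq_len(n_rep), function(i) {
      sim <- generate_summary_stats(synthetic_truth(
        theta = 0.5, k = 30, pleiotropy = "directional", mu_alpha = 0.1,
        sigma_alpha = 0.05, gamma_sd = gamma_sd, palindrome_fraction = 0,
        seed = seed0 + i))
      mr_egger(harmonize_sim(sim))$intercept
    }, numeric(1))
  }
  # strong instruments: orientation by sign(beta_exposure) is essentially
  # error-free and the mean intercept recovers mu_alpha
  strong <- run_mc(1000, gamma_sd = 0.3, seed0 = 5000)
  expect_lt(abs(mean(strong) - 0.1), 0.01)
  # at realistic taxon-GWAS instrument strength, orientation errors at
  # near-zero exposure effects attenuate the intercept towards zero but the
  # directional signal remains clearly visible
  realistic <- run_mc(500, gamma_sd = 0.08, seed0 = 6500)
  expect_gt(mean(realistic), 0.05)
  expect_lt(mean(realistic), 0.115)
})

test_that("weighted median interpolates the inverse-variance-weighted order statistics", {
  eq <- make_harm(ratio = c(1, 2, 3), ratio_se = rep(0.1, 3))
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$beta, 2)

  outl <- make_harm(ratio = c(1, 2, 3, 100), ratio_se = rep(0.1, 4))
  expect_equal(mr_weighted_median(outl, n_boot = 50, seed = 1)$beta, 2.5)

  dom <- make_harm(ratio = c(1, 2, 3), ratio_se = c(0.1, 0.1, 1e-6))
  expect_equal(mr_weighted_median(dom, n_boot = 50, seed = 1)$beta, 3,
               tolerance = 1e-3)
})

test_that("weighted median matches an exhaustive interpolation oracle", {
  # independent re-implementation: walk the sorted ratios accumulating
  # weight, find the bracketing pair around half the total, interpolate
  oracle_wm <- function(r, w) {
    ord <- order(r); r <- r[ord]; w <- w[ord]
    total <- sum(w)
    s <- numeric(length(r))
    acc <- 0
    for (j in seq_along(r)) {
      s[j] <- (acc + w[j] / 2) / total
      acc <- acc + w[j]
    }
    if (s[1] >= 0.5) return(r[1])
    if (s[length(s)] <= 0.5) return(r[length(r)])
    hi <- which(s >= 0.5)[1]; lo <- hi - 1
    r[lo] + (0.5 - s[lo]) / (s[hi] - s[lo]) * (r[hi] - r[lo])
  }
  set.seed(99)
  for (i in 1:50) {
    k <- sample(3:15, 1)
    r <- rnorm(k); se <- runif(k, 0.05, 0.5)
    dat <- make_harm(ratio = r, ratio_se = se)
    expect_equal(mr_weighted_median(dat, n_boot = 10, seed = 1)$beta,
                 oracle_wm(r, se^-2), tolerance = 1e-12)
  }
})

test_that("bootstrap SEs are reproducible for a fixed seed and track dispersion", {
  dat <- make_harm(ratio = c(0.2, 0.5, 0.4, 0.3, 0.6),
                   ratio_se = rep(0.1, 5))
  a <- mr_weighted_median(dat, n_boot = 500, seed = 42)
  b <- mr_weighted_median(dat, n_boot = 500, seed = 42)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  # tighter instruments give a tighter bootstrap SE
  tight <- make_harm(ratio = c(0.2, 0.5, 0.4, 0.3, 0.6),
                     ratio_se = rep(0.02, 5))
  expect_lt(mr_weighted_median(tight, n_boot = 500, seed = 42)$se, a$se)
})

test_that("mode estimators find the majority cluster", {
  maj <- make_harm(ratio = c(0.5, 0.5, 0.5, 2.0), ratio_se = rep(0.1, 4))
  expect_equal(mr_mode(maj, weighted = FALSE, n_boot = 20, seed = 1)$beta,
               0.5, tolerance = 0.05)

  same <- make_harm(ratio = rep(0.7, 4), ratio_se = rep(0.1, 4))
  est <- mr_mode(same, weighted = FALSE, n_boot = 20, seed = 1)
  expect_equal(est$beta, 0.7)
  expect_gt(est$se, 0)
})

test_that("weighting shifts the mode between clusters as the kernel oracle predicts", {
  r <- c(0, 0, 0, 1, 1)
  se <- c(1, 1, 1, 1 / sqrt(10), 1 / sqrt(10))  # weights 1,1,1,10,10
  dat <- make_harm(ratio = r, ratio_se = se)
  simple <- mr_mode(dat, weighted = FALSE, n_boot = 10, seed = 1)$beta
  weighted <- mr_mode(dat, weighted = TRUE, n_boot = 10, seed = 1)$beta
  expect_lt(abs(simple - 0), 0.1)
  expect_lt(abs(weighted - 1), 0.1)

  # independent fine-grid kernel-density oracle
  oracle_mode <- function(r, w) {
    h <- 0.9 * min(sd(r), IQR(r) / 1.349) * length(r)^(-1 / 5)
    grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 20001)
    dens <- vapply(grid, function(g) sum(w * dnorm((g - r) / h)), numeric(1))
    grid[which.max(dens)]
  }
  expect_equal(simple, oracle_mode(r, rep(1, 5)), tolerance = 0.02)
  expect_equal(weighted, oracle_mode(r, se^-2), tolerance = 0.02)
})

test_that("all five estimators are equivariant under joint sign flips", {
  set.seed(8)
  bx <- rnorm(10, 0, 0.1); bx[abs(bx) < 0.01] <- 0.05
  by <- rnorm(10, 0.4 * bx, 0.05)
  dat <- make_harm(ratio = by / bx, ratio_se = 0.05 / abs(bx),
                   beta_exposure = bx)
  flipped <- dat
  flipped$beta_exposure <- -dat$beta_exposure
  flipped$beta_outcome <- -dat$beta_outcome
  e1 <- mr_all(dat, n_boot = 100, seed = 9)
  e2 <- mr_all(flipped, n_boot = 100, seed = 9)
  expect_equal(e1$beta, e2$beta, tolerance = 1e-12)
  expect_equal(e1$se, e2$se, tolerance = 1e-12)
})

test_that("estimators needing three instruments refuse smaller sets", {
  dat <- make_harm(ratio = c(0.5, 1.0), ratio_se = c(0.2, 0.1))
  expect_error(mr_egger(dat), class = "mrpipe_insufficient_instruments")
  expect_error(mr_weighted_median(dat), class = "mrpipe_insufficient_instruments")
  expect_error(mr_mode(dat), class = "mrpipe_insufficient_instruments")
  all5 <- mr_all(dat, n_boot = 10, seed = 1)
  expect_equal(nrow(all5), 5L)
  expect_equal(all5$model_note[all5$method != "IVW"],
               rep("insufficient_instruments", 4))
  expect_false(is.na(all5$beta[all5$method == "IVW"]))
})

test_that("every estimator's CI covers the true effect in most homogeneous replicates", {
  n_rep <- 500
  theta <- 0.5
  hits <- matrix(FALSE, n_rep, 5,
                 dimnames = list(NULL, METHOD_ORDER <- c(
                   "IVW", "MR-Egger", "WeightedMedian", "SimpleMode",
                   "WeightedMode")))
  for (i in seq_len(n_rep)) {
    sim <- generate_summary_stats(synthetic_truth(
      theta = theta, k = 30, palindrome_fraction = 0, seed = 20000 + i))
    est <- mr_all(harmonize_sim(sim), n_boot = 200, seed = 20000 + i)
    hits[i, ] <- est$ci_low <= theta & theta <= est$ci_high
  }
  coverage <- colMeans(hits)
  for (m in colnames(hits)) expect_gte(coverage[[m]], 0.90)
})
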