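# Instrument selection: association p-threshold, LD clumping, F-statistic
# filter and confounder-SNP blacklist, with a per-SNP exclusion ledger.

#' Instrument-selection configuration
#'
#' Defaults follow common practice for microbiome-exposure MR: a relaxed
#' genome-wide threshold of p < 1e-5 (16S taxon GWAS rarely yield
#' genome-wide-significant hits), clumping at r^2 < 0.01 within a 10,000 kb
#' window, and a per-SNP F-statistic floor of 10 to guard against
#' weak-instrument bias.
#'
#' @param p_threshold exposure association p-value threshold.
#' @param clump_r2 LD r^2 above (or at) which the less significant SNP of a
#'   pair is removed.
#' @param clump_window_kb clumping window in kilobases.
#' @param f_min minimum per-SNP F-statistic.
#' @param confounder_blacklist character vector of rsIDs to drop (SNPs known
#'   to associate with confounder traits; supplied by the user, the package
#'   does not scan trait catalogues).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 1e-5, clump_r2 = 0.01,
                             clump_window_kb = 10000, f_min = 10,
                             confounder_blacklist = character()) {
  assert_that(is.numeric(p_threshold) && p_threshold > 0 && p_threshold <= 1,
              "p_threshold must lie in (0, 1]")
  assert_that(is.numeric(clump_r2) && clump_r2 >= 0 && clump_r2 <= 1,
              "clump_r2 must lie in [0, 1]")
  assert_that(is.numeric(clump_window_kb) && clump_window_kb > 0,
              "clump_window_kb must be > 0")
  assert_that(is.numeric(f_min) && f_min >= 0, "f_min must be >= 0")
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 confounder_blacklist = as.character(confounder_blacklist)),
            class = "selection_config")
}

#' Fold an effect-allele frequency to a minor-allele frequency
#'
#' @param eaf numeric vector of allele frequencies in \[0, 1\].
#' @return `pmin(eaf, 1 - eaf)`, i.e. frequencies folded to \[0, 0.5\].
#' @export
fold_maf <- function(eaf) {
  assert_that(all(is.na(eaf) | (eaf >= 0 & eaf <= 1)),
              "allele frequencies must lie in [0, 1]")
  pmin(eaf, 1 - eaf)
}

#' Variance in the exposure explained by one SNP
#'
#' For a biallelic SNP with minor-allele frequency `maf` and per-allele
#' effect `beta` on a standardized exposure, the explained variance is
#' `R^2 = 2 * maf * (1 - maf) * beta^2`.
#'
#' @param maf minor-allele frequency in \[0, 0.5\] (fold with [fold_maf()]
#'   first if you hold effect-allele frequencies).
#' @param beta per-allele effect estimate.
#' @return explained-variance proportion(s).
#' @examples
#' variance_explained(0.25, 0.2)  # 0.015
#' @export
variance_explained <- function(maf, beta) {
  assert_that(all(is.finite(maf)) && all(maf >= 0 & maf <= 1),
              "maf must lie in [0, 1]")
  assert_that(all(maf <= 0.5), "maf must be folded to [0, 0.5]; see fold_maf()")
  assert_that(all(is.finite(beta)), "beta must be finite")
  2 * maf * (1 - maf) * beta^2
}

#' F-statistic for instrument strength
#'
#' `F = R^2 * (n - k - 1) / (k * (1 - R^2))` for `k` instruments jointly
#' explaining a fraction `R^2` of exposure variance in a GWAS of `n`
#' individuals. Per-SNP filtering uses `k = 1`; the same formula with the
#' summed `R^2` gives the set-level F reported alongside an instrument set.
#'
#' @param r2 explained-variance proportion in \[0, 1).
#' @param n exposure GWAS sample size (`n > k + 1`).
#' @param k number of SNPs.
#' @return F value(s).
#' @examples
#' f_statistic(0.015, 18340, 1)  # ~279
#' @export
f_statistic <- function(r2, n, k = 1L) {
  assert_that(all(is.finite(r2)) && all(r2 >= 0 & r2 < 1),
              "r2 must lie in [0, 1)")
  assert_that(all(n > k + 1), "sample size must exceed k + 1")
  assert_that(all(k >= 1), "k must be >= 1")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Greedy LD clumping of associated SNPs
#'
#' Prunes a set of SNPs to an approximately independent subset: SNPs are
#' visited in order of ascending p-value (ties broken by ascending rsID) and
#' a SNP is accepted unless a previously accepted SNP on the same chromosome
#' lies within `clump_window_kb` *and* has LD `r^2 >= clump_r2` with it.
#' Pairs absent from the LD table are treated as unlinked (r^2 = 0), so with
#' an empty table clumping only enforces the window/LD pair rule vacuously
#' and keeps everything.
#'
#' @param snps summary-statistics data.frame with `chrom` and `pos` set.
#' @param ld pairwise LD table: data.frame with columns `snp_a`, `snp_b`,
#'   `r2` (order of a/b irrelevant), or NULL for no LD information.
#' @param config a [selection_config()].
#' @return the accepted subset of `snps`, in genomic (chrom, pos) order.
#' @export
clump <- function(snps, ld = NULL, config = selection_config()) {
  if (nrow(snps) == 0L) return(snps)
  missing_coord <- is.na(snps$chrom) | is.na(snps$pos)
  assert_that(!any(missing_coord),
              sprintf("SNPs lack coordinates required for clumping: %s",
                      paste(utils::head(snps$snp[missing_coord], 5L),
                            collapse = ", ")))
  lookup <- ld_lookup(ld)
  ord <- order(snps$pval, snps$snp)
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      if (snps$chrom[j] != snps$chrom[i]) next
      if (abs(snps$pos[j] - snps$pos[i]) > config$clump_window_kb * 1000) next
      if (lookup(snps$snp[i], snps$snp[j]) >= config$clump_r2) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  res <- snps[sort(accepted), , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Closure giving r2 for a SNP pair, 0 when the pair is absent.
ld_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0L) return(function(a, b) 0)
  assert_that(all(c("snp_a", "snp_b", "r2") %in% names(ld)),
              "LD table needs columns snp_a, snp_b, r2")
  key <- c(paste(ld$snp_a, ld$snp_b, sep = "\r"),
           paste(ld$snp_b, ld$snp_a, sep = "\r"))
  val <- c(ld$r2, ld$r2)
  env <- new.env(parent = emptyenv(), size = length(key))
  for (i in seq_along(key)) assign(key[i], val[i], envir = env)
  function(a, b) {
    v <- get0(paste(a, b, sep = "\r"), envir = env, inherits = FALSE)
    if (is.null(v)) 0 else v
  }
}

#' Select instrumental variables for one exposure
#'
#' Applies the four selection criteria in sequence and records the fate of
#' every input SNP:
#' 1. exposure association `p < p_threshold`;
#' 2. greedy LD [clump()]ing;
#' 3. [harmonize()] against the outcome (palindromic and unalignable SNPs
#'    drop here);
#' 4. per-SNP F-statistic `>= f_min`;
#' 5. removal of blacklisted (confounder-associated) rsIDs.
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @param ld optional pairwise LD table (see [clump()]).
#' @param config a [selection_config()].
#' @param exposure_name label stored on the returned set.
#' @return object of class `instrument_set`: list with `exposure` (label),
#'   `instruments` (harmonized data.frame as in [harmonize()]), `k`,
#'   `f_range` (per-SNP F range), `f_set` (set-level F from summed R^2, NA if
#'   frequencies/sample sizes are missing) and `ledger` (data.frame `snp`,
#'   `stage`, `reason` for every excluded SNP). Every input SNP appears
#'   exactly once in `instruments` or `ledger`.
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               config = selection_config(),
                               exposure_name = "exposure") {
  validate_summary_stats(exposure)
  ledger <- data.frame(snp = character(), stage = character(),
                       reason = character(), stringsAsFactors = FALSE)
  note <- function(snps, stage, reason) {
    if (length(snps)) {
      ledger <<- rbind(ledger, data.frame(snp = snps, stage = stage,
                                          reason = reason,
                                          stringsAsFactors = FALSE))
    }
  }

  pass_p <- !is.na(exposure$pval) & exposure$pval < config$p_threshold
  note(exposure$snp[!pass_p], "p_threshold", "pval_above_threshold")
  cur <- exposure[pass_p, , drop = FALSE]

  if (nrow(cur)) {
    clumped <- clump(cur, ld, config)
    dropped <- setdiff(cur$snp, clumped$snp)
    note(dropped, "clump", "ld_with_more_significant_snp")
    cur <- clumped
  }

  harm <- harmonize(cur, outcome)
  if (nrow(harm$exclusions)) {
    note(harm$exclusions$snp, "harmonize", harm$exclusions$reason)
  }
  ins <- harm$instruments

  weak <- !is.na(ins$f_stat) & ins$f_stat < config$f_min
  unknown_f <- is.na(ins$f_stat)
  note(ins$snp[weak], "f_filter", "f_below_minimum")
  note(ins$snp[unknown_f], "f_filter", "f_not_computable")
  ins <- ins[!weak & !unknown_f, , drop = FALSE]

  black <- ins$snp %in% config$confounder_blacklist
  note(ins$snp[black], "blacklist", "confounder_associated")
  ins <- ins[!black, , drop = FALSE]
  rownames(ins) <- NULL

  r2_sum <- sum(variance_explained(fold_maf(ins$eaf_exposure),
                                   ins$beta_exposure))
  n_med <- stats::median(ins$n_exposure)
  f_set <- if (nrow(ins) && is.finite(r2_sum) && is.finite(n_med) &&
               n_med > nrow(ins) + 1) {
    f_statistic(r2_sum, n_med, nrow(ins))
  } else NA_real_

  structure(list(
    exposure = exposure_name,
    instruments = ins,
    k = nrow(ins),
    f_range = if (nrow(ins)) range(ins$f_stat) else c(NA_real_, NA_real_),
    f_set = f_set,
    ledger = ledger
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for '%s': k = %d (%d excluded)\n",
              x$exposure, x$k, nrow(x$ledger)))
  if (x$k) {
    cat(sprintf("  per-SNP F range: %.2f-%.2f; set-level F: %s\n",
                x$f_range[1], x$f_range[2],
                if (is.na(x$f_set)) "NA" else sprintf("%.2f", x$f_set)))
  }
  invisible(x)
}

#' Read a 3-column LD table (snp_a, snp_b, r2)
#' @param path TSV path.
#' @return data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  assert_that(file.exists(path), sprintf("LD table not found: %s", path))
  ld <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  assert_that(all(c("snp_a", "snp_b", "r2") %in% names(ld)),
              "LD table needs columns snp_a, snp_b, r2")
  ld
}
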