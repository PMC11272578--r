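# Reading GWAS summary-statistic tables and harmonizing exposure/outcome
# records onto a shared effect allele.

#' Canonical summary-statistic columns
#'
#' Internal canonical column names used throughout the package. A
#' `column_map` passed to [read_summary_stats()] maps these canonical names
#' to the names found in a file.
#' @noRd
SUMMARY_COLS <- c("snp", "effect_allele", "other_allele", "eaf",
                  "beta", "se", "pval", "n", "chrom", "pos")

MANDATORY_COLS <- c("snp", "effect_allele", "other_allele", "beta", "se")

#' Default column map for GWAS summary files
#'
#' Maps the canonical field names to the header names commonly used in
#' consortium summary files (`SNP`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`, plus optional `chrom`/`pos` coordinates).
#'
#' @return named character vector: canonical name -> file column name.
#' @export
default_column_map <- function() {
  c(snp = "SNP", effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n",
    chrom = "chrom", pos = "pos")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-separated per-SNP association table (delimiter
#' auto-detected from the header line), renames columns to the package's
#' canonical names via `column_map`, upper-cases alleles, and drops rows with
#' missing effect size or standard error (the number dropped is returned in
#' the `"n_skipped"` attribute).
#'
#' @param path path to the file.
#' @param column_map named character vector mapping canonical names
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`, `chrom`, `pos`) to the file's column names; defaults to
#'   [default_column_map()]. `snp`, alleles, `beta` and `se` are mandatory;
#'   the rest are optional and filled with `NA` when absent.
#' @return data.frame of per-SNP associations with canonical columns, one row
#'   per retained data row, with attribute `n_skipped` (rows dropped for
#'   missing beta/se).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(SNP = "rs1", effect_allele = "a", other_allele = "g",
#'              eaf = 0.2, beta = 0.1, se = 0.02, pval = 5e-7, n = 18340),
#'   f, sep = "\t", quote = FALSE, row.names = FALSE)
#' read_summary_stats(f)
#' @export
read_summary_stats <- function(path, column_map = default_column_map()) {
  assert_that(is.character(path) && length(path) == 1L && file.exists(path),
              sprintf("summary-statistics file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    stop_mrpipe(sprintf("empty summary-statistics file: %s", path),
                "mrpipe_input_error")
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           check.names = FALSE, comment.char = "")
  if (nrow(raw) == 0L) {
    stop_mrpipe(sprintf("summary-statistics file has no data rows: %s", path),
                "mrpipe_input_error")
  }

  map <- default_column_map()
  map[names(column_map)] <- column_map
  for (canon in MANDATORY_COLS) {
    if (!map[[canon]] %in% names(raw)) {
      stop_mrpipe(
        sprintf("mandatory column '%s' (mapped from '%s') missing in %s",
                map[[canon]], canon, path),
        "mrpipe_config_error")
    }
  }

  cols <- lapply(SUMMARY_COLS, function(canon) {
    src <- map[[canon]]
    if (src %in% names(raw)) raw[[src]] else rep(NA, nrow(raw))
  })
  names(cols) <- SUMMARY_COLS
  out <- as.data.frame(cols, stringsAsFactors = FALSE)

  keep <- !is.na(out$beta) & !is.na(out$se)
  n_skipped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out$snp <- as.character(out$snp)
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))
  for (num in c("eaf", "beta", "se", "pval", "n", "pos")) {
    out[[num]] <- as.numeric(out[[num]])
  }
  out$chrom <- as.character(out$chrom)
  rownames(out) <- NULL
  validate_summary_stats(out)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Validate a summary-statistics data frame
#'
#' Checks the per-SNP invariants: alleles are single A/C/G/T letters and
#' differ within a record, `se > 0`, `eaf` in \[0, 1\], `pval` in (0, 1\] and
#' `n >= 2` where supplied. When both `pval` and `beta`/`se` are present the
#' p-value is compared against the two-sided normal p implied by `beta/se`;
#' disagreement beyond 10% relative tolerance raises a warning (consortium
#' files round and truncate), not an error.
#'
#' @param x data.frame with canonical summary-statistic columns.
#' @return `x`, invisibly; errors on hard invariant violations.
#' @export
validate_summary_stats <- function(x) {
  assert_that(is.data.frame(x) && all(MANDATORY_COLS %in% names(x)),
              "expected a summary-statistics data.frame with canonical columns")
  bad_allele <- !(x$effect_allele %in% VALID_ALLELES) |
    !(x$other_allele %in% VALID_ALLELES)
  assert_that(!any(bad_allele),
              sprintf("non-ACGT alleles for: %s",
                      paste(utils::head(x$snp[bad_allele], 5L), collapse = ", ")))
  same <- x$effect_allele == x$other_allele
  assert_that(!any(same),
              sprintf("identical effect/other allele for: %s",
                      paste(utils::head(x$snp[same], 5L), collapse = ", ")))
  assert_that(all(x$se > 0), "standard errors must be > 0")
  ok_eaf <- is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)
  assert_that(all(ok_eaf), "eaf must lie in [0, 1]")
  ok_p <- is.na(x$pval) | (x$pval > 0 & x$pval <= 1)
  assert_that(all(ok_p), "p-values must lie in (0, 1]")
  ok_n <- is.na(x$n) | x$n >= 2
  assert_that(all(ok_n), "sample sizes must be >= 2")

  have_both <- !is.na(x$pval) & !is.na(x$beta) & !is.na(x$se)
  if (any(have_both)) {
    implied <- z_pvalue(x$beta[have_both], x$se[have_both])
    # relative agreement on the p scale; tiny p compared on log scale to
    # sidestep underflow in files reporting p ~ 1e-300
    rel <- abs(x$pval[have_both] - implied) / pmax(implied, .Machine$double.xmin)
    logrel <- abs(log(pmax(x$pval[have_both], .Machine$double.xmin)) -
                    log(pmax(implied, .Machine$double.xmin)))
    off <- rel > 0.1 & logrel > log(1.1)
    if (any(off)) {
      warning(sprintf(
        "p-values inconsistent with beta/se (>10%% relative) for %d SNP(s), e.g. %s",
        sum(off), paste(utils::head(x$snp[have_both][off], 3L), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Is an allele pair palindromic?
#'
#' A biallelic variant is palindromic (strand-ambiguous) when its two alleles
#' are reverse complements of each other, i.e. the pair is A/T or C/G. Such
#' variants cannot be safely oriented between two GWAS and are excluded
#' outright during harmonization.
#'
#' @param a1,a2 allele letters (vectors recycle as in [paste()]).
#' @return logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  assert_that(all(a1 %in% VALID_ALLELES) && all(a2 %in% VALID_ALLELES),
              "alleles must be one of A, C, G, T")
  a2 == unname(complement_allele(a1))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome records onto the exposure's effect allele for every SNP
#' present in both tables, and computes the per-SNP Wald ratio and instrument
#' strength. For each shared SNP:
#'
#' * identical allele pairs keep the outcome effect as-is;
#' * swapped pairs (outcome effect allele equals exposure other allele) have
#'   the outcome beta sign-flipped and its allele frequency complemented;
#' * palindromic (A/T, C/G) variants are excluded unconditionally — no
#'   frequency-based rescue is attempted;
#' * any other allele combination is excluded as `incompatible_alleles`
#'   (records are assumed forward-strand; no strand inference);
#' * a zero exposure beta is excluded as `null_exposure_effect` (the Wald
#'   ratio is undefined);
#' * exposure SNPs absent from the outcome table are excluded as
#'   `missing_outcome`.
#'
#' @param exposure,outcome summary-statistics data.frames (canonical columns,
#'   as returned by [read_summary_stats()]).
#' @return list with elements
#'   \describe{
#'     \item{instruments}{data.frame of harmonized instruments: `snp`,
#'       exposure alleles, `eaf_exposure`, `beta_exposure`, `se_exposure`,
#'       `pval_exposure`, `n_exposure`, `beta_outcome`, `se_outcome`,
#'       `eaf_outcome` (on the exposure's effect allele), `chrom`, `pos`,
#'       `ratio` (Wald ratio), `ratio_se` (first-order SE
#'       `se_outcome / |beta_exposure|`) and per-SNP `f_stat`.}
#'     \item{exclusions}{data.frame `snp`, `reason` for every shared or
#'       unmatched exposure SNP that did not survive.}
#'   }
#'   Input exposure SNPs are partitioned exactly between the two elements.
#' @export
harmonize <- function(exposure, outcome) {
  validate_summary_stats(exposure)
  validate_summary_stats(outcome)
  assert_that(!anyDuplicated(exposure$snp),
              "duplicate SNP ids in exposure table")
  out_idx <- match(exposure$snp, outcome$snp)

  n <- nrow(exposure)
  reason <- rep(NA_character_, n)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    j <- out_idx[i]
    if (is.na(j)) { reason[i] <- "missing_outcome"; next }
    if (is_palindromic(exposure$effect_allele[i], exposure$other_allele[i])) {
      reason[i] <- "palindromic"; next
    }
    if (exposure$beta[i] == 0) { reason[i] <- "null_exposure_effect"; next }
    ea <- outcome$effect_allele[j]; oa <- outcome$other_allele[j]
    if (ea == exposure$effect_allele[i] && oa == exposure$other_allele[i]) {
      beta_out[i] <- outcome$beta[j]
      eaf_out[i] <- outcome$eaf[j]
    } else if (ea == exposure$other_allele[i] && oa == exposure$effect_allele[i]) {
      beta_out[i] <- -outcome$beta[j]
      eaf_out[i] <- 1 - outcome$eaf[j]
    } else {
      reason[i] <- "incompatible_alleles"; next
    }
    se_out[i] <- outcome$se[j]
  }

  keep <- is.na(reason)
  instruments <- data.frame(
    snp = exposure$snp[keep],
    effect_allele = exposure$effect_allele[keep],
    other_allele = exposure$other_allele[keep],
    eaf_exposure = exposure$eaf[keep],
    beta_exposure = exposure$beta[keep],
    se_exposure = exposure$se[keep],
    pval_exposure = exposure$pval[keep],
    n_exposure = exposure$n[keep],
    beta_outcome = beta_out[keep],
    se_outcome = se_out[keep],
    eaf_outcome = eaf_out[keep],
    chrom = exposure$chrom[keep],
    pos = exposure$pos[keep],
    stringsAsFactors = FALSE
  )
  instruments$ratio <- instruments$beta_outcome / instruments$beta_exposure
  instruments$ratio_se <- instruments$se_outcome / abs(instruments$beta_exposure)
  maf <- fold_maf(instruments$eaf_exposure)
  r2 <- ifelse(is.na(maf), NA_real_,
               variance_explained(maf, instruments$beta_exposure))
  instruments$f_stat <- ifelse(
    is.na(r2) | is.na(instruments$n_exposure), NA_real_,
    f_statistic(r2, instruments$n_exposure, 1L))
  rownames(instruments) <- NULL

  exclusions <- data.frame(snp = exposure$snp[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  list(instruments = instruments, exclusions = exclusions)
}

#' Write harmonized instruments and exclusions to TSV
#'
#' @param harmonized list as returned by [harmonize()].
#' @param instruments_path,exclusions_path output file paths.
#' @return invisibly, the input.
#' @export
write_harmonized <- function(harmonized, instruments_path, exclusions_path) {
  write_tsv_(harmonized$instruments, instruments_path)
  write_tsv_(harmonized$exclusions, exclusions_path)
  invisible(harmonized)
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
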