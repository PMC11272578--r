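# Orchestration: one exposure end-to-end, and a scan over many exposures
# against a single outcome, with forest-plot-ready and sensitivity tables.

#' Pipeline run configuration
#'
#' @param selection a [selection_config()].
#' @param effects_model IVW effects model (see [mr_ivw()]).
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param n_sim MR-PRESSO simulation count.
#' @param phi mode-estimator bandwidth factor.
#' @param alpha nominal significance level for the IVW screen and the
#'   sensitivity flags.
#' @param seed base RNG seed; per-exposure seeds are derived from it so a
#'   rerun with the same configuration is bit-identical.
#' @param out_dir optional output directory; when set, result bundles are
#'   written as TSV/JSON.
#' @return object of class `run_config`.
#' @export
run_config <- function(selection = selection_config(),
                       effects_model = "auto", n_boot = 1000, n_sim = 1000,
                       phi = 1, alpha = 0.05, seed = 1L, out_dir = NULL) {
  assert_that(inherits(selection, "selection_config"),
              "selection must be a selection_config")
  assert_that(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  structure(list(selection = selection, effects_model = effects_model,
                 n_boot = n_boot, n_sim = n_sim, phi = phi, alpha = alpha,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

as_stats_table <- function(x, what) {
  if (is.character(x) && length(x) == 1L) return(read_summary_stats(x))
  assert_that(is.data.frame(x), sprintf("%s must be a path or data.frame", what))
  x
}

#' Run the full MR analysis for one exposure
#'
#' Instrument selection, all five estimators, and the sensitivity suite, for
#' a single exposure/outcome pair. Estimators and diagnostics whose
#' instrument-count requirements are unmet are reported as
#' `insufficient_instruments` rather than failing the run; an exposure with
#' no surviving instruments is returned with `status = "skipped"`.
#'
#' @param exposure,outcome summary-statistics data.frames or file paths.
#' @param config a [run_config()].
#' @param exposure_name label used in outputs.
#' @param ld optional LD table for clumping (see [clump()]).
#' @return object of class `mr_result`: list with `exposure` (label),
#'   `status` (`"ok"`/`"skipped"`), `selection` (the `instrument_set`),
#'   `estimates` (five-row data.frame from [mr_all()]), `sensitivity`
#'   (a `sensitivity_report`) and `seed`.
#' @export
run_single <- function(exposure, outcome, config = run_config(),
                       exposure_name = "exposure", ld = NULL) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  exposure <- as_stats_table(exposure, "exposure")
  outcome <- as_stats_table(outcome, "outcome")
  sel <- select_instruments(exposure, outcome, ld = ld,
                            config = config$selection,
                            exposure_name = exposure_name)
  if (sel$k == 0L) {
    return(structure(list(exposure = exposure_name, status = "skipped",
                          reason = "no_instruments", selection = sel,
                          estimates = NULL, sensitivity = NULL,
                          seed = config$seed),
                     class = "mr_result"))
  }
  estimates <- mr_all(sel, effects_model = config$effects_model,
                      n_boot = config$n_boot, phi = config$phi,
                      seed = config$seed)
  sens <- sensitivity_report(sel, n_sim = config$n_sim, alpha = config$alpha,
                             seed = if (is.null(config$seed)) NULL
                                    else config$seed + 1L)
  structure(list(exposure = exposure_name, status = "ok", selection = sel,
                 estimates = estimates, sensitivity = sens,
                 seed = config$seed),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR result for '%s' [%s]\n", x$exposure, x$status))
  if (x$status == "ok") {
    print(forest_table(cbind(exposure = x$exposure, x$estimates)))
  }
  invisible(x)
}

#' Scan many exposures against one outcome
#'
#' Runs [run_single()] for every entry of a manifest (a named list or
#' character vector of exposure tables/paths). Failures are isolated: an
#' unreadable exposure is marked `"errored"` in the skip summary and the
#' scan continues. The IVW p-value screen at `config$alpha` defines the
#' `significant` subset (nominal, uncorrected — matching standard practice
#' for taxon-wide microbiome MR scans); Benjamini-Hochberg q-values over the
#' IVW p-values are additionally reported in `qvalue_bh` as a labelled
#' extension, and play no part in the screen.
#'
#' @param manifest named list/vector of exposure data.frames or file paths.
#' @param outcome outcome summary statistics (data.frame or path).
#' @param config a [run_config()]; per-exposure seeds are `seed + 10 * i`.
#' @param ld optional LD table shared by all exposures.
#' @return object of class `mr_scan`: list with `summary` (one row per
#'   exposure x method), `significant` (exposures with IVW p < alpha),
#'   `sensitivity` (one row per exposure, Table-style diagnostics), `skips`
#'   (skipped/errored exposures with reasons) and `results` (named list of
#'   `mr_result`).
#' @export
run_scan <- function(manifest, outcome, config = run_config(), ld = NULL) {
  assert_that(length(manifest) > 0, "manifest must name at least one exposure")
  nms <- names(manifest)
  assert_that(!is.null(nms) && all(nzchar(nms)),
              "manifest entries must be named")
  outcome <- as_stats_table(outcome, "outcome")

  results <- list()
  skips <- data.frame(exposure = character(), status = character(),
                      reason = character(), stringsAsFactors = FALSE)
  for (i in seq_along(manifest)) {
    nm <- nms[i]
    cfg_i <- config
    if (!is.null(config$seed)) cfg_i$seed <- config$seed + 10L * i
    res <- tryCatch(
      run_single(manifest[[i]], outcome, cfg_i, exposure_name = nm, ld = ld),
      error = function(e) {
        structure(list(exposure = nm, status = "errored",
                       reason = conditionMessage(e)),
                  class = "mr_result")
      })
    results[[nm]] <- res
    if (res$status != "ok") {
      skips <- rbind(skips, data.frame(exposure = nm, status = res$status,
                                       reason = res$reason,
                                       stringsAsFactors = FALSE))
    }
  }

  ok <- Filter(function(r) r$status == "ok", results)
  summary_df <- if (length(ok)) {
    do.call(rbind, c(lapply(ok, function(r) {
      cbind(exposure = r$exposure, r$estimates, stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  } else {
    data.frame(exposure = character(), method = character(),
               pval = numeric(), stringsAsFactors = FALSE)
  }

  ivw <- summary_df[summary_df$method == "IVW", , drop = FALSE]
  qv <- stats::setNames(stats::p.adjust(ivw$pval, method = "BH"),
                        ivw$exposure)
  summary_df$qvalue_bh <- ifelse(summary_df$method == "IVW",
                                 unname(qv[summary_df$exposure]), NA_real_)
  sig_exposures <- ivw$exposure[!is.na(ivw$pval) & ivw$pval < config$alpha]
  significant <- summary_df[summary_df$exposure %in% sig_exposures, ,
                            drop = FALSE]

  sens_df <- if (length(ok)) {
    do.call(rbind, c(lapply(ok, function(r) {
      s <- r$sensitivity
      data.frame(exposure = r$exposure, k = s$k,
                 q_pval = s$q_pval,
                 presso_global_pval = s$presso_global_pval,
                 egger_intercept = s$egger_intercept,
                 egger_intercept_pval = s$egger_intercept_pval,
                 presso_outliers = paste(s$presso_outliers, collapse = ","),
                 loo_stable = if (is.null(s$loo)) NA else s$loo$stable,
                 stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  } else {
    data.frame(exposure = character(), stringsAsFactors = FALSE)
  }

  scan <- structure(list(summary = summary_df, significant = significant,
                         sensitivity = sens_df, skips = skips,
                         results = results, config = config),
                    class = "mr_scan")
  if (!is.null(config$out_dir)) write_scan(scan, config$out_dir)
  scan
}

#' Forest-plot-ready table of MR estimates
#'
#' Formats estimates for a forest plot / results table: odds ratios and CI
#' bounds to 2 decimals, p-values to 3, rows ordered by exposure and then
#' the fixed method order (IVW first).
#'
#' @param estimates data.frame of MrEstimate rows, optionally with an
#'   `exposure` column (added as `"exposure"` when absent).
#' @return data.frame with columns `exposure`, `method`, `or`, `or_ci`,
#'   `pval`, `k` (formatted strings except `k`).
#' @export
forest_table <- function(estimates) {
  assert_that(is.data.frame(estimates) && nrow(estimates) > 0,
              "estimates must be a non-empty data.frame")
  df <- estimates
  if (!"exposure" %in% names(df)) df$exposure <- "exposure"
  df$method <- factor(df$method, levels = METHOD_ORDER)
  df <- df[order(df$exposure, df$method), , drop = FALSE]
  out <- data.frame(
    exposure = df$exposure,
    method = as.character(df$method),
    or = sprintf("%.2f", df$or_value),
    or_ci = sprintf("%.2f-%.2f", df$or_ci_low, df$or_ci_high),
    pval = sprintf("%.3f", df$pval),
    k = df$k,
    stringsAsFactors = FALSE)
  out[df$model_note %in% "insufficient_instruments",
      c("or", "or_ci", "pval")] <- NA
  rownames(out) <- NULL
  out
}

#' Write scan outputs to a directory
#'
#' Emits `summary.tsv`, `significant.tsv`, `sensitivity.tsv`, `forest.tsv`,
#' per-exposure JSON bundles and `run_metadata.yaml` (config and seeds).
#'
#' @param scan an `mr_scan`.
#' @param dir output directory.
#' @return invisibly, the scan.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_(scan$summary, file.path(dir, "summary.tsv"))
  write_tsv_(scan$significant, file.path(dir, "significant.tsv"))
  write_tsv_(scan$sensitivity, file.path(dir, "sensitivity.tsv"))
  if (nrow(scan$summary)) {
    write_tsv_(forest_table(scan$summary), file.path(dir, "forest.tsv"))
  }
  write_tsv_(scan$skips, file.path(dir, "skips.tsv"))
  for (r in scan$results) {
    if (r$status != "ok") next
    bundle <- list(
      exposure = r$exposure,
      estimates = r$estimates,
      sensitivity = list(
        k = r$sensitivity$k, q_stat = r$sensitivity$q_stat,
        q_pval = r$sensitivity$q_pval,
        egger_intercept = r$sensitivity$egger_intercept,
        egger_intercept_pval = r$sensitivity$egger_intercept_pval,
        presso_global_pval = r$sensitivity$presso_global_pval,
        presso_outliers = r$sensitivity$presso_outliers,
        loo = r$sensitivity$loo$table,
        loo_stable = r$sensitivity$loo$stable
      ),
      ledger = r$selection$ledger,
      seed = r$seed
    )
    jsonlite::write_json(bundle,
                         file.path(dir, paste0(r$exposure, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  meta <- list(
    package = "mrpipe",
    version = as.character(utils::packageVersion("mrpipe")),
    seed = scan$config$seed,
    alpha = scan$config$alpha,
    n_boot = scan$config$n_boot,
    n_sim = scan$config$n_sim,
    selection = unclass(scan$config$selection)
  )
  yaml::write_yaml(meta, file.path(dir, "run_metadata.yaml"))
  invisible(scan)
}
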