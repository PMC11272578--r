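# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded estimator internals (bootstraps, MR-PRESSO
#' simulations) do not perturb user-level simulations.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stop_mrpipe <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mrpipe_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Signal that an estimator needs more instruments than are available
#' @noRd
stop_insufficient <- function(method, k, k_min) {
  stop_mrpipe(
    sprintf("%s requires at least %d instruments, got %d", method, k_min, k),
    "mrpipe_insufficient_instruments", method = method, k = k
  )
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_mrpipe(msg, "mrpipe_validation_error")
  invisible(TRUE)
}

VALID_ALLELES <- c("A", "C", "G", "T")

complement_allele <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

# Two-sided normal p-value for an estimate/SE pair.
z_pvalue <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
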