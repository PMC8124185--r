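# Internal helpers shared across modules.

# Derive a per-stage child seed from the global seed. Keeps regeneration of
# one input independent of the others while everything remains reproducible
# from a single integer. Result stays below 2^31 - 1.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stage * 16807) %% 2147483647)
}

#' Signed fold change from a log2 ratio
#'
#' Converts a log2 fold change into the signed-ratio convention in which
#' down-regulation is expressed as a negative reciprocal ratio, so that a
#' symmetric cut such as +/-1.6 can be applied: `2^x` for `x >= 0` and
#' `-2^(-x)` otherwise. The magnitude is therefore always >= 1.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Numeric vector of signed fold changes.
#' @examples
#' signed_fold_change(c(1, 0, -1))  # 2, 1, -2
#' @export
signed_fold_change <- function(log2fc) {
  stopifnot(is.numeric(log2fc))
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Differential-expression thresholds
#'
#' Container for the fold-change and FDR cut-offs used to call a feature
#' up- or down-regulated. The defaults (+/-1.6 on the signed fold change,
#' FDR <= 0.05) are the conventional symmetric cut for microarray and TMT
#' proteomics screens.
#'
#' @param fc_cut Positive signed-fold-change cut, must exceed 1.
#' @param fdr_cut FDR cut in (0, 1).
#' @return A list of class `"analysis_thresholds"`.
#' @export
analysis_thresholds <- function(fc_cut = 1.6, fdr_cut = 0.05) {
  stopifnot(is.numeric(fc_cut), length(fc_cut) == 1L, fc_cut > 1,
            is.numeric(fdr_cut), length(fdr_cut) == 1L,
            fdr_cut > 0, fdr_cut < 1)
  structure(list(fc_cut = fc_cut, fdr_cut = fdr_cut),
            class = "analysis_thresholds")
}

# Fraction helper for validation messages.
check_fraction <- function(x, name, allow_zero = FALSE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok)
    stop(sprintf("'%s' must be a fraction in %s0,1%s (got %s)", name,
                 if (allow_zero) "[" else "(", if (allow_one) "]" else ")",
                 format(x)), call. = FALSE)
  invisible(x)
}
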