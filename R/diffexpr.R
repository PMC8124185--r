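# Per-layer differential expression: filtering, normalization, moderated t,
# BH adjustment and threshold classification.

#' Drop features with any missing value
#'
#' Features that were identified but not quantified in every sample are
#' removed before statistics: a feature is kept only if it has a quantified
#' value in all samples. Row order is preserved.
#'
#' @param m An [expression_matrix()].
#' @return An `ExpressionMatrix` containing only complete features.
#' @export
drop_incomplete_features <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keep <- rowSums(is.na(m$values)) == 0L
  if (!any(keep))
    stop("all features have missing values; nothing left to analyse")
  expression_matrix(m$values[keep, , drop = FALSE], as.character(m$condition))
}

#' Log2-transform an abundance matrix
#'
#' @param m An [expression_matrix()] of strictly positive raw abundances.
#' @return The element-wise log2 matrix.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive abundance at feature '%s', sample '%s'",
                 rownames(m$values)[bad[1L, 1L]],
                 colnames(m$values)[bad[1L, 2L]]))
  }
  out <- m
  out$values <- log2(m$values)
  out
}

#' Median normalization ('diff.median')
#'
#' Translates every sample column additively so that all column medians
#' match the grand median of the matrix: column j is shifted by
#' (grand median - median of column j). Intended for log-scale data.
#' The operation is idempotent.
#'
#' @param m An [expression_matrix()] on the log scale, no missing values.
#' @return The normalized `ExpressionMatrix`.
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (anyNA(m$values))
    stop("median_normalize expects a complete matrix; run drop_incomplete_features() first")
  grand <- stats::median(m$values)
  shifts <- grand - apply(m$values, 2L, stats::median)
  out <- m
  out$values <- sweep(m$values, 2L, shifts, `+`)
  out
}

# Newton solve of trigamma(y) = x, vectorized. Follows the standard
# asymptotic start/stop rules for the strictly decreasing trigamma on (0,Inf).
trigamma_inverse <- function(x) {
  y <- ifelse(x > 1e7, 1 / sqrt(x), 0.5 + 1 / x)
  out <- y
  solve1 <- function(x1, y1) {
    if (!is.finite(x1) || x1 <= 0) return(NA_real_)
    if (x1 > 1e7) return(1 / sqrt(x1))
    if (x1 < 1e-6) return(1 / x1)
    for (i in 1:75) {
      tri <- trigamma(y1)
      dif <- tri * (1 - tri / x1) / psigamma(y1, deriv = 2L)
      y1 <- y1 + dif
      if (abs(dif) / y1 < 1e-10) break
    }
    y1
  }
  for (i in seq_along(x)) out[i] <- solve1(x[i], y[i])
  out
}

# Method-of-moments fit of a scaled inverse-chi-square prior to observed
# residual variances s2 on df degrees of freedom, via the log-variance
# digamma/trigamma matching. Returns the prior df d0 (possibly Inf) and the
# prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    stop("need at least two positive residual variances to fit the prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(df_prior = Inf, var_prior = exp(emean)))
  df_prior <- 2 * trigamma_inverse(evar)
  if (!is.finite(df_prior))
    return(list(df_prior = Inf, var_prior = exp(emean)))
  var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' For each feature the pooled two-sample residual variance \eqn{s_g^2} (on
#' \eqn{d_g = n_1 + n_2 - 2} df) is shrunk towards a prior variance
#' \eqn{s_0^2} estimated from all features, assuming the variances follow a
#' scaled inverse-chi-square distribution with \eqn{d_0} prior df. The prior
#' is fitted by the method of moments on the log variances (digamma/trigamma
#' matching). The posterior variance is
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' and the moderated statistic is
#' \eqn{t_g = \mathrm{log2fc}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})}, referred
#' two-sided to a t distribution on \eqn{d_0 + d_g} df. An infinite prior df
#' makes every posterior variance equal to \eqn{s_0^2} and the reference
#' normal.
#'
#' @param m A normalized log-scale [expression_matrix()], complete, with at
#'   least two replicates per condition.
#' @param prior_df Optional override of the prior degrees of freedom:
#'   `0` gives the ordinary pooled t-test, `Inf` full shrinkage to the common
#'   variance, `NULL` (default) estimates it from the data.
#' @return A data.frame with one row per feature: `feature_id`,
#'   `mean_control`, `mean_treated`, `log2fc`, `s2`, `t_mod`, `df_total`,
#'   `p_value`, plus attributes `df_prior` and `var_prior`.
#' @export
moderated_ttest <- function(m, prior_df = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (anyNA(m$values))
    stop("moderated_ttest expects a complete matrix")
  ctrl <- m$values[, m$condition == "control", drop = FALSE]
  trt  <- m$values[, m$condition == "treated", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(trt)
  df_resid <- n1 + n2 - 2L
  if (df_resid < 1L)
    stop("zero residual degrees of freedom; need more replicates")
  mean_c <- rowMeans(ctrl)
  mean_t <- rowMeans(trt)
  log2fc <- mean_t - mean_c
  ss <- rowSums((ctrl - mean_c)^2) + rowSums((trt - mean_t)^2)
  s2 <- ss / df_resid

  if (is.null(prior_df)) {
    if (nrow(m$values) < 10L) {
      warning("fewer than 10 features: prior estimation is unstable, ",
              "falling back to the ordinary t-test (prior df = 0)")
      prior <- list(df_prior = 0, var_prior = NA_real_)
    } else {
      prior <- tryCatch(fit_variance_prior(s2, df_resid), error = function(e) {
        warning("variance-prior estimation failed (", conditionMessage(e),
                "); using an infinite prior df")
        list(df_prior = Inf, var_prior = exp(mean(log(s2[s2 > 0]))))
      })
    }
  } else {
    stopifnot(is.numeric(prior_df), length(prior_df) == 1L, prior_df >= 0)
    if (is.infinite(prior_df)) {
      z <- log(s2[is.finite(s2) & s2 > 0])
      prior <- list(df_prior = Inf,
                    var_prior = exp(mean(z) - digamma(df_resid / 2) +
                                      log(df_resid / 2)))
    } else {
      est <- if (prior_df > 0) fit_variance_prior(s2, df_resid)
             else list(var_prior = NA_real_)
      prior <- list(df_prior = prior_df, var_prior = est$var_prior)
    }
  }

  d0 <- prior$df_prior
  s02 <- prior$var_prior
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- data.frame(feature_id = rownames(m$values),
                    mean_control = mean_c,
                    mean_treated = mean_t,
                    log2fc = log2fc,
                    s2 = s2,
                    t_mod = t_mod,
                    df_total = df_total,
                    p_value = p,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s02
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment of a p-value vector, in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted p-values (FDR).
#' @export
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must be numeric in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify differential-expression status against thresholds
#'
#' Adds the signed fold change, FDR and a tri-state status to a
#' moderated-t result table. A feature is `up` when its signed fold change
#' is at least `fc_cut` and its FDR at most `fdr_cut`; `down` when the
#' signed fold change is at most `-fc_cut` at the same FDR; otherwise `ns`.
#'
#' @param results A data.frame with columns `feature_id`, `log2fc` and
#'   `p_value` (as returned by [moderated_ttest()]). If an `fdr` column is
#'   already present it is used as is; otherwise FDRs are computed with
#'   [adjust_bh()].
#' @param thresholds An [analysis_thresholds()] object.
#' @return The input with columns `signed_fc`, `fdr` and `status` added, and
#'   an attribute `"status_counts"` (named vector over up/down/ns).
#' @export
classify_de <- function(results, thresholds = analysis_thresholds()) {
  stopifnot(is.data.frame(results),
            all(c("feature_id", "log2fc", "p_value") %in% names(results)),
            inherits(thresholds, "analysis_thresholds"))
  out <- results
  out$signed_fc <- signed_fold_change(out$log2fc)
  if (is.null(out$fdr)) out$fdr <- adjust_bh(out$p_value)
  out$status <- ifelse(
    out$signed_fc >= thresholds$fc_cut & out$fdr <= thresholds$fdr_cut, "up",
    ifelse(out$signed_fc <= -thresholds$fc_cut & out$fdr <= thresholds$fdr_cut,
           "down", "ns"))
  counts <- table(factor(out$status, levels = c("up", "down", "ns")))
  attr(out, "status_counts") <- c(counts)
  out
}

#' Run the full per-layer differential-expression stage
#'
#' Convenience wrapper chaining [drop_incomplete_features()],
#' [log2_transform()] (optional), [median_normalize()], [moderated_ttest()]
#' and [classify_de()].
#'
#' @param m An [expression_matrix()] of raw (or already logged) abundances.
#' @param thresholds An [analysis_thresholds()] object.
#' @param log2 Whether the input is on the raw scale and must be
#'   log2-transformed first (default `TRUE`).
#' @param prior_df Passed to [moderated_ttest()].
#' @return The classified DE table (see [classify_de()]).
#' @export
run_de <- function(m, thresholds = analysis_thresholds(), log2 = TRUE,
                   prior_df = NULL) {
  m <- drop_incomplete_features(m)
  if (log2) m <- log2_transform(m)
  m <- median_normalize(m)
  classify_de(moderated_ttest(m, prior_df = prior_df), thresholds)
}
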