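#' Two-condition expression matrix
#'
#' Light container for a features-by-samples abundance matrix from a
#' two-condition design. Rows are features (transcripts or proteins),
#' columns are samples, and each sample carries a condition label,
#' `"control"` or `"treated"`. Values may be missing (`NA`) for features
#' that were identified but not quantified in every sample.
#'
#' @param values Numeric matrix with unique rownames (feature IDs) and
#'   unique colnames (sample IDs).
#' @param condition Character or factor vector, one entry per column, with
#'   values `"control"` or `"treated"`; at least two samples per condition.
#' @return An object of class `"ExpressionMatrix"`: a list with elements
#'   `values` and `condition` (a factor aligned to the columns).
#' @export
expression_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("'values' must have unique rownames (feature IDs)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("'values' must have unique colnames (sample IDs)")
  condition <- as.character(condition)
  if (length(condition) != ncol(values))
    stop("'condition' must have one entry per sample column")
  bad <- setdiff(unique(condition), c("control", "treated"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(condition, levels = c("control", "treated")))
  if (any(tab < 2L))
    stop("need at least 2 samples per condition (got ",
         paste(tab, collapse = "/"), ")")
  structure(
    list(values = values,
         condition = factor(condition, levels = c("control", "treated"))),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%d control, %d treated)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "control"), sum(x$condition == "treated")))
  if (anyNA(x$values))
    cat(sprintf("  %d missing values\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature IDs of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of feature IDs (rownames).
#' @export
feature_ids <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  rownames(x$values)
}
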