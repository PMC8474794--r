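#' Expression matrix container
#'
#' A light container for a features x samples intensity matrix together
#' with its scale (linear fluorescence units or log2 thereof) and, for
#' two-condition designs, a sample -> condition map.  Tumour cohorts carry
#' no condition map.
#'
#' @param values numeric matrix, features in rows (unique rownames required),
#'   samples in columns (unique colnames required).
#' @param scale `"linear"` or `"log2"`.  Linear-scale values must be
#'   non-negative.
#' @param condition optional named character vector mapping every sample id
#'   to `"case"` or `"control"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("linear", "log2"), condition = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("feature ids (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample ids (colnames) must be present and unique")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop("linear-scale intensities must be non-negative")
  if (!is.null(condition)) {
    condition <- as.character(condition)[match(colnames(values), names(condition))]
    names(condition) <- colnames(values)
    if (anyNA(condition))
      stop("every sample must be labelled when a condition map is given")
    if (!all(condition %in% c("case", "control")))
      stop("condition labels must be 'case' or 'control'")
  }
  structure(list(values = values, scale = scale, condition = condition),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, %s scale\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$condition)) {
    tb <- table(x$condition)
    cat("  conditions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Convert an expression matrix to log2 scale
#'
#' Linear intensities are floored at a small positive offset before taking
#' log2 so that zero intensities do not produce -Inf.
#'
#' @param x an [expr_matrix()].
#' @param offset additive offset applied to linear intensities (default 1).
#' @return an `expr_matrix` on log2 scale.
#' @export
as_log2 <- function(x, offset = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale == "log2") return(x)
  expr_matrix(log2(x$values + offset), scale = "log2", condition = x$condition)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row; the first column holds feature ids and the
#' remaining columns one sample each.
#'
#' @param path TSV file path.
#' @param scale `"linear"` or `"log2"`.
#' @param condition_path optional two-column TSV (sample_id, condition)
#'   mapping samples to `case`/`control`.
#' @return an [expr_matrix()].
#' @export
read_expr_tsv <- function(path, scale = c("linear", "log2"),
                          condition_path = NULL) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a feature column plus samples: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensities in ", path)
  rownames(m) <- as.character(df[[1]])
  cond <- NULL
  if (!is.null(condition_path)) cond <- read_condition_tsv(condition_path)
  expr_matrix(m, scale = scale, condition = cond)
}

#' Read a sample -> condition map from TSV
#'
#' @param path two-column TSV (sample_id, condition with values case/control).
#' @return named character vector.
#' @export
read_condition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("condition TSV needs two columns: ", path)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write an expression matrix to TSV
#'
#' @param x an [expr_matrix()].
#' @param path output file.
#' @param feature_col name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(x, path, feature_col = "feature_id") {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a condition map to TSV
#' @param condition named character vector (sample -> case/control).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_condition_tsv <- function(condition, path) {
  utils::write.table(
    data.frame(sample_id = names(condition), condition = unname(condition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
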