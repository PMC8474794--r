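#' Fold-change centroid
#'
#' An ordered gene -> weight map in which each weight is a signed
#' fold-change ratio.  The centroid is the template profile against which
#' tumour expression profiles are classified.
#'
#' @param weights named numeric vector, names = gene symbols, values =
#'   signed fold changes; no duplicates, no zero weights.
#' @param provenance free-text notes on the source DE run and any sign
#'   reversals.
#' @return an object of class `centroid`.
#' @export
centroid <- function(weights, provenance = character()) {
  if (length(weights) == 0) stop("centroid must contain at least one gene")
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("all centroid weights must be named by gene symbol")
  if (anyDuplicated(.norm_symbol(names(weights))))
    stop("duplicate genes in centroid")
  if (any(!is.finite(weights)) || any(weights == 0))
    stop("all centroid weights must be finite and non-zero")
  structure(list(weights = weights, provenance = provenance),
            class = "centroid")
}

#' @export
print.centroid <- function(x, ...) {
  cat(sprintf("<centroid> %d genes (%d up, %d down)\n",
              length(x$weights), sum(x$weights > 0), sum(x$weights < 0)))
  invisible(x)
}

#' @export
length.centroid <- function(x) length(x$weights)

#' Build a centroid from a DE table
#'
#' One entry per gene; where a gene has several probes the weight is the
#' arithmetic mean of the signed probe fold changes.
#'
#' @param de a non-empty `de_table`.
#' @return a [centroid()].
#' @export
build_centroid <- function(de) {
  if (nrow(de) == 0) stop("cannot build a centroid from an empty DE table")
  w <- tapply(de$fold_change, de$gene_symbol, mean)
  if (any(w == 0))
    stop("probe fold changes average to zero for: ",
         paste(names(w)[w == 0], collapse = ", "))
  # tapply sorts by gene; restore first-appearance order
  ord <- unique(de$gene_symbol)
  w <- stats::setNames(as.numeric(w[ord]), ord)
  centroid(w, provenance = sprintf("built from DE table (%d probes, %d genes)",
                                   nrow(de), length(w)))
}

#' Reverse the sign of selected centroid weights
#'
#' Used to flip genes whose prognostic behaviour opposes their
#' differential-expression direction (tumour-suppressor-like entries).
#' Applying the same reversal twice restores the original centroid.
#'
#' @param cent a [centroid()].
#' @param genes symbols to negate (all must be present).
#' @return a [centroid()] with the listed weights negated.
#' @export
reverse_signs <- function(cent, genes) {
  stopifnot(inherits(cent, "centroid"))
  if (length(genes) == 0) return(cent)
  key <- .norm_symbol(names(cent$weights))
  hit <- match(.norm_symbol(genes), key)
  if (anyNA(hit))
    stop("genes not in centroid: ", paste(genes[is.na(hit)], collapse = ", "))
  w <- cent$weights
  w[hit] <- -w[hit]
  centroid(w, provenance = c(cent$provenance,
                             sprintf("reversed: %s", paste(genes, collapse = ","))))
}

# signed-log transform of centroid weights: a fold change of +4 maps to
# +2, -4 to -2, +/-1 to 0.  Correlating against raw linear ratios would be
# dominated by the largest ones.
transform_weights <- function(cent) {
  stopifnot(inherits(cent, "centroid"))
  stats::setNames(sign(cent$weights) * log2(abs(cent$weights)), names(cent$weights))
}

#' Pearson correlation between a patient profile and a centroid
#'
#' The profile (gene-wise median-centred log2 expression) is correlated
#' with the signed-log transformed centroid weights
#' (`sign(w) * log2(|w|)`) over the genes shared by both; centroid genes
#' absent from the profile are dropped.
#'
#' @param profile named numeric vector of median-centred log2 expression.
#' @param cent a [centroid()].
#' @return Pearson r in `[-1, 1]`.
#' @export
centroid_correlation <- function(profile, cent) {
  t <- transform_weights(cent)
  hit <- match(.norm_symbol(names(t)), .norm_symbol(names(profile)))
  keep <- !is.na(hit)
  if (sum(keep) < 3) stop("fewer than 3 genes shared with the centroid")
  x <- as.numeric(profile[hit[keep]])
  y <- as.numeric(t[keep])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in profile or centroid over shared genes")
  stats::cor(x, y)
}

# shared-gene preparation for cohort classification: log2, median-centre
# each gene across the cohort, restrict to centroid genes present.
.prepare_cohort <- function(cohort, cent) {
  stopifnot(inherits(cohort, "expr_matrix"), inherits(cent, "centroid"))
  cohort <- as_log2(cohort)
  t <- transform_weights(cent)
  hit <- match(.norm_symbol(names(t)), .norm_symbol(rownames(cohort$values)))
  dropped <- names(t)[is.na(hit)]
  keep <- !is.na(hit)
  if (sum(keep) < 3)
    stop("fewer than 3 centroid genes found in the cohort")
  m <- cohort$values[hit[keep], , drop = FALSE]
  m <- m - apply(m, 1, stats::median)
  list(centred = m, template = as.numeric(t[keep]), dropped = dropped)
}

#' Classify a cohort by centroid correlation
#'
#' Each patient's gene-wise median-centred log2 profile is correlated
#' (Pearson) with the transformed centroid; patients with r > 0 form the
#' `positive` (centroid-like) group and the rest the `negative` group —
#' an exact zero is conservatively assigned to `negative`.  Patients whose
#' profile has zero variance over the centroid genes are unclassifiable;
#' more than 5% unclassifiable aborts.
#'
#' @param cohort an [expr_matrix()] (log2, or linear — converted).
#' @param cent a [centroid()].
#' @return a `stratification` data.frame with columns `sample_id`,
#'   `score` (Pearson r) and `group`; attributes `dropped_genes` (centroid
#'   genes absent from the cohort) and `n_unclassifiable`.
#' @export
classify_by_centroid <- function(cohort, cent) {
  prep <- .prepare_cohort(cohort, cent)
  y <- prep$template
  if (stats::sd(y) == 0)
    stop("centroid template has zero variance over cohort genes")
  r <- apply(prep$centred, 2, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  })
  n_bad <- sum(is.na(r))
  if (n_bad > 0.05 * length(r))
    stop(sprintf("%d of %d patients unclassifiable (> 5%%)", n_bad, length(r)))
  out <- data.frame(sample_id = colnames(prep$centred),
                    score = unname(r),
                    group = ifelse(is.na(r), NA_character_,
                                   ifelse(r > 0, "positive", "negative")),
                    stringsAsFactors = FALSE)
  if (length(prep$dropped))
    message(length(prep$dropped), " centroid gene(s) not found in cohort: ",
            paste(prep$dropped, collapse = ", "))
  attr(out, "dropped_genes") <- prep$dropped
  attr(out, "n_unclassifiable") <- n_bad
  class(out) <- c("stratification", "data.frame")
  out
}

#' Weighted median-split composite score
#'
#' Per patient, the mean over signature genes of
#' `sign(weight) * (median-centred log2 expression)` — genes associated
#' with good prognosis enter with negative weighting.  The cohort is split
#' at the median composite score into `high` and `low` groups; scores
#' exactly at the median go to `low`.
#'
#' @param cohort an [expr_matrix()].
#' @param cent a [centroid()].
#' @return a `stratification` data.frame (`sample_id`, `score`, `group`).
#' @export
composite_score <- function(cohort, cent) {
  prep <- .prepare_cohort(cohort, cent)
  s <- as.numeric(colMeans(prep$centred * sign(prep$template)))
  cut <- stats::median(s)
  out <- data.frame(sample_id = colnames(prep$centred),
                    score = s,
                    group = ifelse(s > cut, "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "dropped_genes") <- prep$dropped
  class(out) <- c("stratification", "data.frame")
  out
}

#' Read / write a centroid as TSV (gene_symbol, weight)
#'
#' @param cent a [centroid()].
#' @param path file path.
#' @return `read_centroid_tsv` returns a [centroid()]; the writer returns
#'   `path` invisibly.
#' @export
write_centroid_tsv <- function(cent, path) {
  stopifnot(inherits(cent, "centroid"))
  utils::write.table(
    data.frame(gene_symbol = names(cent$weights), weight = unname(cent$weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroid_tsv
#' @export
read_centroid_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  centroid(stats::setNames(as.numeric(df[[2]]), as.character(df[[1]])),
           provenance = paste("read from", path))
}

#' Write a stratification result as TSV
#' @param s a `stratification` data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_stratification_tsv <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
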