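#' Signed fold change of two condition medians
#'
#' The convention used throughout: the ratio of the larger median over the
#' smaller one, with a negative sign when the control median is the larger,
#' so magnitudes are always >= 1 and down-regulation is signed negative.
#'
#' @param median_case,median_ctrl positive linear-scale median intensities
#'   (vectorized).
#' @return signed fold-change ratio(s), `|fc| >= 1`.
#' @export
fold_change <- function(median_case, median_ctrl) {
  if (any(median_case <= 0) || any(median_ctrl <= 0))
    stop("medians must be strictly positive linear-scale intensities")
  ifelse(median_ctrl > median_case,
         -median_ctrl / median_case,
         median_case / median_ctrl)
}

#' Round half away from zero
#'
#' Reporting convention for fold changes: 5.565 prints as 5.57.  Base R's
#' `round()` rounds half to even, which disagrees on exact halves.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Rank product of one feature's per-comparison ranks
#'
#' The geometric mean of a feature's ranks across `k` replicate
#' comparisons; small values mean consistently extreme regulation.
#'
#' @param ranks numeric vector of ranks, one per comparison; midranks for
#'   ties are allowed.
#' @param k number of comparisons, defaults to `length(ranks)`.
#' @return `(prod(ranks))^(1/k)`.
#' @export
rank_product <- function(ranks, k = length(ranks)) {
  if (length(ranks) == 0) stop("empty rank list")
  if (k < 1) stop("k must be >= 1")
  if (any(ranks < 1)) stop("ranks must be >= 1")
  exp(sum(log(ranks)) / k)
}

# geometric-mean-rank statistics for one label assignment.
# L: features x samples log2 matrix; case/ctrl: column indices.
# Returns list(up=, down=): per-feature rank products over all
# case x control pairwise log-ratios, midranks for ties.
.rp_stats <- function(L, case, ctrl) {
  n <- nrow(L)
  k <- length(case) * length(ctrl)
  sum_log_up <- numeric(n)
  sum_log_down <- numeric(n)
  for (i in case) {
    for (j in ctrl) {
      d <- L[, i] - L[, j]
      r_down <- rank(d, ties.method = "average")   # most down-regulated = 1
      sum_log_down <- sum_log_down + log(r_down)
      r_up <- rank(-d, ties.method = "average")    # most up-regulated = 1
      sum_log_up <- sum_log_up + log(r_up)
    }
  }
  list(up = exp(sum_log_up / k), down = exp(sum_log_down / k))
}

# all (or sampled) assignments of samples to a case arm of size n_case;
# returns a list of integer vectors (case column indices).
.perm_assignments <- function(n_samples, n_case, n_perm) {
  if (identical(n_perm, "exhaustive") || is.infinite(n_perm)) {
    combos <- utils::combn(n_samples, n_case)
    return(lapply(seq_len(ncol(combos)), function(i) combos[, i]))
  }
  lapply(seq_len(n_perm), function(i) sample.int(n_samples, n_case))
}

#' Rank-product differential expression test
#'
#' Two-condition differential expression on a small-replicate array.  Per
#' probe it computes the signed fold change of the condition medians and
#' the up- and down-regulation rank products over all case x control
#' pairwise comparisons (`k = n_case * n_ctrl`).  Significance comes from
#' permuting the condition labels: the one-sided permutation p for each
#' regulation direction is the pooled proportion, over all features and
#' permutations, of permuted rank products at or below the observed one,
#' with a +1 correction so p is never zero.  The reported `p_value` is
#' two-sided: the same pooled-proportion formula applied to the two-sided
#' statistic `min(rp_up, rp_down)`, so that it is approximately uniform
#' under the null despite each probe's direction being picked from the
#' data.  The proportion of false prediction (pfp),
#' the rank-product analogue of an FDR, is the one-sided p of the probe's
#' direction times `n_features / rank(observed RP)` within that direction.
#'
#' @param expr an [expr_matrix()] with a case/control condition map; linear
#'   intensities must be strictly positive (log2 input is used as-is).
#' @param n_perm number of label permutations (>= 100), or `"exhaustive"`
#'   to enumerate every assignment of samples to arms.
#' @param seed integer seed; required unless `n_perm = "exhaustive"`.
#' @param annotation optional named character vector mapping probe id to
#'   gene symbol; unannotated probes keep their probe id.
#' @return a `de_table` data.frame with columns `probe_id`, `gene_symbol`,
#'   `fold_change`, `rp_up`, `rp_down`, `p_value`, `pfp`, `direction`,
#'   sorted by decreasing fold change then increasing p-value.
#' @export
rankprod_test <- function(expr, n_perm = 1000, seed = NULL, annotation = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(expr$condition))
    stop("rankprod_test needs a case/control condition map")
  exhaustive <- identical(n_perm, "exhaustive") || is.infinite(n_perm)
  if (!exhaustive) {
    if (!is.numeric(n_perm) || n_perm < 100)
      stop("n_perm must be >= 100 (or \"exhaustive\")")
    if (is.null(seed)) stop("a seed is required for random permutations")
  }

  case <- which(expr$condition == "case")
  ctrl <- which(expr$condition == "control")
  if (length(case) < 2 || length(ctrl) < 2)
    stop("need at least 2 samples per condition")

  if (expr$scale == "linear") {
    if (any(expr$values <= 0))
      stop("non-positive intensities on linear scale")
    L <- log2(expr$values)
    med_case <- apply(expr$values[, case, drop = FALSE], 1, stats::median)
    med_ctrl <- apply(expr$values[, ctrl, drop = FALSE], 1, stats::median)
  } else {
    L <- expr$values
    med_case <- 2^apply(L[, case, drop = FALSE], 1, stats::median)
    med_ctrl <- 2^apply(L[, ctrl, drop = FALSE], 1, stats::median)
  }

  n <- nrow(L)
  fc <- fold_change(med_case, med_ctrl)
  obs <- .rp_stats(L, case, ctrl)

  run <- function() {
    perms <- .perm_assignments(ncol(L), length(case),
                               if (exhaustive) "exhaustive" else n_perm)
    null_up <- numeric(0)
    null_down <- numeric(0)
    null_min <- numeric(0)
    for (p in perms) {
      s <- .rp_stats(L, p, setdiff(seq_len(ncol(L)), p))
      null_up <- c(null_up, s$up)
      null_down <- c(null_down, s$down)
      null_min <- c(null_min, pmin(s$up, s$down))
    }
    list(up = sort(null_up), down = sort(null_down),
         min = sort(null_min), B = length(perms))
  }
  null <- if (exhaustive) run() else .with_seed(seed, run())

  denom <- n * null$B + 1
  p_up <- (findInterval(obs$up, null$up) + 1) / denom
  p_down <- (findInterval(obs$down, null$down) + 1) / denom
  p_two <- (findInterval(pmin(obs$up, obs$down), null$min) + 1) / denom
  rank_up <- rank(obs$up, ties.method = "average")
  rank_down <- rank(obs$down, ties.method = "average")
  pfp_up <- p_up * n / rank_up
  pfp_down <- p_down * n / rank_down

  up <- fc > 0
  ids <- rownames(L)
  sym <- if (is.null(annotation)) ids else {
    s <- annotation[ids]
    ifelse(is.na(s), ids, s)
  }
  out <- data.frame(
    probe_id = ids,
    gene_symbol = unname(sym),
    fold_change = unname(fc),
    rp_up = obs$up,
    rp_down = obs$down,
    p_value = p_two,
    pfp = ifelse(up, pfp_up, pfp_down),
    direction = ifelse(up, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$fold_change, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write a differential-expression table
#'
#' TSV round-trip for `de_table` objects.
#'
#' @param de a `de_table`.
#' @param path file path.
#' @return `read_de_tsv` returns a `de_table`; `write_de_tsv` returns
#'   `path` invisibly.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol", "fold_change", "p_value", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DE table missing columns: ", paste(miss, collapse = ", "))
  class(df) <- c("de_table", "data.frame")
  df
}
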