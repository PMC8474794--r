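# small in-code fixtures shared across test files

# a tiny linear-scale two-arm matrix with named probes
toy_expr <- function(values, n_case = 3, n_ctrl = 3) {
  m <- as.matrix(values)
  colnames(m) <- c(sprintf("case_%d", seq_len(n_case)),
                   sprintf("ctrl_%d", seq_len(n_ctrl)))
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%02d", seq_len(nrow(m)))
  cond <- stats::setNames(rep(c("case", "control"), c(n_case, n_ctrl)),
                          colnames(m))
  expr_matrix(m, scale = "linear", condition = cond)
}

# a minimal clinical table with all optional covariates populated
toy_clinical <- function(time, event, n = length(time)) {
  clinical_table(data.frame(
    sample_id = sprintf("pt_%03d", seq_len(n)),
    time = time, event = event, endpoint = "DMFS",
    er = rep_len(c("pos", "neg"), n), ln = rep_len(c("neg", "pos"), n),
    grade = rep_len(1:3, n),
    age_gt50 = rep_len(c(TRUE, FALSE), n),
    size_gt20mm = rep_len(c(FALSE, TRUE), n),
    subtype = rep_len(c("lumA", "lumB", "her2", "basal", "normal"), n),
    stringsAsFactors = FALSE))
}

# independent brute-force rank-product machinery (oracle; loops only,
# no shared code with the package internals)
oracle_rp <- function(L, case, ctrl, what = c("up", "down")) {
  what <- match.arg(what)
  n <- nrow(L)
  ratios <- matrix(NA_real_, n, length(case) * length(ctrl))
  k <- 0
  for (i in case) for (j in ctrl) {
    k <- k + 1
    ratios[, k] <- L[, i] - L[, j]
  }
  rp <- numeric(n)
  for (g in seq_len(n)) {
    prod_r <- 1
    for (cc in seq_len(k)) {
      v <- ratios[, cc]
      r <- if (what == "up") sum(v > v[g]) + (1 + sum(v == v[g])) / 2
           else sum(v < v[g]) + (1 + sum(v == v[g])) / 2
      prod_r <- prod_r * r
    }
    rp[g] <- prod_r^(1 / k)
  }
  rp
}

# all assignments of 1..n_samples into a case arm of size n_case
oracle_assignments <- function(n_samples, n_case) {
  combos <- utils::combn(n_samples, n_case)
  lapply(seq_len(ncol(combos)), function(i) combos[, i])
}

# pooled exhaustive permutation p-values, brute force; what = "up"/"down"
# uses the one-sided statistic, "two" the two-sided min(up, down)
oracle_perm_p <- function(L, n_case, what) {
  n <- nrow(L)
  stat <- function(case, ctrl) {
    if (what == "two")
      pmin(oracle_rp(L, case, ctrl, "up"), oracle_rp(L, case, ctrl, "down"))
    else oracle_rp(L, case, ctrl, what)
  }
  all_assign <- oracle_assignments(ncol(L), n_case)
  obs <- stat(seq_len(n_case), (n_case + 1):ncol(L))
  null <- c()
  for (a in all_assign)
    null <- c(null, stat(a, setdiff(seq_len(ncol(L)), a)))
  p <- numeric(n)
  for (g in seq_len(n))
    p[g] <- (sum(null <= obs[g]) + 1) / (n * length(all_assign) + 1)
  p
}

# a small driver/suppressor scenario used by refinement tests: the DE
# table carries pregnancy-side signs; the true prognostic template has
# the suppressors reversed.
planted_scenario <- function() {
  de <- data.frame(
    probe_id = sprintf("pr%02d", 1:7),
    gene_symbol = c("DRV1", "DRV2", "DRV3", "DRV4", "DRV5", "SUP1", "SUP2"),
    fold_change = c(3.2, 2.5, -2.8, -2.1, 1.9, 2.6, -2.4),
    p_value = rep(0.001, 7), pfp = rep(0.01, 7),
    direction = c("up", "up", "down", "down", "up", "up", "down"),
    stringsAsFactors = FALSE)
  class(de) <- c("de_table", "data.frame")
  full <- build_centroid(de)
  truth <- reverse_signs(full, c("SUP1", "SUP2"))
  list(de = de, full = full, truth = truth,
       suppressors = c("SUP1", "SUP2"))
}
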