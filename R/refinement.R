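#' Default cohort subgroups for per-gene screening
#'
#' A named list of predicates over the clinical table, in the spirit of
#' the standard breast-cancer subgroup panels: the full cohort, ER and LN
#' status, the ER-positive/LN-negative combination, histological grades
#' and the five intrinsic subtypes.  Users may supply any named list of
#' functions `clinical_table -> logical` instead.
#'
#' @return named list of predicate functions.
#' @export
default_subgroups <- function() {
  list(
    all       = function(ct) rep(TRUE, nrow(ct)),
    er_pos    = function(ct) ct$er == "pos",
    er_neg    = function(ct) ct$er == "neg",
    ln_pos    = function(ct) ct$ln == "pos",
    ln_neg    = function(ct) ct$ln == "neg",
    erpos_lnneg = function(ct) ct$er == "pos" & ct$ln == "neg",
    grade1    = function(ct) ct$grade == 1,
    grade2    = function(ct) ct$grade == 2,
    grade3    = function(ct) ct$grade == 3,
    lumA      = function(ct) ct$subtype == "lumA",
    lumB      = function(ct) ct$subtype == "lumB",
    her2      = function(ct) ct$subtype == "her2",
    basal     = function(ct) ct$subtype == "basal",
    normal    = function(ct) ct$subtype == "normal"
  )
}

#' Per-gene survival screen across cohort subgroups
#'
#' For each gene and each subgroup, patients in the subgroup are split at
#' the gene's median expression within that subgroup (two quantiles; ties
#' go to the low group) and the two halves are compared by the log-rank
#' test.  The half with the excess of observed over expected events is
#' recorded as the poor-prognosis side.  Subgroups with fewer than
#' `min_n` patients or `min_events` events are skipped; genes absent from
#' the cohort yield missing cells.
#'
#' @param cohort an [expr_matrix()] (genes x patients).
#' @param ct a [clinical_table()] covering the cohort samples.
#' @param genes gene symbols to screen.
#' @param subgroups named list of predicates (default [default_subgroups()]);
#'   predicates returning `NA` for a patient exclude that patient.
#' @param min_n,min_events minimum subgroup size / event count (20 and 5).
#' @return a `screen_matrix`: long-format data.frame with columns `gene`,
#'   `subgroup`, `raw_p`, `adj_p` (filled by [bh_adjust_screen()]),
#'   `direction` (`high-poor` / `low-poor`), `n`, `n_events`; skipped and
#'   missing cells carry `NA` p-values.
#' @export
per_gene_screen <- function(cohort, ct, genes,
                            subgroups = default_subgroups(),
                            min_n = 20, min_events = 5) {
  stopifnot(inherits(cohort, "expr_matrix"))
  cohort <- as_log2(cohort)
  m <- cohort$values[, match(ct$sample_id, colnames(cohort$values)),
                     drop = FALSE]
  if (anyNA(m[1, ])) stop("clinical samples missing from the cohort matrix")
  key <- .norm_symbol(rownames(m))

  rows <- list()
  for (sg in names(subgroups)) {
    sel <- subgroups[[sg]](ct)
    sel[is.na(sel)] <- FALSE
    n_sg <- sum(sel)
    ev_sg <- sum(ct$event[sel])
    usable <- n_sg >= min_n && ev_sg >= min_events
    if (!usable)
      message(sprintf("subgroup '%s' skipped (n=%d, events=%d)",
                      sg, n_sg, ev_sg))
    for (g in genes) {
      gi <- match(.norm_symbol(g), key)
      raw_p <- NA_real_
      dir <- NA_character_
      if (!is.na(gi) && usable) {
        x <- m[gi, sel]
        hi <- x > stats::median(x)       # ties to the low-expression group
        if (length(unique(hi)) == 2) {
          lr <- logrank(ct$time[sel], ct$event[sel],
                        ifelse(hi, "high", "low"))
          raw_p <- lr$p_value
          excess <- lr$observed - lr$expected
          dir <- if (excess[["high"]] > 0) "high-poor" else "low-poor"
        } else {
          raw_p <- 1                      # degenerate split: no information
        }
      } else if (is.na(gi)) {
        message("gene not found in cohort: ", g)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, subgroup = sg, raw_p = raw_p, adj_p = NA_real_,
        direction = dir, n = n_sg, n_events = ev_sg,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_matrix", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR-controlling step-up procedure with monotonicity
#' enforcement: `adj[i] = min_{j: p_j >= p_i} (n * p_j / rank_j)`, capped
#' at 1.  Applied jointly to whatever family of tests is passed in.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq(n, 1) * p_values[o]))[ro]
}

#' Fill the adjusted-p column of a screen matrix
#'
#' The BH family is the full set of computed gene-by-subgroup cells
#' (missing/skipped cells excluded), adjusted jointly — the family size
#' therefore depends on the subgroup panel actually screened.
#'
#' @param sm a `screen_matrix` from [per_gene_screen()].
#' @return the screen matrix with `adj_p` filled.
#' @export
bh_adjust_screen <- function(sm) {
  ok <- !is.na(sm$raw_p)
  sm$adj_p[ok] <- bh_adjust(sm$raw_p[ok])
  sm
}

#' Select signature genes from a screened matrix
#'
#' Keeps every gene whose BH-adjusted p-value falls below `alpha` in at
#' least one subgroup, tagged with its most significant subgroup.
#'
#' @param sm a `screen_matrix` with `adj_p` filled.
#' @param alpha significance threshold (strict: `adj_p < alpha`).
#' @return data.frame `gene`, `best_subgroup`, `best_adj_p`,
#'   `best_direction`; zero rows when nothing passes.
#' @export
select_signature <- function(sm, alpha = 0.05) {
  ok <- !is.na(sm$adj_p) & sm$adj_p < alpha
  hits <- sm[ok, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(gene = character(), best_subgroup = character(),
                      best_adj_p = numeric(), best_direction = character(),
                      stringsAsFactors = FALSE))
  hits <- hits[order(hits$adj_p, hits$raw_p), , drop = FALSE]
  best <- hits[!duplicated(hits$gene), , drop = FALSE]
  best <- best[order(match(best$gene, unique(sm$gene))), , drop = FALSE]
  data.frame(gene = best$gene, best_subgroup = best$subgroup,
             best_adj_p = best$adj_p, best_direction = best$direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify signature genes as drivers or suppressors
#'
#' A gene is concordant (driver-like) when its differential-expression
#' direction matches its prognostic direction — up-regulated with high
#' tumour expression being poor-prognosis, or down-regulated with low
#' expression poor — and discordant (suppressor-like) otherwise.  Genes
#' whose significant cells disagree on prognostic direction are flagged
#' ambiguous and left unclassified.
#'
#' @param de a `de_table` (one row per gene after centroid averaging is
#'   fine; the `direction` of the first matching row is used).
#' @param sm a `screen_matrix` with `adj_p` filled.
#' @param alpha threshold defining the significant cells considered.
#' @return data.frame `gene`, `de_direction`, `prognostic_direction`,
#'   `concordance` (`driver`/`suppressor`/`ambiguous`).
#' @export
classify_direction <- function(de, sm, alpha = 0.05) {
  sel <- select_signature(sm, alpha)
  if (nrow(sel) == 0)
    return(data.frame(gene = character(), de_direction = character(),
                      prognostic_direction = character(),
                      concordance = character(), stringsAsFactors = FALSE))
  de_dir <- vapply(sel$gene, function(g) {
    i <- match(.norm_symbol(g), .norm_symbol(de$gene_symbol))
    if (is.na(i)) NA_character_ else de$direction[i]
  }, character(1))
  if (anyNA(de_dir))
    stop("genes missing from the DE table: ",
         paste(sel$gene[is.na(de_dir)], collapse = ", "))

  conc <- character(nrow(sel))
  prog <- sel$best_direction
  for (i in seq_len(nrow(sel))) {
    g <- sel$gene[i]
    cells <- sm[!is.na(sm$adj_p) & sm$adj_p < alpha &
                  .norm_symbol(sm$gene) == .norm_symbol(g), , drop = FALSE]
    if (length(unique(cells$direction)) > 1) {
      conc[i] <- "ambiguous"
      prog[i] <- NA_character_
    } else {
      concordant <- (de_dir[i] == "up" & prog[i] == "high-poor") |
        (de_dir[i] == "down" & prog[i] == "low-poor")
      conc[i] <- if (concordant) "driver" else "suppressor"
    }
  }
  data.frame(gene = sel$gene, de_direction = unname(de_dir),
             prognostic_direction = prog, concordance = conc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the refined, reversed-sign compact centroid
#'
#' Restricts the full centroid to the classified signature genes and
#' negates the weights of suppressor-class genes, so that the centroid's
#' sign structure matches prognostic rather than developmental direction.
#' Ambiguous genes are excluded.
#'
#' @param cent the full [centroid()].
#' @param calls output of [classify_direction()].
#' @return a compact [centroid()] whose provenance records the reversals.
#' @export
build_refined_centroid <- function(cent, calls) {
  stopifnot(inherits(cent, "centroid"))
  calls <- calls[calls$concordance %in% c("driver", "suppressor"), ,
                 drop = FALSE]
  if (nrow(calls) == 0) stop("no unambiguous genes to build a centroid from")
  hit <- match(.norm_symbol(calls$gene), .norm_symbol(names(cent$weights)))
  if (anyNA(hit))
    stop("selected genes missing from centroid: ",
         paste(calls$gene[is.na(hit)], collapse = ", "))
  w <- cent$weights[hit]
  sub <- centroid(w, provenance = cent$provenance)
  reverse_signs(sub, calls$gene[calls$concordance == "suppressor"])
}

#' Write a screen matrix as long-format TSV
#' @param sm a `screen_matrix`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(sm, path) {
  utils::write.table(as.data.frame(sm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
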