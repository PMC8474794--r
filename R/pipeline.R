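#' Pipeline configuration
#'
#' Collects the file paths (or in-memory objects) and the constants that
#' drive the end-to-end workflow: differential expression -> matrisome
#' filter -> centroid -> stratification -> survival evaluation -> per-gene
#' screening -> refinement -> re-stratification.
#'
#' @param expr expression TSV path or [expr_matrix()] (two-arm design).
#' @param conditions condition TSV path (ignored when `expr` is an object
#'   carrying labels).
#' @param cohort cohort expression TSV path or [expr_matrix()].
#' @param clinical clinical TSV path or [clinical_table()].
#' @param gene_set gene-set TSV path or [gene_set()] (matrisome filter).
#' @param annotation optional probe -> gene TSV path or named vector.
#' @param orthologs optional ortholog override TSV path or
#'   [ortholog_map()].
#' @param out_dir output directory for the report bundle.
#' @param n_perm,seed permutation count and master seed.
#' @param alpha_de raw-p cut-off for the DE filter (default 0.05).
#' @param alpha_refine adjusted-p cut-off for signature selection
#'   (default 0.05).
#' @param cutoff_months administrative follow-up cut-off (default 120,
#'   the 10-year convention).
#' @param endpoint survival endpoint label (DMFS/RFS/PFS).
#' @param method stratification method: `"centroid"` (correlation, cut at
#'   0) or `"median-split"` (weighted composite score).
#' @param covariates Cox covariates (see [cox_fit()]).
#' @param subgroups named list of subgroup predicates.
#' @param cohort_scale `"log2"` (default) or `"linear"` for cohort TSVs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expr, conditions = NULL, cohort, clinical,
                            gene_set, annotation = NULL, orthologs = NULL,
                            out_dir, n_perm = 1000, seed = 1,
                            alpha_de = 0.05, alpha_refine = 0.05,
                            cutoff_months = 120, endpoint = "DMFS",
                            method = c("centroid", "median-split"),
                            covariates = c("er", "ln", "grade3", "age_gt50",
                                           "size_gt20mm"),
                            subgroups = default_subgroups(),
                            cohort_scale = "log2") {
  method <- match.arg(method)
  stopifnot(alpha_de > 0, alpha_de <= 1, alpha_refine >= 0, alpha_refine <= 1,
            cutoff_months > 0)
  structure(list(expr = expr, conditions = conditions, cohort = cohort,
                 clinical = clinical, gene_set = gene_set,
                 annotation = annotation, orthologs = orthologs,
                 out_dir = out_dir, n_perm = n_perm, seed = seed,
                 alpha_de = alpha_de, alpha_refine = alpha_refine,
                 cutoff_months = cutoff_months, endpoint = endpoint,
                 method = method, covariates = covariates,
                 subgroups = subgroups, cohort_scale = cohort_scale),
            class = "pipeline_config")
}

.load_expr <- function(x, scale = "linear", conditions = NULL) {
  if (inherits(x, "expr_matrix")) return(x)
  read_expr_tsv(x, scale = scale, condition_path = conditions)
}

.load_clinical <- function(x) {
  if (is.data.frame(x)) return(clinical_table(x))  # re-validate objects too
  read_clinical_tsv(x)
}

.load_gene_set <- function(x) {
  if (inherits(x, "gene_set")) return(x)
  read_gene_set_tsv(x)
}

.load_orthologs <- function(x) {
  if (is.null(x)) return(ortholog_map())
  if (inherits(x, "ortholog_map")) return(x)
  read_ortholog_tsv(x)
}

.load_annotation <- function(x) {
  if (is.null(x) || is.character(x) && !is.null(names(x))) return(x)
  df <- utils::read.delim(x, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

.summary_to_list <- function(s) {
  list(logrank_statistic = s$logrank$statistic,
       logrank_p = s$logrank$p_value,
       group_sizes = as.list(s$logrank$n),
       n_used = s$n_used, n_excluded = s$n_excluded,
       cox = s$cox)
}

#' Run the full signature pipeline
#'
#' Executes every stage on the configured inputs and writes the report
#' bundle (`de.tsv`, `de_filtered.tsv`, `centroid.tsv`,
#' `stratification.tsv`, `survival_full.json`, `screen.tsv`,
#' `refined_centroid.tsv`, `stratification_refined.tsv`,
#' `survival_refined.json`, `manifest.json`) into `cfg$out_dir`.  If the
#' refinement stage selects no gene the pipeline records that and stops
#' before re-stratification.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with all intermediate objects (`de`,
#'   `de_filtered`, `centroid`, `stratification`, `survival_full`,
#'   `screen`, `calls`, `refined_centroid`, `stratification_refined`,
#'   `survival_refined`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  expr <- stage("load", .load_expr(cfg$expr, "linear", cfg$conditions))
  cohort <- stage("load", .load_expr(cfg$cohort, cfg$cohort_scale))
  clin <- stage("load", .load_clinical(cfg$clinical))
  gs <- stage("load", .load_gene_set(cfg$gene_set))
  om <- stage("load", .load_orthologs(cfg$orthologs))
  ann <- stage("load", .load_annotation(cfg$annotation))

  de <- stage("de", rankprod_test(expr, n_perm = cfg$n_perm, seed = cfg$seed,
                                  annotation = ann))
  write_de_tsv(de, file.path(cfg$out_dir, "de.tsv"))

  de_f <- stage("filter", {
    sig <- de[de$p_value < cfg$alpha_de, , drop = FALSE]
    filter_by_gene_set(sig, gs)
  })
  write_de_tsv(de_f, file.path(cfg$out_dir, "de_filtered.tsv"))

  cent <- stage("centroid", {
    cen <- build_centroid(de_f)
    w <- cen$weights
    names(w) <- map_orthologs(names(w), om)
    centroid(w, provenance = c(cen$provenance, "symbols mapped to human"))
  })
  write_centroid_tsv(cent, file.path(cfg$out_dir, "centroid.tsv"))

  strat_fun <- if (cfg$method == "centroid") classify_by_centroid
               else composite_score
  strat <- stage("stratify", strat_fun(cohort, cent))
  write_stratification_tsv(strat, file.path(cfg$out_dir, "stratification.tsv"))

  clin_cut <- apply_followup_cutoff(clin, cfg$cutoff_months)
  surv_full <- stage("survive", cox_fit(clin_cut, strat, cfg$covariates))
  jsonlite::write_json(.summary_to_list(surv_full),
                       file.path(cfg$out_dir, "survival_full.json"),
                       auto_unbox = TRUE, digits = NA)

  sm <- stage("screen", {
    s <- per_gene_screen(cohort, clin_cut, names(cent$weights),
                         subgroups = cfg$subgroups)
    bh_adjust_screen(s)
  })
  write_screen_tsv(sm, file.path(cfg$out_dir, "screen.tsv"))

  de_h <- de_f
  de_h$gene_symbol <- map_orthologs(de_h$gene_symbol, om)
  calls <- stage("refine", classify_direction(de_h, sm, cfg$alpha_refine))

  result <- list(de = de, de_filtered = de_f, centroid = cent,
                 stratification = strat, survival_full = surv_full,
                 screen = sm, calls = calls,
                 refined_centroid = NULL, stratification_refined = NULL,
                 survival_refined = NULL)

  manifest <- list(
    package = "matrisig",
    version = as.character(utils::packageVersion("matrisig")),
    seed = cfg$seed, n_perm = cfg$n_perm, alpha_de = cfg$alpha_de,
    alpha_refine = cfg$alpha_refine, cutoff_months = cfg$cutoff_months,
    endpoint = cfg$endpoint, method = cfg$method,
    covariates = cfg$covariates,
    subgroups = names(cfg$subgroups),
    n_signature_genes = nrow(calls))

  if (nrow(calls[calls$concordance != "ambiguous", , drop = FALSE]) == 0) {
    manifest$stopped <- "refined signature empty; re-stratification skipped"
    message(manifest$stopped)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(result))
  }

  refined <- stage("refine", build_refined_centroid(cent, calls))
  write_centroid_tsv(refined, file.path(cfg$out_dir, "refined_centroid.tsv"))

  strat_r <- stage("restratify", strat_fun(cohort, refined))
  write_stratification_tsv(strat_r,
                           file.path(cfg$out_dir, "stratification_refined.tsv"))
  surv_r <- stage("survive", cox_fit(clin_cut, strat_r, cfg$covariates))
  jsonlite::write_json(.summary_to_list(surv_r),
                       file.path(cfg$out_dir, "survival_refined.json"),
                       auto_unbox = TRUE, digits = NA)

  result$refined_centroid <- refined
  result$stratification_refined <- strat_r
  result$survival_refined <- surv_r
  manifest$reversed_genes <- calls$gene[calls$concordance == "suppressor"]
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
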