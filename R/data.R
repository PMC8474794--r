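#' Shipped 18-gene pregnancy-associated-fibroblast signature
#'
#' The compact matrisome signature distributed with the package: 18 human
#' gene symbols with signed fold-change weights taken from the
#' pregnancy-day-3 versus virgin fibroblast comparison (probe averages
#' where a gene had several probes).  Eleven genes are concordant
#' ("driver"-like: developmental and prognostic direction agree); seven
#' are discordant ("suppressor"-like) and have their weights negated in
#' the refined form used for stratification.
#'
#' @param refined if `TRUE` (default) return the reversed-sign form used
#'   for prognostic stratification; if `FALSE`, the raw
#'   differential-expression weights.
#' @return a [centroid()] of 18 genes.
#' @export
paf18_signature <- function(refined = TRUE) {
  path <- system.file("extdata", "paf18_signature.tsv", package = "matrisig",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cen <- centroid(stats::setNames(df$weight, df$gene_symbol),
                  provenance = "shipped 18-gene PAF matrisome signature")
  if (refined) reverse_signs(cen, df$gene_symbol[df$class == "suppressor"])
  else cen
}

#' Shipped mouse matrisome gene-set excerpt
#'
#' A 64-symbol excerpt of the mouse matrisome (core and affiliated genes)
#' sufficient for the examples and tests; substitute the full published
#' matrisome master list for real analyses via [read_gene_set_tsv()].
#'
#' @return a [gene_set()].
#' @export
matrisome_genes <- function() {
  read_gene_set_tsv(
    system.file("extdata", "matrisome_mouse_subset.tsv", package = "matrisig",
                mustWork = TRUE),
    name = "mouse matrisome (excerpt)")
}

#' Shipped default mouse-to-human ortholog overrides
#'
#' Covers the renamed/dual-name symbols that the uppercase rule cannot
#' map (e.g. Figf -> VEGFD).
#'
#' @return an [ortholog_map()].
#' @export
default_orthologs <- function() {
  read_ortholog_tsv(
    system.file("extdata", "orthologs_default.tsv", package = "matrisig",
                mustWork = TRUE))
}
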