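#' Gene sets and ortholog maps
#'
#' Gene-set membership (e.g. the matrisome: core ECM, ECM-modifying
#' enzymes, growth factors, matricellular proteins) is handled as a plain
#' set of symbols with an optional per-symbol category.  Symbols are
#' compared case-insensitively after stripping whitespace; no fuzzy
#' matching is attempted.
#'
#' @param symbols character vector of gene symbols.
#' @param category optional character vector parallel to `symbols`
#'   (e.g. "core matrisome" / "matrisome-affiliated").
#' @param name label for the set.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(symbols, category = NULL, name = "gene_set") {
  key <- .norm_symbol(symbols)
  keep <- !duplicated(key)
  structure(list(name = name,
                 symbols = symbols[keep],
                 key = key[keep],
                 category = if (is.null(category)) NULL else category[keep]),
            class = "gene_set")
}

.norm_symbol <- function(x) toupper(trimws(as.character(x)))

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Read a gene set from a two-column TSV (symbol, category)
#'
#' @param path TSV path; the category column is optional.
#' @param name label for the set (defaults to the file name).
#' @return a [gene_set()].
#' @export
read_gene_set_tsv <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_set(df[[1]],
           category = if (ncol(df) >= 2) df[[2]] else NULL,
           name = name)
}

#' Filter a DE table by gene-set membership
#'
#' Retains exactly the probes whose (case-normalized) gene symbol belongs
#' to the set.  Probe multiplicity is preserved: several probes for one
#' gene all survive, so probe and gene counts may differ downstream.
#'
#' @param de a `de_table` with `gene_symbol` populated.
#' @param gs a [gene_set()].
#' @return the filtered `de_table` (possibly empty).
#' @export
filter_by_gene_set <- function(de, gs) {
  stopifnot(inherits(gs, "gene_set"))
  if (is.null(de$gene_symbol)) stop("DE table has no gene_symbol column")
  out <- de[.norm_symbol(de$gene_symbol) %in% gs$key, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Ortholog map: mouse symbols to human symbols
#'
#' The default rule is uppercasing (Wisp2 -> WISP2), which covers the bulk
#' of one-to-one mouse/human orthologs; explicit override entries win over
#' the rule (e.g. renamed genes such as Figf -> VEGFD).
#'
#' @param mouse,human parallel character vectors of override entries;
#'   conflicting entries for the same mouse symbol are an error.
#' @param default_rule apply the uppercase rule to unmapped symbols.
#' @return an object of class `ortholog_map`.
#' @export
ortholog_map <- function(mouse = character(), human = character(),
                         default_rule = TRUE) {
  stopifnot(length(mouse) == length(human))
  key <- .norm_symbol(mouse)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(unique(dup), function(k)
      length(unique(human[key == k])) > 1, logical(1))
    if (any(conflict))
      stop("conflicting ortholog overrides for: ",
           paste(unique(dup)[conflict], collapse = ", "))
    keep <- !duplicated(key)
    mouse <- mouse[keep]; human <- human[keep]; key <- key[keep]
  }
  structure(list(mouse = mouse, human = human, key = key,
                 default_rule = default_rule),
            class = "ortholog_map")
}

#' Read an ortholog override map from a two-column TSV (mouse, human)
#'
#' @param path TSV path.
#' @param default_rule apply the uppercase rule to unmapped symbols.
#' @return an [ortholog_map()].
#' @export
read_ortholog_tsv <- function(path, default_rule = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ortholog_map(df[[1]], df[[2]], default_rule = default_rule)
}

#' Map mouse gene symbols to human symbols
#'
#' Override entries take precedence; remaining symbols fall back to the
#' uppercase rule when enabled.  With the rule disabled, symbols without
#' an override map to `NA` and are reported in the `unmapped` attribute.
#'
#' @param symbols character vector of mouse symbols.
#' @param om an [ortholog_map()]; default has no overrides.
#' @return character vector of human symbols, with attribute `unmapped`
#'   listing symbols that could not be mapped.
#' @export
map_orthologs <- function(symbols, om = ortholog_map()) {
  stopifnot(inherits(om, "ortholog_map"))
  key <- .norm_symbol(symbols)
  hit <- match(key, om$key)
  out <- om$human[hit]
  if (om$default_rule) out[is.na(hit)] <- key[is.na(hit)]
  attr(out, "unmapped") <- unique(symbols[is.na(out)])
  out
}
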