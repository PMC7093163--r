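#' Construct an expression panel
#'
#' An expression panel is a genes-by-cell-types matrix of non-negative
#' expression values (fpkm) tagged with the gene-identifier namespace it is
#' expressed in (for the reference mouse cortex panel, `"mouse_symbol"`;
#' after ortholog mapping, `"human_ensembl"`).
#'
#' Duplicate gene identifiers are resolved by per-column arithmetic mean,
#' with a warning: averaging is unbiased and independent of row order.
#'
#' @param values numeric matrix, one row per gene (rownames = gene ids), one
#'   column per cell type (colnames = unique cell-type labels). At least two
#'   cell types are required and all values must be finite and non-negative.
#' @param namespace character tag of the gene-identifier system.
#' @return An object of class `"expression_panel"`: a list with elements
#'   `values` (the matrix) and `namespace`.
#' @export
expression_panel <- function(values, namespace = "mouse_symbol") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_eshrd("eshrd_structure_error", "panel values must be a numeric matrix")
  if (ncol(values) < 2L)
    stop_eshrd("eshrd_structure_error",
               "panel needs at least 2 cell-type columns, got %d", ncol(values))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop_eshrd("eshrd_structure_error", "cell-type labels must be unique and named")
  if (is.null(rownames(values)))
    stop_eshrd("eshrd_structure_error", "gene ids (rownames) are required")
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_eshrd("eshrd_value_error",
               "negative or non-numeric expression value at gene '%s', cell type '%s'",
               rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]])
  if (anyDuplicated(rownames(values))) {
    ids <- rownames(values)
    ndup <- sum(duplicated(ids))
    warning(sprintf("%d duplicate gene row(s) collapsed by per-column mean", ndup))
    values <- rowsum(values, group = ids, reorder = FALSE) /
      as.vector(table(ids)[unique(ids)])
  }
  structure(list(values = values, namespace = namespace),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("Expression panel: %d genes x %d cell types (%s)\n",
              nrow(x$values), ncol(x$values), x$namespace))
  cat("Cell types:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Read an expression panel from TSV
#'
#' Expects a header row `gene_id<TAB><cell1><TAB>...` followed by one row per
#' gene with decimal-point floats. Duplicate gene rows are averaged (with a
#' warning); negative or non-numeric values are rejected naming the offending
#' row and column.
#'
#' @param path path to the tab-separated panel file.
#' @param namespace gene-identifier namespace tag of the panel.
#' @return An [expression_panel].
#' @export
read_expression_panel <- function(path, namespace = "mouse_symbol") {
  if (!file.exists(path))
    stop_eshrd("eshrd_format_error", "panel file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop_eshrd("eshrd_structure_error",
               "panel needs a gene-id column plus >= 2 cell-type columns")
  ids <- as.character(df[[1L]])
  num <- df[-1L]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]) | is.na(num[[j]]))
    if (length(bad) > 0L)
      stop_eshrd("eshrd_value_error",
                 "non-numeric expression value at row %d (gene '%s'), column '%s'",
                 bad[1L], ids[bad[1L]], names(num)[j])
    num[[j]] <- v
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop_eshrd("eshrd_value_error",
               "negative expression value at row %d (gene '%s'), column '%s'",
               neg[1L, 1L], ids[neg[1L, 1L]], colnames(values)[neg[1L, 2L]])
  panel <- expression_panel(values, namespace = namespace)
  eshrd_log("read panel: %d genes, %d cell types from %s",
            nrow(panel$values), ncol(panel$values), path)
  panel
}

#' Remove genes at or below the expression floor
#'
#' The reference panel reports a detection floor (0.1 fpkm); a gene whose
#' value in every cell type sits at or below that floor carries no
#' cell-specificity information and would only contribute false-positive
#' noise, so it is removed. Retained genes have at least one value strictly
#' above the floor, guaranteeing a positive maximal enrichment score
#' downstream.
#'
#' @param panel an [expression_panel].
#' @param floor expression floor (fpkm); must be positive.
#' @return The filtered panel, with attributes `n_removed` and `n_retained`.
#' @export
filter_low_expression <- function(panel, floor = 0.1) {
  stopifnot(inherits(panel, "expression_panel"), floor > 0)
  keep <- apply(panel$values > floor, 1L, any)
  n_removed <- sum(!keep)
  n_retained <- sum(keep)
  if (n_retained == 0L)
    stop_eshrd("eshrd_value_error",
               "all %d genes removed at floor %g: wrong units or wrong floor?",
               nrow(panel$values), floor)
  eshrd_log("floor filter at %g fpkm: %d removed, %d retained",
            floor, n_removed, n_retained)
  out <- expression_panel(panel$values[keep, , drop = FALSE],
                          namespace = panel$namespace)
  attr(out, "n_removed") <- n_removed
  attr(out, "n_retained") <- n_retained
  out
}

#' Read an ortholog map from TSV
#'
#' Expects a header `source_id<TAB>target_id`. Exact duplicate pairs are
#' dropped silently; empty identifiers are rejected.
#'
#' @param path path to the two-column tab-separated mapping file.
#' @return data.frame with columns `source_id`, `target_id`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% names(df)))
    stop_eshrd("eshrd_format_error",
               "ortholog map must have columns 'source_id' and 'target_id'")
  ortholog_map(df$source_id, df$target_id)
}

#' Construct an ortholog map
#'
#' @param source_id character vector of source-namespace gene ids.
#' @param target_id character vector of target-namespace gene ids.
#' @return data.frame with columns `source_id`, `target_id`, exact duplicate
#'   pairs removed.
#' @export
ortholog_map <- function(source_id, target_id) {
  source_id <- as.character(source_id)
  target_id <- as.character(target_id)
  stopifnot(length(source_id) == length(target_id))
  if (any(!nzchar(source_id)) || any(!nzchar(target_id)) ||
      anyNA(source_id) || anyNA(target_id))
    stop_eshrd("eshrd_value_error", "ortholog map ids must be non-empty strings")
  df <- unique(data.frame(source_id = source_id, target_id = target_id,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Map a panel across species via an ortholog table
#'
#' Translates panel gene identifiers into the target namespace. The mapping
#' policy, applied to the map restricted to genes present in the panel:
#' \itemize{
#'   \item unmapped source genes are dropped (counted);
#'   \item ambiguous many-to-many entries (a source with several targets, at
#'     least one of which is also hit by another source) are dropped entirely
#'     -- the ambiguity cannot be resolved without external evidence;
#'   \item one-to-many sources are duplicated under each target id;
#'   \item many-to-one collisions (several sources, one target) are resolved
#'     by per-column arithmetic mean.
#' }
#'
#' @param panel an [expression_panel] in the map's source namespace.
#' @param omap data.frame from [ortholog_map] / [read_ortholog_map].
#' @param target_namespace namespace tag for the returned panel.
#' @return An [expression_panel] keyed by target ids, with attribute
#'   `mapping_counts` (named integer vector).
#' @export
map_orthologs <- function(panel, omap, target_namespace = "human_ensembl") {
  stopifnot(inherits(panel, "expression_panel"),
            all(c("source_id", "target_id") %in% names(omap)))
  ids <- rownames(panel$values)
  pairs <- omap[omap$source_id %in% ids, , drop = FALSE]
  n_unmapped <- sum(!(ids %in% pairs$source_id))
  if (nrow(pairs) == 0L)
    stop_eshrd("eshrd_value_error",
               "no panel gene maps: likely namespace mismatch (panel is '%s')",
               panel$namespace)
  tgt_per_src <- table(pairs$source_id)
  src_per_tgt <- table(pairs$target_id)
  multi_target <- names(tgt_per_src)[tgt_per_src > 1L]
  ambiguous <- vapply(multi_target, function(s) {
    any(src_per_tgt[pairs$target_id[pairs$source_id == s]] > 1L)
  }, logical(1L))
  drop_src <- multi_target[ambiguous]
  pairs <- pairs[!(pairs$source_id %in% drop_src), , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop_eshrd("eshrd_value_error", "all mapped genes were ambiguous many-to-many")
  expanded <- panel$values[pairs$source_id, , drop = FALSE]
  counts <- as.vector(table(pairs$target_id)[unique(pairs$target_id)])
  values <- rowsum(expanded, group = pairs$target_id, reorder = FALSE) / counts
  n_multi <- sum(table(pairs$target_id) > 1L)
  eshrd_log(paste0("ortholog mapping: %d source genes -> %d target ids ",
                   "(%d unmapped, %d ambiguous dropped, %d many-to-one merged)"),
            length(unique(pairs$source_id)), nrow(values), n_unmapped,
            length(drop_src), n_multi)
  out <- expression_panel(values, namespace = target_namespace)
  attr(out, "mapping_counts") <- c(
    n_source = length(ids), n_mapped = length(unique(pairs$source_id)),
    n_unmapped = n_unmapped, n_ambiguous_dropped = length(drop_src),
    n_targets = nrow(values))
  out
}

#' Write an expression panel to TSV
#'
#' @param panel an [expression_panel].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_panel <- function(panel, path) {
  df <- data.frame(gene_id = rownames(panel$values), panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_eshrd_tsv(df, path)
}
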