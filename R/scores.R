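#' Per-cell-type enrichment scores
#'
#' For gene \eqn{g} and cell type \eqn{c}, the enrichment score is the fpkm
#' in that cell type divided by the mean fpkm over all other cell types:
#' \deqn{ES_c(g) = x_c(g) / \mathrm{mean}_{c' \ne c}\, x_{c'}(g).}
#' Before scoring, every value below `floor` is raised to `floor` so that all
#' denominators are strictly positive (the panel's detection floor is the
#' natural lower bound for a "measured" value). ES is a ratio, so it is
#' invariant to rescaling a gene's whole row.
#'
#' @param panel an [expression_panel], already floor-filtered so that every
#'   gene has at least one value above `floor`.
#' @param floor detection floor used to clamp values before scoring.
#' @return A list of class `"enrichment_profiles"` with elements `es`
#'   (genes x cell types matrix) and `es_high` (named vector of row maxima).
#' @export
compute_enrichment_scores <- function(panel, floor = 0.1) {
  stopifnot(inherits(panel, "expression_panel"), floor > 0)
  x <- pmax(panel$values, floor)
  if (any(x <= 0))
    stop_eshrd("eshrd_internal_error", "non-positive value survived flooring")
  k <- ncol(x)
  other_mean <- (rowSums(x) - x) / (k - 1L)
  es <- x / other_mean
  structure(list(es = es, es_high = apply(es, 1L, max)),
            class = "enrichment_profiles")
}

#' @export
print.enrichment_profiles <- function(x, ...) {
  cat(sprintf("Enrichment profiles: %d genes x %d cell types\n",
              nrow(x$es), ncol(x$es)))
  invisible(x)
}

#' Classify one enrichment-score profile
#'
#' With \eqn{ES_{high}} the maximal score of the gene, cell types split into
#' a high set \eqn{H = \{c : ES_c \ge \alpha_{high} ES_{high}\}} and a low
#' set \eqn{L = \{c : ES_c \le \alpha_{low} ES_{high}\}}. When every cell
#' type falls in \eqn{H \cup L} the gene is cell-specific (\eqn{|H| = 1}) or
#' multiple-cell-specific (\eqn{|H| > 1}), labelled by the high set; any
#' score strictly inside the open interval makes the gene `"mixed"` --
#' boundaries belong to the high/low sets so the three classes partition.
#' A gene whose high set is the full cell-type set (e.g. perfectly uniform
#' expression) is also labelled `"mixed"`: expressed-everywhere is the
#' operational meaning of mixed. The result is deterministic and independent
#' of cell-type ordering.
#'
#' @param es named numeric vector of enrichment scores, one per cell type.
#' @param alpha_low,alpha_high fractions of `es_high` bounding the low and
#'   high sets; `0 < alpha_low < alpha_high <= 1`.
#' @param cell_order canonical cell-type order used to serialize multi-cell
#'   labels (defaults to the order of `es`).
#' @return A single label string: `"mixed"` or a slash-joined non-empty set
#'   of cell types (e.g. `"MO/NFO"`).
#' @export
classify_gene <- function(es, alpha_low = 0.25, alpha_high = 0.75,
                          cell_order = names(es)) {
  stopifnot(alpha_low > 0, alpha_low < alpha_high, alpha_high <= 1,
            !is.null(names(es)))
  es_high <- max(es)
  if (es_high <= 0)
    stop_eshrd("eshrd_value_error", "es_high must be positive")
  high <- es >= alpha_high * es_high
  low <- es <= alpha_low * es_high
  if (any(!high & !low) || all(high)) return("mixed")
  join_label(names(es)[high], cell_order)
}

#' Classify every gene of an enrichment-profile set
#'
#' Vectorized form of [classify_gene] over a profile matrix.
#'
#' @param profiles an `"enrichment_profiles"` object (or a bare ES matrix
#'   with column names).
#' @inheritParams classify_gene
#' @return Named character vector of labels, one per gene.
#' @export
classify_genes <- function(profiles, alpha_low = 0.25, alpha_high = 0.75) {
  es <- if (inherits(profiles, "enrichment_profiles")) profiles$es else profiles
  stopifnot(is.matrix(es), !is.null(colnames(es)),
            alpha_low > 0, alpha_low < alpha_high, alpha_high <= 1)
  es_high <- apply(es, 1L, max)
  high <- es >= alpha_high * es_high
  low <- es <= alpha_low * es_high
  mixed <- rowSums(!high & !low) > 0L | rowSums(high) == ncol(es)
  cells <- colnames(es)
  labels <- vapply(seq_len(nrow(es)), function(i) {
    if (mixed[i]) "mixed" else paste(cells[high[i, ]], collapse = "/")
  }, character(1L))
  names(labels) <- rownames(es)
  labels
}

#' Collapse oligodendrocyte sub-types into a pan-oligodendrocyte class
#'
#' The reference panel resolves three oligodendrocyte sub-types (myelinating
#' MO, newly formed NFO, precursor OPC). For lineage-level analyses these,
#' and their pairwise combinations, are combined into a single class `"O"`:
#' a label that is a non-empty subset of the sub-types collapses to `"O"`;
#' sub-types inside a set that also contains other cells are collectively
#' renamed `"O"` within the set (e.g. `"OPC/M"` becomes `"M/O"` in canonical
#' order); `"mixed"` and non-oligodendrocyte labels are unchanged.
#'
#' @param labels character vector of labels from [classify_genes].
#' @param cell_order canonical cell-type order of the panel.
#' @param oligo_subtypes cell types forming the pan-oligodendrocyte class.
#' @return Character vector of collapsed labels, serialized in the collapsed
#'   canonical order (sub-types replaced, in place, by `"O"`).
#' @export
collapse_oligo <- function(labels, cell_order,
                           oligo_subtypes = c("MO", "NFO", "OPC")) {
  known <- c(cell_order, "mixed")
  collapsed_order <- unique(replace(cell_order, cell_order %in% oligo_subtypes, "O"))
  vapply(labels, function(lab) {
    if (lab == "mixed") return("mixed")
    cells <- split_label(lab)
    if (!all(cells %in% known))
      stop_eshrd("eshrd_value_error", "unknown cell-type label in '%s'", lab)
    cells <- unique(replace(cells, cells %in% oligo_subtypes, "O"))
    join_label(cells, collapsed_order)
  }, character(1L), USE.NAMES = !is.null(names(labels)))
}
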