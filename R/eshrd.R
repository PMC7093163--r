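#' Build a cell-type specificity classification from a reference panel
#'
#' The main fitting function. Starting from a cell-sorted reference
#' expression panel (genes x cell types, fpkm), it (1) removes genes at or
#' below the detection floor in every cell type, (2) optionally maps gene
#' identifiers into a target namespace through an ortholog table,
#' (3) computes per-cell-type enrichment scores, (4) classifies every gene
#' as cell-specific, multiple-cell-specific or mixed, and (5) derives the
#' pan-oligodendrocyte collapsed view of each label.
#'
#' The returned object is the classifier: apply it to bulk
#' differential-expression results with [predict.eshrd] to obtain
#' cell-type-annotated DEGs.
#'
#' @param panel an [expression_panel], or a path to a panel TSV.
#' @param ortholog_map optional data.frame from [ortholog_map] /
#'   [read_ortholog_map] (or a path); when supplied, identifiers are mapped
#'   after floor filtering.
#' @param floor detection floor in fpkm; genes at or below it everywhere are
#'   removed and surviving sub-floor values are clamped to it before scoring.
#' @param alpha_low,alpha_high classification thresholds as fractions of a
#'   gene's maximal enrichment score; defaults 0.25 and 0.75.
#' @param oligo_subtypes cell-type labels collapsed into the
#'   pan-oligodendrocyte class when present in the panel.
#' @param namespace namespace tag used when `panel` is a path.
#' @param target_namespace namespace tag after ortholog mapping.
#' @return An object of class `"eshrd"`: a list with the filtered (and
#'   mapped) `panel`, the enrichment-score `profiles`, the `classification`
#'   data.frame (`gene_id`, `label`, `collapsed_label`), the parameters used,
#'   bookkeeping `counts`, and provenance (`panel_hash`).
#' @examples
#' sc <- panel_scenario(n_genes = 300, noise_cv = 0, seed = 1)
#' sim <- generate_panel(sc)
#' fit <- eshrd(sim$panel)
#' summary(fit)
#' @export
eshrd <- function(panel, ortholog_map = NULL, floor = 0.1,
                  alpha_low = 0.25, alpha_high = 0.75,
                  oligo_subtypes = c("MO", "NFO", "OPC"),
                  namespace = "mouse_symbol",
                  target_namespace = "human_ensembl") {
  cl <- match.call()
  stopifnot(floor > 0, alpha_low > 0, alpha_low < alpha_high, alpha_high <= 1)
  if (is.character(panel)) panel <- read_expression_panel(panel, namespace)
  stopifnot(inherits(panel, "expression_panel"))
  if (nrow(panel$values) == 0L)
    stop_eshrd("eshrd_value_error", "empty panel")
  n_input <- nrow(panel$values)

  panel <- filter_low_expression(panel, floor = floor)
  counts <- c(n_input = n_input,
              n_removed_floor = attr(panel, "n_removed"),
              n_retained = attr(panel, "n_retained"))
  if (!is.null(ortholog_map)) {
    if (is.character(ortholog_map)) ortholog_map <- read_ortholog_map(ortholog_map)
    panel <- map_orthologs(panel, ortholog_map, target_namespace)
    counts <- c(counts, attr(panel, "mapping_counts"))
  }

  profiles <- compute_enrichment_scores(panel, floor = floor)
  labels <- classify_genes(profiles, alpha_low = alpha_low,
                           alpha_high = alpha_high)
  cell_types <- colnames(panel$values)
  collapsed <- collapse_oligo(labels, cell_types, oligo_subtypes)
  classification <- data.frame(gene_id = rownames(panel$values),
                               label = unname(labels),
                               collapsed_label = unname(collapsed),
                               stringsAsFactors = FALSE)
  structure(list(
    call = cl,
    panel = panel,
    profiles = profiles,
    classification = classification,
    cell_types = cell_types,
    oligo_subtypes = intersect(oligo_subtypes, cell_types),
    params = list(floor = floor, alpha_low = alpha_low,
                  alpha_high = alpha_high),
    counts = counts,
    panel_hash = panel_hash(panel)
  ), class = "eshrd")
}

# Provenance hash of the panel actually classified (values + ids + order).
#' @noRd
panel_hash <- function(panel) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(rownames(panel$values), colnames(panel$values),
               signif(panel$values, 10)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.eshrd <- function(x, ...) {
  cat("Cell-type specificity classification (enrichment-score based)\n\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat(sprintf("Panel: %d genes x %d cell types (%s)\n",
              nrow(x$panel$values), length(x$cell_types), x$panel$namespace))
  cat(sprintf("Thresholds: floor = %g fpkm, alpha_low = %g, alpha_high = %g\n",
              x$params$floor, x$params$alpha_low, x$params$alpha_high))
  tab <- sort(table(x$classification$collapsed_label), decreasing = TRUE)
  cat(sprintf("Classes (collapsed): %d; most prevalent: %s (%.1f%%)\n",
              length(tab), names(tab)[1L],
              100 * tab[[1L]] / nrow(x$classification)))
  invisible(x)
}

#' Class-proportion summary of a fitted classification
#'
#' @param object an `"eshrd"` object.
#' @param collapsed summarize the pan-oligodendrocyte collapsed labels
#'   (default) or the raw labels.
#' @param ... unused.
#' @return A `"summary.eshrd"` object: data.frame of per-class gene counts
#'   and percentages (summing to 100), plus the bookkeeping counts.
#' @export
summary.eshrd <- function(object, collapsed = TRUE, ...) {
  lab <- if (collapsed) object$classification$collapsed_label
         else object$classification$label
  tab <- sort(table(lab), decreasing = TRUE)
  df <- data.frame(class = names(tab), n = as.integer(tab),
                   pct = 100 * as.integer(tab) / length(lab),
                   stringsAsFactors = FALSE)
  structure(list(classes = df, counts = object$counts,
                 params = object$params, n_genes = length(lab)),
            class = "summary.eshrd")
}

#' @export
print.summary.eshrd <- function(x, ...) {
  cat(sprintf("Classification of %d genes", x$n_genes))
  if ("n_removed_floor" %in% names(x$counts))
    cat(sprintf(" (%d of %d input genes removed at floor %g)",
                x$counts[["n_removed_floor"]], x$counts[["n_input"]],
                x$params$floor))
  cat("\n\n")
  df <- x$classes
  df$pct <- sprintf("%.1f", df$pct)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Enrichment-score matrix of a fitted classification
#'
#' @param object an `"eshrd"` object.
#' @param ... unused.
#' @return The genes x cell-types matrix of enrichment scores.
#' @export
coef.eshrd <- function(object, ...) object$profiles$es

#' @export
as.data.frame.eshrd <- function(x, ...) x$classification

#' Barplot of collapsed class proportions
#'
#' @param x an `"eshrd"` object.
#' @param max_classes plot at most this many classes (most prevalent first).
#' @param ... passed to [graphics::barplot].
#' @export
plot.eshrd <- function(x, max_classes = 10, ...) {
  tab <- sort(table(x$classification$collapsed_label), decreasing = TRUE)
  tab <- 100 * tab / sum(tab)
  tab <- tab[seq_len(min(length(tab), max_classes))]
  graphics::barplot(tab, ylab = "% of classified genes",
                    xlab = "cell class", las = 2, ...)
  invisible(x)
}

#' Annotate differential-expression results with cell classes
#'
#' Applies a fitted classification to a bulk differential-expression table:
#' selects DEGs at the FDR threshold (strict `<`), attaches each gene's
#' label and collapsed label, and marks genes absent from the classification
#' table as `"unclassified"`.
#'
#' @param object an `"eshrd"` object.
#' @param newdata data.frame of DE results with columns `gene_id`, `log2fc`,
#'   `pvalue`, `fdr` (e.g. from [read_de_table]), or a path to such a TSV.
#' @param fdr_threshold DEG selection threshold; records with
#'   `fdr < fdr_threshold` are kept. Use `Inf` to keep everything.
#' @param dataset optional dataset/region tag attached to the output.
#' @param type `"annotate"` returns the annotated DEG table; `"summary"`
#'   additionally reduces it with [summarize_classes].
#' @param ... unused.
#' @return The annotated DEG data.frame, or its per-class summary.
#' @export
predict.eshrd <- function(object, newdata, fdr_threshold = 0.05,
                          dataset = NULL, type = c("annotate", "summary"),
                          ...) {
  type <- match.arg(type)
  if (is.character(newdata)) newdata <- read_de_table(newdata, dataset = dataset)
  degs <- if (is.finite(fdr_threshold))
    filter_degs(newdata, fdr_threshold = fdr_threshold) else newdata
  ann <- annotate_degs(degs, object, dataset = dataset)
  if (type == "summary") summarize_classes(ann) else ann
}

#' Simulate differential-expression tables from a fitted classification
#'
#' Uses the fitted labels as ground truth for the synthetic DE generator:
#' each simulated table plants DEGs with per-class direction probabilities
#' and effect sizes over the classified gene universe (see
#' [generate_de_table]).
#'
#' @param object an `"eshrd"` object.
#' @param nsim number of DE tables to simulate.
#' @param seed master seed; table `i` uses a deterministic sub-seed.
#' @param ... scenario overrides passed to [de_scenario] (e.g. `n_degs`,
#'   `up_probability`, `class_weights`).
#' @return A list of `nsim` DE data.frames with truth columns.
#' @export
simulate.eshrd <- function(object, nsim = 1, seed = 1, ...) {
  lapply(seq_len(nsim), function(i) {
    sc <- de_scenario(classification = object$classification,
                      seed = derive_seed(seed, paste0("sim", i)),
                      dataset = paste0("SIM", i), ...)
    generate_de_table(sc)
  })
}

#' Write a classification table to TSV
#'
#' Columns `gene_id`, `label`, `collapsed_label`; multi-cell sets are
#' slash-joined in the panel's canonical cell order, mixed spelled `mixed`.
#'
#' @param object an `"eshrd"` object or a classification data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(object, path) {
  df <- if (inherits(object, "eshrd")) object$classification else object
  write_eshrd_tsv(df, path)
}

#' Read a classification table written by [write_classification]
#'
#' @param path path to the TSV.
#' @return data.frame with columns `gene_id`, `label`, `collapsed_label`.
#' @export
read_classification <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "label", "collapsed_label")
  if (!all(need %in% names(df)))
    stop_eshrd("eshrd_format_error",
               "classification table must have columns %s",
               paste(need, collapse = ", "))
  df
}
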