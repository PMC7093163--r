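#' Sign concordance of two paired log2 fold-change vectors
#'
#' Percentage of gene pairs whose fold changes agree in sign. Pairs where
#' either value is exactly zero have no defined sign and are excluded from
#' the denominator.
#'
#' @param lfc_a,lfc_b numeric vectors of equal length, paired by gene.
#' @return Concordance percentage in \[0, 100\], or `NA` when no pair has a
#'   defined sign.
#' @export
sign_concordance <- function(lfc_a, lfc_b) {
  if (length(lfc_a) != length(lfc_b))
    stop_eshrd("eshrd_value_error", "log2FC vectors differ in length (%d vs %d)",
               length(lfc_a), length(lfc_b))
  keep <- lfc_a != 0 & lfc_b != 0
  if (!any(keep)) return(NA_real_)
  100 * mean(sign(lfc_a[keep]) == sign(lfc_b[keep]))
}

#' Spearman rank correlation with two-sided p-value
#'
#' Average ranks for ties; p-value from the t approximation (two-sided).
#' A constant vector has no defined rank correlation and returns `NA`.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return list with elements `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L)
    stop_eshrd("eshrd_value_error", "need at least 3 pairs, got %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' @noRd
concordance_class_genes <- function(classification, cell_class) {
  cls <- if (inherits(classification, "eshrd")) classification$classification
         else classification
  genes <- cls$gene_id[cls$collapsed_label == cell_class]
  if (length(genes) == 0L)
    stop_eshrd("eshrd_value_error",
               "class '%s' absent from the classification", cell_class)
  genes
}

#' @noRd
concordance_point <- function(de_a, de_b, genes) {
  overlap <- intersect(intersect(de_a$gene_id, de_b$gene_id), genes)
  n <- length(overlap)
  if (n == 0L)
    return(list(n_overlap = 0L, concordance_pct = NA_real_,
                rho = NA_real_, rho_p = NA_real_))
  a <- de_a$log2fc[match(overlap, de_a$gene_id)]
  b <- de_b$log2fc[match(overlap, de_b$gene_id)]
  sp <- if (n >= 3L) spearman_rho(a, b) else list(rho = NA_real_, p = NA_real_)
  list(n_overlap = n, concordance_pct = sign_concordance(a, b),
       rho = sp$rho, rho_p = sp$p)
}

#' FDR-sweep concordance between two differential-expression tables
#'
#' Validates homogenate-derived cell-specific DE calls against an
#' independent cell-resolved table: for every FDR cutoff on an inclusive
#' grid, both tables are restricted to genes of the focal collapsed class
#' passing `fdr < cutoff` (strict), intersected, and the sign concordance
#' and Spearman correlation of the paired log2 fold changes computed.
#'
#' @param de_a,de_b DE data.frames sharing a gene namespace (e.g. bulk
#'   homogenate vs cell-sorted/LCM results).
#' @param classification an `"eshrd"` object or classification data.frame.
#' @param cell_class focal collapsed class (e.g. `"O"`).
#' @param grid_start,grid_end,grid_step inclusive cutoff grid; the default
#'   0.05 to 1.00 in steps of 0.001 gives 951 evaluation points.
#' @param filter_side apply the FDR cutoff to both tables (default) or to
#'   one side only.
#' @return data.frame with one row per cutoff: `cutoff`, `n_overlap`,
#'   `concordance_pct`, `rho`, `rho_p` (statistics `NA` where undefined).
#' @export
concordance_sweep <- function(de_a, de_b, classification, cell_class,
                              grid_start = 0.05, grid_end = 1.00,
                              grid_step = 0.001,
                              filter_side = c("both", "a", "b")) {
  filter_side <- match.arg(filter_side)
  genes <- concordance_class_genes(classification, cell_class)
  cutoffs <- seq(grid_start, grid_end, by = grid_step)
  a_cls <- de_a[de_a$gene_id %in% genes, , drop = FALSE]
  b_cls <- de_b[de_b$gene_id %in% genes, , drop = FALSE]
  rows <- lapply(cutoffs, function(f) {
    a <- if (filter_side %in% c("both", "a"))
      a_cls[a_cls$fdr < f, , drop = FALSE] else a_cls
    b <- if (filter_side %in% c("both", "b"))
      b_cls[b_cls$fdr < f, , drop = FALSE] else b_cls
    p <- concordance_point(a, b, genes)
    data.frame(cutoff = f, n_overlap = p$n_overlap,
               concordance_pct = p$concordance_pct, rho = p$rho,
               rho_p = p$rho_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance at fixed log2 fold-change cutoffs
#'
#' The cell-resolved table (side b, e.g. snRNA-seq) is filtered by absolute
#' log2 fold change only -- no p-value filter, to admit more genes -- while
#' side a contributes its class-restricted DEGs at `fdr_a`. Points supported
#' by fewer than `min_overlap` overlapping genes are flagged `low_support`
#' rather than removed, so all points remain visible.
#'
#' @param de_a bulk DE table (DEGs selected at `fdr_a`).
#' @param de_b cell-resolved DE table (filtered by `|log2fc| >= cutoff`).
#' @param classification an `"eshrd"` object or classification data.frame.
#' @param cell_class focal collapsed class.
#' @param lfc_cutoffs absolute log2FC thresholds applied to side b.
#' @param fdr_a DEG threshold for side a (strict `<`).
#' @param min_overlap support threshold for the `low_support` flag.
#' @return data.frame: `cutoff`, `n_overlap`, `concordance_pct`, `rho`,
#'   `rho_p`, `low_support`.
#' @export
lfc_cutoff_concordance <- function(de_a, de_b, classification, cell_class,
                                   lfc_cutoffs = c(0, 0.25, 0.50, 1.00),
                                   fdr_a = 0.05, min_overlap = 10) {
  genes <- concordance_class_genes(classification, cell_class)
  a <- de_a[de_a$gene_id %in% genes & de_a$fdr < fdr_a, , drop = FALSE]
  rows <- lapply(lfc_cutoffs, function(L) {
    b <- de_b[abs(de_b$log2fc) >= L, , drop = FALSE]
    p <- concordance_point(a, b, genes)
    data.frame(cutoff = L, n_overlap = p$n_overlap,
               concordance_pct = p$concordance_pct, rho = p$rho,
               rho_p = p$rho_p, low_support = p$n_overlap < min_overlap)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
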