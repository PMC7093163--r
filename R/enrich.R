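#' Permutation test for cell-class over-representation among DEGs
#'
#' Asks whether more DEGs carry a given cell class than expected if the DEG
#' set were a random draw from the gene universe. Each of `n_perm`
#' iterations samples `|deg_gene_ids|` genes without replacement from the
#' universe and counts how many carry `cell_class`; the observed count is
#' compared to this permutation null. The empirical p-value uses the add-one
#' correction, \eqn{p = (1 + \#\{resampled \ge observed\}) / (n_{perm}+1)},
#' so it is never exactly zero; the significance flag records the companion
#' criterion that the observed count strictly exceed the resampled count in
#' at least 95\% of permutations.
#'
#' The universe should be the set of genes measurable in the dataset that
#' received a classification, not the whole reference panel: enrichment is
#' relative to what could have been detected.
#'
#' @param universe_labels named character vector mapping every universe gene
#'   id to its (collapsed) class label.
#' @param deg_gene_ids character vector of DEG ids; must be a subset of the
#'   universe.
#' @param cell_class the focal class label.
#' @param n_perm number of permutations (the procedure's standard is 50,000).
#' @param seed RNG seed (mandatory: results are only meaningful if
#'   reproducible).
#' @return An object of class `"perm_enrich"`: observed count, null mean/sd,
#'   the full null histogram (`table`), `empirical_p`, `significant`,
#'   `n_perm` and `seed`.
#' @export
permutation_enrichment <- function(universe_labels, deg_gene_ids, cell_class,
                                   n_perm = 50000, seed) {
  stopifnot(!is.null(names(universe_labels)), length(universe_labels) > 0,
            n_perm >= 1)
  if (missing(seed)) stop_eshrd("eshrd_value_error", "seed is required")
  n_univ <- length(universe_labels)
  n_deg <- length(deg_gene_ids)
  if (n_deg < 1L)
    stop_eshrd("eshrd_value_error", "empty DEG set")
  if (n_deg > n_univ)
    stop_eshrd("eshrd_value_error",
               "DEG set (%d) larger than universe (%d)", n_deg, n_univ)
  if (!all(deg_gene_ids %in% names(universe_labels)))
    stop_eshrd("eshrd_value_error", "DEG set is not a subset of the universe")
  is_class <- unname(universe_labels == cell_class)
  if (!any(is_class))
    stop_eshrd("eshrd_value_error",
               "universe contains no gene of class '%s'", cell_class)
  observed <- sum(universe_labels[deg_gene_ids] == cell_class)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    sum(is_class[sample.int(n_univ, n_deg)])
  }, integer(1L))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  empirical_p <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  significant <- mean(observed > null_counts) >= 0.95
  structure(list(cell_class = cell_class, observed = observed,
                 n_deg = n_deg, n_universe = n_univ,
                 n_class_universe = sum(is_class),
                 null_mean = mean(null_counts), null_sd = stats::sd(null_counts),
                 null_histogram = table(null_counts),
                 empirical_p = empirical_p, significant = significant,
                 n_perm = n_perm, seed = seed),
            class = "perm_enrich")
}

#' @export
print.perm_enrich <- function(x, ...) {
  cat(sprintf("Permutation enrichment for class '%s'\n", x$cell_class))
  cat(sprintf("  observed %d of %d DEGs (universe: %d of %d in class)\n",
              x$observed, x$n_deg, x$n_class_universe, x$n_universe))
  cat(sprintf("  null mean %.2f (sd %.2f), %d permutations, seed %d\n",
              x$null_mean, x$null_sd, x$n_perm, x$seed))
  cat(sprintf("  empirical p = %.4g%s\n", x$empirical_p,
              if (x$significant) "  (significant at the 95%% criterion)" else ""))
  invisible(x)
}

#' Enrichment scan over datasets and cell classes
#'
#' Runs [permutation_enrichment] for every (dataset, class) combination of
#' an annotated DEG table against a classified universe. Per-combination
#' seeds are derived deterministically from the master seed and the
#' combination's name, so adding a class or dataset never perturbs the
#' other results.
#'
#' @param annotated annotated DEG data.frame ([annotate_degs] /
#'   [predict.eshrd]); unclassified genes are ignored.
#' @param universe an `"eshrd"` object, a classification data.frame, or a
#'   named label vector defining the gene universe. For a per-dataset
#'   universe, pass a named list keyed by dataset.
#' @param classes classes to test; default: every class present among the
#'   dataset's DEGs.
#' @param n_perm permutations per test.
#' @param seed master seed.
#' @return data.frame with one row per (dataset, class): `observed`,
#'   `expected_mean`, `empirical_p`, `significant`, `n_perm`, `seed`.
#' @export
enrichment_scan <- function(annotated, universe, classes = NULL,
                            n_perm = 50000, seed) {
  if (missing(seed)) stop_eshrd("eshrd_value_error", "seed is required")
  as_labels <- function(u) {
    if (inherits(u, "eshrd")) u <- u$classification
    if (is.data.frame(u)) stats::setNames(u$collapsed_label, u$gene_id) else u
  }
  ds <- if ("dataset" %in% names(annotated)) as.character(annotated$dataset)
        else rep("all", nrow(annotated))
  ds[is.na(ds)] <- "all"
  rows <- list()
  for (d in unique(ds)) {
    sub <- annotated[ds == d & annotated$collapsed_label != "unclassified", ,
                     drop = FALSE]
    if (nrow(sub) == 0L) next
    labels <- if (is.list(universe) && !is.data.frame(universe) &&
                  !inherits(universe, "eshrd")) as_labels(universe[[d]])
              else as_labels(universe)
    deg_ids <- intersect(sub$gene_id, names(labels))
    cl_set <- if (is.null(classes)) sort(unique(sub$collapsed_label)) else classes
    for (cl in cl_set) {
      if (!any(labels == cl)) next
      r <- permutation_enrichment(labels, deg_ids, cl, n_perm = n_perm,
                                  seed = derive_seed(seed, paste(d, cl)))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = d, class = cl, observed = r$observed,
        expected_mean = r$null_mean, empirical_p = r$empirical_p,
        significant = r$significant, n_perm = n_perm, seed = r$seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(dataset = character(0), class = character(0),
               observed = integer(0), expected_mean = numeric(0),
               empirical_p = numeric(0), significant = logical(0),
               n_perm = integer(0), seed = integer(0))
  rownames(out) <- NULL
  out
}
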