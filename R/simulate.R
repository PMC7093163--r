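#' Scenario for a synthetic reference panel
#'
#' Describes a reference panel with planted ground truth. Defaults state the
#' world the method was developed for: the 7 brain cell types of the
#' cell-sorted cortex panel, a 0.1 fpkm detection floor, a 50-fold
#' specificity ratio for planted marker genes, and class proportions
#' mirroring the reference database (mixed ~73\%, the rest split over
#' cell-specific and a small multiple-cell class).
#'
#' @param n_genes number of genes.
#' @param cell_types cell-type labels.
#' @param class_proportions named target fractions per planted label; names
#'   are `"mixed"`, single cell types, or slash-joined multi-cell sets.
#'   Must sum to 1.
#' @param specificity_fold ratio of focal-cell to background fpkm for
#'   planted specific genes (> 1).
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise (0 = noise-free).
#' @param floor fpkm detection floor; generated values are clamped to it.
#' @param baseline_fpkm median background expression level.
#' @param gene_sdlog log-sd of the per-gene overall expression scale
#'   (row scaling does not affect enrichment scores).
#' @param mixed_position relative position (fraction of the top enrichment
#'   score) of the intermediate cell planted in mixed genes; 0.5 puts it in
#'   the middle of the indeterminate band.
#' @param seed RNG seed.
#' @return A `"panel_scenario"` list.
#' @export
panel_scenario <- function(n_genes = 2000,
                           cell_types = c("N", "A", "M", "MO", "NFO", "OPC", "EC"),
                           class_proportions = c(mixed = 0.734, M = 0.066,
                                                 N = 0.059, EC = 0.057,
                                                 A = 0.036, MO = 0.011,
                                                 NFO = 0.010, OPC = 0.010,
                                                 "N/A" = 0.017),
                           specificity_fold = 50, noise_cv = 0.25,
                           floor = 0.1, baseline_fpkm = 5, gene_sdlog = 0.5,
                           mixed_position = 0.5, seed = NULL) {
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop_eshrd("eshrd_value_error", "class proportions must sum to 1 (got %g)",
               sum(class_proportions))
  stopifnot(specificity_fold > 1, noise_cv >= 0, floor > 0,
            mixed_position > 0, mixed_position < 1,
            length(cell_types) >= 2, !is.null(names(class_proportions)))
  planted_cells <- setdiff(unique(unlist(strsplit(
    setdiff(names(class_proportions), "mixed"), "/", fixed = TRUE))), "")
  if (!all(planted_cells %in% cell_types))
    stop_eshrd("eshrd_value_error", "planted class names must use panel cell types")
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 class_proportions = class_proportions,
                 specificity_fold = specificity_fold, noise_cv = noise_cv,
                 floor = floor, baseline_fpkm = baseline_fpkm,
                 gene_sdlog = gene_sdlog, mixed_position = mixed_position,
                 seed = seed),
            class = "panel_scenario")
}

# Intermediate-cell multiplier m such that, with one focal cell at fold F and
# k-2 background cells at 1, the intermediate cell's enrichment score equals
# t * ES_high exactly (noise-free):  m^2 + (k-2) m - t F (F + k - 2) = 0.
#' @noRd
mixed_intermediate <- function(fold, k, t) {
  (-(k - 2) + sqrt((k - 2)^2 + 4 * t * fold * (fold + k - 2))) / 2
}

# Largest-remainder apportionment of n items to the target fractions.
#' @noRd
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a synthetic reference panel with known labels
#'
#' Cell-specific genes carry `specificity_fold` times the background fpkm in
#' their focal cell(s); mixed genes additionally carry one randomly chosen
#' intermediate cell placed (noise-free) exactly in the indeterminate band
#' between the low and high thresholds. Each gene's row is scaled by a
#' log-normal overall expression level, multiplicative log-normal noise with
#' the requested CV is applied per value, and everything is clamped at the
#' floor. With `noise_cv = 0` the construction is exact and classification
#' must recover every planted label.
#'
#' @param scenario a [panel_scenario].
#' @return list with elements `panel` (an [expression_panel]) and `truth`
#'   (named character vector of planted labels, slash-joined in panel cell
#'   order, `"mixed"` for mixed genes).
#' @export
generate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "panel_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  k <- length(scenario$cell_types)
  n <- scenario$n_genes
  counts <- apportion(n, scenario$class_proportions)
  truth <- rep(names(counts), counts)[sample.int(n)]
  F <- scenario$specificity_fold
  m_mid <- mixed_intermediate(F, k, scenario$mixed_position)

  values <- matrix(1, nrow = n, ncol = k,
                   dimnames = list(sprintf("gene%05d", seq_len(n)),
                                   scenario$cell_types))
  canon <- scenario$cell_types
  for (i in seq_len(n)) {
    if (truth[i] == "mixed") {
      pick <- sample.int(k, 2L)
      values[i, pick[1L]] <- F
      values[i, pick[2L]] <- m_mid
    } else {
      cells <- split_label(truth[i])
      values[i, match(cells, canon)] <- F
      truth[i] <- join_label(cells, canon)
    }
  }
  scale <- scenario$baseline_fpkm *
    stats::rlnorm(n, meanlog = 0, sdlog = scenario$gene_sdlog)
  values <- values * scale
  if (scenario$noise_cv > 0) {
    s2 <- log(1 + scenario$noise_cv^2)
    noise <- stats::rlnorm(n * k, meanlog = -s2 / 2, sdlog = sqrt(s2))
    values <- values * matrix(noise, nrow = n)
  }
  values <- pmax(values, scenario$floor)
  list(panel = expression_panel(values, namespace = "synthetic"),
       truth = stats::setNames(truth, rownames(values)))
}

#' Scenario for a synthetic differential-expression table
#'
#' @param classification ground-truth labels: a classification data.frame
#'   (`gene_id`, `collapsed_label`), an `"eshrd"` object, or a named label
#'   vector.
#' @param n_degs number of planted DEGs.
#' @param up_probability probability that a DEG is upregulated; scalar or a
#'   named per-class vector (unnamed classes fall back to 0.5).
#' @param class_weights optional named sampling-weight multipliers per class
#'   for DEG selection (e.g. `c(N = 3)` plants a 3-fold enrichment of class
#'   N among DEGs relative to the universe).
#' @param lfc_mean,lfc_sd mean and sd of the absolute log2 fold change of
#'   planted DEGs.
#' @param null_lfc_sd sd of the (zero-centred) log2 fold change of non-DEGs.
#' @param deg_p_max planted DEG p-values are uniform on (0, `deg_p_max`];
#'   non-DEG p-values are uniform on \[0, 1\]. The FDR column is computed
#'   from all p-values by the Benjamini-Hochberg step-up rule.
#' @param dataset dataset tag of the generated table.
#' @param seed RNG seed.
#' @return A `"de_scenario"` list.
#' @export
de_scenario <- function(classification, n_degs = 200, up_probability = 0.5,
                        class_weights = NULL, lfc_mean = 1, lfc_sd = 0.5,
                        null_lfc_sd = 0.1, deg_p_max = 1e-6,
                        dataset = "SIM", seed = NULL) {
  if (inherits(classification, "eshrd"))
    classification <- classification$classification
  if (!is.data.frame(classification))
    classification <- data.frame(gene_id = names(classification),
                                 collapsed_label = unname(classification),
                                 stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "collapsed_label") %in% names(classification)),
            all(up_probability >= 0), all(up_probability <= 1),
            n_degs >= 0, n_degs <= nrow(classification))
  structure(list(classification = classification, n_degs = n_degs,
                 up_probability = up_probability,
                 class_weights = class_weights, lfc_mean = lfc_mean,
                 lfc_sd = lfc_sd, null_lfc_sd = null_lfc_sd,
                 deg_p_max = deg_p_max, dataset = dataset, seed = seed),
            class = "de_scenario")
}

#' Generate a synthetic differential-expression table
#'
#' DEGs are drawn from the classified universe (optionally class-weighted),
#' given small p-values and planted directions/effect sizes; the remaining
#' genes get uniform null p-values and near-zero fold changes. The FDR
#' column is the Benjamini-Hochberg adjustment of the generated p-values.
#'
#' @param scenario a [de_scenario].
#' @return data.frame with columns `gene_id`, `log2fc`, `pvalue`, `fdr`,
#'   `dataset`, plus truth columns `is_deg` and `true_direction` (+1/-1 for
#'   DEGs, `NA` otherwise).
#' @export
generate_de_table <- function(scenario) {
  stopifnot(inherits(scenario, "de_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  cls <- scenario$classification
  n <- nrow(cls)
  w <- rep(1, n)
  if (!is.null(scenario$class_weights)) {
    hit <- match(cls$collapsed_label, names(scenario$class_weights))
    w[!is.na(hit)] <- scenario$class_weights[hit[!is.na(hit)]]
  }
  is_deg <- rep(FALSE, n)
  if (scenario$n_degs > 0)
    is_deg[sample.int(n, scenario$n_degs, prob = w)] <- TRUE

  up_p <- rep(0.5, n)
  if (length(scenario$up_probability) == 1L && is.null(names(scenario$up_probability))) {
    up_p[] <- scenario$up_probability
  } else {
    hit <- match(cls$collapsed_label, names(scenario$up_probability))
    up_p[!is.na(hit)] <- scenario$up_probability[hit[!is.na(hit)]]
  }
  direction <- ifelse(stats::runif(n) < up_p, 1, -1)
  magnitude <- abs(stats::rnorm(n, scenario$lfc_mean, scenario$lfc_sd))
  magnitude <- pmax(magnitude, 1e-6)  # a planted DEG always has a sign
  lfc <- ifelse(is_deg, direction * magnitude,
                stats::rnorm(n, 0, scenario$null_lfc_sd))
  p <- ifelse(is_deg, stats::runif(n) * scenario$deg_p_max, stats::runif(n))
  data.frame(gene_id = cls$gene_id, log2fc = lfc, pvalue = p,
             fdr = stats::p.adjust(p, method = "BH"),
             dataset = scenario$dataset, is_deg = is_deg,
             true_direction = ifelse(is_deg, direction, NA_real_),
             stringsAsFactors = FALSE)
}
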