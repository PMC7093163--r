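#' Read a differential-expression result table
#'
#' Expects a TSV with one row per gene carrying the log2 fold change
#' (case vs control), p-value and FDR-adjusted p-value. Column names are
#' configurable through `columns` so tables from different pipelines can be
#' ingested without editing. Malformed numerics and out-of-range statistics
#' are rejected with row-level messages; duplicate gene ids are an error
#' (ambiguous, never silently de-duplicated).
#'
#' @param path path to the TSV.
#' @param dataset dataset/region tag (e.g. `"TCX"`) stored in a `dataset`
#'   column.
#' @param columns named character vector mapping the canonical names
#'   `gene_id`, `log2fc`, `pvalue`, `fdr` to the file's column names.
#' @return data.frame with columns `gene_id`, `log2fc`, `pvalue`, `fdr`,
#'   `dataset`.
#' @export
read_de_table <- function(path, dataset = NULL,
                          columns = c(gene_id = "gene_id", log2fc = "log2fc",
                                      pvalue = "pvalue", fdr = "fdr")) {
  need <- c("gene_id", "log2fc", "pvalue", "fdr")
  stopifnot(all(need %in% names(columns)))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(unname(columns[need]), names(df))
  if (length(missing) > 0L)
    stop_eshrd("eshrd_format_error", "DE table missing column(s): %s",
               paste(missing, collapse = ", "))
  out <- data.frame(gene_id = as.character(df[[columns[["gene_id"]]]]),
                    log2fc = suppressWarnings(as.numeric(df[[columns[["log2fc"]]]])),
                    pvalue = suppressWarnings(as.numeric(df[[columns[["pvalue"]]]])),
                    fdr = suppressWarnings(as.numeric(df[[columns[["fdr"]]]])),
                    stringsAsFactors = FALSE)
  out$dataset <- if (is.null(dataset)) NA_character_ else dataset
  validate_de_records(out)
  eshrd_log("read DE table %s: %d records", path, nrow(out))
  out
}

#' @noRd
validate_de_records <- function(df) {
  bad <- which(!is.finite(df$log2fc) | is.na(df$pvalue) | is.na(df$fdr))
  if (length(bad) > 0L)
    stop_eshrd("eshrd_value_error",
               "malformed numeric in DE record at row %d (gene '%s')",
               bad[1L], df$gene_id[bad[1L]])
  bad <- which(df$fdr < 0 | df$fdr > 1 | df$pvalue > 1 | df$pvalue < 0)
  if (length(bad) > 0L)
    stop_eshrd("eshrd_value_error",
               "p-value/FDR out of [0,1] at row %d (gene '%s')",
               bad[1L], df$gene_id[bad[1L]])
  if (anyDuplicated(df$gene_id))
    stop_eshrd("eshrd_value_error",
               "duplicate gene_id '%s' in DE table (ambiguous)",
               df$gene_id[duplicated(df$gene_id)][1L])
  invisible(df)
}

#' Select differentially expressed genes
#'
#' Keeps records with `fdr` strictly below the threshold.
#'
#' @param records DE data.frame (see [read_de_table]).
#' @param fdr_threshold threshold in (0, 1].
#' @return The filtered data.frame.
#' @export
filter_degs <- function(records, fdr_threshold = 0.05) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  records[records$fdr < fdr_threshold, , drop = FALSE]
}

#' Attach cell-class labels to DEG records
#'
#' Each record gains `label` and `collapsed_label`; genes absent from the
#' classification table are tagged `"unclassified"` in both columns and
#' counted separately downstream.
#'
#' @param degs DE data.frame.
#' @param classification an `"eshrd"` object or a classification data.frame
#'   (`gene_id`, `label`, `collapsed_label`).
#' @param dataset optional dataset tag overriding the records' own.
#' @return The annotated data.frame.
#' @export
annotate_degs <- function(degs, classification, dataset = NULL) {
  cls <- if (inherits(classification, "eshrd")) classification$classification
         else classification
  idx <- match(degs$gene_id, cls$gene_id)
  degs$label <- ifelse(is.na(idx), "unclassified", cls$label[idx])
  degs$collapsed_label <- ifelse(is.na(idx), "unclassified",
                                 cls$collapsed_label[idx])
  if (!is.null(dataset)) degs$dataset <- dataset
  n_un <- sum(is.na(idx))
  eshrd_log("annotated %d DEGs: %d classified, %d unclassified",
            nrow(degs), nrow(degs) - n_un, n_un)
  degs
}

#' Per-class prevalence and direction summary of annotated DEGs
#'
#' For each (dataset, collapsed class): the DEG count, the count and
#' percentage with `log2fc > 0` (a fold change of exactly 0 is not
#' upregulated), and the class prevalence among *classified* DEGs --
#' unclassified genes are excluded from the prevalence denominator and
#' reported via the `n_unclassified` attribute.
#'
#' @param annotated data.frame from [annotate_degs] / [predict.eshrd].
#' @param by_dataset split by the `dataset` column when present.
#' @return data.frame with columns `dataset`, `class`, `n`, `n_up`,
#'   `pct_up`, `prevalence_pct`; attribute `n_unclassified` holds the
#'   per-dataset unclassified counts.
#' @export
summarize_classes <- function(annotated, by_dataset = TRUE) {
  stopifnot(all(c("gene_id", "log2fc", "collapsed_label") %in% names(annotated)))
  ds <- if (by_dataset && "dataset" %in% names(annotated))
    as.character(annotated$dataset) else rep("all", nrow(annotated))
  ds[is.na(ds)] <- "all"
  res <- list(); n_un <- integer(0)
  for (d in unique(ds)) {
    sub <- annotated[ds == d, , drop = FALSE]
    uncl <- sub$collapsed_label == "unclassified"
    n_un[d] <- sum(uncl)
    sub <- sub[!uncl, , drop = FALSE]
    if (nrow(sub) == 0L) next
    total <- nrow(sub)
    for (cl in unique(sub$collapsed_label)) {
      lfc <- sub$log2fc[sub$collapsed_label == cl]
      n <- length(lfc); n_up <- sum(lfc > 0)
      res[[length(res) + 1L]] <- data.frame(
        dataset = d, class = cl, n = n, n_up = n_up,
        pct_up = if (n > 0) 100 * n_up / n else NA_real_,
        prevalence_pct = 100 * n / total, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(dataset = character(0), class = character(0),
               n = integer(0), n_up = integer(0), pct_up = numeric(0),
               prevalence_pct = numeric(0))
  out <- out[order(out$dataset, -out$n), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unclassified") <- n_un
  out
}
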