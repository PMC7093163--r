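#' End-to-end pipeline: reference build, DEG classification, enrichment
#'
#' Orchestrates the full analysis from files to files: build the
#' classification from a reference panel (plus optional ortholog map),
#' classify each differential-expression table at the FDR threshold,
#' summarize class prevalence and direction per dataset, run the permutation
#' enrichment scan, and write a machine-readable run manifest (parameters,
#' input hashes, seed, versions) alongside the outputs.
#'
#' @param config named list with elements:
#'   \describe{
#'     \item{panel}{path to the reference panel TSV (required).}
#'     \item{ortholog_map}{optional path to the ortholog map TSV.}
#'     \item{de_tables}{named list/vector of DE table paths, keyed by
#'       dataset tag.}
#'     \item{out_dir}{output directory (created if absent; required).}
#'     \item{floor, alpha_low, alpha_high, fdr_threshold, n_perm}{parameters
#'       with the module defaults (0.1, 0.25, 0.75, 0.05, 50000).}
#'     \item{seed}{master seed, required when any DE table is supplied.}
#'   }
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  fit <- eshrd(config$panel, ortholog_map = config$ortholog_map,
               floor = config$floor, alpha_low = config$alpha_low,
               alpha_high = config$alpha_high)
  out$classification <- file.path(config$out_dir, "classification.tsv")
  write_classification(fit, out$classification)

  summaries <- list(); annotated_all <- list()
  for (ds in names(config$de_tables)) {
    de <- read_de_table(config$de_tables[[ds]], dataset = ds)
    ann <- predict(fit, de, fdr_threshold = config$fdr_threshold, dataset = ds)
    annotated_all[[ds]] <- ann
    f <- file.path(config$out_dir, sprintf("annotated_%s.tsv", ds))
    write_eshrd_tsv(ann, f)
    out[[paste0("annotated_", ds)]] <- f
    summaries[[ds]] <- summarize_classes(ann)
  }
  if (length(summaries) > 0) {
    out$summary <- file.path(config$out_dir, "class_summary.tsv")
    write_eshrd_tsv(do.call(rbind, summaries), out$summary)
    scan <- enrichment_scan(do.call(rbind, annotated_all), fit,
                            n_perm = config$n_perm, seed = config$seed)
    out$enrichment <- file.path(config$out_dir, "enrichment.tsv")
    write_eshrd_tsv(scan, out$enrichment)
  }

  out$manifest <- file.path(config$out_dir, "manifest.json")
  inputs <- c(panel = config$panel,
              if (!is.null(config$ortholog_map))
                c(ortholog_map = config$ortholog_map),
              unlist(config$de_tables))
  manifest <- list(
    package = "eshrd",
    version = as.character(utils::packageVersion("eshrd")),
    r_version = R.version.string,
    parameters = config[c("floor", "alpha_low", "alpha_high",
                          "fdr_threshold", "n_perm", "seed")],
    inputs = lapply(as.list(inputs), function(f) unname(tools::md5sum(f))),
    panel_hash = fit$panel_hash,
    outputs = lapply(out, basename))
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' @noRd
validate_config <- function(config) {
  if (!is.list(config))
    stop_eshrd("eshrd_config_error", "config must be a list")
  defaults <- list(ortholog_map = NULL, de_tables = list(), floor = 0.1,
                   alpha_low = 0.25, alpha_high = 0.75, fdr_threshold = 0.05,
                   n_perm = 50000, seed = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$panel) || !file.exists(config$panel))
    stop_eshrd("eshrd_config_error", "config$panel missing or file not found")
  if (is.null(config$out_dir))
    stop_eshrd("eshrd_config_error", "config$out_dir is required")
  config$de_tables <- as.list(config$de_tables)
  if (length(config$de_tables) > 0) {
    if (is.null(names(config$de_tables)) || any(!nzchar(names(config$de_tables))))
      stop_eshrd("eshrd_config_error", "de_tables must be named by dataset")
    absent <- !vapply(config$de_tables, file.exists, logical(1L))
    if (any(absent))
      stop_eshrd("eshrd_config_error", "DE table not found: %s",
                 config$de_tables[[which(absent)[1L]]])
    if (is.null(config$seed))
      stop_eshrd("eshrd_config_error",
                 "config$seed is required for the enrichment scan")
  }
  with_range <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || x <= lo || x > hi)
      stop_eshrd("eshrd_config_error", "config$%s out of range", nm)
  }
  with_range(config$floor, 0, Inf, "floor")
  with_range(config$alpha_high, config$alpha_low, 1, "alpha_high")
  with_range(config$fdr_threshold, 0, 1, "fdr_threshold")
  config
}
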