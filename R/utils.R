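# Internal helpers shared across the package.

#' @keywords internal
#' @noRd
eshrd_log <- function(...) {
  message(sprintf(...))
}

# Deterministic 31-bit sub-seed from a master seed and a character key.
# Polynomial rolling hash mod (2^31 - 1); stable across platforms so that
# adding one (dataset, class) pair never perturbs another's stream.
#' @noRd
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Slash-join a set of cell types in the canonical (panel) order.
#' @noRd
join_label <- function(cells, cell_order) {
  paste(cell_order[cell_order %in% cells], collapse = "/")
}

#' @noRd
split_label <- function(label) {
  strsplit(label, "/", fixed = TRUE)[[1L]]
}

# Fixed-precision TSV writer: numeric columns serialized at 6 significant
# digits for reproducible diffs across runs.
#' @noRd
write_eshrd_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- signif(out[[j]], 6)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
stop_eshrd <- function(class, fmt, ...) {
  stop(structure(class = c(class, "eshrd_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
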