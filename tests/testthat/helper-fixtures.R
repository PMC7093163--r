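# Fixture builders and independent oracles used across the suite.

cells7 <- c("N", "A", "M", "MO", "NFO", "OPC", "EC")

write_panel_tsv <- function(values, path = tempfile(fileext = ".tsv"),
                            ids = rownames(values)) {
  df <- data.frame(gene_id = ids, values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_de_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_panel <- function(values, cells = cells7[seq_len(ncol(values))],
                       ids = sprintf("g%d", seq_len(nrow(values)))) {
  dimnames(values) <- list(ids, cells)
  expression_panel(values, namespace = "test")
}

random_panel <- function(n_genes, n_cells, seed) {
  set.seed(seed)
  make_panel(matrix(rlnorm(n_genes * n_cells, meanlog = 1, sdlog = 1.5),
                    nrow = n_genes),
             cells = paste0("c", seq_len(n_cells)))
}

# Independent brute-force classifier: literal enumeration of the high/low
# partition from the class definitions, one cell at a time.
brute_classify <- function(es, alpha_low = 0.25, alpha_high = 0.75) {
  es_high <- max(es)
  high <- character(0); low <- character(0); interior <- FALSE
  for (cell in names(es)) {
    if (es[[cell]] >= alpha_high * es_high) high <- c(high, cell)
    else if (es[[cell]] <= alpha_low * es_high) low <- c(low, cell)
    else interior <- TRUE
  }
  if (interior || length(high) == length(es)) return("mixed")
  paste(names(es)[names(es) %in% high], collapse = "/")
}

# Brute-force Benjamini-Hochberg step-up rejection set at level alpha:
# largest k with p_(k) <= alpha * k / n rejects the k smallest p-values.
bh_reject <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(n)) if (p[ord[i]] <= alpha * i / n) k <- i
  rejected <- rep(FALSE, n)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

quiet <- function(expr) suppressMessages(expr)
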