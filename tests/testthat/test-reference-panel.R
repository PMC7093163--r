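# Reference-panel ingestion, filtering, ortholog mapping, enrichment scores
# and gene classification.

test_that("panel ingestion validates structure and values", {
  v <- matrix(c(1, 2, 3, 4, 5, 6, 7,
                2, 2, 2, 2, 2, 2, 2,
                0.1, 0.1, 9, 0.1, 0.1, 0.1, 0.1), nrow = 3, byrow = TRUE)
  path <- write_panel_tsv(make_panel(v)$values)
  p <- quiet(read_expression_panel(path, namespace = "mouse_symbol"))
  expect_s3_class(p, "expression_panel")
  expect_equal(dim(p), c(3L, 7L))
  expect_identical(p$namespace, "mouse_symbol")
  expect_equal(unname(p$values[1, ]), c(1, 2, 3, 4, 5, 6, 7))

  # negative value rejected naming row and column
  v2 <- v; v2[2, 3] <- -1.0
  err <- expect_error(quiet(read_expression_panel(write_panel_tsv(make_panel(v2)$values))),
                      class = "eshrd_value_error")
  expect_match(conditionMessage(err), "g2")
  expect_match(conditionMessage(err), "M")

  # non-numeric value rejected
  df <- data.frame(gene_id = c("a", "b"), c1 = c("1.0", "oops"), c2 = c(2, 3))
  f <- tempfile(); write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(quiet(read_expression_panel(f)), class = "eshrd_value_error")

  # fewer than 2 cell-type columns
  df <- data.frame(gene_id = c("a", "b"), c1 = c(1, 2))
  f <- tempfile(); write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(quiet(read_expression_panel(f)), class = "eshrd_structure_error")
})

test_that("duplicate gene rows collapse to the per-column mean with a warning", {
  v <- matrix(c(1, 2, 3,
                5, 6, 7,
                2, 2, 2), nrow = 3, byrow = TRUE)
  path <- write_panel_tsv(v, ids = c("Gfap", "Gfap", "Aldoc"))
  # colnames needed for the TSV header
  dimnames(v) <- list(NULL, c("N", "A", "M"))
  path <- write_panel_tsv(v, ids = c("Gfap", "Gfap", "Aldoc"))
  expect_warning(p <- quiet(read_expression_panel(path)), "duplicate")
  expect_equal(nrow(p$values), 2L)
  expect_equal(unname(p$values["Gfap", ]), c(3, 4, 5))  # mean of (1,2,3),(5,6,7)
  expect_equal(unname(p$values["Aldoc", ]), c(2, 2, 2))
})

test_that("floor filter removes genes at/below the floor everywhere", {
  v <- rbind(rep(0.1, 7),                       # all at floor -> removed
             c(0.1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.1),  # one above -> retained
             rep(0.05, 7),                      # below floor  -> removed
             rep(5, 7))
  p <- make_panel(v)
  out <- quiet(filter_low_expression(p, floor = 0.1))
  expect_equal(rownames(out$values), c("g2", "g4"))
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(attr(out, "n_retained"), 2L)
  # every retained gene has at least one value strictly above the floor
  expect_true(all(apply(out$values > 0.1, 1, any)))
  # all genes removed -> error signalling wrong units/floor
  expect_error(quiet(filter_low_expression(make_panel(rbind(rep(0.01, 7))), 0.1)),
               class = "eshrd_value_error")
})

test_that("ortholog mapping applies the drop/duplicate/average policy", {
  v <- rbind(c(1, 2), c(3, 4), c(10, 20), c(30, 40), c(7, 7), c(9, 9))
  p <- make_panel(v, cells = c("N", "A"),
                  ids = c("Gfap", "Unmapped", "Ma", "Mb", "OneToMany", "Amb"))
  omap <- ortholog_map(
    source_id = c("Gfap", "Ma", "Mb", "OneToMany", "OneToMany", "Amb", "Amb", "Other"),
    target_id = c("ENSG_A", "ENSG_B", "ENSG_B", "ENSG_C", "ENSG_D", "ENSG_E", "ENSG_B", "ENSG_E"))
  out <- quiet(map_orthologs(p, omap))
  expect_identical(out$namespace, "human_ensembl")
  # 1:1 mapping keeps values unchanged
  expect_equal(unname(out$values["ENSG_A", ]), c(1, 2))
  # many-to-one: per-column mean of Ma, Mb
  expect_equal(unname(out$values["ENSG_B", ]), c(20, 30))
  # one-to-many: row duplicated under each target
  expect_equal(unname(out$values["ENSG_C", ]), c(7, 7))
  expect_equal(unname(out$values["ENSG_D", ]), c(7, 7))
  # many-to-many source dropped entirely; unmapped gene dropped
  expect_false("ENSG_E" %in% rownames(out$values))
  cnt <- attr(out, "mapping_counts")
  expect_equal(cnt[["n_unmapped"]], 1L)
  expect_equal(cnt[["n_ambiguous_dropped"]], 1L)
  # zero genes mapped -> namespace-mismatch error
  expect_error(quiet(map_orthologs(p, ortholog_map("zzz", "ENSG_Z"))),
               class = "eshrd_value_error")
})

test_that("enrichment scores match the ratio definition", {
  # uniform gene: ES = 1 everywhere
  pr <- compute_enrichment_scores(make_panel(rbind(rep(5, 7))))
  expect_equal(unname(pr$es[1, ]), rep(1, 7))
  # two-cell panel (4, 2): ES = (2, 0.5)
  pr <- compute_enrichment_scores(make_panel(rbind(c(4, 2)), cells = c("a", "b")))
  expect_equal(unname(pr$es[1, ]), c(2, 0.5))
  # hand-computed 7-cell marker: ES1 = 70/0.1 = 700, others 0.1/(70.5/6)
  pr <- compute_enrichment_scores(make_panel(rbind(c(70, rep(0.1, 6)))))
  expect_equal(pr$es[1, 1], 700)
  expect_equal(unname(pr$es[1, 2]), 0.1 / ((70 + 5 * 0.1) / 6), tolerance = 1e-12)
  expect_equal(unname(pr$es_high[1]), 700)
  expect_equal(pr$es_high, apply(pr$es, 1, max))
})

test_that("classification follows the high/low partition rule", {
  es7 <- function(x) setNames(x, cells7)
  # uniform -> full high set -> mixed
  expect_identical(classify_gene(es7(rep(1, 7))), "mixed")
  # strong single marker: thresholds 175 / 525 checked by hand
  expect_identical(classify_gene(es7(c(700, rep(0.0085, 6)))), "N")
  # one cell strictly inside (2, 6) -> mixed
  expect_identical(classify_gene(es7(c(8, 4, rep(0.5, 5)))), "mixed")
  # two co-dominant cells: 7 >= 6, rest 0.5 <= 2
  expect_identical(classify_gene(es7(c(8, 7, rep(0.5, 5)))), "N/A")
  # boundary values belong to the high/low sets, not to mixed
  expect_identical(classify_gene(es7(c(8, 6, 2, 2, 2, 2, 2))), "N/A")
  # vectorized form agrees with the scalar form
  p <- random_panel(50, 7, seed = 11)
  pr <- compute_enrichment_scores(p)
  labs <- classify_genes(pr)
  one <- vapply(seq_len(50), function(i) classify_gene(pr$es[i, ]), character(1))
  expect_identical(unname(labs), one)
})

test_that("classification is invariant to row scaling and column order", {
  p <- random_panel(40, 7, seed = 3)
  # the ratio is exactly scale-free only away from the clamp floor, so use a
  # floor far below the generated values
  pr <- compute_enrichment_scores(p, floor = 1e-12)
  labs <- classify_genes(pr)
  # scale invariance: multiplying a gene row by k > 0 changes nothing
  set.seed(4)
  k <- runif(40, 0.01, 100)
  scaled <- make_panel(p$values * k, cells = colnames(p$values),
                       ids = rownames(p$values))
  pr2 <- compute_enrichment_scores(scaled, floor = 1e-12)
  expect_equal(pr2$es, pr$es, tolerance = 1e-12)
  expect_identical(classify_genes(pr2), labs)
  # permutation invariance: label sets unchanged under column reordering
  perm <- sample(7)
  permuted <- expression_panel(p$values[, perm], namespace = "test")
  labs_perm <- classify_genes(compute_enrichment_scores(permuted, floor = 1e-12))
  canon_sets <- lapply(strsplit(labs, "/"), sort)
  perm_sets <- lapply(strsplit(labs_perm, "/"), sort)
  expect_identical(perm_sets, canon_sets)
})

test_that("raising alpha_low shrinks the mixed class monotonically", {
  # raising alpha_low widens the low set and narrows the indeterminate band:
  # genes can only leave mixed for a high-set label, never the reverse, and
  # the high set itself (hence every non-mixed label) is untouched
  p <- random_panel(300, 7, seed = 9)
  pr <- compute_enrichment_scores(p)
  lo <- classify_genes(pr, alpha_low = 0.25)
  hi <- classify_genes(pr, alpha_low = 0.6)
  moved <- lo != hi
  expect_gt(sum(moved), 0)
  expect_true(all(lo[moved] == "mixed"))
  expect_true(all(hi[lo != "mixed"] == lo[lo != "mixed"]))
})

test_that("pan-oligodendrocyte collapsing follows the rename rule", {
  expect_identical(unname(collapse_oligo("MO/NFO", cells7)), "O")
  expect_identical(unname(collapse_oligo("mixed", cells7)), "mixed")
  expect_identical(unname(collapse_oligo("M/OPC", cells7)), "M/O")
  expect_identical(unname(collapse_oligo(c("MO", "NFO", "OPC"), cells7)),
                   c("O", "O", "O"))
  expect_identical(unname(collapse_oligo("N", cells7)), "N")
  expect_identical(unname(collapse_oligo("MO/NFO/EC", cells7)), "O/EC")
  expect_error(collapse_oligo("XX/N", cells7), class = "eshrd_value_error")
})

test_that("eshrd() composes filter, map, score, classify, collapse", {
  sim <- generate_panel(panel_scenario(n_genes = 200, noise_cv = 0, seed = 21))
  fit <- quiet(eshrd(sim$panel))
  expect_s3_class(fit, "eshrd")
  # totality/exclusivity: one label per retained gene, proportions sum to 1
  expect_identical(fit$classification$gene_id, rownames(fit$panel$values))
  expect_false(anyDuplicated(fit$classification$gene_id) > 0)
  s <- summary(fit)
  expect_equal(sum(s$classes$pct), 100, tolerance = 1e-12)
  # provenance records thresholds and panel hash
  expect_equal(fit$params$alpha_low, 0.25)
  expect_equal(fit$params$alpha_high, 0.75)
  expect_match(fit$panel_hash, "^[0-9a-f]{32}$")
  # empty panel is an error
  # degenerate empty panel is rejected (R drops zero-length rownames, so the
  # structural check fires first)
  expect_error(quiet(eshrd(expression_panel(
    matrix(numeric(0), 0, 2,
           dimnames = list(character(0), c("a", "b")))))),
    class = "eshrd_error")
  # classification table round-trips through TSV
  f <- tempfile(fileext = ".tsv")
  write_classification(fit, f)
  back <- read_classification(f)
  expect_identical(back, fit$classification)
})
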