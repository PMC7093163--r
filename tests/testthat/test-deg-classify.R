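# DEG ingestion, FDR filtering, class annotation and per-dataset summaries.

de_fixture <- function() {
  data.frame(gene_id = sprintf("g%d", 1:6),
             log2fc = c(1.2, -0.3, -0.8, 2.0, -1.1, 0),
             pvalue = c(1e-5, 2e-4, 1e-3, 1e-6, 5e-4, 0.9),
             fdr = c(0.001, 0.01, 0.049, 0.0005, 0.05, 0.95))
}

test_that("DE tables read, validate and support configurable column names", {
  f <- write_de_tsv(de_fixture())
  de <- quiet(read_de_table(f, dataset = "TCX"))
  expect_equal(nrow(de), 6)
  expect_identical(unique(de$dataset), "TCX")

  # out-of-range FDR rejected naming the row
  bad <- de_fixture(); bad$fdr[3] <- 1.3
  err <- expect_error(quiet(read_de_table(write_de_tsv(bad))),
                      class = "eshrd_value_error")
  expect_match(conditionMessage(err), "row 3")

  # malformed numeric rejected
  bad <- de_fixture(); bad$log2fc <- as.character(bad$log2fc); bad$log2fc[2] <- "x"
  expect_error(quiet(read_de_table(write_de_tsv(bad))), class = "eshrd_value_error")

  # duplicate gene ids are ambiguous, not silently de-duplicated
  bad <- de_fixture(); bad$gene_id[2] <- "g1"
  expect_error(quiet(read_de_table(write_de_tsv(bad))), class = "eshrd_value_error")

  # alternative column names mapped via config give the same records
  alt <- de_fixture()
  names(alt) <- c("ensembl", "logFC", "P.Value", "adj.P.Val")
  de2 <- quiet(read_de_table(write_de_tsv(alt), dataset = "TCX",
                             columns = c(gene_id = "ensembl", log2fc = "logFC",
                                         pvalue = "P.Value", fdr = "adj.P.Val")))
  expect_identical(de2, de)
})

test_that("DEG selection is strict at the FDR threshold and monotone", {
  de <- de_fixture()
  kept <- filter_degs(de, 0.05)
  expect_identical(kept$gene_id, c("g1", "g2", "g3", "g4"))  # 0.05 excluded
  expect_equal(nrow(filter_degs(de, 1.0)), 6)                # all fdr < 1 kept
  expect_equal(nrow(filter_degs(de[0, ], 0.05)), 0)
  # n_degs non-decreasing in the threshold
  ns <- vapply(c(0.01, 0.05, 0.2, 0.5, 1), function(t) nrow(filter_degs(de, t)),
               numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("annotation attaches labels and counts unclassified genes", {
  cls <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    label = c("N", "mixed", "MO/NFO", "M"),
                    collapsed_label = c("N", "mixed", "O", "M"))
  ann <- quiet(annotate_degs(de_fixture(), cls, dataset = "TCX"))
  expect_identical(ann$collapsed_label, c("N", "mixed", "O", "M",
                                          "unclassified", "unclassified"))
  # conservation: classified + unclassified = total
  expect_equal(sum(ann$collapsed_label != "unclassified") +
                 sum(ann$collapsed_label == "unclassified"), nrow(ann))
})

test_that("class summaries count direction and prevalence correctly", {
  ann <- data.frame(gene_id = sprintf("g%d", 1:8),
                    log2fc = c(1.2, -0.3, -0.8, 2.0, -1.1, 0.5, 0, 3),
                    dataset = "TCX",
                    collapsed_label = c(rep("M", 5), "N", "N", "unclassified"))
  s <- summarize_classes(ann)
  m <- s[s$class == "M", ]
  expect_equal(m$n, 5); expect_equal(m$n_up, 2); expect_equal(m$pct_up, 40)
  n <- s[s$class == "N", ]
  expect_equal(n$n_up, 1)  # log2fc = 0 is not upregulated
  expect_equal(attr(s, "n_unclassified")[["TCX"]], 1L)
  # prevalence over classified DEGs sums to 100
  expect_equal(sum(s$prevalence_pct), 100, tolerance = 1e-10)
  # direction bookkeeping per class
  expect_true(all(s$n_up <= s$n))
})

test_that("planted direction probabilities are recovered from simulations", {
  sim <- generate_panel(panel_scenario(n_genes = 800, noise_cv = 0, seed = 31))
  fit <- quiet(eshrd(sim$panel))
  de <- generate_de_table(de_scenario(fit, n_degs = 300,
                                      up_probability = c(M = 0.6, mixed = 0.5),
                                      seed = 32, dataset = "SIM"))
  ann <- quiet(annotate_degs(de[de$is_deg, ], fit))
  s <- summarize_classes(ann)
  m <- s[s$class == "M", ]
  # within the binomial 95% interval around 60%
  half <- 100 * 1.96 * sqrt(0.6 * 0.4 / m$n)
  expect_gt(m$pct_up, 60 - half)
  expect_lt(m$pct_up, 60 + half)
  # degenerate direction: all up
  de2 <- generate_de_table(de_scenario(fit, n_degs = 100, up_probability = 1,
                                       seed = 33))
  ann2 <- quiet(annotate_degs(de2[de2$is_deg, ], fit))
  s2 <- summarize_classes(ann2)
  expect_true(all(s2$pct_up == 100))
})

test_that("predict() chains DEG selection, annotation and summary", {
  sim <- generate_panel(panel_scenario(n_genes = 400, noise_cv = 0, seed = 41))
  fit <- quiet(eshrd(sim$panel))
  de <- simulate(fit, nsim = 1, seed = 42, n_degs = 60)[[1]]
  ann <- quiet(predict(fit, de))
  expect_true(all(c("label", "collapsed_label") %in% names(ann)))
  expect_true(all(ann$fdr < 0.05))
  s <- quiet(predict(fit, de, type = "summary"))
  expect_equal(sum(s$prevalence_pct), 100, tolerance = 1e-10)
})
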