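test_that("differential screen keeps large fold changes and guards zeros", {
  mat <- expression_matrix(rbind(
    flat = rep(1, 6),
    spike = c(1, 1, 1, 10, 1, 1),
    zeros = rep(0, 6),
    weak = c(0.1, 0.1, 0.1, 0.5, 0.1, 0.1)  # big ratio, peak below 1
  ))
  kept <- differential_screen(mat)
  expect_identical(as.character(kept), "spike")
  expect_named(attr(kept, "criteria"),
               c("fold_threshold", "min_peak", "pseudocount"))
  expect_error(differential_screen(mat, fold_threshold = 1),
               class = "budchill_config_error")
  expect_error(differential_screen(mat, pseudocount = 0),
               class = "budchill_config_error")
})

test_that("screening is column-order invariant and scale covariant", {
  set.seed(31)
  mat <- matrix(rexp(60 * 6, rate = 0.2), nrow = 60,
                dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:6)))
  base <- differential_screen(mat)
  perm <- differential_screen(mat[, c(4, 1, 6, 2, 5, 3)])
  expect_setequal(as.character(base), as.character(perm))
  k <- 7.5
  scaled <- differential_screen(mat * k, pseudocount = 0.1 * k,
                                min_peak = 1 * k)
  expect_setequal(as.character(base), as.character(scaled))
})

test_that("expression matrix validation rejects malformed input", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), NULL))
  expect_error(expression_matrix(m), class = "budchill_input_error")
  m2 <- matrix(c(-1, 1, 1, 1), 2, dimnames = list(c("a", "b"), NULL))
  expect_error(expression_matrix(m2), class = "budchill_input_error")
})

test_that("keyword classifier assigns temperature, photoperiod and none", {
  cls <- keyword_classify(toy_annotations())
  got <- setNames(cls$class, cls$gene_id)
  expect_identical(unname(got["g_cor"]), "temperature")
  expect_identical(unname(got["g_lhca"]), "photoperiod")
  expect_identical(unname(got["g_ref"]), "none")
  expect_true(nchar(cls$matched[cls$gene_id == "g_cor"]) > 0)

  # dual matches resolve to temperature with the both-flag set
  dual <- data.frame(gene_id = "d1", homolog_locus = NA,
                     homolog_name = "X",
                     description = "cold response of photosystem assembly")
  cd <- keyword_classify(dual)
  expect_identical(cd$class, "temperature")
  expect_true(cd$both)

  expect_error(keyword_rules(temperature_keywords = c("cold", "shared"),
                             photoperiod_keywords = c("shared")),
               class = "budchill_config_error")
})

test_that("homolog summary counts groups and totals the gene set", {
  ann <- toy_annotations()
  res <- summarize_by_homolog(c("g_cor", "g_soc", "g_none"), ann)
  expect_equal(attr(res, "total"), 3L)
  expect_equal(res$n[res$homolog_name == "No Arabidopsis gene name"], 1L)
  expect_equal(sum(res$n), 3L)

  empty <- summarize_by_homolog(character(0), ann)
  expect_equal(attr(empty, "total"), 0L)
  expect_equal(nrow(empty), 0L)

  expect_error(summarize_by_homolog("missing", ann),
               class = "budchill_lookup_error")
})

test_that("heatmap standardization gives zero-mean unit-sd rows clipped to the bound", {
  expect_equal(unname(heatmap_normalize(rbind(r = c(1, 3)))[1, ]),
               c(-1, 1))
  expect_equal(unname(heatmap_normalize(rbind(r = rep(4, 6)))[1, ]),
               rep(0, 6))

  set.seed(8)
  mat <- matrix(rexp(40 * 6), nrow = 40,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
  z <- heatmap_normalize(mat, clip = 100)  # effectively unclipped
  expect_equal(unname(rowMeans(z)), rep(0, 40), tolerance = 1e-9)
  expect_equal(unname(sqrt(rowMeans(z^2))), rep(1, 40), tolerance = 1e-9)

  out <- rbind(o = c(rep(0, 11), 8))  # outlier beyond 3 population sd
  zo <- heatmap_normalize(out)
  expect_equal(max(zo), 3)
  expect_gte(attr(zo, "n_clipped"), 1L)
})

test_that("2^-dCt relative expression behaves as cycle arithmetic dictates", {
  expect_identical(relative_expression(20, 20), 1)
  expect_equal(relative_expression(21, 20), 0.5)
  expect_equal(relative_expression(20 + 3.321928, 20), 0.1,
               tolerance = 1e-6)
  # strictly decreasing in target Ct
  ct <- seq(15, 30, by = 0.5)
  expect_true(all(diff(relative_expression(ct, 20)) < 0))
  expect_error(relative_expression(NA, 20), class = "budchill_input_error")
})

test_that("qPCR aggregation averages technical then biological replicates", {
  tg <- matrix(25, nrow = 3, ncol = 3)
  rf <- matrix(25, nrow = 3, ncol = 3)
  res <- aggregate_qpcr(tg, rf)
  expect_equal(res$mean, 1)
  expect_equal(res$sd, 0)
  expect_false(any(res$flagged))

  # biological replicates with dCt 0, 1, 2 give mean of 1, 0.5, 0.25
  tg2 <- matrix(c(20, 21, 22), nrow = 3, ncol = 3)
  rf2 <- matrix(20, nrow = 3, ncol = 3)
  res2 <- aggregate_qpcr(tg2, rf2)
  expect_equal(res2$per_replicate, c(1, 0.5, 0.25))
  expect_equal(res2$mean, mean(c(1, 0.5, 0.25)))

  # a noisy triplicate is flagged but still aggregated
  tg3 <- rbind(c(20, 20.8, 20.1), c(21, 21, 21), c(22, 22, 22))
  res3 <- aggregate_qpcr(tg3, rf2)
  expect_identical(res3$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(length(res3$per_replicate), 3L)

  expect_error(aggregate_qpcr(matrix(NA_real_, 1, 3), matrix(20, 1, 3)),
               class = "budchill_input_error")
  expect_error(aggregate_qpcr(matrix(50, 1, 3), matrix(20, 1, 3)),
               class = "budchill_input_error")
})

test_that("long-format qPCR tables summarize per gene and checkpoint", {
  sim <- simulate_expression_pair(expression_sim_config(n_genes = 3,
                                                        seed = 4))
  qs <- summarize_qpcr(sim$qpcr_b)
  expect_true(all(qs$n_bio == 3))
  expect_setequal(unique(qs$gene_id), sim$truth$gene_id)
  # recovered relative expression tracks the simulated abundance ratio
  g <- sim$truth$gene_id[1]
  cp <- "cp3"
  expected <- sim$matrix_b[g, cp] / 10  # simulated reference scale
  got <- qs$mean[qs$gene_id == g & qs$date == cp]
  expect_equal(got, unname(expected), tolerance = 0.25)
})

test_that("expression matrix and annotations round-trip through delimited text", {
  dir <- withr::local_tempdir()
  mat <- expression_matrix(matrix(c(1.5, 0, 2, 8), 2,
                                  dimnames = list(c("g1", "g2"),
                                                  c("cp1", "cp2"))))
  p <- file.path(dir, "expr.tsv")
  write.table(cbind(gene_id = rownames(mat), as.data.frame(mat)), p,
              sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_expression_matrix(p)
  expect_equal(unclass(back)[, ], unclass(mat)[, ])

  ann <- toy_annotations()
  pa <- file.path(dir, "ann.csv")
  write.csv(ann, pa, row.names = FALSE)
  back_ann <- read_annotations(pa)
  expect_identical(back_ann$gene_id, ann$gene_id)
  expect_identical(back_ann$homolog_name, ann$homolog_name)
})
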