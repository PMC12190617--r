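make_toy_matrix <- function() {
  # 6 genes x 5 cells; gene2 expressed in only 2 cells; cell5 expresses 1 gene
  m <- Matrix::Matrix(0, 6, 5, sparse = TRUE,
                      dimnames = list(paste0("g", 1:6), paste0("c", 1:5)))
  m[1, 1:4] <- 5
  m[2, 1:2] <- 1          # fails min_cells = 3
  m[3, 1:4] <- 2
  m[4, 1:4] <- 3
  m[5, c(1, 2, 3, 4)] <- 1
  m[6, 1:4] <- 2
  m[3, 5] <- 1            # cell5: a single expressed gene
  m
}

test_that("QC filter follows the hand-enumerated trace and is idempotent", {
  m <- make_toy_matrix()
  f <- qc_filter(m, min_cells = 3, min_features = 2)
  expect_equal(dim(f), c(5, 4))
  expect_false("g2" %in% rownames(f))
  expect_false("c5" %in% colnames(f))
  rep <- attr(f, "qc_report")
  expect_equal(unname(rep), c(6, 5, 5, 4))
  expect_lte(rep["genes_after"], rep["genes_before"])
  expect_lte(rep["cells_after"], rep["cells_before"])
  # idempotent
  f2 <- qc_filter(f, min_cells = 3, min_features = 2)
  expect_equal(as.matrix(f2), as.matrix(f))
  # passing matrix unchanged
  ok <- Matrix::Matrix(1, 4, 4, sparse = TRUE,
                       dimnames = list(paste0("g", 1:4), paste0("c", 1:4)))
  expect_equal(as.matrix(qc_filter(ok, 3, 2)), as.matrix(ok))
  expect_error(qc_filter(m, min_cells = 10, min_features = 2), "empty")
})

test_that("CP10K-log1p normalization: arithmetic and depth invariance", {
  m <- Matrix::Matrix(c(1, 9999, 0, 10), 2, 2, sparse = TRUE,
                      dimnames = list(c("g1", "g2"), c("c1", "c2")))
  norm <- normalize_cp10k(m)
  # cell with total 10000 and count 1 -> ln(2)
  expect_equal(norm["g1", "c1"], log(2))
  expect_equal(norm["g1", "c2"], 0)   # zero stays zero
  # doubling a cell's counts changes nothing
  norm2 <- normalize_cp10k(m * 2)
  expect_equal(as.matrix(norm2), as.matrix(norm))
})

test_that("rank-sum statistic equals brute-force enumeration on 5 vs 5 cells", {
  set.seed(50)
  for (i in 1:10) {
    xa <- sample(0:4, 5, replace = TRUE) + 0   # ties on purpose
    xb <- sample(0:4, 5, replace = TRUE) + 0
    ts <- pqtlmr:::rank_sum_test(c(xa, xb), rep(c(TRUE, FALSE), each = 5))
    brute <- rank_sum_brute(xa, xb)
    expect_equal(ts$u, brute$u)
    expect_equal(ts$w, brute$w)
    # cross-check p against the standard implementation (normal approx,
    # no continuity correction)
    ref <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE,
                                               correct = FALSE))
    if (ts$p < 1) expect_equal(ts$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give p = 1 and log2fc = 0", {
  expr <- Matrix::Matrix(rep(c(1, 2, 0, 3), times = 6), 4, 6, sparse = TRUE,
                         dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  de <- wilcoxon_de(expr, paste0("c", 1:3), paste0("c", 4:6))
  expect_true(all(de$p == 1))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p_bonf >= de$p))
  expect_true(all(de$p_bonf <= 1))
})

test_that("Wilcoxon p is invariant under strictly monotone transforms", {
  sim <- simulate_counts(10, c(T_cell = 40), seed = 51)
  expr <- normalize_cp10k(sim$counts + 0)  # no QC: keep all genes
  ann <- sim$annotation
  a <- ann$barcode[ann$condition == "case"]
  b <- ann$barcode[ann$condition == "control"]
  de1 <- wilcoxon_de(expr, a, b)
  cube <- expr; cube@x <- cube@x^3
  de2 <- wilcoxon_de(cube, a, b)
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
})

test_that("a planted 4-fold shift is detected at the published thresholds", {
  sim <- simulate_counts(60, c(T_cell = 200),
                         de_genes = data.frame(gene = "gene0010",
                                               cell_type = "T_cell",
                                               condition = "case",
                                               log2_effect = 2),
                         dispersion = 0.4, seed = 52)
  m <- qc_filter(sim$counts, min_cells = 3, min_features = 5)
  expr <- normalize_cp10k(m)
  ann <- sim$annotation
  de <- wilcoxon_de(expr, ann$barcode[ann$condition == "case"],
                    ann$barcode[ann$condition == "control"])
  hit <- de[de$gene == "gene0010", ]
  expect_lt(hit$p_bonf, 0.05)
  expect_gt(hit$log2fc, 1.2)
  expect_lt(hit$log2fc, 2.8)
})

test_that("candidate screen: detection flags, specificity, absent genes", {
  sim <- simulate_counts(
    40, c(T_cell = 150, keratinocyte = 150),
    de_genes = data.frame(gene = "gene0003", cell_type = "T_cell",
                          condition = "case", log2_effect = 3),
    seed = 53)
  m <- qc_filter(sim$counts, min_cells = 3, min_features = 5)
  expr <- normalize_cp10k(m)
  scr <- candidate_screen(m, expr, sim$annotation,
                          c("gene0003", "gene0004", "ghost"))
  expect_s3_class(scr, "candidate_screen")
  g3 <- scr[scr$gene == "gene0003", ]
  expect_equal(g3$specific_celltype, "T_cell")
  expect_equal(g3$specific_condition, "case")
  flat <- scr[scr$gene == "gene0004", ]
  expect_true(is.na(flat$specific_celltype))
  ghost <- scr[scr$gene == "ghost", ]
  expect_false(ghost$detected_case)
  expect_false(ghost$detected_control)
  expect_true(is.na(ghost$log2fc))
})
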