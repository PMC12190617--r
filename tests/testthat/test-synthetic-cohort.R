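test_that("AR(1) LD matrix construction and PSD property", {
  expect_equal(make_ld_matrix(3, 0), diag(3), ignore_attr = TRUE)
  r <- make_ld_matrix(2, 0.9)
  expect_equal(r[1, 2], 0.9)
  expect_error(make_ld_matrix(3, 1), "rho")
  expect_error(make_ld_matrix(3, -0.1), "rho")
  set.seed(7)
  for (rho in runif(5)) {
    m <- make_ld_matrix(30, rho)
    expect_equal(m, t(m))
    expect_true(min(eigen(m, symmetric = TRUE,
                          only.values = TRUE)$values) >= -1e-10)
  }
})

test_that("simulation is deterministic and leaves the caller's RNG alone", {
  cfg <- scenario_config(n_snps = 15, seed = 99)
  s1 <- simulate_region(cfg)
  set.seed(123); before <- rnorm(1)
  s2 <- simulate_region(cfg)
  set.seed(123); after <- rnorm(1)
  expect_identical(as.data.frame(s1$protein_stats),
                   as.data.frame(s2$protein_stats))
  expect_identical(as.data.frame(s1$disease_stats),
                   as.data.frame(s2$disease_stats))
  expect_identical(before, after)
})

test_that("H0 has null true marginals; H4 shares the causal variant", {
  s0 <- simulate_region(scenario_config(n_snps = 10, scenario = "H0",
                                        seed = 1))
  expect_true(all(s0$truth$true_marginal_protein == 0))
  expect_true(all(s0$truth$true_marginal_disease == 0))
  s4 <- simulate_region(scenario_config(n_snps = 10, scenario = "H4",
                                        seed = 1))
  expect_identical(s4$truth$causal_snp_protein, s4$truth$causal_snp_disease)
  s3 <- simulate_region(scenario_config(n_snps = 10, scenario = "H3",
                                        seed = 1))
  expect_false(s3$truth$causal_snp_protein == s3$truth$causal_snp_disease)
})

test_that("simulated SE matches the analytic 1/sqrt(2f(1-f)N) exactly", {
  cfg <- scenario_config(n_snps = 12, seed = 4)
  s <- simulate_region(cfg)
  f <- s$protein_stats$eaf
  expect_equal(s$protein_stats$se,
               1 / sqrt(2 * f * (1 - f) * cfg$n_exposure))
  n_eff <- 4 * cfg$n_case * cfg$n_control / (cfg$n_case + cfg$n_control)
  expect_equal(s$disease_stats$se, 1 / sqrt(2 * f * (1 - f) * n_eff))
})

test_that("H4 lead-ratio Monte Carlo mean recovers theta", {
  cfg <- scenario_config(n_snps = 15, ld_rho = 0.5, theta = 0.2,
                         b_protein = 0.15)
  n_rep <- 1000
  ratios <- vapply(seq_len(n_rep), function(i) {
    cfg$seed <- 1000L + i
    s <- simulate_region(cfg)
    lead <- which.min(s$protein_stats$p)
    s$disease_stats$beta[lead] / s$protein_stats$beta[lead]
  }, numeric(1))
  mc_se <- sd(ratios) / sqrt(n_rep)
  expect_lt(abs(mean(ratios) - cfg$theta), 3 * mc_se)
})

test_that("panel truth bookkeeping: causal count, row count, H1 thetas are 0", {
  base <- scenario_config(n_snps = 10)
  p0 <- simulate_panel(8, 0, base, seed = 2)
  expect_true(all(p0$truth$theta == 0))
  p1 <- simulate_panel(20, 0.1, base, seed = 2)
  expect_equal(sum(p1$truth$scenario == "H4"), 2)
  expect_equal(nrow(p1$truth), 20)
  # regions are independent: snp ids disjoint across proteins
  ids <- unlist(lapply(p1$studies, function(s) s$protein_stats$snp_id))
  expect_equal(anyDuplicated(ids), 0)
})

test_that("NB counts: null ratios near 1, planted +2 effect lands in [3, 5.3]", {
  null_sim <- simulate_counts(40, c(T_cell = 500), de_genes = NULL,
                              seed = 31)
  ann <- null_sim$annotation
  case <- ann$barcode[ann$condition == "case"]
  ctrl <- ann$barcode[ann$condition == "control"]
  mc <- Matrix::rowMeans(null_sim$counts[, case])
  mn <- Matrix::rowMeans(null_sim$counts[, ctrl])
  keep <- mn > 0.5   # ratios of tiny means are noise-dominated
  expect_true(median(abs(log2(mc[keep] / mn[keep]))) < 0.35)

  de <- simulate_counts(40, c(T_cell = 500),
                        de_genes = data.frame(gene = "gene0005",
                                              cell_type = "T_cell",
                                              condition = "case",
                                              log2_effect = 2),
                        seed = 32)
  ann <- de$annotation
  ratio <- mean(de$counts["gene0005", ann$condition == "case"]) /
    mean(de$counts["gene0005", ann$condition == "control"])
  expect_gt(ratio, 3); expect_lt(ratio, 5.3)
})

test_that("MTX output is byte-identical across runs at the same seed", {
  d1 <- file.path(tempdir(), "mtx1"); d2 <- file.path(tempdir(), "mtx2")
  sim1 <- simulate_counts(20, c(T_cell = 30), seed = 5)
  sim2 <- simulate_counts(20, c(T_cell = 30), seed = 5)
  write_counts_mtx(sim1, d1); write_counts_mtx(sim2, d2)
  expect_identical(readBin(file.path(d1, "matrix.mtx"), "raw", 1e6),
                   readBin(file.path(d2, "matrix.mtx"), "raw", 1e6))
  back <- read_counts_mtx(d1)
  expect_equal(as.matrix(back$counts), as.matrix(sim1$counts))
})
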