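test_that("reading a well-formed TSV returns all records and handles shuffled columns", {
  df <- toy_sumstats_df(3)
  p1 <- write_sumstats_tsv(df)
  tab <- read_summary_stats(p1)
  expect_equal(nrow(tab), 3)
  expect_equal(unname(attr(tab, "validation_report")["n_kept"]), 3)

  shuffled <- write_sumstats_tsv(df, cols = c("P", "N", "SNP", "EA", "OA",
                                              "CHR", "POS", "SE", "BETA",
                                              "EAF"))
  tab2 <- read_summary_stats(shuffled)
  expect_equal(as.data.frame(tab2), as.data.frame(tab),
               ignore_attr = TRUE)
})

test_that("invalid rows are dropped and counted; structural errors are hard", {
  df <- toy_sumstats_df(3)
  df$se[2] <- 0
  tab <- read_summary_stats(write_sumstats_tsv(df))
  expect_equal(nrow(tab), 2)
  expect_equal(unname(attr(tab, "validation_report")["dropped_se"]), 1)

  # missing mandatory column names the column
  p <- write_sumstats_tsv(df, cols = c("SNP", "CHR", "POS", "EA", "OA",
                                       "EAF", "BETA", "SE", "P"))
  expect_error(read_summary_stats(p), "N")
  # empty file
  p2 <- tempfile(); writeLines("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN", p2)
  expect_error(read_summary_stats(p2), "empty")
})

test_that("comma-grouped and scientific numbers parse; round trip is exact", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
               "rs1\t1\t1,234,567\tA\tG\t0.3\t1.5e-2\t3e-3\t5.7e-7\t54,219"),
             p)
  tab <- read_summary_stats(p)
  expect_equal(tab$pos, 1234567L)
  expect_equal(tab$beta, 0.015)
  expect_equal(tab$n, 54219)

  cfg <- scenario_config(n_snps = 20, seed = 11)
  stats <- simulate_region(cfg)$protein_stats
  p2 <- tempfile(fileext = ".tsv")
  write_summary_stats(stats, p2)
  back <- read_summary_stats(p2)
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    expect_identical(back[[col]], stats[[col]], label = col)
  }
})

test_that("cis_region arithmetic, clamping at 1, and zero window", {
  g <- gene_annotation("G1", "P1", "chr1", 5e6, 5.01e6)
  r <- cis_region(g, 1e6)
  expect_equal(r, list(chrom = "chr1", start = 4e6, end = 6.01e6))
  g2 <- gene_annotation("G2", "P2", "chr1", 5e5, 6e5)
  expect_equal(cis_region(g2, 1e6)$start, 1)
  expect_equal(cis_region(g, 0), list(chrom = "chr1", start = 5e6,
                                      end = 5.01e6))
})

test_that("extract_region membership matches brute force", {
  tab <- toy_sumstats(10)   # positions 110..200 step 10
  all_r <- list(chrom = "1", start = 1, end = 1e9)
  expect_equal(as.data.frame(extract_region(tab, all_r)),
               as.data.frame(tab))
  none <- extract_region(tab, list(chrom = "1", start = 500, end = 600))
  expect_equal(nrow(none), 0)
  # region spanning variants 3..7
  r <- list(chrom = "1", start = tab$pos[3], end = tab$pos[7])
  got <- extract_region(tab, r)
  brute <- tab$snp_id[tab$pos >= r$start & tab$pos <= r$end]
  expect_equal(got$snp_id, brute)
  expect_equal(nrow(got), 5)
})

test_that("harmonization handles the four allele orientations", {
  ex <- toy_sumstats_df(1); ex$ea <- "A"; ex$oa <- "G"
  ex$eaf <- 0.2; ex$beta <- 0.5; ex$p <- 1e-4
  mk <- function(ea, oa, beta = 0.3, eaf = 0.2) {
    ou <- ex; ou$ea <- ea; ou$oa <- oa; ou$beta <- beta; ou$eaf <- eaf
    harmonize(summary_stats(ex), summary_stats(ou))
  }
  expect_equal(mk("A", "G")$beta_y, 0.3)                 # identical
  sw <- mk("G", "A")                                     # swapped
  expect_equal(sw$beta_y, -0.3)
  expect_equal(sw$eaf_y, 0.8)
  expect_equal(mk("T", "C")$beta_y, 0.3)                 # strand flip
  cs <- mk("C", "T")                                     # flip + swap
  expect_equal(cs$beta_y, -0.3)
  # incompatible alleles dropped
  inc <- mk("C", "G")
  expect_equal(nrow(inc), 0)
  expect_equal(unname(attr(inc, "harmonization_report")["n_dropped_incompatible"]), 1)
})

test_that("palindromic SNPs are frequency-aligned below the MAF bound, dropped above", {
  ex <- toy_sumstats_df(1); ex$ea <- "A"; ex$oa <- "T"
  ex$eaf <- 0.10; ex$beta <- 0.5
  pal <- function(eaf_y, ea = "A", oa = "T") {
    ou <- ex; ou$ea <- ea; ou$oa <- oa; ou$beta <- 0.3; ou$eaf <- eaf_y
    harmonize(summary_stats(ex), summary_stats(ou))
  }
  # same labels, frequencies disagree (0.10 vs 0.88) -> outcome flipped
  fl <- pal(0.88)
  expect_equal(fl$beta_y, -0.3)
  expect_equal(fl$eaf_y, 0.12)
  # same labels, frequencies agree -> kept as-is
  kp <- pal(0.12)
  expect_equal(kp$beta_y, 0.3)
  # swapped labels, frequencies (after swap alignment) agree -> genuine swap
  sw <- pal(0.88, ea = "T", oa = "A")
  expect_equal(sw$beta_y, -0.3)
  # ambiguous MAF >= 0.42 -> dropped
  amb <- pal(0.45)
  expect_equal(nrow(amb), 0)
  expect_equal(unname(attr(amb, "harmonization_report")["n_dropped_palindromic"]), 1)
})

test_that("swap transform is an involution on (beta, eaf)", {
  swap <- function(beta, eaf) c(-beta, 1 - eaf)
  set.seed(42)
  for (i in 1:20) {
    b <- rnorm(1); f <- runif(1)
    expect_identical(swap(swap(b, f)[1], swap(b, f)[2]), c(b, f))
  }
})
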