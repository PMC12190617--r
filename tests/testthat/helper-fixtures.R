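# Fixtures built in code: tiny summary-statistic tables, instrument sets
# and temp TSVs used across the suite.

toy_sumstats_df <- function(n = 5, chrom = "1", pos_start = 100,
                            beta = 0.1, se = 0.02, eaf = 0.3) {
  data.frame(snp_id = paste0("rs", seq_len(n)), chrom = chrom,
             pos = pos_start + seq_len(n) * 10,
             ea = "A", oa = "G", eaf = eaf, beta = beta, se = se,
             p = 0.5, n = 10000, stringsAsFactors = FALSE)
}

toy_sumstats <- function(...) summary_stats(toy_sumstats_df(...))

write_sumstats_tsv <- function(df, path = tempfile(fileext = ".tsv"),
                               cols = c("SNP", "CHR", "POS", "EA", "OA",
                                        "EAF", "BETA", "SE", "P", "N")) {
  out <- data.frame(SNP = df$snp_id, CHR = df$chrom, POS = df$pos,
                    EA = df$ea, OA = df$oa, EAF = df$eaf, BETA = df$beta,
                    SE = df$se, P = df$p, N = df$n)
  write.table(out[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

# A bare instrument set: the minimal data.frame the MR estimators accept.
toy_instruments <- function(beta_x, beta_y, se_y, se_x = 0.01) {
  data.frame(snp_id = paste0("rs", seq_along(beta_x)),
             beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y,
             stringsAsFactors = FALSE)
}

# Independent weighted-least-squares-through-origin oracle for IVW.
wls_origin_oracle <- function(bx, by, sy) {
  w <- 1 / sy^2
  x <- bx * sqrt(w); y <- by * sqrt(w)
  beta <- solve(t(x) %*% x, t(x) %*% y)[1, 1]
  se <- sqrt(solve(t(x) %*% x)[1, 1])
  list(beta = beta, se = se)
}

# Naive (non-log) colocalization oracle for small regions.
coloc_naive_oracle <- function(beta1, se1, beta2, se2, priors) {
  abf <- function(beta, se, w) {
    z <- beta / se; r <- w / (w + se^2)
    exp(0.5 * (log(1 - r) + r * z^2))
  }
  b1 <- abf(beta1, se1, priors$w_quant)
  b2 <- abf(beta2, se2, priors$w_binary)
  l0 <- 1
  l1 <- priors$p1 * sum(b1)
  l2 <- priors$p2 * sum(b2)
  l3 <- priors$p1 * priors$p2 * (sum(b1) * sum(b2) - sum(b1 * b2))
  l4 <- priors$p12 * sum(b1 * b2)
  pp <- c(l0, l1, l2, l3, l4)
  setNames(pp / sum(pp), c("pph0", "pph1", "pph2", "pph3", "pph4"))
}

# Exact rank-sum statistic by brute-force pair counting.
rank_sum_brute <- function(xa, xb) {
  u <- sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  w <- u + length(xa) * (length(xa) + 1) / 2
  list(u = u, w = w)
}
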