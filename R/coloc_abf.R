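# Single-causal-variant Bayesian colocalization via Wakefield approximate
# Bayes factors.  All hypothesis sums are carried in log space with
# log-sum-exp so strong signals cannot overflow.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association with the protein only
#' (`p1`), the disease only (`p2`), or both (`p12`), plus the prior effect
#' variances of the Wakefield ABF: `w_quant` for a quantitative trait (SD
#' units, default 0.15^2) and `w_binary` for a binary trait (log-odds,
#' default 0.2^2).
#'
#' @param p1,p2,p12 per-SNP priors; `0 < p12 <= min(p1, p2)` required.
#' @param w_quant,w_binary prior effect variances (> 0).
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w_quant = 0.15^2, w_binary = 0.2^2) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), w_quant > 0, w_binary > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 w_quant = w_quant, w_binary = w_binary),
            class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and prior effect
#' variance `w`: with `z = beta/se`, `V = se^2`, `r = w/(w + V)`,
#' `log ABF = 0.5*(log(1 - r) + r*z^2)`.
#'
#' @param beta,se effect estimate and standard error (`se > 0`).
#' @param w prior effect variance (> 0).
#' @return numeric log ABF (vectorized).
#' @export
log_abf <- function(beta, se, w) {
  stopifnot(all(se > 0), all(w > 0))
  z <- beta / se
  r <- w / (w + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

# Core posterior computation from two vectors of per-SNP log ABFs.
coloc_posteriors <- function(labf1, labf2, priors) {
  s1 <- logsumexp(labf1)                 # log sum ABF1
  s2 <- logsumexp(labf2)
  s12 <- logsumexp(labf1 + labf2)        # log sum over shared-SNP products
  l0 <- 0
  l1 <- log(priors$p1) + s1
  l2 <- log(priors$p2) + s2
  # sum over ordered distinct pairs = (sum1 * sum2) - shared diagonal
  l3 <- if (length(labf1) > 1L) {
    log(priors$p1) + log(priors$p2) + logdiffexp(s1 + s2, s12)
  } else -Inf
  l4 <- log(priors$p12) + s12
  ll <- c(l0, l1, l2, l3, l4)
  pp <- exp(ll - logsumexp(ll))
  stats::setNames(pp / sum(pp), c("pph0", "pph1", "pph2", "pph3", "pph4"))
}

#' Bayesian colocalization of a protein-disease region
#'
#' Computes per-SNP Wakefield log ABFs for both traits on the harmonized
#' region (protein with `w_quant`, disease with `w_binary`) and the
#' posterior probabilities of the five sharing hypotheses: H0 no
#' association, H1 protein only, H2 disease only, H3 two distinct causal
#' variants, H4 one shared causal variant.  PPH4 > 0.9 under the primary
#' prior is the robust colocalization criterion; PPH4 > 0.8 at
#' p12 = 5e-6 the sensitivity criterion.
#'
#' @param region_pair harmonized region, as returned by [harmonize()]
#'   (columns `beta_x, se_x, beta_y, se_y`, one row per shared SNP).
#' @param priors [coloc_priors()].
#' @return list of class `coloc_result`: `pph` (named posteriors summing
#'   to 1), `n_snps`, `lead_shared_snp` (SNP maximizing per-SNP H4
#'   support), `priors_used`.
#' @export
colocalize <- function(region_pair, priors = coloc_priors()) {
  n <- nrow(region_pair)
  if (is.null(n) || n == 0L) {
    stop("no shared SNPs in region after harmonization", call. = FALSE)
  }
  labf1 <- log_abf(region_pair$beta_x, region_pair$se_x, priors$w_quant)
  labf2 <- log_abf(region_pair$beta_y, region_pair$se_y, priors$w_binary)
  pph <- coloc_posteriors(labf1, labf2, priors)
  lead <- if ("snp_id" %in% names(region_pair)) {
    region_pair$snp_id[which.max(labf1 + labf2)]
  } else NA_character_
  structure(list(pph = pph, n_snps = n, lead_shared_snp = lead,
                 priors_used = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc (%d SNPs, p12 = %g): PPH0-4 = %s; lead shared SNP %s\n",
    x$n_snps, x$priors_used$p12,
    paste(sprintf("%.3f", x$pph), collapse = " "), x$lead_shared_snp))
  invisible(x)
}

#' Prior sensitivity analysis over p12
#'
#' Re-evaluates the posteriors on one fixed region for each value of the
#' shared-causal prior `p12`, reusing the per-SNP log ABFs.  PPH4 is
#' non-decreasing in p12.
#'
#' @param region_pair harmonized region (see [colocalize()]).
#' @param p12_grid non-empty numeric vector of p12 values, emitted in
#'   input order.
#' @param priors base [coloc_priors()] (p1, p2, effect variances).
#' @return list of `coloc_result`, one per grid value.
#' @export
coloc_sensitivity <- function(region_pair, p12_grid = c(1e-5, 5e-6),
                              priors = coloc_priors()) {
  stopifnot(length(p12_grid) >= 1)
  n <- nrow(region_pair)
  if (is.null(n) || n == 0L) {
    stop("no shared SNPs in region after harmonization", call. = FALSE)
  }
  labf1 <- log_abf(region_pair$beta_x, region_pair$se_x, priors$w_quant)
  labf2 <- log_abf(region_pair$beta_y, region_pair$se_y, priors$w_binary)
  lead <- if ("snp_id" %in% names(region_pair)) {
    region_pair$snp_id[which.max(labf1 + labf2)]
  } else NA_character_
  lapply(p12_grid, function(p12) {
    pr <- priors; pr$p12 <- p12
    structure(list(pph = coloc_posteriors(labf1, labf2, pr), n_snps = n,
                   lead_shared_snp = lead, priors_used = pr),
              class = "coloc_result")
  })
}

#' Colocalization over a gene's region
#'
#' Convenience wrapper: extracts the colocalization window (gene body
#' +/- `window`, default 500 kb) from both tables, harmonizes them and
#' runs [colocalize()] at the primary prior and [coloc_sensitivity()] at
#' the sensitivity prior.  The classification is `"robust"` if PPH4 > 0.9
#' at p12 = 1e-5, `"supported"` if PPH4 > 0.8 at p12 = 5e-6, else
#' `"not_colocalized"`.
#'
#' @param protein_stats,disease_stats `summary_stats` tables.
#' @param gene one-row `gene_annotation`.
#' @param window region half-width in bp (default 5e5).
#' @param priors base [coloc_priors()].
#' @param p12_sensitivity sensitivity value of p12 (default 5e-6).
#' @return list: `primary` and `sensitivity` (`coloc_result`s),
#'   `classification`.
#' @export
coloc_region <- function(protein_stats, disease_stats, gene, window = 5e5,
                         priors = coloc_priors(), p12_sensitivity = 5e-6) {
  region <- cis_region(gene, window)
  pair <- harmonize(extract_region(protein_stats, region),
                    extract_region(disease_stats, region))
  res <- coloc_sensitivity(pair, c(priors$p12, p12_sensitivity), priors)
  primary <- res[[1]]; sens <- res[[2]]
  classification <- if (primary$pph["pph4"] > 0.9) "robust"
  else if (sens$pph["pph4"] > 0.8) "supported"
  else "not_colocalized"
  list(primary = primary, sensitivity = sens,
       classification = classification)
}
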