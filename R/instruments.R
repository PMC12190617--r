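# cis-pQTL instrument selection: cis restriction, significance threshold,
# cross-protein pleiotropy filter, instrument-strength (F) filter, greedy
# LD clumping, harmonization with the outcome.

#' Instrument-selection configuration
#'
#' Defaults follow the discovery design: 1 Mb cis window, Bonferroni pQTL
#' threshold 1.7e-11 (5e-8 divided by the number of assayed proteins), SNPs
#' associated with fewer than three proteins, LD clumping at r^2 < 0.001,
#' and first-stage F > 10.
#'
#' @param cis_window cis window in bp around the gene body.
#' @param p_instrument pQTL significance threshold.
#' @param max_proteins_per_snp maximum number of distinct proteins a SNP may
#'   be associated with and still be used (default 2, i.e. "fewer than 3").
#' @param clump_r2 LD r^2 above which variants are considered dependent.
#' @param f_min minimum first-stage F statistic.
#' @param palindrome_maf see [harmonize()].
#' @return list of class `selection_config`.
#' @export
selection_config <- function(cis_window = 1e6, p_instrument = 1.7e-11,
                             max_proteins_per_snp = 2, clump_r2 = 0.001,
                             f_min = 10, palindrome_maf = 0.42) {
  stopifnot(cis_window >= 0, p_instrument > 0, p_instrument <= 1,
            max_proteins_per_snp >= 0, clump_r2 > 0, f_min >= 0)
  structure(list(cis_window = cis_window, p_instrument = p_instrument,
                 max_proteins_per_snp = max_proteins_per_snp,
                 clump_r2 = clump_r2, f_min = f_min,
                 palindrome_maf = palindrome_maf),
            class = "selection_config")
}

#' Instrument strength: variance explained and first-stage F
#'
#' `R^2 = 2*EAF*(1-EAF)*beta^2` (variance in the standardized trait
#' explained by one variant) and `F = R^2*(N-2)/(1-R^2)`.
#'
#' @param eaf effect-allele frequency in (0, 1).
#' @param beta per-allele effect estimate.
#' @param n sample size (> 2).
#' @return list with `r2_explained` and `f_stat` (vectorized).
#' @export
f_statistic <- function(eaf, beta, n) {
  stopifnot(all(eaf > 0 & eaf < 1), all(n > 2))
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  if (any(r2 >= 1)) {
    stop("R^2 >= 1: beta/eaf are not on a standardized-trait scale",
         call. = FALSE)
  }
  list(r2_explained = r2, f_stat = r2 * (n - 2) / (1 - r2))
}

# Deterministic ordering used for lead selection and clump seeds:
# smallest p, then largest F, then lexicographic snp_id.
lead_order <- function(p, f_stat, snp_id) {
  order(p, -f_stat, snp_id)
}

#' Lead cis-pQTL for a protein
#'
#' Among variants in the gene's cis region that pass the significance
#' threshold and the F filter, returns the one with the smallest p-value
#' (ties: larger F, then lexicographic snp_id), or `NULL` if none passes.
#'
#' @param protein_stats `summary_stats` for the protein.
#' @param gene one-row `gene_annotation`.
#' @param config [selection_config()].
#' @return one-row data.frame (snp_id, beta, se, p, eaf, n, r2_explained,
#'   f_stat) or `NULL`.
#' @export
lead_cis_pqtl <- function(protein_stats, gene, config = selection_config()) {
  cis <- extract_region(protein_stats, cis_region(gene, config$cis_window))
  if (nrow(cis) == 0L) return(NULL)
  fs <- f_statistic(cis$eaf, cis$beta, cis$n)
  keep <- cis$p <= config$p_instrument & fs$f_stat >= config$f_min
  if (!any(keep)) return(NULL)
  cand <- cis[keep, , drop = FALSE]
  f_stat <- fs$f_stat[keep]; r2 <- fs$r2_explained[keep]
  i <- lead_order(cand$p, f_stat, cand$snp_id)[1]
  data.frame(snp_id = cand$snp_id[i], beta = cand$beta[i], se = cand$se[i],
             p = cand$p[i], eaf = cand$eaf[i], n = cand$n[i],
             r2_explained = r2[i], f_stat = f_stat[i],
             stringsAsFactors = FALSE)
}

#' Cross-protein pleiotropy filter
#'
#' Excludes SNPs associated (at the instrument threshold) with more than
#' `max_proteins_per_snp` distinct proteins — by default, with three or
#' more.
#'
#' @param snp_protein_map data.frame with columns `snp_id`, `protein_id`
#'   listing associations at the instrument threshold.
#' @param config [selection_config()].
#' @return character vector of excluded snp ids (possibly empty).
#' @export
cross_protein_filter <- function(snp_protein_map,
                                 config = selection_config()) {
  if (is.null(snp_protein_map) || nrow(snp_protein_map) == 0L) {
    return(character(0))
  }
  counts <- tapply(snp_protein_map$protein_id, snp_protein_map$snp_id,
                   function(x) length(unique(x)))
  names(counts)[counts > config$max_proteins_per_snp]
}

#' Greedy LD clumping
#'
#' Repeatedly retains the unclaimed variant with the smallest p-value (ties
#' broken by larger F then snp_id) and discards all unclaimed variants with
#' `r^2 >= r2_max` to it.  The result is invariant to the input order of
#' candidates.
#'
#' @param candidates data.frame with columns `snp_id`, `p` and optionally
#'   `f_stat` (used only for tie-breaks).
#' @param ld LD correlation matrix (dimnames = snp ids); entries are r, so
#'   r^2 is taken internally.
#' @param r2_max clumping threshold on r^2.
#' @return character vector of retained snp ids, in retention order.
#' @export
clump <- function(candidates, ld, r2_max = 0.001) {
  if (nrow(candidates) == 0L) return(character(0))
  if (!all(candidates$snp_id %in% rownames(ld))) {
    stop("candidate variant(s) missing from the LD matrix: ",
         paste(setdiff(candidates$snp_id, rownames(ld)), collapse = ", "),
         call. = FALSE)
  }
  f <- if ("f_stat" %in% names(candidates)) candidates$f_stat else
    rep(0, nrow(candidates))
  ord <- lead_order(candidates$p, f, candidates$snp_id)
  queue <- candidates$snp_id[ord]
  retained <- character(0)
  while (length(queue)) {
    lead <- queue[1]
    retained <- c(retained, lead)
    r2 <- ld[lead, queue]^2
    queue <- queue[r2 < r2_max]
  }
  retained
}

#' Build the full instrument set for one protein-outcome pair
#'
#' Applies, in order: cis restriction, significance threshold,
#' cross-protein filter, F filter, LD clumping, harmonization with the
#' outcome.  The per-step removal counts are returned as the
#' `"selection_log"` attribute (the counts sum to input minus retained).
#'
#' @param protein_stats,disease_stats `summary_stats` tables (exposure and
#'   outcome).
#' @param gene one-row `gene_annotation` for the protein.
#' @param ld LD correlation matrix covering the cis candidates.
#' @param config [selection_config()].
#' @param snp_protein_map optional cross-protein association map (see
#'   [cross_protein_filter()]).
#' @return data.frame of class `instrument_set`, one row per retained
#'   instrument: `snp_id, beta_x, se_x, p_x, beta_y, se_y, p_y, eaf, n_x,
#'   r2_explained, f_stat`; attributes `protein_id`, `outcome_id`,
#'   `selection_log`, `clump_r2`.
#' @export
build_instrument_set <- function(protein_stats, disease_stats, gene, ld,
                                 config = selection_config(),
                                 snp_protein_map = NULL) {
  log <- data.frame(step = character(0), n_in = integer(0),
                    n_removed = integer(0))
  note <- function(step, n_in, n_out) {
    rbind(log, data.frame(step = step, n_in = n_in, n_removed = n_in - n_out))
  }

  cis <- extract_region(protein_stats, cis_region(gene, config$cis_window))
  log <- note("cis_restriction", nrow(protein_stats), nrow(cis))

  sig <- cis[cis$p <= config$p_instrument, , drop = FALSE]
  log <- note("p_threshold", nrow(cis), nrow(sig))

  excluded <- cross_protein_filter(snp_protein_map, config)
  xp <- sig[!(sig$snp_id %in% excluded), , drop = FALSE]
  log <- note("cross_protein_filter", nrow(sig), nrow(xp))

  if (nrow(xp)) {
    fs <- f_statistic(xp$eaf, xp$beta, xp$n)
    xp$r2_explained <- fs$r2_explained
    xp$f_stat <- fs$f_stat
  } else {
    xp$r2_explained <- numeric(0); xp$f_stat <- numeric(0)
  }
  strong <- xp[xp$f_stat >= config$f_min, , drop = FALSE]
  log <- note("f_filter", nrow(xp), nrow(strong))

  kept_ids <- clump(data.frame(snp_id = strong$snp_id, p = strong$p,
                               f_stat = strong$f_stat),
                    ld, config$clump_r2)
  clumped <- strong[match(kept_ids, strong$snp_id), , drop = FALSE]
  log <- note("ld_clump", nrow(strong), nrow(clumped))

  pair <- harmonize(clumped, disease_stats,
                    palindrome_maf = config$palindrome_maf)
  log <- note("harmonize", nrow(clumped), nrow(pair))

  idx <- match(pair$snp_id, clumped$snp_id)
  out <- data.frame(snp_id = pair$snp_id,
                    beta_x = pair$beta_x, se_x = pair$se_x, p_x = pair$p_x,
                    beta_y = pair$beta_y, se_y = pair$se_y, p_y = pair$p_y,
                    eaf = pair$eaf_x, n_x = pair$n_x,
                    r2_explained = clumped$r2_explained[idx],
                    f_stat = clumped$f_stat[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            class = c("instrument_set", "data.frame"),
            protein_id = gene$protein_id[1],
            outcome_id = attr(disease_stats, "trait_id"),
            selection_log = log, clump_r2 = config$clump_r2)
}
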