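# Orchestration of the drug-target discovery workflow: proteome-wide
# Wald-ratio screen, multi-instrument confirmation, external replication,
# reverse-MR adjudication, colocalization, LD pleiotropy scan, tier
# assignment, and the wide per-protein report.

#' Pipeline configuration
#'
#' @param selection [selection_config()] for discovery instruments.
#' @param alpha family-wise error rate for the discovery screen (the
#'   per-protein threshold is `alpha / n_tested`).
#' @param replication_p per-dataset replication threshold (default 0.05).
#' @param require_concordance replication passes must match the discovery
#'   effect direction (default TRUE).
#' @param reverse_p significance threshold in reverse MR (default 0.05).
#' @param reverse_gwas_p genome-wide threshold for disease instruments in
#'   reverse MR (default 5e-8).
#' @param reverse_rule `"egger_gate"` (default): a protein is flagged as
#'   reverse-causal only when both IVW and MR-Egger are significant;
#'   `"ivw_only"`: IVW significance alone flags.
#' @param coloc_window colocalization half-window in bp (default 5e5).
#' @param priors [coloc_priors()] used at the colocalization stage.
#' @param p12_sensitivity sensitivity p12 (default 5e-6).
#' @param pph4_robust PPH4 threshold for robust colocalization (0.9).
#' @param neighbor_r2 r^2 threshold of the pleiotropy neighbour scan (0.8).
#' @param wm_boot,seed weighted-median bootstrap size and pipeline seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(selection = selection_config(), alpha = 0.05,
                            replication_p = 0.05, require_concordance = TRUE,
                            reverse_p = 0.05, reverse_gwas_p = 5e-8,
                            reverse_rule = c("egger_gate", "ivw_only"),
                            coloc_window = 5e5, priors = coloc_priors(),
                            p12_sensitivity = 5e-6, pph4_robust = 0.9,
                            neighbor_r2 = 0.8, wm_boot = 1000, seed = 1L) {
  structure(list(selection = selection, alpha = alpha,
                 replication_p = replication_p,
                 require_concordance = require_concordance,
                 reverse_p = reverse_p, reverse_gwas_p = reverse_gwas_p,
                 reverse_rule = match.arg(reverse_rule),
                 coloc_window = coloc_window, coloc_priors = priors,
                 p12_sensitivity = p12_sensitivity,
                 pph4_robust = pph4_robust, neighbor_r2 = neighbor_r2,
                 wm_boot = wm_boot, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Wald ratio at the lead cis-pQTL of one study (lead selection on the
# exposure, then harmonization restricted to that SNP).  NULL when no
# valid, harmonizable lead exists.
lead_wald <- function(protein_stats, disease_stats, gene, config) {
  lead <- lead_cis_pqtl(protein_stats, gene, config$selection)
  if (is.null(lead)) return(NULL)
  pair <- harmonize(protein_stats[protein_stats$snp_id == lead$snp_id, ,
                                  drop = FALSE],
                    disease_stats,
                    palindrome_maf = config$selection$palindrome_maf)
  if (nrow(pair) == 0L) return(NULL)
  list(lead = lead, pair = pair, result = wald_ratio(pair))
}

#' Proteome-wide discovery screen
#'
#' One Wald-ratio MR per protein at its lead cis-pQTL; significance at the
#' Bonferroni threshold `alpha / n_tested`, where `n_tested` counts only
#' proteins with a valid harmonized lead instrument.
#'
#' @param panel a `simulated_panel`, or a list with `studies` (each having
#'   `protein_stats`, `disease_stats`, `gene`) — a shared outcome table may
#'   be supplied via `disease_stats`.
#' @param config [pipeline_config()].
#' @param disease_stats optional shared outcome `summary_stats` overriding
#'   each study's own.
#' @return data.frame of class `discovery_result`: one row per tested
#'   protein with `protein_id, snp_id, beta, se, p, or_, ci_low, ci_high,
#'   f_stat, significant`; attributes `n_tested`, `threshold`,
#'   `n_no_instrument`.
#' @export
discovery_screen <- function(panel, config = pipeline_config(),
                             disease_stats = NULL) {
  studies <- panel$studies
  stopifnot(length(studies) >= 1)
  rows <- list()
  n_no_instrument <- 0L
  for (pid in names(studies)) {
    s <- studies[[pid]]
    outcome <- disease_stats %||% s$disease_stats
    lw <- lead_wald(s$protein_stats, outcome, s$gene, config)
    if (is.null(lw)) {
      n_no_instrument <- n_no_instrument + 1L
      next
    }
    r <- lw$result
    rows[[pid]] <- data.frame(protein_id = pid, snp_id = lw$lead$snp_id,
                              beta = r$beta, se = r$se, p = r$p,
                              or_ = r$or_, ci_low = r$ci_low,
                              ci_high = r$ci_high,
                              f_stat = lw$lead$f_stat,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), snp_id = character(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      or_ = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), f_stat = numeric(0))
  }
  n_tested <- nrow(out)
  threshold <- if (n_tested > 0) bonferroni_threshold(config$alpha, n_tested)
  else NA_real_
  out$significant <- out$p < threshold
  rownames(out) <- NULL
  structure(out, class = c("discovery_result", "data.frame"),
            n_tested = n_tested, threshold = threshold,
            n_no_instrument = n_no_instrument)
}

#' Multi-instrument confirmation for one protein
#'
#' Builds the clumped instrument set and runs IVW (primary), MR-Egger and
#' the weighted median when at least 3 instruments survive, plus
#' Cochran's Q when at least 2 do.  A protein whose set is empty is
#' reported as unconfirmable rather than raising an error.
#'
#' @param study element of a `simulated_panel` (list with `protein_stats`,
#'   `disease_stats`, `gene`, `ld`).
#' @param config [pipeline_config()].
#' @param disease_stats optional shared outcome table.
#' @param snp_protein_map optional cross-protein association map.
#' @return list: `instruments` (`instrument_set`), `ivw`, `egger`,
#'   `weighted_median` (`mr_result` or NULL), `q` (list or NULL),
#'   `confirmable` (logical).
#' @export
confirm_multi_instrument <- function(study, config = pipeline_config(),
                                     disease_stats = NULL,
                                     snp_protein_map = NULL) {
  outcome <- disease_stats %||% study$disease_stats
  set <- build_instrument_set(study$protein_stats, outcome, study$gene,
                              study$ld, config$selection, snp_protein_map)
  k <- nrow(set)
  if (k == 0L) {
    return(list(instruments = set, ivw = NULL, egger = NULL,
                weighted_median = NULL, q = NULL, confirmable = FALSE))
  }
  list(instruments = set,
       ivw = ivw(set),
       egger = if (k >= 3) mr_egger(set) else NULL,
       weighted_median = if (k >= 3)
         weighted_median(set, n_boot = config$wm_boot, seed = config$seed)
       else NULL,
       q = if (k >= 2) cochran_q(set) else NULL,
       confirmable = TRUE)
}

#' External replication of one protein
#'
#' Runs IVW (Wald for a single instrument) against each named replication
#' dataset; a dataset "passes" when `p < replication_p` and (by default)
#' the effect direction agrees with discovery.
#'
#' @param protein_id protein being replicated.
#' @param discovery_beta discovery-stage effect estimate (for direction
#'   concordance).
#' @param replication_datasets named list; each element a list with
#'   `protein_stats`, `disease_stats`, `gene`, `ld` for this protein.
#'   `NULL` elements (protein not assayed in that cohort) are skipped.
#' @param config [pipeline_config()].
#' @return list of class `replication_result`: `protein_id`, `results`
#'   (named list of `mr_result` or NULL), `pass` (named logical), `n_pass`,
#'   `available`.
#' @export
replicate_protein <- function(protein_id, discovery_beta,
                              replication_datasets,
                              config = pipeline_config()) {
  results <- list(); pass <- logical(0)
  for (nm in names(replication_datasets)) {
    ds <- replication_datasets[[nm]]
    if (is.null(ds)) { results[nm] <- list(NULL); next }
    set <- build_instrument_set(ds$protein_stats, ds$disease_stats, ds$gene,
                                ds$ld, config$selection)
    if (nrow(set) == 0L) { results[nm] <- list(NULL); next }
    res <- ivw(set)
    ok <- res$p < config$replication_p
    if (config$require_concordance) {
      ok <- ok && sign(res$beta) == sign(discovery_beta)
    }
    results[[nm]] <- res
    pass[nm] <- ok
  }
  usable <- !vapply(results, is.null, logical(1))
  structure(list(protein_id = protein_id, results = results,
                 pass = pass, n_pass = sum(pass),
                 available = any(usable)),
            class = "replication_result")
}

#' Reverse-causality adjudication rule
#'
#' Pure decision rule on the reverse-MR p-values.  Under the default
#' `"egger_gate"` rule a protein is flagged as reverse-causal only when
#' both reverse IVW and reverse MR-Egger reach `reverse_p`; an IVW-only
#' signal with a null Egger is annotated `"not considered reverse causal"`
#' (the adjudication applied to borderline IVW hits).  When Egger is
#' unavailable (< 3 instruments), IVW alone decides, annotated
#' low-confidence.
#'
#' @param ivw_p,egger_p reverse-MR p-values (`egger_p` may be NA).
#' @param config [pipeline_config()].
#' @return list: `flagged`, `annotation`, `low_confidence`.
#' @export
reverse_adjudicate <- function(ivw_p, egger_p, config = pipeline_config()) {
  egger_available <- !is.na(egger_p)
  if (!egger_available) {
    flagged <- ivw_p < config$reverse_p
    return(list(flagged = flagged,
                annotation = if (flagged) "ivw_only_low_confidence" else "none",
                low_confidence = TRUE))
  }
  ivw_sig <- ivw_p < config$reverse_p
  egger_sig <- egger_p < config$reverse_p
  if (config$reverse_rule == "ivw_only") {
    return(list(flagged = ivw_sig,
                annotation = if (ivw_sig) "ivw_significant" else "none",
                low_confidence = FALSE))
  }
  if (ivw_sig && !egger_sig) {
    return(list(flagged = FALSE, annotation = "not_considered_reverse_causal",
                low_confidence = FALSE))
  }
  list(flagged = ivw_sig && egger_sig,
       annotation = if (ivw_sig && egger_sig) "reverse_causal" else "none",
       low_confidence = FALSE)
}

#' Reverse Mendelian randomization (disease to protein)
#'
#' Instruments are disease-associated variants at genome-wide significance
#' (`p < 5e-8`), F >= 10, clumped at r^2 < 0.001, harmonized against the
#' protein as outcome.  Runs reverse IVW and (with >= 3 instruments)
#' reverse MR-Egger and applies [reverse_adjudicate()].
#'
#' @param disease_stats,protein_stats exposure (disease) and outcome
#'   (protein) `summary_stats`.
#' @param ld LD matrix covering the disease instruments.
#' @param config [pipeline_config()].
#' @return list of class `reverse_mr_result`: `ivw`, `egger`, `q`,
#'   `flagged`, `annotation`, `low_confidence`, `n_instruments`.
#' @export
reverse_mr <- function(disease_stats, protein_stats, ld,
                       config = pipeline_config()) {
  sig <- disease_stats[disease_stats$p < config$reverse_gwas_p, ,
                       drop = FALSE]
  if (nrow(sig)) {
    fs <- f_statistic(sig$eaf, sig$beta, sig$n)
    sig <- sig[fs$f_stat >= config$selection$f_min, , drop = FALSE]
    fstat <- fs$f_stat[fs$f_stat >= config$selection$f_min]
  } else fstat <- numeric(0)
  if (nrow(sig) == 0L) {
    return(structure(list(ivw = NULL, egger = NULL, q = NULL,
                          flagged = FALSE, annotation = "no_instruments",
                          low_confidence = TRUE, n_instruments = 0L),
                     class = "reverse_mr_result"))
  }
  kept <- clump(data.frame(snp_id = sig$snp_id, p = sig$p, f_stat = fstat),
                ld, config$selection$clump_r2)
  sig <- sig[match(kept, sig$snp_id), , drop = FALSE]
  pair <- harmonize(sig, protein_stats,
                    palindrome_maf = config$selection$palindrome_maf)
  if (nrow(pair) == 0L) {
    return(structure(list(ivw = NULL, egger = NULL, q = NULL,
                          flagged = FALSE, annotation = "no_instruments",
                          low_confidence = TRUE, n_instruments = 0L),
                     class = "reverse_mr_result"))
  }
  res_ivw <- ivw(pair)
  res_egger <- if (nrow(pair) >= 3) mr_egger(pair) else NULL
  q <- if (nrow(pair) >= 2) cochran_q(pair) else NULL
  adj <- reverse_adjudicate(res_ivw$p,
                            if (is.null(res_egger)) NA_real_ else res_egger$p,
                            config)
  structure(list(ivw = res_ivw, egger = res_egger, q = q,
                 flagged = adj$flagged, annotation = adj$annotation,
                 low_confidence = adj$low_confidence,
                 n_instruments = nrow(pair)),
            class = "reverse_mr_result")
}

#' LD-based horizontal-pleiotropy scan around one protein's lead pQTL
#'
#' Three steps: (1) find cis variants in high LD (`r^2 > neighbor_r2`)
#' with the focal protein's lead pQTL; (2) collect the other proteins
#' whose gene body overlaps the focal cis region; (3) MR each such protein
#' against the disease using its own cis-pQTL instruments (`p < 5e-8`,
#' F >= 10, clumped).  Proteins reaching `p < 0.05` are reported as
#' potential LD-mediated confounders; `clean` means none did.
#'
#' @param protein_id focal protein.
#' @param protein_stats_list named list of `summary_stats`, one per protein
#'   in the region (must include the focal protein).
#' @param disease_stats outcome table.
#' @param ld region LD matrix.
#' @param genes `gene_annotation` rows for all proteins considered.
#' @param config [pipeline_config()].
#' @return list of class `pleiotropy_scan_result`: `neighbor_snps`,
#'   `cis_proteins_tested`, `significant_confounders` (named list of
#'   `mr_result`), `clean`.
#' @export
pleiotropy_scan <- function(protein_id, protein_stats_list, disease_stats,
                            ld, genes, config = pipeline_config()) {
  gene <- genes[genes$protein_id == protein_id, , drop = FALSE]
  stopifnot(nrow(gene) == 1)
  focal <- protein_stats_list[[protein_id]]
  lead <- lead_cis_pqtl(focal, gene, config$selection)
  if (is.null(lead)) stop("focal protein has no lead instrument",
                          call. = FALSE)
  region <- cis_region(gene, config$selection$cis_window)

  cis_tab <- extract_region(focal, region)
  in_ld <- cis_tab$snp_id[cis_tab$snp_id %in% rownames(ld)]
  r2 <- ld[lead$snp_id, in_ld]^2
  neighbor_snps <- in_ld[r2 > config$neighbor_r2]

  overlaps <- genes$protein_id != protein_id &
    genes$chrom == region$chrom &
    genes$start <= region$end & genes$end >= region$start
  others <- genes$protein_id[overlaps]
  others <- intersect(others, names(protein_stats_list))

  confounders <- list()
  scan_cfg <- config$selection
  scan_cfg$p_instrument <- 5e-8
  for (op in others) {
    og <- genes[genes$protein_id == op, , drop = FALSE]
    set <- tryCatch(
      build_instrument_set(protein_stats_list[[op]], disease_stats, og, ld,
                           scan_cfg),
      error = function(e) NULL)
    if (is.null(set) || nrow(set) == 0L) next
    res <- ivw(set)
    if (res$p < 0.05) confounders[[op]] <- res
  }
  structure(list(protein_id = protein_id, lead_snp = lead$snp_id,
                 neighbor_snps = neighbor_snps,
                 cis_proteins_tested = others,
                 significant_confounders = confounders,
                 clean = length(confounders) == 0L),
            class = "pleiotropy_scan_result")
}

#' Evidence tier for one discovery-significant protein
#'
#' Total and mutually exclusive rules: tier 3 when no replication data are
#' available; tier 4 when replication data exist but no dataset passes;
#' tier 1 when at least two datasets pass and colocalization is robust
#' (PPH4 above `pph4_robust` at the primary p12); tier 2 otherwise.
#'
#' @param protein_id protein.
#' @param replication a `replication_result` (or list with `available`,
#'   `n_pass`).
#' @param pph4 PPH4 at the primary p12 prior.
#' @param config [pipeline_config()].
#' @return list of class `tier_assignment`: `protein_id`, `tier` (integer
#'   1-4), `rationale` (named logical flags).
#' @export
assign_tier <- function(protein_id, replication, pph4,
                        config = pipeline_config()) {
  available <- isTRUE(replication$available)
  n_pass <- if (available) replication$n_pass else 0L
  coloc_robust <- !is.na(pph4) && pph4 > config$pph4_robust
  tier <- if (!available) 3L
  else if (n_pass == 0L) 4L
  else if (n_pass >= 2L && coloc_robust) 1L
  else 2L
  structure(list(protein_id = protein_id, tier = tier,
                 rationale = c(replication_available = available,
                               replicated = n_pass >= 2L,
                               coloc_robust = coloc_robust)),
            class = "tier_assignment")
}

#' Run the full target-discovery pipeline on a panel
#'
#' Discovery screen, then for each Bonferroni-significant protein:
#' multi-instrument confirmation, SMR at the lead pQTL, replication (when
#' datasets are supplied), reverse MR, colocalization with p12 sensitivity,
#' and tier assignment.  Deterministic for a fixed `config$seed`.
#'
#' @param panel a `simulated_panel` (or equivalently shaped list).
#' @param config [pipeline_config()].
#' @param replication_panels optional named list of panels with the same
#'   protein ids, used as external replication datasets.
#' @return list of class `target_report_input` with per-stage results and
#'   the `discovery` table.
#' @export
run_target_pipeline <- function(panel, config = pipeline_config(),
                                replication_panels = NULL) {
  discovery <- discovery_screen(panel, config)
  hits <- discovery$protein_id[discovery$significant]
  per_protein <- list()
  for (pid in hits) {
    s <- panel$studies[[pid]]
    conf <- confirm_multi_instrument(s, config)
    lw <- lead_wald(s$protein_stats, s$disease_stats, s$gene, config)
    smr <- if (!is.null(lw)) {
      smr_test(list(beta = lw$pair$beta_x, se = lw$pair$se_x),
               list(beta = lw$pair$beta_y, se = lw$pair$se_y))
    }
    repl <- if (!is.null(replication_panels)) {
      datasets <- lapply(replication_panels, function(rp) rp$studies[[pid]])
      replicate_protein(pid, discovery$beta[discovery$protein_id == pid],
                        datasets, config)
    } else {
      structure(list(protein_id = pid, results = list(), pass = logical(0),
                     n_pass = 0L, available = FALSE),
                class = "replication_result")
    }
    rev <- reverse_mr(s$disease_stats, s$protein_stats, s$ld, config)
    col <- coloc_region(s$protein_stats, s$disease_stats, s$gene,
                        window = config$coloc_window,
                        priors = config$coloc_priors,
                        p12_sensitivity = config$p12_sensitivity)
    tier <- assign_tier(pid, repl, unname(col$primary$pph["pph4"]), config)
    per_protein[[pid]] <- list(confirm = conf, smr = smr,
                               replication = repl, reverse = rev,
                               coloc = col, tier = tier)
  }
  structure(list(discovery = discovery, per_protein = per_protein,
                 config = config),
            class = "target_report_input")
}

#' Compile the wide per-protein report
#'
#' One row per discovery-significant protein: discovery p, per-dataset
#' "OR (95% CI)" and p, reverse-MR p, PPH4 at both p12 priors as "x/y",
#' and the tier.  A JSON provenance blob (seed, thresholds, package
#' version) is attached as the `"provenance"` attribute.
#'
#' @param pipeline output of [run_target_pipeline()].
#' @return data.frame of class `target_report`.
#' @export
compile_report <- function(pipeline) {
  per <- pipeline$per_protein
  rows <- lapply(names(per), function(pid) {
    x <- per[[pid]]
    disc <- pipeline$discovery[pipeline$discovery$protein_id == pid, ]
    repl_p <- vapply(x$replication$results, function(r)
      if (is.null(r)) NA_real_ else r$p, numeric(1))
    best_repl <- if (length(repl_p) && any(!is.na(repl_p)))
      min(repl_p, na.rm = TRUE) else NA_real_
    data.frame(
      protein_id = pid,
      or_ci = format_or_ci(disc$or_, disc$ci_low, disc$ci_high),
      p_discovery = disc$p,
      p_replication = best_repl,
      n_replication_pass = x$replication$n_pass,
      p_reverse = if (is.null(x$reverse$ivw)) NA_real_ else x$reverse$ivw$p,
      reverse_flagged = x$reverse$flagged,
      pph4 = sprintf("%.3f/%.3f",
                     x$coloc$primary$pph["pph4"],
                     x$coloc$sensitivity$pph["pph4"]),
      smr_p = if (is.null(x$smr)) NA_real_ else x$smr$p,
      q_p = if (is.null(x$confirm$q)) NA_real_ else x$confirm$q$p,
      tier = paste0("Tier", x$tier$tier),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), or_ci = character(0),
               p_discovery = numeric(0), p_replication = numeric(0),
               n_replication_pass = integer(0), p_reverse = numeric(0),
               reverse_flagged = logical(0), pph4 = character(0),
               smr_p = numeric(0), q_p = numeric(0), tier = character(0))
  rownames(out) <- NULL
  cfg <- pipeline$config
  prov <- jsonlite::toJSON(list(
    seed = cfg$seed, alpha = cfg$alpha,
    p_instrument = cfg$selection$p_instrument,
    clump_r2 = cfg$selection$clump_r2, f_min = cfg$selection$f_min,
    cis_window = cfg$selection$cis_window,
    coloc_window = cfg$coloc_window,
    p12 = cfg$coloc_priors$p12, p12_sensitivity = cfg$p12_sensitivity,
    pph4_robust = cfg$pph4_robust,
    n_tested = attr(pipeline$discovery, "n_tested"),
    threshold = attr(pipeline$discovery, "threshold"),
    package_version = as.character(utils::packageVersion("pqtlmr"))),
    auto_unbox = TRUE, digits = NA)
  structure(out, class = c("target_report", "data.frame"),
            provenance = prov)
}
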