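# Synthetic summary-statistics and single-cell count generators.
#
# The GWAS simulator works on the standardized-genotype, standardized-trait
# scale: with LD correlation matrix R and a single causal variant with
# standardized effect b, the vector of true marginal effects is R[, causal]*b
# and the sampling distribution of the estimated standardized betas is
# MVN(mean = true marginals, cov = R/N).  Reported effects are rescaled per
# SNP to the allele-dosage scale, beta_j = beta_std_j / sqrt(2 f_j (1-f_j)),
# so the reported standard error is exactly 1/sqrt(2 f_j (1-f_j) N).
# Z-scores (and hence p-values, F statistics, ratio estimates, ABFs) are
# identical on the two scales.

SCENARIOS <- c("H0", "H1", "H2", "H3", "H4")

#' Scenario configuration for a simulated cis region
#'
#' Defaults mirror the study design the generator emulates: a ~54k-sample
#' proteomic exposure GWAS and a ~10k-case / ~400k-control disease GWAS
#' (effective N about 40k), AR(1) local LD with adjacent-SNP correlation
#' 0.9, a single causal cis-pQTL of 0.15 SD per allele, and a causal
#' protein-to-disease effect of 0.2 log-odds per SD.
#'
#' @param n_snps number of variants in the region.
#' @param ld_rho AR(1) adjacent-SNP correlation, in `[0, 1)`.
#' @param n_exposure exposure (protein) GWAS sample size.
#' @param n_case,n_control disease GWAS case/control counts; the effective
#'   sample size `4*n_case*n_control/(n_case+n_control)` scales the disease
#'   sampling variance.
#' @param scenario causal configuration: `"H0"` no signal, `"H1"`
#'   protein-only, `"H2"` disease-only, `"H3"` distinct causal variants,
#'   `"H4"` one shared causal variant.
#' @param b_protein causal pQTL effect (standardized trait SD per
#'   standardized genotype).
#' @param theta causal protein-to-disease effect (log odds per SD of
#'   protein), the estimand of every MR operation.
#' @param direct_effect extra pleiotropic disease effect at the disease
#'   causal variant (log-odds scale), added on top of `theta * b_protein`.
#' @param seed integer seed; the same config is bit-reproducible.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_snps = 100, ld_rho = 0.9,
                            n_exposure = 54219,
                            n_case = 10312, n_control = 397564,
                            scenario = "H4",
                            b_protein = 0.15, theta = 0.2,
                            direct_effect = 0, seed = 1L) {
  stopifnot(ld_rho >= 0, ld_rho < 1, n_snps >= 1,
            n_exposure >= 2, n_case >= 2, n_control >= 2,
            scenario %in% SCENARIOS)
  structure(list(n_snps = as.integer(n_snps), ld_rho = ld_rho,
                 n_exposure = n_exposure, n_case = n_case,
                 n_control = n_control, scenario = scenario,
                 b_protein = b_protein, theta = theta,
                 direct_effect = direct_effect, seed = as.integer(seed)),
            class = "scenario_config")
}

#' AR(1) linkage-disequilibrium matrix
#'
#' `r[i, j] = rho^|i - j|`: symmetric, unit diagonal and positive definite
#' for `rho` in `[0, 1)`.  Row/column names are the SNP ids.
#'
#' @param n_snps number of variants.
#' @param rho adjacent-variant allelic correlation in `[0, 1)`.
#' @param snp_ids optional ids (default `rs1..rsn`).
#' @return numeric matrix with snp ids as dimnames.
#' @export
make_ld_matrix <- function(n_snps, rho, snp_ids = NULL) {
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("`rho` must be in [0, 1)", call. = FALSE)
  }
  idx <- seq_len(n_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  snp_ids <- snp_ids %||% paste0("rs", idx)
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

# Draw one trait's summary statistics given the region layout.
# true_std: vector of true marginal standardized effects; chol_r: upper
# Cholesky factor of the LD matrix.
draw_trait_stats <- function(true_std, eaf, n, chol_r) {
  m <- length(true_std)
  z <- as.vector(stats::rnorm(m) %*% chol_r)   # MVN(0, R)
  beta_std <- true_std + z / sqrt(n)
  scale_f <- sqrt(2 * eaf * (1 - eaf))
  beta <- beta_std / scale_f
  se <- 1 / (scale_f * sqrt(n))
  p <- two_sided_p(beta / se)
  list(beta = beta, se = se, p = p)
}

#' Simulate a cis region: protein + disease summary statistics with LD
#'
#' Draws effect-allele frequencies from Uniform(0.05, 0.5), places the
#' causal variant(s) deterministically (protein at ~1/3 of the region under
#' H1/H3, disease at ~2/3 under H2/H3, both at the region midpoint under
#' H4), and samples estimated effects from the multivariate normal
#' summary-statistic model described above.  The disease's true effect at
#' its causal variant is `theta * b_protein + direct_effect` (under H4 this
#' is the mediated effect through the protein plus any direct pleiotropy).
#' A gene body is placed around the protein causal variant so that the
#' default 1 Mb cis window covers the region.
#'
#' @param config a [scenario_config()].
#' @param chrom chromosome label for the region.
#' @param pos_start position of the first variant (bp).
#' @param spacing distance between adjacent variants (bp).
#' @param protein_id,snp_prefix identifiers used in the generated tables.
#' @return list of class `simulated_study` with elements `protein_stats`,
#'   `disease_stats` (both `summary_stats`), `ld` (matrix), `gene`
#'   (one-row `gene_annotation`) and `truth` (causal snp ids, theta,
#'   scenario, and the true marginal standardized effect vectors).
#' @export
simulate_region <- function(config, chrom = "1", pos_start = 1e6,
                            spacing = 5000, protein_id = "PROT1",
                            snp_prefix = "rs") {
  stopifnot(inherits(config, "scenario_config"))
  m <- config$n_snps
  snp_ids <- paste0(snp_prefix, seq_len(m))
  r <- make_ld_matrix(m, config$ld_rho, snp_ids)
  chol_r <- chol(r)
  pos <- as.integer(pos_start + (seq_len(m) - 1L) * spacing)

  idx_mid <- max(1L, as.integer(ceiling(m / 2)))
  idx_lo <- max(1L, as.integer(ceiling(m / 3)))
  idx_hi <- max(1L, as.integer(ceiling(2 * m / 3)))
  causal_x <- switch(config$scenario,
                     H0 = NA_integer_, H2 = NA_integer_,
                     H1 = idx_lo, H3 = idx_lo, H4 = idx_mid)
  causal_y <- switch(config$scenario,
                     H0 = NA_integer_, H1 = NA_integer_,
                     H2 = idx_hi, H3 = idx_hi, H4 = idx_mid)

  gamma <- config$theta * config$b_protein + config$direct_effect
  true_x <- if (is.na(causal_x)) rep(0, m) else r[, causal_x] * config$b_protein
  true_y <- if (is.na(causal_y)) rep(0, m) else r[, causal_y] * gamma

  n_eff <- 4 * config$n_case * config$n_control /
    (config$n_case + config$n_control)

  sim <- with_seed(config$seed, {
    eaf <- stats::runif(m, 0.05, 0.5)
    px <- draw_trait_stats(true_x, eaf, config$n_exposure, chol_r)
    py <- draw_trait_stats(true_y, eaf, n_eff, chol_r)
    list(eaf = eaf, px = px, py = py)
  })

  mk <- function(tr, n, type) {
    summary_stats(data.frame(snp_id = snp_ids, chrom = chrom, pos = pos,
                             ea = "A", oa = "G", eaf = sim$eaf,
                             beta = tr$beta, se = tr$se, p = tr$p, n = n),
                  trait_id = if (type == "quantitative") protein_id
                             else "disease",
                  trait_type = type,
                  n_case = if (type == "binary") config$n_case else NULL,
                  n_control = if (type == "binary") config$n_control else NULL)
  }
  gene_anchor <- if (!is.na(causal_x)) causal_x else idx_mid
  gene <- gene_annotation(gene_id = paste0(protein_id, "_gene"),
                          protein_id = protein_id, chrom = chrom,
                          start = max(1, pos[gene_anchor] - spacing),
                          end = pos[gene_anchor] + spacing)
  structure(list(
    protein_stats = mk(sim$px, config$n_exposure, "quantitative"),
    disease_stats = mk(sim$py, n_eff, "binary"),
    ld = r,
    gene = gene,
    truth = list(causal_snp_protein = if (is.na(causal_x)) NA_character_
                                      else snp_ids[causal_x],
                 causal_snp_disease = if (is.na(causal_y)) NA_character_
                                      else snp_ids[causal_y],
                 theta = config$theta, scenario = config$scenario,
                 true_marginal_protein = true_x,
                 true_marginal_disease = true_y)),
    class = "simulated_study")
}

#' Simulate a protein panel of independent cis regions
#'
#' `ceil(frac_causal * n_proteins)` proteins are simulated under H4 (shared
#' causal variant, `theta` from `base_config`); the remainder under H1
#' (real cis-pQTL, null disease effect).  Regions are independent: each
#' protein gets its own chromosome label and SNP id prefix.
#'
#' @param n_proteins number of proteins.
#' @param frac_causal fraction with a true causal effect on disease.
#' @param base_config [scenario_config()] template; per-region seeds are
#'   derived from `seed`.
#' @param seed integer master seed.
#' @return list of class `simulated_panel` with `studies` (named list of
#'   `simulated_study`), `truth` (one row per protein: protein_id, scenario,
#'   theta, causal snp ids) and `genes` (combined `gene_annotation`).
#' @export
simulate_panel <- function(n_proteins, frac_causal,
                           base_config = scenario_config(), seed = 1L) {
  stopifnot(frac_causal >= 0, frac_causal <= 1, n_proteins >= 1)
  n_causal <- as.integer(ceiling(frac_causal * n_proteins))
  studies <- vector("list", n_proteins)
  ids <- sprintf("PROT%03d", seq_len(n_proteins))
  for (i in seq_len(n_proteins)) {
    cfg <- base_config
    cfg$scenario <- if (i <= n_causal) "H4" else "H1"
    if (cfg$scenario == "H1") cfg$theta <- 0
    cfg$seed <- as.integer((as.numeric(seed) + 7919 * i) %%
                             .Machine$integer.max)
    studies[[i]] <- simulate_region(cfg, chrom = as.character(i),
                                    protein_id = ids[i],
                                    snp_prefix = sprintf("rs%03d_", i))
  }
  names(studies) <- ids
  truth <- data.frame(
    protein_id = ids,
    scenario = vapply(studies, function(s) s$truth$scenario, character(1)),
    theta = vapply(studies, function(s) s$truth$theta, numeric(1)),
    causal_snp_protein = vapply(studies, function(s)
      s$truth$causal_snp_protein, character(1)),
    causal_snp_disease = vapply(studies, function(s)
      s$truth$causal_snp_disease, character(1)),
    stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(studies, function(s) s$gene))
  class(genes) <- c("gene_annotation", "data.frame")
  rownames(genes) <- NULL
  structure(list(studies = studies, truth = truth, genes = genes),
            class = "simulated_panel")
}

#' Simulate negative-binomial single-cell counts
#'
#' Generates a genes-by-cells sparse integer count matrix with case/control
#' conditions and labelled cell types.  Baseline per-gene means are
#' log-normal, scaled so the expected per-cell depth equals `depth`; a DE
#' gene's mean is multiplied by `2^log2_effect` in its (cell type,
#' condition) stratum; counts are negative binomial with the given
#' dispersion (`size = 1/dispersion`).
#'
#' @param n_genes number of genes.
#' @param cells_per_type named integer vector: cells per cell type, per
#'   condition (each condition gets this many cells of each type).
#' @param de_genes data.frame with columns `gene`, `cell_type`, `condition`,
#'   `log2_effect` (may be empty / NULL).
#' @param dispersion NB dispersion (1/size); 0.5 is typical droplet data.
#' @param depth expected total counts per cell.
#' @param seed integer seed.
#' @return list with `counts` (dgCMatrix, genes x cells) and `annotation`
#'   (data.frame: barcode, condition, cell_type, sample_id).
#' @export
simulate_counts <- function(n_genes, cells_per_type, de_genes = NULL,
                            dispersion = 0.5, depth = 5000, seed = 1L) {
  stopifnot(depth > 0, n_genes >= 1, !is.null(names(cells_per_type)))
  conditions <- c("case", "control")
  ann <- do.call(rbind, lapply(conditions, function(cond) {
    do.call(rbind, lapply(names(cells_per_type), function(ct) {
      k <- cells_per_type[[ct]]
      data.frame(condition = cond, cell_type = ct,
                 sample_id = paste0(cond, "_s1"),
                 stringsAsFactors = FALSE)[rep(1, k), , drop = FALSE]
    }))
  }))
  ann$barcode <- sprintf("cell%05d", seq_len(nrow(ann)))
  rownames(ann) <- NULL
  ann <- ann[, c("barcode", "condition", "cell_type", "sample_id")]
  genes <- sprintf("gene%04d", seq_len(n_genes))

  counts <- with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
    base <- base / sum(base) * depth          # expected depth per cell
    mu <- matrix(base, nrow = n_genes, ncol = nrow(ann))
    if (!is.null(de_genes) && nrow(de_genes)) {
      for (k in seq_len(nrow(de_genes))) {
        gi <- match(de_genes$gene[k], genes)
        if (is.na(gi)) stop("DE gene not in matrix: ", de_genes$gene[k],
                            call. = FALSE)
        cells <- ann$cell_type == de_genes$cell_type[k] &
          ann$condition == de_genes$condition[k]
        mu[gi, cells] <- mu[gi, cells] * 2^de_genes$log2_effect[k]
      }
    }
    m <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                               size = 1 / dispersion),
                nrow = n_genes)
    m
  })
  dimnames(counts) <- list(genes, ann$barcode)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       annotation = ann)
}

#' Write a count matrix as MatrixMarket + sidecar files
#'
#' Writes `matrix.mtx` (coordinate integer), `features.tsv`, `barcodes.tsv`
#' and `annotation.tsv` into `dir`.
#'
#' @param sim output of [simulate_counts()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sim$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sim$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(sim$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#' @param dir directory containing matrix.mtx, features.tsv, barcodes.tsv
#'   and optionally annotation.tsv.
#' @return list with `counts` (dgCMatrix) and `annotation` (or NULL).
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  dimnames(counts) <- list(readLines(file.path(dir, "features.tsv")),
                           readLines(file.path(dir, "barcodes.tsv")))
  ann_path <- file.path(dir, "annotation.tsv")
  ann <- if (file.exists(ann_path)) {
    utils::read.delim(ann_path, stringsAsFactors = FALSE)
  }
  list(counts = counts, annotation = ann)
}
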