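# Single-cell candidate-gene screen: QC filtering, CP10K-log1p
# normalization, Wilcoxon rank-sum differential expression, and the
# candidate-specificity table.

#' Quality-control filter for a sparse count matrix
#'
#' Retains genes expressed (count > 0) in at least `min_cells` cells, then
#' cells retaining at least `min_features` expressed genes, in that order.
#' Idempotent.  The before/after dimensions are attached as the
#' `"qc_report"` attribute.
#'
#' @param m genes-by-cells sparse (or dense) nonnegative integer matrix
#'   with dimnames.
#' @param min_cells minimum cells per gene (default 3).
#' @param min_features minimum expressed genes per cell (default 200).
#' @return filtered matrix with a `"qc_report"` attribute.
#' @export
qc_filter <- function(m, min_cells = 3, min_features = 200) {
  genes_before <- nrow(m); cells_before <- ncol(m)
  gene_cells <- Matrix::rowSums(m > 0)
  m2 <- m[gene_cells >= min_cells, , drop = FALSE]
  cell_features <- Matrix::colSums(m2 > 0)
  m2 <- m2[, cell_features >= min_features, drop = FALSE]
  report <- c(genes_before = genes_before, cells_before = cells_before,
              genes_after = nrow(m2), cells_after = ncol(m2))
  if (nrow(m2) == 0L || ncol(m2) == 0L) {
    stop("matrix empty after QC (", paste(names(report), report,
                                          sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  attr(m2, "qc_report") <- report
  m2
}

#' CP10K-log1p normalization
#'
#' Per cell: `x -> ln(1 + 10000 * x / total_counts)`.  Depth-invariant:
#' doubling every count in a cell leaves the result unchanged.
#'
#' @param m QC-filtered genes-by-cells count matrix.
#' @param scale_factor library-size target (default 1e4).
#' @return sparse normalized expression matrix.
#' @export
normalize_cp10k <- function(m, scale_factor = 1e4) {
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) stop("cell with zero total counts", call. = FALSE)
  scaled <- m %*% Matrix::Diagonal(x = scale_factor / totals)
  out <- scaled
  out@x <- log1p(out@x)   # sparse: zeros map to log1p(0) = 0
  dimnames(out) <- dimnames(m)
  out
}

# Tie-corrected normal-approximation rank-sum test for one numeric vector
# split by a logical group indicator; returns W (rank sum of group A),
# U, z and the two-sided p (no continuity correction).
rank_sum_test <- function(x, in_a) {
  n_a <- sum(in_a); n_b <- sum(!in_a)
  r <- rank(x)
  w <- sum(r[in_a])
  u <- w - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  n <- n_a + n_b
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  v <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(w = w, u = u, z = 0, p = 1))
  z <- (u - mu) / sqrt(v)
  list(w = w, u = u, z = z, p = two_sided_p(z))
}

#' Wilcoxon rank-sum differential expression
#'
#' Two-sided tie-corrected normal-approximation rank-sum test per gene
#' between two cell groups on normalized expression, with
#' `log2fc = log2((mean expm1(A) + eps) / (mean expm1(B) + eps))`
#' (natural-scale means, pseudocount 1e-9) and the fraction of cells
#' expressing in each group.  Bonferroni correction is over the genes
#' tested in the call.
#'
#' @param expr normalized genes-by-cells matrix (see [normalize_cp10k()]).
#' @param cells_a,cells_b barcodes (or column indices) of the two groups.
#' @param genes optional subset of genes to test (default all).
#' @param n_tests Bonferroni denominator (default: number of genes tested;
#'   pass a larger value when combining comparisons).
#' @return data.frame: `gene, log2fc, p, p_bonf, pct_a, pct_b, w_stat,
#'   unreliable` (flag set when a group has fewer than 3 cells).
#' @export
wilcoxon_de <- function(expr, cells_a, cells_b, genes = NULL,
                        n_tests = NULL) {
  a <- expr[, cells_a, drop = FALSE]
  b <- expr[, cells_b, drop = FALSE]
  if (ncol(a) == 0L || ncol(b) == 0L) stop("empty group", call. = FALSE)
  genes <- genes %||% rownames(expr)
  genes <- intersect(genes, rownames(expr))
  n_tests <- n_tests %||% length(genes)
  unreliable <- ncol(a) < 3 || ncol(b) < 3
  eps <- 1e-9
  rows <- lapply(genes, function(g) {
    xa <- as.numeric(a[g, ]); xb <- as.numeric(b[g, ])
    ts <- rank_sum_test(c(xa, xb),
                        c(rep(TRUE, length(xa)), rep(FALSE, length(xb))))
    data.frame(gene = g,
               log2fc = log2((mean(expm1(xa)) + eps) /
                               (mean(expm1(xb)) + eps)),
               p = ts$p, p_bonf = min(1, ts$p * n_tests),
               pct_a = mean(xa > 0), pct_b = mean(xb > 0),
               w_stat = ts$w, unreliable = unreliable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate-gene expression screen
#'
#' For each candidate gene: detection flags per condition (any nonzero
#' count), the case-vs-control DE result, per-cell-type one-vs-rest DE
#' within each condition, and a cell-type specificity call — the gene is
#' "specific to cell type T in condition C" when its one-vs-rest test in C
#' is significant (`log2fc > lfc_min`, Bonferroni p < `alpha`) and the
#' same test in the other condition is not.
#'
#' @param counts QC-filtered genes-by-cells count matrix (used for
#'   detection flags).
#' @param expr normalized matrix from [normalize_cp10k()].
#' @param ann annotation data.frame with `barcode`, `condition`
#'   (case/control), `cell_type`.
#' @param candidate_genes character vector; genes absent from the matrix
#'   get a row with `detected_case = detected_control = FALSE`.
#' @param lfc_min log2 fold-change threshold (default 0.5).
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @return data.frame of class `candidate_screen`: one row per candidate
#'   with detection flags, case-vs-control `log2fc`/`p_bonf`, and
#'   `specific_celltype`/`specific_condition` (NA when no call).  The full
#'   per-cell-type DE tables are in the `"celltype_de"` attribute.
#' @export
candidate_screen <- function(counts, expr, ann, candidate_genes,
                             lfc_min = 0.5, alpha = 0.05) {
  stopifnot(all(ann$barcode %in% colnames(expr)))
  present <- candidate_genes[candidate_genes %in% rownames(expr)]
  case_cells <- ann$barcode[ann$condition == "case"]
  ctrl_cells <- ann$barcode[ann$condition == "control"]
  cell_types <- sort(unique(ann$cell_type))
  # Bonferroni over every comparison run in this call
  n_comparisons <- length(present) * (1 + 2 * length(cell_types))

  cc_de <- if (length(present)) {
    wilcoxon_de(expr, case_cells, ctrl_cells, genes = present,
                n_tests = n_comparisons)
  }
  ct_de <- list()
  for (cond in c("case", "control")) {
    cond_cells <- ann$barcode[ann$condition == cond]
    for (ct in cell_types) {
      in_ct <- ann$barcode[ann$condition == cond & ann$cell_type == ct]
      rest <- setdiff(cond_cells, in_ct)
      if (length(in_ct) == 0L || length(rest) == 0L || !length(present)) next
      ct_de[[paste(cond, ct, sep = ":")]] <-
        wilcoxon_de(expr, in_ct, rest, genes = present,
                    n_tests = n_comparisons)
    }
  }

  rows <- lapply(candidate_genes, function(g) {
    if (!(g %in% present)) {
      return(data.frame(gene = g, detected_case = FALSE,
                        detected_control = FALSE, log2fc = NA_real_,
                        p_bonf = NA_real_, de_significant = FALSE,
                        specific_celltype = NA_character_,
                        specific_condition = NA_character_,
                        stringsAsFactors = FALSE))
    }
    det_case <- any(counts[g, case_cells] > 0)
    det_ctrl <- any(counts[g, ctrl_cells] > 0)
    cc <- cc_de[cc_de$gene == g, ]
    sig_in <- function(cond, ct) {
      tab <- ct_de[[paste(cond, ct, sep = ":")]]
      if (is.null(tab)) return(FALSE)
      row <- tab[tab$gene == g, ]
      nrow(row) == 1 && row$log2fc > lfc_min && row$p_bonf < alpha
    }
    spec_ct <- NA_character_; spec_cond <- NA_character_
    for (cond in c("case", "control")) {
      other <- setdiff(c("case", "control"), cond)
      for (ct in cell_types) {
        if (sig_in(cond, ct) && !sig_in(other, ct)) {
          spec_ct <- ct; spec_cond <- cond
          break
        }
      }
      if (!is.na(spec_ct)) break
    }
    data.frame(gene = g, detected_case = det_case,
               detected_control = det_ctrl,
               log2fc = cc$log2fc, p_bonf = cc$p_bonf,
               de_significant = abs(cc$log2fc) > lfc_min &
                 cc$p_bonf < alpha,
               specific_celltype = spec_ct, specific_condition = spec_cond,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("candidate_screen", "data.frame"),
            celltype_de = ct_de)
}
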