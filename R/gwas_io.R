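# Reading, validating, writing and harmonizing GWAS/pQTL summary statistics.
#
# A summary-statistics table is a data.frame with columns
#   snp_id, chrom, pos, ea, oa, eaf, beta, se, p, n
# sorted by (chrom, pos), with attributes trait_id, trait_type
# ("quantitative" or "binary") and, for binary traits, n_case / n_control.
# Coordinates are 1-based inclusive. For binary traits `n` holds the
# effective sample size 4*n_case*n_control/(n_case+n_control).

SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "ea", "oa",
                  "eaf", "beta", "se", "p", "n")
FILE_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated summary-statistics table
#'
#' Builds the package's universal interchange object for per-variant
#' association records of one trait.  Rows violating the per-variant
#' invariants (alleles in A/C/G/T with `ea != oa`, `0 < eaf < 1`, `se > 0`,
#' `0 < p <= 1`) are dropped; the drop counts are attached as the
#' `"validation_report"` attribute.  Rows are sorted by (chrom, pos) and
#' `snp_id` must be unique after validation.
#'
#' @param df data.frame with columns `snp_id, chrom, pos, ea, oa, eaf, beta,
#'   se, p, n` (extra columns are kept).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"quantitative"` (e.g. protein levels, effects in SD
#'   units) or `"binary"` (effects are log odds ratios).
#' @param n_case,n_control case/control counts for binary traits.  When
#'   given, the effective sample size `4*n_case*n_control/(n_case+n_control)`
#'   replaces `n`.
#' @return A `summary_stats` data.frame.
#' @export
summary_stats <- function(df, trait_id = "trait",
                          trait_type = c("quantitative", "binary"),
                          n_case = NULL, n_control = NULL) {
  trait_type <- match.arg(trait_type)
  missing_cols <- setdiff(SUMSTAT_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  for (col in c("eaf", "beta", "se", "p", "n")) df[[col]] <- as.numeric(df[[col]])

  n_in <- nrow(df)
  bad_allele <- !(df$ea %in% VALID_ALLELES) | !(df$oa %in% VALID_ALLELES) |
    df$ea == df$oa
  bad_eaf <- is.na(df$eaf) | df$eaf <= 0 | df$eaf >= 1
  bad_se <- is.na(df$se) | df$se <= 0
  bad_p <- is.na(df$p) | df$p <= 0 | df$p > 1
  bad_other <- is.na(df$beta) | is.na(df$n) | is.na(df$pos)
  keep <- !(bad_allele | bad_eaf | bad_se | bad_p | bad_other)
  report <- c(n_input = n_in,
              dropped_allele = sum(bad_allele),
              dropped_eaf = sum(bad_eaf & !bad_allele),
              dropped_se = sum(bad_se & !bad_allele & !bad_eaf),
              dropped_p = sum(bad_p & !bad_allele & !bad_eaf & !bad_se),
              dropped_na = sum(bad_other & !bad_allele & !bad_eaf & !bad_se &
                                 !bad_p),
              n_kept = sum(keep))
  df <- df[keep, , drop = FALSE]
  if (anyDuplicated(df$snp_id)) {
    stop("duplicated snp_id in summary statistics for trait ", trait_id,
         call. = FALSE)
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL

  if (trait_type == "binary" && !is.null(n_case) && !is.null(n_control)) {
    df$n <- 4 * n_case * n_control / (n_case + n_control)
  }
  structure(df,
            class = c("summary_stats", "data.frame"),
            trait_id = trait_id, trait_type = trait_type,
            n_case = n_case, n_control = n_control,
            validation_report = report)
}

#' Read a summary-statistics TSV
#'
#' Expects a tab-delimited file with header columns
#' `SNP CHR POS EA OA EAF BETA SE P N` in any order (case-insensitive);
#' optional `N_CASE`/`N_CONTROL` columns supply case/control counts for
#' binary traits.  Scientific notation and comma-grouped numbers are
#' accepted.  Invalid rows are dropped and counted in the
#' `"validation_report"` attribute of the result.
#'
#' @param path file path.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_id trait name; defaults to the file name.
#' @return A `summary_stats` table.
#' @export
read_summary_stats <- function(path,
                               trait_type = c("quantitative", "binary"),
                               trait_id = NULL) {
  trait_type <- match.arg(trait_type)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path,
                            call. = FALSE)
  names(raw) <- toupper(names(raw))
  missing_cols <- setdiff(FILE_COLS, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))
  df <- data.frame(snp_id = raw$SNP, chrom = raw$CHR, pos = num(raw$POS),
                   ea = raw$EA, oa = raw$OA, eaf = num(raw$EAF),
                   beta = num(raw$BETA), se = num(raw$SE), p = num(raw$P),
                   n = num(raw$N), stringsAsFactors = FALSE)
  n_case <- if ("N_CASE" %in% names(raw)) num(raw$N_CASE)[1] else NULL
  n_control <- if ("N_CONTROL" %in% names(raw)) num(raw$N_CONTROL)[1] else NULL
  summary_stats(df, trait_id = trait_id %||% basename(path),
                trait_type = trait_type,
                n_case = n_case, n_control = n_control)
}

#' Write a summary-statistics table as TSV
#'
#' Inverse of [read_summary_stats()]: writes the canonical header
#' `SNP CHR POS EA OA EAF BETA SE P N` with full double precision, so a
#' read-write-read round trip reproduces all numeric fields exactly.
#'
#' @param stats a `summary_stats` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.frame(SNP = stats$snp_id, CHR = stats$chrom, POS = stats$pos,
                    EA = stats$ea, OA = stats$oa,
                    EAF = format(stats$eaf, digits = 17, trim = TRUE),
                    BETA = format(stats$beta, digits = 17, trim = TRUE),
                    SE = format(stats$se, digits = 17, trim = TRUE),
                    P = format(stats$p, digits = 17, trim = TRUE),
                    N = format(stats$n, digits = 17, trim = TRUE))
  nc <- attr(stats, "n_case"); nctrl <- attr(stats, "n_control")
  if (!is.null(nc) && !is.null(nctrl)) {
    out$N_CASE <- nc
    out$N_CONTROL <- nctrl
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene annotation table
#'
#' @param gene_id,protein_id character vectors.
#' @param chrom chromosome labels.
#' @param start,end 1-based inclusive gene-body coordinates, `start <= end`.
#' @return data.frame with class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, protein_id = gene_id, chrom, start, end) {
  stopifnot(all(start <= end), all(start >= 1))
  structure(data.frame(gene_id = as.character(gene_id),
                       protein_id = as.character(protein_id),
                       chrom = as.character(chrom),
                       start = as.integer(start), end = as.integer(end),
                       stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

#' Read a gene-annotation TSV (`GENE PROTEIN CHR START END` header)
#' @param path file path.
#' @return A `gene_annotation` data.frame.
#' @export
read_gene_annotation <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  names(raw) <- toupper(names(raw))
  gene_annotation(raw$GENE, raw$PROTEIN, raw$CHR, raw$START, raw$END)
}

#' Cis region around a gene
#'
#' The cis window is measured from the gene-body boundaries: the region is
#' `[max(1, start - window), end + window]` on the gene's chromosome.  The
#' default 1 Mb window defines cis-pQTL eligibility; a 500 kb window is the
#' colocalization region.
#'
#' @param gene one-row `gene_annotation` (or list with chrom/start/end).
#' @param window window size in bp, `>= 0`.
#' @return list with `chrom`, `start`, `end` (1-based inclusive).
#' @export
cis_region <- function(gene, window = 1e6) {
  stopifnot(window >= 0)
  list(chrom = as.character(gene$chrom[1]),
       start = max(1, gene$start[1] - window),
       end = gene$end[1] + window)
}

#' Subset a summary-statistics table to a genomic region
#'
#' @param stats a `summary_stats` table.
#' @param region list with `chrom`, `start`, `end` (see [cis_region()]).
#' @return The subset (possibly empty), original order and attributes kept.
#' @export
extract_region <- function(stats, region) {
  keep <- stats$chrom == region$chrom &
    stats$pos >= region$start & stats$pos <= region$end
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("trait_id", "trait_type", "n_case", "n_control")) {
    attr(out, a) <- attr(stats, a)
  }
  class(out) <- class(stats)
  out
}

allele_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(ea, oa) allele_complement(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins the two tables on `snp_id` and aligns the outcome effect to
#' the exposure's effect allele.  Matching handles the four allele
#' orientations: identical, swapped (outcome beta negated, eaf
#' complemented), strand-complemented, and strand-complemented + swapped.
#' Palindromic SNPs (A/T or C/G) carry no strand information from alleles
#' alone, so they are aligned by allele frequency when both minor-allele
#' frequencies are below `palindrome_maf` and dropped otherwise; pairs with
#' incompatible alleles are dropped.  Every drop and flip is counted in the
#' `"harmonization_report"` attribute.
#'
#' @param exposure,outcome `summary_stats` tables.
#' @param palindrome_maf MAF threshold above which palindromic SNPs are
#'   considered frequency-ambiguous and dropped (default 0.42).
#' @return data.frame with one row per aligned SNP: `snp_id, chrom, pos, ea,
#'   oa, eaf_x, beta_x, se_x, p_x, n_x, eaf_y, beta_y, se_y, p_y, n_y`.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf = 0.42) {
  common <- intersect(exposure$snp_id, outcome$snp_id)
  ex <- exposure[match(common, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(common, outcome$snp_id), , drop = FALSE]

  n_in <- length(common)
  same <- ou$ea == ex$ea & ou$oa == ex$oa
  swapped <- ou$ea == ex$oa & ou$oa == ex$ea
  flip_ea <- allele_complement(ou$ea); flip_oa <- allele_complement(ou$oa)
  comp_same <- flip_ea == ex$ea & flip_oa == ex$oa
  comp_swapped <- flip_ea == ex$oa & flip_oa == ex$ea
  pal <- is_palindromic(ex$ea, ex$oa)

  action <- rep("incompatible", n_in)
  action[comp_swapped & !pal] <- "swap"
  action[comp_same & !pal] <- "keep"
  action[swapped & !pal] <- "swap"
  action[same & !pal] <- "keep"

  # Palindromic: alleles always "match"; orient by frequency when both
  # traits' MAFs are safely below 0.5, otherwise drop as ambiguous.
  if (any(pal)) {
    maf_x <- pmin(ex$eaf, 1 - ex$eaf)
    maf_y <- pmin(ou$eaf, 1 - ou$eaf)
    informative <- pal & (same | swapped | comp_same | comp_swapped) &
      maf_x < palindrome_maf & maf_y < palindrome_maf
    ea_matches_sw <- pal & (swapped | comp_same)
    eaf_y_aligned <- ifelse(ea_matches_sw, 1 - ou$eaf, ou$eaf)
    agree <- (ex$eaf < 0.5) == (eaf_y_aligned < 0.5)
    action[informative & ea_matches_sw & agree] <- "swap"
    action[informative & ea_matches_sw & !agree] <- "keep"
    action[informative & !ea_matches_sw & agree] <- "keep"
    action[informative & !ea_matches_sw & !agree] <- "swap"
    action[pal & (same | swapped | comp_same | comp_swapped) &
             !informative] <- "drop_palindromic"
  }

  keep <- action %in% c("keep", "swap")
  sgn <- ifelse(action == "swap", -1, 1)
  eaf_y <- ifelse(action == "swap", 1 - ou$eaf, ou$eaf)

  out <- data.frame(snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
                    ea = ex$ea, oa = ex$oa,
                    eaf_x = ex$eaf, beta_x = ex$beta, se_x = ex$se,
                    p_x = ex$p, n_x = ex$n,
                    eaf_y = eaf_y, beta_y = sgn * ou$beta, se_y = ou$se,
                    p_y = ou$p, n_y = ou$n,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "harmonization_report") <- c(
    n_exposure = nrow(exposure), n_outcome = nrow(outcome),
    n_shared = n_in,
    n_kept = sum(action == "keep"), n_flipped = sum(action == "swap"),
    n_dropped_palindromic = sum(action == "drop_palindromic"),
    n_dropped_incompatible = sum(action == "incompatible"))
  out
}
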