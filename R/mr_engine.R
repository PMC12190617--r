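# Two-sample MR estimators and tests on a harmonized instrument set:
# Wald ratio, IVW, MR-Egger, weighted median, Cochran's Q, the SMR
# chi-square test, and Bonferroni thresholds.
#
# An instrument set here is any data.frame with columns beta_x, se_x,
# beta_y, se_y (one row per instrument), e.g. build_instrument_set() output.

mr_result <- function(method, beta, se, p, n_snps, ...) {
  out <- list(method = method, beta = beta, se = se, p = p,
              or_ = exp(beta),
              ci_low = exp(beta - stats::qnorm(0.975) * se),
              ci_high = exp(beta + stats::qnorm(0.975) * se),
              n_snps = n_snps, ...)
  class(out) <- "mr_result"
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %s: beta = %.4g (se %.4g), p = %.3g, OR %s, n_snps = %d\n",
              x$method, x$beta, x$se, x$p,
              format_or_ci(x$or_, x$ci_low, x$ci_high), x$n_snps))
  invisible(x)
}

#' Wald ratio estimate for a single instrument
#'
#' `beta = beta_y / beta_x` with the first-order delta-method standard
#' error `se = se_y / |beta_x|` and a two-sided normal p-value.
#'
#' @param inst one-row data.frame (or list) with `beta_x, se_x, beta_y,
#'   se_y`.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(inst) {
  if (inst$beta_x[1] == 0) stop("beta_x is zero: Wald ratio undefined",
                                call. = FALSE)
  beta <- inst$beta_y[1] / inst$beta_x[1]
  se <- inst$se_y[1] / abs(inst$beta_x[1])
  mr_result("wald", beta, se, two_sided_p(beta / se), 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights `1/se_y^2`:
#' `beta = sum(beta_x*beta_y/se_y^2) / sum(beta_x^2/se_y^2)`,
#' `se_fixed = sqrt(1/sum(beta_x^2/se_y^2))`.  Under the multiplicative
#' random-effects model the SE is inflated by `max(1, sqrt(Q/df))`.  The
#' default picks fixed effects for 3 or fewer instruments and
#' multiplicative random effects otherwise; a single instrument reduces
#' exactly to the Wald ratio.
#'
#' @param insts instrument set (>= 1 row).
#' @param model `"auto"`, `"fixed"` or `"multiplicative_random"`.
#' @return An `mr_result` with extra fields `model`, `q`, `q_df`, `q_p`
#'   (heterogeneity, when `n_snps >= 2`).
#' @export
ivw <- function(insts, model = c("auto", "fixed", "multiplicative_random")) {
  model <- match.arg(model)
  k <- nrow(insts)
  if (is.null(k) || k == 0L) stop("empty instrument set", call. = FALSE)
  if (model == "auto") {
    model <- if (k <= 3) "fixed" else "multiplicative_random"
  }
  w <- 1 / insts$se_y^2
  denom <- sum(insts$beta_x^2 * w)
  beta <- sum(insts$beta_x * insts$beta_y * w) / denom
  se <- sqrt(1 / denom)
  het <- if (k >= 2) cochran_q_stat(insts, beta) else
    list(q = NA_real_, df = NA_integer_, p = NA_real_)
  if (model == "multiplicative_random" && k >= 2) {
    se <- se * max(1, sqrt(het$q / het$df))
  }
  mr_result("ivw", beta, se, two_sided_p(beta / se), k,
            model = model, q = het$q, q_df = het$df, q_p = het$p)
}

#' MR-Egger regression
#'
#' Weighted linear regression `beta_y = intercept + slope * beta_x` with
#' weights `1/se_y^2`, after orienting every instrument so `beta_x >= 0`
#' (Egger's convention).  Standard errors are scaled by
#' `max(1, sqrt(RSS/(n-2)))`; the intercept and its p-value test
#' directional pleiotropy.
#'
#' @param insts instrument set with at least 3 rows.
#' @return An `mr_result` (slope as `beta`) with `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_egger <- function(insts) {
  k <- nrow(insts)
  if (is.null(k) || k < 3) stop("MR-Egger requires at least 3 instruments",
                                call. = FALSE)
  sgn <- ifelse(insts$beta_x < 0, -1, 1)
  bx <- sgn * insts$beta_x
  by <- sgn * insts$beta_y
  w <- 1 / insts$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # summary() scales SEs by sigma = sqrt(RSS/(n-2)); floor the scale at 1 so
  # under-dispersed sets keep at least the fixed-effect SE.
  scale_up <- max(1, sm$sigma) / sm$sigma
  est <- sm$coefficients
  slope <- est["bx", "Estimate"]; slope_se <- est["bx", "Std. Error"] * scale_up
  icpt <- est["(Intercept)", "Estimate"]
  icpt_se <- est["(Intercept)", "Std. Error"] * scale_up
  mr_result("egger", slope, slope_se, two_sided_p(slope / slope_se), k,
            egger_intercept = icpt, egger_intercept_se = icpt_se,
            egger_intercept_p = two_sided_p(icpt / icpt_se))
}

# Weighted median of `x` with weights `w`: linear interpolation of the
# weighted empirical CDF at 0.5 using midpoint cumulative weights.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Per-instrument ratio estimates are ordered and weighted by the inverse
#' variance of the ratio (first-order: `se_y/|beta_x|`); the estimate is
#' the weighted median (midpoint-interpolated weighted empirical CDF at
#' 0.5).  It is consistent when instruments carrying at least half the
#' weight are valid.  The SE comes from a seeded parametric bootstrap
#' (resampling `beta_x`, `beta_y` from their sampling normals).
#'
#' @param insts instrument set with at least 3 rows.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return An `mr_result` with extra fields `n_boot`, `seed`.
#' @export
weighted_median <- function(insts, n_boot = 1000, seed = 1L) {
  k <- nrow(insts)
  if (is.null(k) || k < 3) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  ratio <- insts$beta_y / insts$beta_x
  ratio_se <- insts$se_y / abs(insts$beta_x)
  w <- 1 / ratio_se^2
  beta <- weighted_median_point(ratio, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, insts$beta_x, insts$se_x)
      by <- stats::rnorm(k, insts$beta_y, insts$se_y)
      r <- by / bx
      weighted_median_point(r, (bx / insts$se_y)^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  mr_result("weighted_median", beta, se, two_sided_p(beta / se), k,
            n_boot = n_boot, seed = seed)
}

cochran_q_stat <- function(insts, beta_ivw) {
  w <- (insts$beta_x / insts$se_y)^2
  theta <- insts$beta_y / insts$beta_x
  q <- sum(w * (theta - beta_ivw)^2)
  df <- nrow(insts) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Cochran's Q heterogeneity test
#'
#' Per-instrument ratios `theta_j = beta_y/beta_x` with first-order weights
#' `w_j = (beta_x/se_y)^2`; `Q = sum w_j (theta_j - theta_ivw)^2` follows a
#' chi-square with `n_snps - 1` df under homogeneity.
#'
#' @param insts instrument set with at least 2 rows.
#' @return list with `q`, `df`, `p`.
#' @export
cochran_q <- function(insts) {
  k <- nrow(insts)
  if (is.null(k) || k < 2) stop("Cochran's Q requires at least 2 instruments",
                                call. = FALSE)
  w <- 1 / insts$se_y^2
  beta_ivw <- sum(insts$beta_x * insts$beta_y * w) / sum(insts$beta_x^2 * w)
  cochran_q_stat(insts, beta_ivw)
}

#' SMR test at the lead cis-pQTL
#'
#' Summary-data-based MR at a single shared variant: with
#' `z_x = beta_x/se_x` and `z_y = beta_y/se_y`, the statistic
#' `T = z_x^2 z_y^2 / (z_x^2 + z_y^2)` is compared to a chi-square with
#' 1 df; the effect estimate is the ratio `beta_y/beta_x`.
#'
#' @param lead_x,lead_y lists/one-row data.frames with `beta`, `se` at the
#'   same (harmonized) variant for exposure and outcome.
#' @return An `mr_result` with extra field `t_smr`.
#' @export
smr_test <- function(lead_x, lead_y) {
  stopifnot(lead_x$se[1] > 0, lead_y$se[1] > 0)
  if (lead_x$beta[1] == 0) stop("beta_x is zero: SMR ratio undefined",
                                call. = FALSE)
  zx <- lead_x$beta[1] / lead_x$se[1]
  zy <- lead_y$beta[1] / lead_y$se[1]
  if (zx == 0 && zy == 0) stop("both z-scores zero", call. = FALSE)
  t_smr <- zx^2 * zy^2 / (zx^2 + zy^2)
  p <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  beta <- lead_y$beta[1] / lead_x$beta[1]
  # delta-method SE consistent with the SMR z-statistic
  se <- abs(beta) / sqrt(t_smr)
  mr_result("smr", beta, se, max(p, .Machine$double.xmin), 1L, t_smr = t_smr)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`; e.g. 0.05/1954 = 2.56e-5 for a 1954-protein screen
#' and 5e-8/2923 = 1.7e-11 for pQTL instrument selection over 2923
#' proteins.
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests (>= 1).
#' @return numeric threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  alpha / n_tests
}
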