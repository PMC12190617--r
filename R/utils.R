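# Internal numerical and bookkeeping helpers shared across modules.

#' @keywords internal
#' @importFrom stats pnorm pchisq qnorm rnorm runif rlnorm rnbinom sd approx
#'   setNames lm
#' @importFrom utils read.delim write.table packageVersion
"_PACKAGE"

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# state. All package randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# log(sum(exp(x))) without overflow; -Inf for empty input.
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when a == b (within fp noise).
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  d <- b - a
  if (d >= 0) return(-Inf)     # cancellation: treat as empty sum
  a + log1p(-exp(d))
}

# Two-sided normal p-value from a z-score, floored at the smallest normal
# double so extreme signals never produce p == 0 (the p in (0,1] invariant).
two_sided_p <- function(z) {
  lp <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  pmax(pmin(exp(lp), 1), .Machine$double.xmin)
}

# "1.23 (1.13–1.33)" style odds-ratio formatting: round to 2 decimals,
# drop trailing zeros (so 2.00 prints as "2"), en dash between bounds.
format_or_ci <- function(or_, ci_low, ci_high) {
  fmt1 <- function(x) {
    vapply(x, function(v) {
      if (is.na(v)) return(NA_character_)
      format(round(v, 2), scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
    }, character(1))
  }
  ifelse(is.na(or_), NA_character_,
         paste0(fmt1(or_), " (", fmt1(ci_low), "–", fmt1(ci_high), ")"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
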