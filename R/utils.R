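# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
.check_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and positive", name), call. = FALSE)
  }
  invisible(x)
}

# log(sum(exp(x))) without overflow; the workhorse of colocalization sums.
logsum <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a > b.
logdiff <- function(a, b) {
  a + log1p(-exp(b - a))
}

#' Two-sided normal p-value from a z-score, computed on the log scale
#'
#' Survival functions are evaluated with `log.p = TRUE` so that the
#' natural-log (and -log10) p-value remains finite for arbitrarily large
#' |z|, even where the p-value itself underflows double precision.
#'
#' @param z numeric vector of z-scores.
#' @return list with `p` (double, may underflow to 0 for |z| > ~38.5),
#'   `log_p` (natural log, always finite) and `neglog10_p`.
#' @export
#' @examples
#' z_to_p(1.96)$p
z_to_p <- function(z) {
  log_p <- stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  log_p <- pmin(log_p, 0)
  list(p = exp(log_p), log_p = log_p, neglog10_p = -log_p / log(10))
}

# Sample Pearson r between two dosage/haplotype vectors, NA-safe.
.pair_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 2L) return(NA_real_)
  r <- suppressWarnings(stats::cor(x[ok], y[ok]))
  if (is.na(r)) return(NA_real_)
  r^2
}

#' Deterministic child seed from a master seed and a label
#'
#' Derives a reproducible sub-seed for each named source of randomness
#' so a single master seed drives the whole pipeline; the result stays
#' below 2^31 and is always a valid integer seed.
#'
#' @param seed integer master seed.
#' @param label character label naming the randomness source.
#' @return an integer seed.
#' @export
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}
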