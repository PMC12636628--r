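# Wakefield approximate-Bayes-factor colocalization, the SMR Wald-ratio
# causal test and a HEIDI-style instrument-heterogeneity check.

#' Wakefield log approximate Bayes factor
#'
#' For a normal effect prior with standard deviation `sd_prior`,
#' lABF = 0.5 (log(1 - r) + r z^2) with r = sd_prior^2 / (sd_prior^2 +
#' se^2) and z = beta/se. Vectorized.
#'
#' @param beta,se effect estimate and positive standard error.
#' @param sd_prior positive prior effect SD (conventionally 0.2 for
#'   quantitative traits, 0.15 log-odds for case-control).
#' @return log ABF (natural log).
#' @export
wakefield_labf <- function(beta, se, sd_prior) {
  .check_pos(se, "se"); .check_pos(sd_prior, "sd_prior")
  r <- sd_prior^2 / (sd_prior^2 + se^2)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Build a colocalization dataset
#'
#' @param variant_id variant ids (aligned between the two traits).
#' @param beta,se effect estimates and standard errors.
#' @param trait_type `"quant"` or `"cc"`; sets the default `sd_prior`
#'   (0.2 / 0.15).
#' @param sd_prior override of the effect-scale prior SD.
#' @return a `coloc_dataset` list.
#' @export
coloc_dataset <- function(variant_id, beta, se,
                          trait_type = c("quant", "cc"), sd_prior = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(sd_prior)) sd_prior <- if (trait_type == "quant") 0.2 else 0.15
  .check_pos(se, "se")
  structure(list(variant_id = variant_id, beta = beta, se = se,
                 trait_type = trait_type, sd_prior = sd_prior),
            class = "coloc_dataset")
}

.coloc_posteriors <- function(l1, l2, p1, p2, p12) {
  # log-space sums over single-causal-variant configurations
  s1 <- logsum(l1); s2 <- logsum(l2); s12 <- logsum(l1 + l2)
  lh0 <- 0
  lh1 <- log(p1) + s1
  lh2 <- log(p2) + s2
  lh3 <- log(p1) + log(p2) + logdiff(s1 + s2, s12)
  lh4 <- log(p12) + s12
  lh <- c(lh0, lh1, lh2, lh3, lh4)
  post <- exp(lh - logsum(lh))
  stats::setNames(post, c("pp0", "pp1", "pp2", "pp3", "pp4"))
}

#' Approximate-Bayes-factor colocalization of two traits at a locus
#'
#' Enumerates the five single-causal-variant hypotheses (no association;
#' trait-1 only; trait-2 only; two distinct causal variants; one shared
#' causal variant) in log space from per-variant Wakefield ABFs. In
#' `"adjusted"` or `"best"` mode a second pass with an elevated shared
#' prior `p12_adjusted` is run and, for `"best"`, the result with the
#' larger PP4 is returned (mode recorded on the result).
#'
#' @param d1,d2 [coloc_dataset()]s sharing at least `min_variants`
#'   variants (aligned by id).
#' @param p1,p2,p12 per-variant prior probabilities (defaults 1e-4, 1e-4,
#'   1e-5).
#' @param mode `"default"`, `"adjusted"` or `"best"`.
#' @param p12_adjusted elevated shared prior for the adjusted pass
#'   (default 5e-5).
#' @param min_variants minimum shared variants (default 10).
#' @return a `coloc_result` list: `pp0`..`pp4`, `n_snps`, `priors`,
#'   `mode`.
#' @export
coloc_abf <- function(d1, d2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      mode = c("default", "adjusted", "best"),
                      p12_adjusted = 5e-5, min_variants = 10) {
  mode <- match.arg(mode)
  shared <- intersect(d1$variant_id, d2$variant_id)
  if (length(shared) < min_variants) {
    stop(sprintf("only %d shared variants (need >= %d)", length(shared),
                 min_variants), call. = FALSE)
  }
  i1 <- match(shared, d1$variant_id); i2 <- match(shared, d2$variant_id)
  l1 <- wakefield_labf(d1$beta[i1], d1$se[i1], d1$sd_prior)
  l2 <- wakefield_labf(d2$beta[i2], d2$se[i2], d2$sd_prior)
  res_def <- .coloc_posteriors(l1, l2, p1, p2, p12)
  pick <- function(post, used_p12, used_mode) {
    structure(c(as.list(post),
                list(n_snps = length(shared),
                     priors = c(p1 = p1, p2 = p2, p12 = used_p12),
                     mode = used_mode)),
              class = "coloc_result")
  }
  if (mode == "default") return(pick(res_def, p12, "default"))
  res_adj <- .coloc_posteriors(l1, l2, p1, p2, p12_adjusted)
  if (mode == "adjusted") return(pick(res_adj, p12_adjusted, "adjusted"))
  if (res_adj[["pp4"]] >= res_def[["pp4"]]) pick(res_adj, p12_adjusted, "adjusted")
  else pick(res_def, p12, "default")
}

#' Classify a PP4 posterior into the colocalization support tiers
#'
#' @param pp4 posterior probability of a shared causal variant, in \[0,1\].
#' @return `"strong"` (>= 0.7), `"suggestive"` (>= 0.4) or `"none"`.
#' @export
classify_pp4 <- function(pp4) {
  if (any(pp4 < 0 | pp4 > 1)) stop("pp4 must lie in [0,1]", call. = FALSE)
  ifelse(pp4 >= 0.7, "strong", ifelse(pp4 >= 0.4, "suggestive", "none"))
}

#' Summary-based Mendelian randomization (Wald ratio) test
#'
#' b_xy = b_gwas / b_qtl and z^2_smr = z_gwas^2 z_qtl^2 /
#' (z_gwas^2 + z_qtl^2), referred to chi-square(1).
#'
#' @param z_gwas,z_qtl z-scores at the top cis-QTL instrument
#'   (`z_qtl` must be nonzero).
#' @param b_gwas,b_qtl effect estimates (for the Wald ratio).
#' @return list with `b_xy`, `z2_smr`, `p_smr`.
#' @export
smr_test <- function(z_gwas, z_qtl, b_gwas, b_qtl) {
  if (z_qtl == 0) stop("z_qtl must be nonzero", call. = FALSE)
  z2 <- z_gwas^2 * z_qtl^2 / (z_gwas^2 + z_qtl^2)
  list(b_xy = b_gwas / b_qtl, z2_smr = z2,
       p_smr = stats::pchisq(z2, df = 1, lower.tail = FALSE))
}

#' HEIDI-style test for LD-driven heterogeneity of Wald ratios
#'
#' Compares the Wald ratio at each eligible instrument to the top
#' instrument's; delta-method variances and LD-derived covariances give a
#' multivariate normal for the differences, and the sum of squared
#' standardized differences is referred to a Satterthwaite-matched scaled
#' chi-square (a documented simplification of the original saddlepoint
#' approach — hence "heidi_like"). Small p flags LD-driven heterogeneity
#' (distinct causal variants).
#'
#' @param b_gwas,se_gwas,b_qtl,se_qtl per-variant effect estimates for the
#'   outcome GWAS and the exposure QTL, aligned.
#' @param ld_matrix signed correlation matrix over the same variants.
#' @param top_idx index of the top instrument (default: max |z_qtl|).
#' @param p_qtl_enter instrument eligibility threshold on the QTL p
#'   (default 1.6e-3).
#' @param r2_range eligible LD to the top instrument (default (0.05,
#'   0.9)), as in the original instrument-selection convention.
#' @param max_snps cap on instruments beside the top (default 20).
#' @return list with `p_heidi` (NA when fewer than 3 eligible
#'   instruments) and `n_heidi_snps`.
#' @export
heidi_like <- function(b_gwas, se_gwas, b_qtl, se_qtl, ld_matrix,
                       top_idx = NULL, p_qtl_enter = 1.6e-3,
                       r2_range = c(0.05, 0.9), max_snps = 20) {
  z_q <- b_qtl / se_qtl
  if (is.null(top_idx)) top_idx <- which.max(abs(z_q))
  p_q <- z_to_p(z_q)$p
  r2_top <- ld_matrix[, top_idx]^2
  elig <- which(p_q < p_qtl_enter & seq_along(z_q) != top_idx &
                  r2_top > r2_range[1] & r2_top < r2_range[2])
  if (length(elig) > max_snps) elig <- elig[order(p_q[elig])][seq_len(max_snps)]
  if (length(elig) < 3) return(list(p_heidi = NA_real_, n_heidi_snps = length(elig)))
  idx <- c(top_idx, elig)
  bg <- b_gwas[idx]; sg <- se_gwas[idx]
  bq <- b_qtl[idx]; sq <- se_qtl[idx]
  R <- ld_matrix[idx, idx, drop = FALSE]
  bxy <- bg / bq
  # delta-method covariance of the Wald ratios; GWAS and QTL samples are
  # independent, so the two error sources add
  K <- length(idx)
  C <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    C[i, j] <- R[i, j] * sg[i] * sg[j] / (bq[i] * bq[j]) +
      bg[i] * bg[j] * R[i, j] * sq[i] * sq[j] / (bq[i]^2 * bq[j]^2)
  }
  m <- K - 1
  d <- bxy[-1] - bxy[1]
  V <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    V[i, j] <- C[i + 1, j + 1] - C[i + 1, 1] - C[1, j + 1] + C[1, 1]
  }
  dv <- diag(V)
  if (any(dv <= 0)) return(list(p_heidi = NA_real_, n_heidi_snps = m))
  zd <- d / sqrt(dv)
  A <- V / sqrt(outer(dv, dv))       # correlation of the z_d
  stat <- sum(zd^2)
  e <- m                              # tr(A)
  v <- 2 * sum(A^2)                   # 2 tr(A^2)
  c_scale <- v / (2 * e)
  df <- 2 * e^2 / v
  p <- stats::pchisq(stat / c_scale, df = df, lower.tail = FALSE)
  list(p_heidi = p, n_heidi_snps = m)
}

#' Combine SMR and colocalization evidence for one protein
#'
#' SMR support requires FDR-significant SMR with non-significant
#' heterogeneity (p_heidi > 0.05); colocalization support requires at
#' least suggestive PP4 (>= 0.4).
#'
#' @param smr list with `q_smr` (FDR-adjusted SMR p) and `p_heidi`, or
#'   `NULL`.
#' @param coloc a `coloc_result` (or list with `pp4`), or `NULL`.
#' @return `"both"`, `"smr_only"`, `"coloc_only"` or `"none"`.
#' @export
validate_protein <- function(smr, coloc) {
  smr_ok <- !is.null(smr) && !is.na(smr$q_smr) && smr$q_smr < 0.05 &&
    (is.na(smr$p_heidi) || smr$p_heidi > 0.05)
  col_ok <- !is.null(coloc) && coloc$pp4 >= 0.4
  if (smr_ok && col_ok) "both" else if (smr_ok) "smr_only"
  else if (col_ok) "coloc_only" else "none"
}
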