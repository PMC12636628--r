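# Shared in-code fixtures for the test suite. Everything is generated at
# run time under fixed seeds; no data files are read.

# small record constructor for meta-analysis tests
rec <- function(beta, se, eaf = 0.3, ea = "A", oa = "G", id = "rs1",
                chrom = "1", pos = 100L, n = 1000) {
  assoc_record(id, chrom, pos, ea, oa, eaf, beta, se, n = n)
}

# a compact LD-blocked panel reused across locus/pwas tests
small_panel <- function(seed = 101, n_blocks = 4, vpb = 6, r = 0.85,
                        n_hap = 3000) {
  simulate_panel(n_blocks, vpb, r, n_hap, seed = seed)
}

# per-variant marginal linear-regression summary stats for a quantitative
# trait; the independent route used by PWAS/QTL oracles
marginal_lm_stats <- function(g, y) {
  out <- apply(g, 2, function(x) {
    if (stats::var(x) == 0) return(c(0, Inf))
    summary(stats::lm(y ~ x))$coefficients[2, 1:2]
  })
  data.frame(variant_id = colnames(g), beta = out[1, ], se = out[2, ],
             stringsAsFactors = FALSE)
}

# vectorized marginal linear-regression summary statistics (closed form);
# used where per-variant lm() loops would dominate runtime
fast_marginal <- function(g, y) {
  n <- length(y)
  gv <- apply(g, 2, stats::var)
  gv[gv == 0] <- NA
  b <- as.numeric(stats::cov(g, y)) / gv
  rv <- (stats::var(y) * (n - 1) - b^2 * gv * (n - 1)) / (n - 2)
  se <- sqrt(rv / (gv * (n - 1)))
  data.frame(variant_id = colnames(g), beta = b, se = se,
             stringsAsFactors = FALSE)
}

# exhaustive double-precision colocalization oracle: direct sums over all
# single-causal-variant configurations (no log-space tricks)
coloc_enum_oracle <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  b1 <- exp(l1); b2 <- exp(l2)
  m <- length(b1)
  s1 <- sum(b1); s2 <- sum(b2)
  s3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) s3 <- s3 + b1[i] * b2[j]
  }
  s4 <- sum(b1 * b2)
  w <- c(1, p1 * s1, p2 * s2, p1 * p2 * s3, p12 * s4)
  stats::setNames(w / sum(w), c("pp0", "pp1", "pp2", "pp3", "pp4"))
}

# ledger factory for prioritization tests
mk_ledger <- function(origin = "gwas_locus", gene = "G1", locus = "L1",
                      hits = NULL, pwas_hit = NULL,
                      da_sex_p = NA_real_, da_int_p = NA_real_) {
  if (is.null(hits)) {
    hits <- data.frame(qtl_type = character(), dataset = character(),
                       pp4 = numeric())
  }
  evidence_ledger(gene, locus, origin, pwas_hit = pwas_hit,
                  xqtl_hits = hits, da_sex_p = da_sex_p,
                  da_interaction_p = da_int_p)
}

hits_df <- function(...) {
  x <- list(...)
  data.frame(qtl_type = vapply(x, `[[`, "", 1),
             dataset = vapply(x, `[[`, "", 2),
             pp4 = vapply(x, function(h) as.numeric(h[[3]]), 0),
             stringsAsFactors = FALSE)
}
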