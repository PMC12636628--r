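# Weight training, the weighted-burden statistic, grouped FDR and the
# sex-specificity classification rules.

test_that("single-variant models reduce to the variant's GWAS z", {
  gwas <- data.frame(variant_id = "v1", beta = 0.12, se = 0.03)
  ld <- matrix(1, 1, dimnames = list("v1", "v1"))
  m <- weight_model("G", "v1", 0.7, c(0, 1e6), "top1", 0.1, 0.001)
  res <- pwas_assoc(m, gwas, ld, lambda = 0)
  expect_equal(res$z, 0.12 / 0.03, tolerance = 1e-12)
  # negative weight flips the sign
  mneg <- weight_model("G", "v1", -0.7, c(0, 1e6), "top1", 0.1, 0.001)
  expect_equal(pwas_assoc(mneg, gwas, ld, lambda = 0)$z, -4, tolerance = 1e-12)
})

test_that("perfectly correlated variants with equal weights match one variant", {
  gwas <- data.frame(variant_id = c("v1", "v2"), beta = c(0.12, 0.12),
                     se = c(0.03, 0.03))
  ld <- matrix(1, 2, 2, dimnames = list(c("v1", "v2"), c("v1", "v2")))
  m2 <- weight_model("G", c("v1", "v2"), c(0.5, 0.5), c(0, 1e6), "enet",
                     0.1, 0.001)
  res <- pwas_assoc(m2, gwas, ld, lambda = 0)
  expect_equal(res$z, 4, tolerance = 1e-10)
})

test_that("coverage accounting refuses models mostly absent from the GWAS", {
  gwas <- data.frame(variant_id = "v1", beta = 0.1, se = 0.05)
  ld <- matrix(1, 1, dimnames = list("v1", "v1"))
  m <- weight_model("G", c("v1", "v2"), c(0.2, 0.8), c(0, 1e6), "enet",
                    0.1, 0.001)
  expect_error(pwas_assoc(m, gwas, ld), "coverage")
  res <- pwas_assoc(m, gwas, ld, coverage_floor = 0.1)
  expect_equal(res$coverage, 0.2)
})

test_that("summary-level z tracks the individual-level two-stage oracle", {
  set.seed(50)
  panel <- small_panel(seed = 51, n_blocks = 1, vpb = 8, n_hap = 6000)
  zs <- matrix(NA_real_, 30, 2)
  for (i in 1:30) {
    g <- draw_genotypes(panel, 1500, seed = 51 + i)
    w <- numeric(8); w[sample(8, 2)] <- rnorm(2, 0, 0.6)
    prot_gen <- as.numeric(g %*% w)
    y <- 0.3 * prot_gen + rnorm(1500)
    gwas <- marginal_lm_stats(g, y)
    model <- weight_model("G", colnames(g), w, c(0, 1e6), "truth", NA, NA)
    zs[i, 1] <- pwas_assoc(model, gwas, cor(g), lambda = 0.01)$z
    zs[i, 2] <- summary(lm(y ~ prot_gen))$coefficients[2, 3]
  }
  expect_gt(cor(zs[, 1], zs[, 2]), 0.95)
})

test_that("grouped Benjamini-Hochberg matches hand computation", {
  q <- bh_fdr(c(0.01, 0.02, 0.03, 0.9))
  expect_equal(q, c(0.04, 0.04, 0.04, 0.9), tolerance = 1e-12)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.01, 0.02, 0.03, 0.9)
  joint <- bh_fdr(p)
  grouped <- bh_fdr(p, grouping = c(1, 1, 2, 2))
  expect_false(isTRUE(all.equal(joint, grouped)))
  expect_equal(grouped, c(0.02, 0.02, 0.06, 0.9), tolerance = 1e-12)
  expect_length(bh_fdr(numeric()), 0)
})

mk_res <- function(gene, gwas_sex, stratum, z, p, q, tissue = "brain") {
  data.frame(gene_id = gene, gwas_sex = gwas_sex, weight_stratum = stratum,
             tissue = tissue, z = z, p = p, p_fdr = q,
             stringsAsFactors = FALSE)
}

test_that("sex-specificity classification follows the discovery rule table", {
  # primary female hit, male far from significant -> female, primary
  r1 <- rbind(mk_res("A", "female", "female", 4, 1e-5, 0.01),
              mk_res("A", "male", "male", 1, 0.33, 0.6),
              mk_res("A", "male", "combined", 0.8, 0.4, 0.7))
  c1 <- classify_sex_specific(r1)
  expect_equal(c1$sex_bias, "female")
  expect_equal(c1$discovery, "primary")
  # opposite sex nominally significant and concordant -> none
  r2 <- rbind(mk_res("A", "female", "female", 4, 1e-5, 0.01),
              mk_res("A", "male", "male", 2.2, 0.03, 0.2))
  expect_equal(classify_sex_specific(r2)$sex_bias, "none")
  # opposite sex significant but discordant in direction -> still biased
  r3 <- rbind(mk_res("A", "female", "female", 4, 1e-5, 0.01),
              mk_res("A", "male", "male", -2.2, 0.03, 0.2))
  expect_equal(classify_sex_specific(r3)$sex_bias, "female")
  # secondary-only and both routes
  r4 <- rbind(mk_res("A", "female", "combined", 4, 1e-5, 0.01),
              mk_res("A", "male", "combined", 0.5, 0.6, 0.8))
  expect_equal(classify_sex_specific(r4)$discovery, "secondary")
  r5 <- rbind(mk_res("A", "female", "female", 4, 1e-5, 0.01),
              mk_res("A", "female", "combined", 4, 1e-5, 0.01),
              mk_res("A", "male", "male", 0.5, 0.6, 0.8))
  expect_equal(classify_sex_specific(r5)$discovery, "both")
  # male-biased symmetric path
  r6 <- rbind(mk_res("B", "male", "male", -4, 1e-5, 0.01),
              mk_res("B", "female", "female", 1, 0.4, 0.6))
  expect_equal(classify_sex_specific(r6)$sex_bias, "male")
})

test_that("the locus rule demotes proteins when the top protein is unbiased", {
  res <- rbind(
    mk_res("TOP", "female", "female", 6, 1e-9, 1e-7),
    mk_res("TOP", "male", "male", 5, 1e-6, 1e-4),    # concordant -> TOP unbiased
    mk_res("B", "female", "female", 4.4, 1e-5, 0.01),
    mk_res("B", "male", "male", 0.5, 0.6, 0.8))
  lm_ <- data.frame(gene_id = c("TOP", "B"), locus_id = "L1")
  out <- classify_sex_specific(res, locus_map = lm_)
  expect_equal(out$sex_bias[out$gene_id == "B"], "none")
  # without the locus map B stays biased
  out2 <- classify_sex_specific(res)
  expect_equal(out2$sex_bias[out2$gene_id == "B"], "female")
  # classification order-invariant
  out3 <- classify_sex_specific(res[rev(seq_len(nrow(res))), ], locus_map = lm_)
  expect_equal(out3[order(out3$gene_id), "sex_bias"],
               out[order(out$gene_id), "sex_bias"])
})

test_that("cross-ancestry and sensitivity consistency rules evaluate", {
  expect_true(afr_consistency_pwas(4, 1.5, 0.5, 0.2, 4e4, 5e3))
  expect_false(afr_consistency_pwas(4, 0, 0.5, 0, 4e4, 4e4))  # dilution
  expect_false(afr_consistency_pwas(4, 2, 1.5, 2.5, 4e4, 1e4)) # opp. sex wakes
  expect_true(sensitivity_consistency(list(z_disc = 3),
                                      list(z_disc = 2.5, p_disc = 0.01,
                                           p_opp = 0.4)))
  expect_false(sensitivity_consistency(list(z_disc = 3),
                                       list(z_disc = -2.5, p_disc = 0.01,
                                            p_opp = 0.4)))
  expect_false(sensitivity_consistency(list(z_disc = 3),
                                       list(z_disc = 2.5, p_disc = 0.06,
                                            p_opp = 0.4)))
})

test_that("weight training screens heritability and recovers causal structure", {
  panel <- small_panel(seed = 61, n_blocks = 1, vpb = 8, n_hap = 3000)
  g <- draw_genotypes(panel, 400, seed = 62)
  # pure-noise abundance fails the screen in most runs
  fails <- vapply(1:10, function(i) {
    set.seed(100 + i)
    isTRUE(train_weights(g, rnorm(400), seed = 100 + i,
                         n_perm = 60, herit_p_max = 0.02)$herit_fail)
  }, TRUE)
  expect_gte(mean(fails), 0.9)
  # a single strong causal variant is captured with sensible CV r2
  h2 <- 0.3
  gs <- scale(g[, 4])[, 1]
  y <- sqrt(h2) * gs + rnorm(400, 0, sqrt(1 - h2))
  m <- train_weights(g, y, seed = 63, n_perm = 120)
  expect_s3_class(m, "weight_model")
  expect_lt(abs(m$cv_r2 - h2), 0.12)
  top <- which.max(abs(m$weights))
  expect_gt(abs(cor(g[, top], g[, 4])), 0.5)
  # determinism given the seed
  m2 <- train_weights(g, y, seed = 63, n_perm = 120)
  expect_identical(m$weights, m2$weights)
  # all-monomorphic window is a herit-fail with reason
  gmono <- matrix(1, 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(train_weights(gmono, rnorm(50), seed = 1)$reason,
               "no_polymorphic_variants")
})

test_that("weight models round-trip through JSON", {
  m <- weight_model("G1", c("v1", "v2"), c(0.5, -0.2), c(100, 200), "lasso",
                    0.22, 0.004, tissue = "csf", stratum = "female")
  f <- tempfile(fileext = ".json")
  write_weight_model(m, f)
  m2 <- read_weight_model(f)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$stratum, "female")
})

test_that("MHC-style region masking drops the right rows", {
  tab <- data.frame(chrom = c("6", "6", "7"), pos = c(3e7, 5e7, 3e7))
  out <- mask_region(tab, "6", 2.5e7, 3.4e7)
  expect_equal(nrow(out), 2)
  expect_false(any(out$chrom == "6" & out$pos == 3e7))
})
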