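# Cubic-Hill LD from unphased genotypes, tag selection, SV imputation,
# conditional/stratified association and the locus pheWAS.

test_that("cubex equals direct haplotype counting when phase is unambiguous", {
  # no double heterozygotes: every haplotype is countable
  tab <- matrix(c(30, 10, 0,
                  8, 0, 4,
                  0, 6, 12), 3, 3, byrow = TRUE)
  res <- cubex_ld(tab)
  n <- sum(tab)
  # direct count of AB haplotypes (dosage coding: row i = dosage i-1 at A)
  f_direct <- (2 * tab[3, 3] + tab[3, 2] + tab[2, 3]) / (2 * n)
  expect_equal(res$f_AB, f_direct, tolerance = 1e-12)
})

test_that("cubex agrees with the EM fixed point on random tables", {
  set.seed(110)
  worst <- 0
  for (i in 1:400) {
    p <- runif(1, 0.1, 0.9); q <- runif(1, 0.1, 0.9)
    r <- runif(1, -0.8, 0.8)
    rmax <- min(sqrt(p * (1 - q) / (q * (1 - p))),
                sqrt(q * (1 - p) / (p * (1 - q))))
    r <- r * rmax
    f11 <- p * q + r * sqrt(p * (1 - p) * q * (1 - q))
    hp <- c(f11, p - f11, q - f11, 1 - p - q + f11)
    h <- sample(4, 2 * 400, replace = TRUE, prob = pmax(hp, 0))
    a <- as.integer(h %in% c(1, 2)); b <- as.integer(h %in% c(1, 3))
    g1 <- a[seq(1, 800, 2)] + a[seq(2, 800, 2)]
    g2 <- b[seq(1, 800, 2)] + b[seq(2, 800, 2)]
    tab <- two_locus_table(g1, g2)
    if (sum(tab) == 0) next
    cx <- tryCatch(cubex_ld(tab), error = function(e) NULL)
    if (is.null(cx)) next
    em <- em_ld(tab)
    worst <- max(worst, abs(cx$f_AB - em$f_AB))
  }
  expect_lt(worst, 1e-6)
})

test_that("cubex recovers phased-truth r2 and is label-swap invariant", {
  sv <- simulate_sv_locus(5000, 0.75, 0.35, seed = 111)
  tab <- two_locus_table(sv$genotypes[, "SV"], sv$genotypes[, "tag1"])
  cx <- cubex_ld(tab)
  expect_lt(abs(cx$r2 - sv$realized_r2[["tag1"]]), 0.05)
  # swapping allele labels at either locus leaves r2 unchanged
  cx_a <- cubex_ld(two_locus_table(2 - sv$genotypes[, "SV"],
                                   sv$genotypes[, "tag1"]))
  cx_b <- cubex_ld(two_locus_table(sv$genotypes[, "SV"],
                                   2 - sv$genotypes[, "tag1"]))
  expect_equal(cx$r2, cx_a$r2, tolerance = 1e-9)
  expect_equal(cx$r2, cx_b$r2, tolerance = 1e-9)
  # independent loci drift to zero
  set.seed(112)
  g1 <- rbinom(4000, 2, 0.3); g2 <- rbinom(4000, 2, 0.4)
  expect_lt(cubex_ld(two_locus_table(g1, g2))$r2, 0.01)
  mono <- two_locus_table(rep(0, 100), rbinom(100, 2, 0.5))
  expect_error(cubex_ld(mono), "polymorphic")
})

test_that("tag panels keep only informative SNVs in deterministic order", {
  sv <- simulate_sv_locus(3000, c(0.75, 0.5, 0.3), 0.35, seed = 113)
  pan <- select_tag_panel(sv$genotypes[, "SV"], sv$genotypes[, -1])
  expect_equal(pan$snv, c("tag1", "tag2", "tag3"))
  expect_true(all(diff(pan$r2) <= 0))
  weak <- simulate_sv_locus(3000, 0.05, 0.35, seed = 114)
  expect_error(select_tag_panel(weak$genotypes[, "SV"],
                                weak$genotypes[, -1, drop = FALSE]),
               "no tag")
})

test_that("SV imputation accuracy tracks LD strength", {
  # perfect tag: deterministic mapping, accuracy 1
  sv1 <- simulate_sv_locus(400, 1.0, 0.3, seed = 115)
  m1 <- train_sv_imputer(sv1$genotypes[, "tag1", drop = FALSE],
                         sv1$sv_genotype, n_splits = 10, seed = 116)
  expect_equal(m1$mean_accuracy, 1)
  # r2 ~ 0.75: accuracy strictly between the class-prior baseline and 1
  sv2 <- simulate_sv_locus(1500, 0.75, 0.35, seed = 117)
  m2 <- train_sv_imputer(sv2$genotypes[, "tag1", drop = FALSE],
                         sv2$sv_genotype, n_splits = 15, seed = 118)
  expect_gt(m2$mean_accuracy, m2$class_prior_baseline)
  expect_lt(m2$mean_accuracy, 1)
  # reproducible given seed
  m2b <- train_sv_imputer(sv2$genotypes[, "tag1", drop = FALSE],
                          sv2$sv_genotype, n_splits = 15, seed = 118)
  expect_identical(m2$accuracy_distribution, m2b$accuracy_distribution)
  # shuffled labels fall to the class-prior baseline
  set.seed(119)
  m3 <- train_sv_imputer(sv2$genotypes[, "tag1", drop = FALSE],
                         sample(sv2$sv_genotype), n_splits = 15, seed = 120)
  expect_lt(m3$mean_accuracy, m3$class_prior_baseline + 0.05)
})

test_that("imputation generalizes and enforces its panel schema", {
  sv <- simulate_sv_locus(3000, c(0.9, 0.6), 0.35, seed = 121)
  tr <- 1:1500; te <- 1501:3000
  m <- train_sv_imputer(sv$genotypes[tr, -1], sv$sv_genotype[tr],
                        n_splits = 20, seed = 122)
  calls <- impute_sv(m, sv$genotypes[te, -1])
  acc <- mean(calls$call == sv$sv_genotype[te])
  expect_lt(abs(acc - m$mean_accuracy), 0.05)
  expect_error(impute_sv(m, sv$genotypes[te, "tag1", drop = FALSE]),
               "absent")
  expect_equal(nrow(impute_sv(m, sv$genotypes[0, -1])), 0)
})

test_that("conditioning dissects SV-mediated from SV-independent signals", {
  set.seed(123)
  sv <- simulate_sv_locus(4000, 0.75, 0.35, seed = 124)
  prot <- sv$sv_genotype * 0.5 + rnorm(4000)
  un <- conditional_assoc(prot, sv$genotypes[, "tag1"])
  cn <- conditional_assoc(prot, sv$genotypes[, "tag1"],
                          g_condition = sv$sv_genotype)
  expect_lt(un$p, 1e-10)
  expect_gt(cn$p, 0.05)
  # a signal on the tag itself survives conditioning
  y <- rbinom(4000, 1, plogis(-1 + 0.6 * sv$genotypes[, "tag1"]))
  c2 <- conditional_assoc(y, sv$genotypes[, "tag1"],
                          g_condition = sv$sv_genotype)
  expect_lt(c2$p, 0.01)
  # orthogonal conditioning leaves the estimate essentially unchanged
  g_orth <- rbinom(4000, 2, 0.4)
  c3 <- conditional_assoc(prot, sv$genotypes[, "tag1"], g_condition = g_orth)
  expect_lt(abs(c3$beta - un$beta), 3 * un$se)
  # collinear condition is flagged non-estimable
  c4 <- conditional_assoc(prot, sv$genotypes[, "tag1"],
                          g_condition = sv$genotypes[, "tag1"])
  expect_false(c4$estimable)
})

test_that("stratified association isolates stratum-specific effects", {
  set.seed(125)
  n <- 3000
  g <- rbinom(n, 2, 0.3)
  strata <- sample(c("e33_f", "e33_m", "e34_f"), n, replace = TRUE)
  y <- rnorm(n) + ifelse(strata == "e33_f", 0.4 * g, 0)
  res <- stratified_assoc(y, g, strata_labels = strata)
  expect_lt(res$p[res$stratum == "e33_f"], 1e-6)
  expect_gt(min(res$p[res$stratum != "e33_f"]), 0.01)
  expect_false(any(res$underpowered))
  tiny <- stratified_assoc(y[1:40], g[1:40],
                           strata_labels = rep(c("a", "b"), c(35, 5)))
  expect_true(tiny$underpowered[tiny$stratum == "b"])
})

test_that("locus pheWAS applies MAC, missingness and Bonferroni rules", {
  set.seed(126)
  n <- 400
  g_ok <- rbinom(n, 2, 0.3)
  g_rare <- c(rep(1, 4), rep(0, n - 4))           # MAC 4
  g_miss <- g_ok; g_miss[1:80] <- NA               # 20% missing
  G <- cbind(v_ok = g_ok, v_rare = g_rare, v_miss = g_miss)
  P <- matrix(rnorm(n * 40), n, 40,
              dimnames = list(NULL, paste0("apt", 1:40)))
  P[, 7] <- P[, 7] + 0.5 * g_ok                    # planted trans effect
  res <- locus_phewas(G, P)
  expect_equal(res$threshold, 0.05 / 40)
  expect_setequal(res$excluded_variants$variant, c("v_rare", "v_miss"))
  expect_equal(res$excluded_variants$reason[
    res$excluded_variants$variant == "v_rare"], "mac")
  expect_true(all(res$significant$variant == "v_ok"))
  expect_true("apt7" %in% res$significant$protein)
  expect_lte(nrow(res$significant), 3)  # essentially only the planted one
})
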