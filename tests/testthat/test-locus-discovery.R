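# Windowing, clumping, the sex-bias filter chain and novelty rules.

mk_records <- function(pos, p, chrom = "1") {
  data.frame(variant_id = paste0("v", seq_along(pos)), chrom = chrom,
             pos = pos, p = p, stringsAsFactors = FALSE)
}

test_that("window clustering chains qualifying variants transitively", {
  r <- mk_records(c(1e6, 2.5e6), c(1e-6, 1e-6))
  expect_length(window_cluster(r), 2)
  r2 <- mk_records(c(1.0e6, 1.9e6, 2.8e6), c(1e-6, 1e-6, 1e-6))
  loci <- window_cluster(r2)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$span, c(1.0e6, 2.8e6))
  expect_length(window_cluster(mk_records(1e6, 0.5)), 0)
  # non-qualifying variants between qualifying ones do not bridge
  r3 <- mk_records(c(1e6, 1.5e6, 3e6), c(1e-6, 0.9, 1e-6))
  expect_length(window_cluster(r3), 2)
  expect_error(window_cluster(mk_records(c(2e6, 1e6), c(1e-6, 1e-6))),
               "sorted")
})

test_that("region masking removes APOE-like windows before clustering", {
  r <- mk_records(c(1e6, 6e6), c(1e-9, 1e-9))
  loci <- window_cluster(r, mask = list(chrom = "1", start = 5e6, end = 11e6))
  expect_length(loci, 1)
  expect_equal(loci[[1]]$span, c(1e6, 1e6))
})

test_that("greedy clumping absorbs by LD with deterministic tie-breaks", {
  ld0 <- diag(3); dimnames(ld0) <- list(paste0("v", 1:3), paste0("v", 1:3))
  rows <- mk_records(c(100, 200, 300), c(1e-8, 1e-7, 1e-6))
  sig <- ld_clump(rows, ld0)
  expect_length(sig, 3)
  ld <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(paste0("v", 1:2), paste0("v", 1:2)))
  rows2 <- mk_records(c(100, 200), c(1e-6, 1e-8))
  sig2 <- ld_clump(rows2, ld)
  expect_length(sig2, 1)
  expect_equal(sig2[[1]]$lead, "v2")
  # p tie breaks to the lower position
  rows3 <- mk_records(c(200, 100), c(1e-8, 1e-8))
  rows3$variant_id <- c("v2", "v1")
  sig3 <- ld_clump(rows3, ld)
  expect_equal(sig3[[1]]$lead, "v1")
  bad <- mk_records(100, 1e-8); bad$variant_id <- "vX"
  expect_error(ld_clump(bad, ld0), "missing LD")
})

test_that("clumping output is invariant to input row order", {
  set.seed(40)
  panel <- small_panel()
  ld <- panel_r2(panel)
  rows <- data.frame(variant_id = panel$variant_ids,
                     pos = panel$positions,
                     p = runif(length(panel$variant_ids), 1e-9, 1e-5))
  s1 <- ld_clump(rows, ld)
  s2 <- ld_clump(rows[sample(nrow(rows)), ], ld)
  expect_identical(vapply(s1, `[[`, "", "lead"), vapply(s2, `[[`, "", "lead"))
})

# a merged table with a single-variant locus carrying chosen statistics
mk_merged <- function(p_f, p_m, p_het, id = "v1", pos = 1e6, ratio = 2) {
  data.frame(variant_id = id, chrom = "1", pos = pos, ea = "A", oa = "G",
             eaf = 0.3, beta_f = 0.2, se_f = 0.03, p_f = p_f, n_f = 1e5,
             beta_m = 0.1, se_m = 0.03, p_m = p_m,
             n_m = 1e5, z_het = 2, p_het = p_het, effect_ratio = ratio,
             stringsAsFactors = FALSE)
}

test_that("sex-bias filter keeps genome-wide sex-heterogeneous leads only", {
  ld <- diag(1); dimnames(ld) <- list("v1", "v1")
  loci <- list(list(chrom = "1", span = c(1e6, 1e6), variants = 1L))
  keep <- sex_bias_filter(loci, mk_merged(4e-9, 0.2, 1.2e-3), ld)
  expect_length(keep$loci, 1)
  expect_equal(keep$loci[[1]]$discovery_sex, "female")
  drop_het <- sex_bias_filter(loci, mk_merged(3e-9, 0.2, 0.2), ld)
  expect_length(drop_het$loci, 0)
  expect_equal(drop_het$exclusion_log$reason, "not_het")
  drop_gw <- sex_bias_filter(loci, mk_merged(1e-6, 0.2, 1e-3), ld)
  expect_equal(drop_gw$exclusion_log$reason, "not_gw")
  # het-GWAS route admits sub-genome-wide per-sex signals
  het_route <- sex_bias_filter(loci, mk_merged(2.7e-4, 1.2e-5, 1.28e-8), ld)
  expect_length(het_route$loci, 1)
  expect_equal(het_route$loci[[1]]$discovery_sex, "het_gwas")
})

test_that("known-variant LD exclusion and the single-signal rule fire", {
  ids <- c("v1", "vknown")
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(ids, ids))
  loci <- list(list(chrom = "1", span = c(1e6, 1e6), variants = 1L))
  merged <- mk_merged(4e-9, 0.2, 1.2e-3)
  catalog <- data.frame(variant_id = "vknown", chrom = "1", pos = 1.1e6,
                        p_f = 1e-10, p_m = 0.5, p_sexhet = 0.4, maf = 0.2)
  res <- sex_bias_filter(loci, merged, ld, catalog = catalog)
  expect_length(res$loci, 0)
  expect_equal(res$exclusion_log$reason, "known_variant_ld")
  # catalog variant that is itself sex-heterogeneous does not exclude
  catalog$p_sexhet <- 0.01
  expect_length(sex_bias_filter(loci, merged, ld, catalog = catalog)$loci, 1)
  # two independent signals at one locus: only the best survives
  merged2 <- rbind(mk_merged(4e-9, 0.2, 1.2e-3, id = "v1", pos = 1e6),
                   mk_merged(4e-10, 0.2, 1.0e-3, id = "v2", pos = 1.2e6))
  ld2 <- diag(2); dimnames(ld2) <- list(c("v1", "v2"), c("v1", "v2"))
  loci2 <- list(list(chrom = "1", span = c(1e6, 1.2e6), variants = 1:2))
  res2 <- sex_bias_filter(loci2, merged2, ld2)
  expect_length(res2$loci, 1)
  expect_equal(res2$loci[[1]]$lead, "v2")
  expect_equal(res2$exclusion_log$reason, "secondary_signal")
  # every excluded signal appears exactly once in the log
  expect_equal(anyDuplicated(res2$exclusion_log$variant_id), 0)
})

test_that("low effect ratios warn by default and drop in hard mode", {
  ld <- diag(1); dimnames(ld) <- list("v1", "v1")
  loci <- list(list(chrom = "1", span = c(1e6, 1e6), variants = 1L))
  merged <- mk_merged(4e-9, 0.2, 1.2e-3, ratio = 1.2)
  expect_warning(sex_bias_filter(loci, merged, ld), "ratio")
  res <- suppressWarnings(sex_bias_filter(loci, merged, ld))
  expect_length(res$loci, 1)
  hard <- sex_bias_filter(loci, merged, ld, ratio_hard = TRUE)
  expect_length(hard$loci, 0)
  expect_equal(hard$exclusion_log$reason, "ratio_below_min")
})

test_that("novelty classification follows distance-then-LD with overrides", {
  lead <- mk_merged(1e-9, 0.2, 1e-3, id = "lead", pos = 5e6)
  ids <- c("lead", "known")
  mk_ld <- function(r2) matrix(c(1, r2, r2, 1), 2, dimnames = list(ids, ids))
  far <- data.frame(variant_id = "known", chrom = "1", pos = 7.5e6)
  expect_equal(classify_novelty(lead, far, mk_ld(0.9)),
               "novel_locus_novel_variant")
  near <- data.frame(variant_id = "known", chrom = "1", pos = 5.4e6)
  expect_equal(classify_novelty(lead, near, mk_ld(0.002)),
               "known_locus_novel_variant")
  expect_equal(classify_novelty(lead, near, mk_ld(0.3)),
               "known_locus_known_variant")
  expect_equal(classify_novelty(lead, near, mk_ld(0.3), overrides = "lead"),
               "known_locus_novel_variant")
  expect_error(classify_novelty(lead, near[0, ], mk_ld(0.3)), "catalog")
  nold <- matrix(1, 1, dimnames = list("lead", "lead"))
  expect_error(classify_novelty(lead, near, nold), "missing LD")
})

test_that("cross-ancestry consistency improves, worsens or stays EUR-only", {
  eur <- list(female = list(beta = 0.3, se = 0.05),
              male = list(beta = 0.05, se = 0.05))
  concordant <- list(female = list(beta = 0.35, se = 0.15),
                     male = list(beta = 0.0, se = 0.15))
  expect_equal(afr_consistency(eur, concordant)$status, "yes")
  discordant <- list(female = list(beta = 0.18, se = 0.02),
                     male = list(beta = 0.18, se = 0.02))
  expect_equal(afr_consistency(eur, discordant)$status, "no")
  expect_equal(afr_consistency(eur, NULL)$status, "eur_only")
})

test_that("planted sex-biased loci are recovered end to end", {
  panel <- simulate_panel(8, 6, 0.85, 4000, seed = 41)
  leads <- vapply(1:8, function(b) {
    panel$variant_ids[which(panel$block_map == b)[3]]
  }, "")
  # blocks 1-3 female-biased (ratio 2), 4-6 unbiased, 7-8 null
  eff <- planted_effects(leads[1:6],
                         beta_female = c(rep(0.24, 3), rep(0.2, 3)),
                         beta_male = c(rep(0.12, 3), rep(0.2, 3)))
  cs <- cohort_spec("c", 25000, 25000)
  gf <- simulate_case_control_gwas(panel, eff, cs, "female", seed = 42)
  gm <- simulate_case_control_gwas(panel, eff, cs, "male", seed = 43)
  merged <- merge_sexes(gf, gm)
  res <- suppressWarnings(discover_loci(merged, panel_r2(panel)))
  got <- vapply(res$loci, `[[`, "", "lead")
  biased_blocks <- panel$block_map[match(got, panel$variant_ids)]
  expect_gte(sum(biased_blocks %in% 1:3), 2)
  expect_lte(sum(biased_blocks %in% 4:8), 1)
})
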