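# Seed-deterministic generators for every input the pipeline consumes:
# LD-blocked haplotype panels, sex-stratified case-control GWAS summary
# statistics with planted effects, proxy phenotypes, cis-QTL data with
# known weight models, and a structural-variant locus tagged by SNVs.

# Latent Gaussian correlation that yields a target Pearson correlation
# between two thresholded (binary) variables with frequencies f1, f2.
# P11(rho) is the bivariate normal orthant mass below the two thresholds,
# computed by one-dimensional quadrature of the conditional CDF.
.biv_p11 <- function(rho, t1, t2) {
  if (abs(rho) >= 1) rho <- sign(rho) * 0.999999
  f <- function(z) stats::dnorm(z) * stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2))
  stats::integrate(f, -8.5, t1, rel.tol = 1e-9)$value
}

.latent_rho <- function(target_r, f1, f2) {
  if (target_r == 0) return(0)
  t1 <- stats::qnorm(f1); t2 <- stats::qnorm(f2)
  sd12 <- sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  g <- function(rho) (.biv_p11(rho, t1, t2) - f1 * f2) / sd12 - target_r
  hi <- 0.999999
  if (g(hi) < 0) return(hi)  # target unreachable at these frequencies; saturate
  stats::uniroot(g, c(0, hi), tol = 1e-7)$root
}

#' Simulate an LD-blocked haplotype panel
#'
#' Haplotypes are produced by a block copula: within a block, latent
#' Gaussians follow a first-order autoregression whose latent correlation
#' is calibrated so that *binary* (allele-scale) correlation between
#' adjacent variants equals `within_block_r`; blocks are mutually
#' independent. This exercises clumping and colocalization without a
#' coalescent simulation.
#'
#' @param n_blocks,variants_per_block positive block geometry.
#' @param within_block_r target adjacent-variant allele correlation in
#'   \[0,1).
#' @param n_haplotypes number of haplotypes (2 x individuals).
#' @param seed integer seed; identical seeds give identical panels.
#' @param maf_range range effect-allele frequencies are drawn from.
#' @param chrom chromosome label; `block_gap`/`variant_gap` control base-pair
#'   spacing.
#' @return a `haplotype_panel` list: `variant_ids`, `positions`, `chrom`,
#'   `ea`, `oa`, `eaf` (realized), `haplotypes` (0/1 matrix, 2N x M),
#'   `block_map` (variant -> block index).
#' @export
simulate_panel <- function(n_blocks, variants_per_block, within_block_r,
                           n_haplotypes, seed,
                           maf_range = c(0.15, 0.5), chrom = "1",
                           block_gap = 3e6, variant_gap = 2e4) {
  if (n_blocks < 1 || variants_per_block < 1 || n_haplotypes < 2) {
    stop("panel dimensions must be positive", call. = FALSE)
  }
  if (within_block_r < 0 || within_block_r >= 1) {
    stop("`within_block_r` must lie in [0,1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  m <- n_blocks * variants_per_block
  # one frequency per block: variants in strong LD share similar MAF,
  # and equal frequencies keep any binary correlation in [0,1) feasible
  freq <- rep(stats::runif(n_blocks, maf_range[1], maf_range[2]),
              each = variants_per_block)
  haps <- matrix(0L, n_haplotypes, m)
  block_map <- rep(seq_len(n_blocks), each = variants_per_block)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_map == b)
    z <- stats::rnorm(n_haplotypes)
    haps[, idx[1]] <- as.integer(z < stats::qnorm(freq[idx[1]]))
    if (length(idx) > 1) {
      # frequencies are constant within a block, so one calibration serves
      # every adjacent pair of the block
      rho <- .latent_rho(within_block_r, freq[idx[1]], freq[idx[1]])
      for (k in 2:length(idx)) {
        z <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n_haplotypes)
        haps[, idx[k]] <- as.integer(z < stats::qnorm(freq[idx[k]]))
      }
    }
  }
  pos <- integer(m)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_map == b)
    pos[idx] <- as.integer((b - 1) * block_gap + seq_along(idx) * variant_gap)
  }
  ids <- sprintf("v%d_%d", block_map, stats::ave(seq_len(m), block_map, FUN = seq_along))
  structure(list(
    variant_ids = ids, positions = pos, chrom = chrom,
    ea = rep("A", m), oa = rep("G", m),
    eaf = colMeans(haps), haplotypes = haps, block_map = block_map
  ), class = "haplotype_panel")
}

#' Pairwise allele-scale r-squared between panel variants
#'
#' @param panel a `haplotype_panel`.
#' @param ids optional subset of variant ids.
#' @return square matrix of r^2 with variant ids as dimnames.
#' @export
panel_r2 <- function(panel, ids = NULL) {
  j <- if (is.null(ids)) seq_along(panel$variant_ids) else
    match(ids, panel$variant_ids)
  if (anyNA(j)) stop("unknown variant ids in `ids`", call. = FALSE)
  r <- suppressWarnings(stats::cor(panel$haplotypes[, j, drop = FALSE]))
  r[is.na(r)] <- 0
  out <- r^2
  dimnames(out) <- list(panel$variant_ids[j], panel$variant_ids[j])
  out
}

#' Draw unphased genotypes (dosages) from a haplotype panel
#'
#' @param panel a `haplotype_panel`.
#' @param n individuals; haplotypes are resampled with replacement when
#'   `2n` exceeds the panel.
#' @param seed integer seed.
#' @return n x M integer dosage matrix (columns named by variant id).
#' @export
draw_genotypes <- function(panel, n, seed) {
  set.seed(as.integer(seed))
  nh <- nrow(panel$haplotypes)
  i1 <- sample.int(nh, n, replace = TRUE)
  i2 <- sample.int(nh, n, replace = TRUE)
  g <- panel$haplotypes[i1, , drop = FALSE] + panel$haplotypes[i2, , drop = FALSE]
  colnames(g) <- panel$variant_ids
  g
}

#' Cohort specification for simulated GWAS
#'
#' @param name cohort name.
#' @param n_cases,n_controls positive counts (for proxy designs these are
#'   proxy-case / proxy-control counts).
#' @param design `"case_control"` or `"proxy"`.
#' @param ancestry ancestry label.
#' @return a `cohort_spec` list with derived `case_fraction` and `n_eff`.
#' @export
cohort_spec <- function(name, n_cases, n_controls,
                        design = c("case_control", "proxy"),
                        ancestry = "EUR") {
  design <- match.arg(design)
  .check_pos(n_cases, "n_cases"); .check_pos(n_controls, "n_controls")
  structure(list(
    name = name, n_cases = n_cases, n_controls = n_controls,
    design = design, ancestry = ancestry,
    case_fraction = n_cases / (n_cases + n_controls),
    n_eff = effective_sample_size(n_cases, n_controls, design == "proxy")
  ), class = "cohort_spec")
}

#' Table of planted per-sex variant effects
#'
#' @param variant_id variant ids (must exist in the panel when simulated).
#' @param beta_female,beta_male log-odds effects per sex.
#' @param mechanism `"direct"` or `"via_protein"`.
#' @param target_gene optional mediating gene for `via_protein` effects.
#' @return `data.frame` of planted effects.
#' @export
planted_effects <- function(variant_id, beta_female, beta_male,
                            mechanism = "direct", target_gene = NA_character_) {
  k <- length(variant_id)
  data.frame(variant_id = variant_id, beta_female = beta_female,
             beta_male = beta_male,
             mechanism = rep(mechanism, length.out = k),
             target_gene = rep(target_gene, length.out = k),
             stringsAsFactors = FALSE)
}

#' Simulate a sex-stratified case-control GWAS over a panel
#'
#' Two modes. `"logistic"` samples individual genotypes, draws case status
#' from an additive logistic model (with two APOE-like dosage covariates)
#' and fits per-variant logistic regressions — exact but slow. `"approx"`
#' draws each variant's effect estimate from its asymptotic normal
#' distribution around the LD-induced marginal effect, with the logistic
#' score standard error `1/sqrt(2 f (1-f) N_eff)` — fast, validated against
#' the fit mode. Proxy cohorts attenuate planted effects by
#' `proxy_attenuation` (single-parent transmission heuristic) and carry
#' `N_eff/4`.
#'
#' @param panel a `haplotype_panel`.
#' @param effects output of [planted_effects()]; every `variant_id` must
#'   exist in the panel.
#' @param spec a [cohort_spec()].
#' @param sex `"female"` or `"male"` — selects which planted beta applies.
#' @param seed integer seed.
#' @param mode `"approx"` (default) or `"logistic"`.
#' @param covariate_model list with `apoe_beta` (length-2 effects of the two
#'   APOE-like dosage covariates, logistic mode only) and `apoe_freq`.
#' @param proxy_attenuation divisor applied to planted betas in proxy
#'   cohorts (default 2).
#' @param mac_flag_max records with minor allele count at or below this are
#'   flagged `mac_flag` for the downstream MAC filter (default 20).
#' @return `data.frame` of per-variant association records (columns of
#'   [assoc_record()] plus `mac`, `mac_flag`, `case_fraction`).
#' @export
simulate_case_control_gwas <- function(panel, effects, spec, sex, seed,
                                       mode = c("approx", "logistic"),
                                       covariate_model = list(
                                         apoe_beta = c(0.8, -0.4),
                                         apoe_freq = c(0.15, 0.08)),
                                       proxy_attenuation = 2,
                                       mac_flag_max = 20) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(effects) > 0 && !all(effects$variant_id %in% panel$variant_ids)) {
    missing <- setdiff(effects$variant_id, panel$variant_ids)
    stop(sprintf("effect variants absent from panel: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bcol <- if (identical(sex, "female")) "beta_female" else "beta_male"
  beta_true <- stats::setNames(rep(0, length(panel$variant_ids)), panel$variant_ids)
  if (nrow(effects) > 0) beta_true[effects$variant_id] <- effects[[bcol]]
  if (spec$design == "proxy") beta_true <- beta_true / proxy_attenuation

  m <- length(panel$variant_ids)
  f <- panel$eaf
  neff <- spec$n_eff
  n_total <- spec$n_cases + spec$n_controls
  set.seed(child_seed(seed, paste0(spec$name, "_", sex)))

  if (mode == "approx") {
    # marginal (LD-tagged) effect of each variant given the planted causal set
    marg <- rep(0, m)
    hit <- which(beta_true != 0)
    if (length(hit)) {
      H <- panel$haplotypes
      vj <- apply(H, 2, stats::var)
      for (c_idx in hit) {
        blk <- which(panel$block_map == panel$block_map[c_idx])
        cv <- as.numeric(stats::cov(H[, blk, drop = FALSE], H[, c_idx]))
        marg[blk] <- marg[blk] + cv / vj[blk] * beta_true[c_idx]
      }
    }
    se <- 1 / sqrt(2 * f * (1 - f) * neff)
    beta_hat <- stats::rnorm(m, marg, se)
    mac <- round(2 * n_total * pmin(f, 1 - f))
  } else {
    g <- draw_genotypes(panel, n_total, child_seed(seed, paste0(spec$name, sex, "g")))
    a1 <- stats::rbinom(n_total, 2, covariate_model$apoe_freq[1])
    a2 <- stats::rbinom(n_total, 2, covariate_model$apoe_freq[2])
    eta <- stats::qlogis(spec$case_fraction) +
      g[, names(beta_true), drop = FALSE] %*% beta_true +
      covariate_model$apoe_beta[1] * (a1 - mean(a1)) +
      covariate_model$apoe_beta[2] * (a2 - mean(a2))
    y <- stats::rbinom(n_total, 1, stats::plogis(as.numeric(eta)))
    beta_hat <- se <- numeric(m)
    for (j in seq_len(m)) {
      fit <- suppressWarnings(
        stats::glm(y ~ g[, j] + a1 + a2, family = stats::binomial()))
      co <- summary(fit)$coefficients
      if ("g[, j]" %in% rownames(co)) {
        beta_hat[j] <- co["g[, j]", 1]; se[j] <- co["g[, j]", 2]
      } else {
        beta_hat[j] <- 0; se[j] <- Inf
      }
    }
    f <- colMeans(g) / 2
    mac <- as.integer(round(2 * n_total * pmin(f, 1 - f)))
    neff <- effective_sample_size(sum(y), sum(1 - y),
                                  spec$design == "proxy")
  }
  zp <- z_to_p(beta_hat / se)
  data.frame(
    variant_id = panel$variant_ids, chrom = panel$chrom, pos = panel$positions,
    ea = panel$ea, oa = panel$oa, eaf = f,
    beta = beta_hat, se = se, p = zp$p, neglog10_p = zp$neglog10_p,
    n = neff, info = 1, case_fraction = spec$case_fraction,
    mac = mac, mac_flag = mac <= mac_flag_max,
    stringsAsFactors = FALSE
  )
}

#' Build a proxy phenotype from parental disease history
#'
#' For female analyses the proxy phenotype is maternal disease status:
#' subjects whose mother was affected (at parental age >= `age_min`) are
#' proxy-cases, subjects reporting an affected father are excluded, and
#' parents younger than `age_min` contribute an unknown phenotype.
#' Symmetric for male analyses (paternal status, affected mothers exclude).
#'
#' @param subject_table `data.frame` with `mother_affected`,
#'   `father_affected` (0/1) and `mother_age`, `father_age`.
#' @param sex_of_analysis `"female"` or `"male"`.
#' @param age_min minimum informative parental age (default 65).
#' @return `data.frame` with `phenotype` (1 proxy-case, 0 proxy-control,
#'   NA unknown/excluded), `excluded`, `reason`.
#' @export
build_proxy_phenotype <- function(subject_table, sex_of_analysis, age_min = 65) {
  need <- c("mother_affected", "father_affected", "mother_age", "father_age")
  if (!all(need %in% names(subject_table))) {
    stop("subject table must carry parental affection status and ages",
         call. = FALSE)
  }
  if (identical(sex_of_analysis, "female")) {
    par_aff <- subject_table$mother_affected; par_age <- subject_table$mother_age
    oth_aff <- subject_table$father_affected
  } else {
    par_aff <- subject_table$father_affected; par_age <- subject_table$father_age
    oth_aff <- subject_table$mother_affected
  }
  n <- nrow(subject_table)
  pheno <- rep(NA_real_, n)
  reason <- rep("", n)
  informative <- !is.na(par_age) & par_age >= age_min
  pheno[informative] <- as.numeric(par_aff[informative] == 1)
  reason[!informative] <- "parent_age_unknown"
  excl <- !is.na(oth_aff) & oth_aff == 1
  pheno[excl] <- NA_real_
  reason[excl] <- "other_parent_affected"
  data.frame(phenotype = pheno, excluded = excl, reason = reason,
             stringsAsFactors = FALSE)
}

#' Simulate cis-QTL summary statistics and true weight models
#'
#' Each gene model plants causal cis effects on a protein abundance;
#' per-variant marginal linear regressions within the gene's cis window
#' give the QTL summary statistics, and the planted (variant, effect)
#' pairs form the ground-truth weight model. `shared_with_gwas` labels
#' carry the colocalization ground truth.
#'
#' @param panel a `haplotype_panel`.
#' @param gene_models list of lists, each with `gene_id`, `tss`,
#'   `causal_ids`, `beta` (per causal variant; used for both sexes unless
#'   `beta_male` given) and optional `shared_with_gwas` flag.
#' @param n individuals to simulate.
#' @param seed integer seed.
#' @param cis_window cis half-window in bp (default 1 Mb).
#' @param sigma residual SD of abundance (default 1).
#' @return list per gene: `gene_id`, `qtl` (association table), `weights`
#'   (true weight model), `truth` (`shared_with_gwas`), `genotypes`,
#'   `abundance`.
#' @export
simulate_qtl_and_weights <- function(panel, gene_models, n, seed,
                                     cis_window = 1e6, sigma = 1) {
  out <- vector("list", length(gene_models))
  for (gi in seq_along(gene_models)) {
    gm <- gene_models[[gi]]
    j <- match(gm$causal_ids, panel$variant_ids)
    if (anyNA(j)) stop("causal variant absent from panel", call. = FALSE)
    if (any(abs(panel$positions[j] - gm$tss) > cis_window)) {
      stop(sprintf("causal variant outside the %d bp cis window of %s",
                   cis_window, gm$gene_id), call. = FALSE)
    }
    cis <- which(abs(panel$positions - gm$tss) <= cis_window)
    g <- draw_genotypes(panel, n, child_seed(seed, gm$gene_id))
    set.seed(child_seed(seed, paste0(gm$gene_id, "_y")))
    y <- as.numeric(g[, j, drop = FALSE] %*% gm$beta) + stats::rnorm(n, 0, sigma)
    gc <- g[, cis, drop = FALSE]
    gv <- apply(gc, 2, stats::var)
    gv[gv == 0] <- NA
    b <- as.numeric(stats::cov(gc, y)) / gv
    # residual variance of the marginal fit, variant by variant
    rv <- (stats::var(y) * (n - 1) - b^2 * gv * (n - 1)) / (n - 2)
    se <- sqrt(rv / (gv * (n - 1)))
    zp <- z_to_p(b / se)
    qtl <- data.frame(
      variant_id = panel$variant_ids[cis], chrom = panel$chrom,
      pos = panel$positions[cis], ea = panel$ea[cis], oa = panel$oa[cis],
      eaf = panel$eaf[cis], beta = b, se = se, p = zp$p,
      neglog10_p = zp$neglog10_p, n = n, info = 1,
      stringsAsFactors = FALSE
    )
    out[[gi]] <- list(
      gene_id = gm$gene_id,
      qtl = qtl,
      weights = weight_model(gm$gene_id,
                             variants = gm$causal_ids, weights = gm$beta,
                             window = c(gm$tss - cis_window, gm$tss + cis_window),
                             model_name = "truth", cv_r2 = NA_real_,
                             herit_p = NA_real_),
      truth = list(shared_with_gwas = isTRUE(gm$shared_with_gwas)),
      genotypes = gc, abundance = y
    )
  }
  names(out) <- vapply(gene_models, `[[`, "", "gene_id")
  out
}

#' Simulate a structural-variant locus with SNV tags at target r-squared
#'
#' Generates phased haplotypes carrying a biallelic SV allele plus one tag
#' SNV per requested r^2 target (tags conditionally independent given the
#' SV), then collapses them to unphased genotypes. The feasibility bound
#' r_max^2 = min(p(1-q)/(q(1-p)), q(1-p)/(p(1-q))) for SV frequency p and
#' tag frequency q is enforced.
#'
#' @param n individuals (2n haplotypes).
#' @param tag_r2_targets vector of target phased r^2 values in (0,1].
#' @param sv_freq SV allele frequency in (0,1).
#' @param seed integer seed.
#' @param tag_freqs tag allele frequencies (default = `sv_freq`, which
#'   makes every r^2 up to 1 feasible).
#' @return list with `haplotypes` (2n x (1+K)), `genotypes` (n x (1+K)),
#'   `sv_genotype`, `realized_r2` (phased), `tag_ids`.
#' @export
simulate_sv_locus <- function(n, tag_r2_targets, sv_freq, seed,
                              tag_freqs = rep(sv_freq, length(tag_r2_targets))) {
  if (sv_freq <= 0 || sv_freq >= 1) {
    stop("monomorphic SV: `sv_freq` must lie strictly within (0,1)",
         call. = FALSE)
  }
  if (any(tag_r2_targets <= 0 | tag_r2_targets > 1)) {
    stop("`tag_r2_targets` must lie in (0,1]", call. = FALSE)
  }
  p <- sv_freq
  for (k in seq_along(tag_r2_targets)) {
    q <- tag_freqs[k]
    rmax2 <- min(p * (1 - q) / (q * (1 - p)), q * (1 - p) / (p * (1 - q)))
    if (tag_r2_targets[k] > rmax2 + 1e-12) {
      stop(sprintf(paste0("target r2 %.3f infeasible for frequencies p=%.3f,",
                          " q=%.3f (bound min(p,q)(1-max(p,q))/",
                          "(max(p,q)(1-min(p,q))) = %.3f)"),
                   tag_r2_targets[k], p, q, rmax2), call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  nh <- 2L * n
  sv <- stats::rbinom(nh, 1, p)
  K <- length(tag_r2_targets)
  tags <- matrix(0L, nh, K)
  for (k in seq_len(K)) {
    q <- tag_freqs[k]
    r <- sqrt(tag_r2_targets[k])
    p11 <- p * q + r * sqrt(p * (1 - p) * q * (1 - q))
    pr1 <- min(1, p11 / p)           # P(tag=1 | sv=1)
    pr0 <- max(0, (q - p11) / (1 - p))  # P(tag=1 | sv=0)
    tags[, k] <- ifelse(sv == 1, stats::rbinom(nh, 1, pr1),
                        stats::rbinom(nh, 1, pr0))
  }
  haps <- cbind(SV = sv, tags)
  colnames(haps) <- c("SV", sprintf("tag%d", seq_len(K)))
  i <- seq(1, nh, by = 2)
  geno <- haps[i, , drop = FALSE] + haps[i + 1, , drop = FALSE]
  realized <- vapply(seq_len(K), function(k) .pair_r2(sv, tags[, k]), 0)
  list(haplotypes = haps, genotypes = geno, sv_genotype = geno[, "SV"],
       realized_r2 = stats::setNames(realized, colnames(haps)[-1]),
       tag_ids = colnames(haps)[-1])
}

#' Write a haplotype panel as a (phased) VCF
#'
#' @param panel a `haplotype_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  nh <- nrow(panel$haplotypes)
  stopifnot(nh %% 2 == 0)
  i <- seq(1, nh, by = 2)
  gt <- matrix(paste(panel$haplotypes[i, ], panel$haplotypes[i + 1, ], sep = "|"),
               nrow = length(i))
  samples <- sprintf("S%04d", seq_along(i))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  body <- apply(cbind(panel$chrom, panel$positions, panel$variant_ids,
                      panel$oa, panel$ea, ".", "PASS", ".", "GT",
                      t(gt)), 1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}
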