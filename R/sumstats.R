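# Summary-statistics data model: rescaling, effective sample size,
# fixed/random-effects meta-analysis, sex-heterogeneity testing and QC.

#' Construct a variant association record
#'
#' One variant's association in one stratum (one cohort or one
#' meta-analysis). This is the atomic data unit consumed by meta-analysis,
#' locus discovery, PWAS and colocalization.
#'
#' @param variant_id variant identifier.
#' @param chrom chromosome label.
#' @param pos 1-based base-pair position.
#' @param ea,oa effect and other allele (must differ).
#' @param eaf effect-allele frequency in (0,1).
#' @param beta log-odds (or linear) effect of the effect allele.
#' @param se positive standard error.
#' @param p association p-value; recomputed from `beta/se` when `NULL`.
#' @param n sample size (effective or raw, caller's convention).
#' @param info imputation quality in \[0,1\].
#' @param direction per-cohort sign string ("+", "-", "?" per cohort).
#' @return a one-row `data.frame` of class `assoc_record`.
#' @export
assoc_record <- function(variant_id, chrom, pos, ea, oa, eaf, beta, se,
                         p = NULL, n = NA_real_, info = 1,
                         direction = NA_character_) {
  .check_pos(se, "se")
  if (identical(ea, oa)) stop("effect and other allele must differ", call. = FALSE)
  if (!is.na(eaf) && (eaf <= 0 || eaf >= 1)) {
    stop("`eaf` must lie strictly within (0,1)", call. = FALSE)
  }
  if (is.null(p)) p <- z_to_p(beta / se)$p
  out <- data.frame(
    variant_id = variant_id, chrom = as.character(chrom), pos = as.integer(pos),
    ea = ea, oa = oa, eaf = eaf, beta = beta, se = se, p = p,
    n = n, info = info, direction = direction,
    stringsAsFactors = FALSE
  )
  class(out) <- c("assoc_record", class(out))
  out
}

#' Rescale linear-mixed-model effect estimates to the logistic scale
#'
#' Case-control GWAS run through a linear mixed model report effects on the
#' observed 0/1 scale. Dividing beta and its standard error by mu(1-mu),
#' where mu is the sample case fraction, places them on the standard
#' log-odds scale. The z-score (and therefore the p-value) is invariant.
#'
#' @param beta_raw,se_raw LMM-scale effect and standard error.
#' @param case_fraction sample case fraction mu, strictly in (0,1).
#' @return list with elements `beta` and `se` on the log-odds scale.
#' @export
#' @examples
#' rescale_lmm_to_logistic(0.025, 0.005, 0.5) # beta = 0.1
rescale_lmm_to_logistic <- function(beta_raw, se_raw, case_fraction) {
  if (any(case_fraction <= 0) || any(case_fraction >= 1)) {
    stop("`case_fraction` must be strictly within (0,1)", call. = FALSE)
  }
  .check_pos(se_raw, "se_raw")
  scale <- case_fraction * (1 - case_fraction)
  list(beta = beta_raw / scale, se = se_raw / scale)
}

#' Effective sample size for (proxy) case-control designs
#'
#' N_eff = 4 N v (1-v) with v the case fraction; contributions from
#' proxy-phenotype cohorts (case status inferred from parental history)
#' are divided by 4 to reflect their reduced power.
#'
#' @param n_cases,n_controls positive counts.
#' @param is_proxy logical; proxy-phenotype cohort?
#' @return effective sample size (double).
#' @export
#' @examples
#' effective_sample_size(100, 100)              # 200
#' effective_sample_size(100, 100, is_proxy = TRUE) # 50
effective_sample_size <- function(n_cases, n_controls, is_proxy = FALSE) {
  .check_pos(n_cases, "n_cases")
  .check_pos(n_controls, "n_controls")
  n <- n_cases + n_controls
  v <- n_cases / n
  neff <- 4 * n * v * (1 - v)
  ifelse(is_proxy, neff / 4, neff)
}

# Harmonize a record's alleles to a reference (ea, oa) pair.
# Tries effect/other swap, then strand complement, then both.
# Returns the flipped record or NULL when unresolvable.
.complement <- function(a) chartr("ACGT", "TGCA", toupper(a))

harmonize_alleles <- function(rec, ea, oa) {
  same <- function(x, y) toupper(x) == toupper(y)
  if (same(rec$ea, ea) && same(rec$oa, oa)) return(rec)
  flip <- function(r) {
    r$beta <- -r$beta
    if (!is.na(r$eaf)) r$eaf <- 1 - r$eaf
    tmp <- r$ea; r$ea <- r$oa; r$oa <- tmp
    r
  }
  if (same(rec$ea, oa) && same(rec$oa, ea)) return(flip(rec))
  cea <- .complement(rec$ea); coa <- .complement(rec$oa)
  if (same(cea, ea) && same(coa, oa)) { rec$ea <- ea; rec$oa <- oa; return(rec) }
  if (same(cea, oa) && same(coa, ea)) { rec$ea <- oa; rec$oa <- ea; return(flip(rec)) }
  NULL
}

# Ambiguous strand (A/T, C/G) variants cannot be harmonized reliably when
# near 50% frequency; they are dropped rather than guessed.
is_strand_ambiguous <- function(ea, oa, eaf) {
  pal <- toupper(ea) == .complement(oa)
  pal & !is.na(eaf) & eaf >= 0.4 & eaf <= 0.6
}

.meta_core <- function(records) {
  if (!is.data.frame(records)) records <- do.call(rbind, records)
  if (nrow(records) < 1L) stop("need at least one record", call. = FALSE)
  ref <- records[1, ]
  out <- ref
  if (nrow(records) > 1L) {
    for (i in 2:nrow(records)) {
      h <- harmonize_alleles(records[i, ], ref$ea, ref$oa)
      if (is.null(h)) {
        stop(sprintf("allele mismatch for %s: %s/%s vs %s/%s",
                     records$variant_id[i], records$ea[i], records$oa[i],
                     ref$ea, ref$oa), call. = FALSE)
      }
      records[i, ] <- h
    }
  }
  records
}

#' Fixed-effects (inverse-variance weighted) meta-analysis
#'
#' @param records a `data.frame` of [assoc_record()] rows for the same
#'   variant across cohorts; alleles are harmonized to the first record
#'   (effect/other swap, then strand complement; an unresolvable mismatch
#'   errors).
#' @return one-row `data.frame` with pooled `beta`, `se`, `p`, Cochran's
#'   `q_stat`, `k_cohorts`, `tau2` (0 for fixed effects), a per-cohort
#'   `direction` string and pooled `n`/`eaf`.
#' @export
meta_fixed <- function(records) {
  records <- .meta_core(records)
  w <- 1 / records$se^2
  beta <- sum(w * records$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (records$beta - beta)^2)
  .meta_finish(records, beta, se, q, tau2 = 0)
}

.meta_finish <- function(records, beta, se, q, tau2) {
  zp <- z_to_p(beta / se)
  n <- if (all(is.na(records$n))) NA_real_ else sum(records$n, na.rm = TRUE)
  w0 <- 1 / records$se^2
  eaf <- if (all(is.na(records$eaf))) NA_real_ else {
    sum(w0 * records$eaf, na.rm = TRUE) / sum(w0[!is.na(records$eaf)])
  }
  out <- data.frame(
    variant_id = records$variant_id[1], chrom = records$chrom[1],
    pos = records$pos[1], ea = records$ea[1], oa = records$oa[1],
    eaf = eaf, beta = beta, se = se, p = zp$p, neglog10_p = zp$neglog10_p,
    n = n, info = min(records$info, na.rm = TRUE),
    direction = paste(ifelse(records$beta > 0, "+",
                             ifelse(records$beta < 0, "-", "0")),
                      collapse = ""),
    k_cohorts = nrow(records), q_stat = q, tau2 = tau2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("meta_record", class(out))
  out
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Between-cohort variance tau^2 = max(0, (Q - (k-1)) / (S1 - S2/S1)) with
#' S1 = sum of fixed-effect weights and S2 = sum of squared weights; cohorts
#' are then pooled with weights 1/(se^2 + tau^2). With homogeneous cohorts
#' (Q <= k-1) the result reduces to the fixed-effects one.
#'
#' @inheritParams meta_fixed
#' @return one-row `data.frame` as for [meta_fixed()] with `tau2 >= 0`.
#' @export
meta_random <- function(records) {
  records <- .meta_core(records)
  k <- nrow(records)
  if (k < 2L) stop("random-effects meta-analysis needs >= 2 cohorts", call. = FALSE)
  w <- 1 / records$se^2
  beta_fe <- sum(w * records$beta) / sum(w)
  q <- sum(w * (records$beta - beta_fe)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / denom)
  wr <- 1 / (records$se^2 + tau2)
  beta <- sum(wr * records$beta) / sum(wr)
  se <- sqrt(1 / sum(wr))
  .meta_finish(records, beta, se, q, tau2 = tau2)
}

#' Sex-heterogeneity z-test between female and male effect estimates
#'
#' z = (bF - bM) / sqrt(seF^2 + seM^2 - 2 rho seF seM). With disjoint
#' female/male samples rho = 0; a nonzero rho corrects for stratum overlap.
#' The cross-sex effect ratio max(|bF|,|bM|)/min(|bF|,|bM|) is reported on
#' the log-odds scale; opposite-sign effects still give a well-defined
#' magnitude ratio.
#'
#' @param female,male one-row records (or lists) with `beta` and `se`.
#' @param rho cross-stratum correlation of estimation errors, default 0.
#' @return list with `z_het`, `p_het`, `neglog10_p_het`, `effect_ratio`.
#' @export
sex_heterogeneity_test <- function(female, male, rho = 0) {
  bF <- female$beta; sF <- female$se
  bM <- male$beta; sM <- male$se
  .check_pos(sF, "female se"); .check_pos(sM, "male se")
  v <- sF^2 + sM^2 - 2 * rho * sF * sM
  if (v <= 0) stop("nonpositive heterogeneity variance (check rho)", call. = FALSE)
  z <- (bF - bM) / sqrt(v)
  zp <- z_to_p(z)
  mags <- c(abs(bF), abs(bM))
  ratio <- if (min(mags) == 0) {
    if (max(mags) == 0) NA_real_ else Inf
  } else max(mags) / min(mags)
  list(z_het = z, p_het = zp$p, neglog10_p_het = zp$neglog10_p,
       effect_ratio = ratio)
}

#' Merge per-sex meta-analysis tables and attach sex-heterogeneity statistics
#'
#' @param female_table,male_table per-variant meta tables sharing
#'   `variant_id`; male rows are allele-harmonized to female rows.
#' @param rho cross-stratum correlation passed to
#'   [sex_heterogeneity_test()].
#' @return a `data.frame` with `_f`/`_m` suffixed stratum columns plus
#'   `z_het`, `p_het`, `effect_ratio`.
#' @export
merge_sexes <- function(female_table, male_table, rho = 0) {
  shared <- intersect(female_table$variant_id, male_table$variant_id)
  f <- female_table[match(shared, female_table$variant_id), ]
  m <- male_table[match(shared, male_table$variant_id), ]
  for (i in seq_along(shared)) {
    h <- harmonize_alleles(m[i, ], f$ea[i], f$oa[i])
    if (is.null(h)) next
    m[i, ] <- h
  }
  het <- mapply(function(i) {
    unlist(sex_heterogeneity_test(f[i, ], m[i, ], rho = rho)[
      c("z_het", "p_het", "effect_ratio")])
  }, seq_along(shared))
  out <- data.frame(
    variant_id = shared, chrom = f$chrom, pos = f$pos,
    ea = f$ea, oa = f$oa, eaf = f$eaf,
    beta_f = f$beta, se_f = f$se, p_f = f$p, n_f = f$n,
    beta_m = m$beta, se_m = m$se, p_m = m$p, n_m = m$n,
    z_het = het["z_het", ], p_het = het["p_het", ],
    effect_ratio = het["effect_ratio", ],
    stringsAsFactors = FALSE
  )
  if ("neglog10_p" %in% names(f)) {
    out$neglog10_p_f <- f$neglog10_p
    out$neglog10_p_m <- m$neglog10_p
  }
  out
}

#' Post-meta-analysis variant QC filter
#'
#' Keeps variants that (1) are observed in the designated anchor cohort,
#' (2) reach a minimum cohort coverage ("genotyping rate" across
#' meta-analyzed cohorts), and (3) do not show large allele-frequency
#' deviations across the designated frequency-check cohorts.
#'
#' @param merged_table `data.frame`; one row per variant.
#' @param presence logical matrix (variant x cohort) of per-cohort presence;
#'   column names are cohort names.
#' @param eaf_by_cohort numeric matrix (variant x cohort) of per-cohort
#'   effect-allele frequencies (NA where absent).
#' @param anchor_cohort cohort whose presence is mandatory.
#' @param freq_cohorts cohorts entering the frequency-deviation check;
#'   default all columns of `eaf_by_cohort`.
#' @param rate_min minimum fraction of cohorts in which the variant is
#'   present (default 0.9).
#' @param freq_dev_max maximum allowed pairwise EAF deviation (default 0.2).
#' @return list with `kept` (filtered table) and `drop_log`
#'   (`data.frame` of variant_id + machine-readable `reason`).
#' @export
qc_filter <- function(merged_table, presence, eaf_by_cohort, anchor_cohort,
                      freq_cohorts = colnames(eaf_by_cohort),
                      rate_min = 0.9, freq_dev_max = 0.2) {
  if (!anchor_cohort %in% colnames(presence)) {
    stop(sprintf("unknown anchor cohort '%s'", anchor_cohort), call. = FALSE)
  }
  reasons <- character(nrow(merged_table))
  in_anchor <- presence[, anchor_cohort]
  rate <- rowMeans(presence)
  fsub <- eaf_by_cohort[, intersect(freq_cohorts, colnames(eaf_by_cohort)),
                        drop = FALSE]
  dev <- apply(fsub, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else max(x) - min(x)
  })
  reasons[dev > freq_dev_max] <- "freq_deviation"
  reasons[rate < rate_min] <- "genotyping_rate"
  reasons[!in_anchor] <- "anchor"
  drop <- reasons != ""
  list(
    kept = merged_table[!drop, , drop = FALSE],
    drop_log = data.frame(variant_id = merged_table$variant_id[drop],
                          reason = reasons[drop], stringsAsFactors = FALSE)
  )
}

#' Sample-size-weighted z-score meta-analysis
#'
#' z = (sqrt(n1) z1 + sqrt(n2) z2) / sqrt(n1 + n2); used to combine
#' association z-scores across ancestries when effect scales differ.
#'
#' @param z1,z2 z-scores; `n1,n2` positive (effective) sample sizes.
#' @return combined z-score.
#' @export
meta_z_samplesize <- function(z1, n1, z2, n2) {
  .check_pos(n1, "n1"); .check_pos(n2, "n2")
  (sqrt(n1) * z1 + sqrt(n2) * z2) / sqrt(n1 + n2)
}

#' Write / read GWAS summary statistics (tab-delimited, optionally gzipped)
#'
#' Fixed header CHR, BP, EA, OA, EAF, BETA, SE, P, N, INFO, CASE_FRAC
#' (plus ID and any extra columns present).
#'
#' @param x summary-statistics `data.frame`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly (writer); a `data.frame` (reader).
#' @export
write_sumstats <- function(x, path) {
  map <- c(variant_id = "ID", chrom = "CHR", pos = "BP", ea = "EA", oa = "OA",
           eaf = "EAF", beta = "BETA", se = "SE", p = "P", n = "N",
           info = "INFO", case_fraction = "CASE_FRAC")
  y <- x
  hit <- names(map)[names(map) %in% names(y)]
  names(y)[match(hit, names(y))] <- map[hit]
  data.table::fwrite(y, path, sep = "\t", compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  y <- utils::read.table(con, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  map <- c(ID = "variant_id", CHR = "chrom", BP = "pos", EA = "ea", OA = "oa",
           EAF = "eaf", BETA = "beta", SE = "se", P = "p", N = "n",
           INFO = "info", CASE_FRAC = "case_fraction")
  hit <- names(map)[names(map) %in% names(y)]
  names(y)[match(hit, names(y))] <- map[hit]
  y
}
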