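# From sex-merged genome-wide results to independent sex-biased loci:
# window clustering, LD clumping, the sex-bias filter chain, novelty
# classification and cross-ancestry consistency.

#' Cluster qualifying variants into candidate loci by transitive windowing
#'
#' Variants with p below `p_enter` are merged into one locus whenever
#' consecutive qualifying variants on a chromosome lie within `window` bp
#' (merge-interval semantics of a sliding window).
#'
#' @param records `data.frame` sorted by (chrom, pos) with a `p` column
#'   (the per-sex discovery p used for clustering).
#' @param p_enter entry threshold (default 1e-5).
#' @param window chaining distance in bp (default 1 Mb).
#' @param mask optional region to drop before clustering, list with
#'   `chrom`, `start`, `end` (e.g. the APOE +/-5 Mb region).
#' @return list of loci, each with `chrom`, `span` (min/max qualifying
#'   position) and `variants` (row indices into `records`).
#' @export
window_cluster <- function(records, p_enter = 1e-5, window = 1e6, mask = NULL) {
  ord <- order(records$chrom, records$pos)
  if (!identical(ord, seq_len(nrow(records)))) {
    stop("records must be sorted by (chrom, pos)", call. = FALSE)
  }
  keep <- records$p < p_enter
  if (!is.null(mask)) {
    inmask <- records$chrom == mask$chrom & records$pos >= mask$start &
      records$pos <= mask$end
    keep <- keep & !inmask
  }
  idx <- which(keep)
  if (!length(idx)) return(list())
  loci <- list()
  cur <- idx[1]
  for (i in idx[-1]) {
    last <- cur[length(cur)]
    if (records$chrom[i] == records$chrom[last] &&
        records$pos[i] - records$pos[last] <= window) {
      cur <- c(cur, i)
    } else {
      loci[[length(loci) + 1L]] <- cur
      cur <- i
    }
  }
  loci[[length(loci) + 1L]] <- cur
  lapply(loci, function(v) {
    list(chrom = records$chrom[v[1]],
         span = range(records$pos[v]),
         variants = v)
  })
}

#' Greedy LD clumping of a candidate locus into independent signals
#'
#' The most significant remaining variant seeds a signal and absorbs all
#' variants with r^2 at or above `r2_independent` to it; repeats until no
#' variant remains. P-value ties break to the lower (chrom, pos).
#'
#' @param locus_rows `data.frame` of the locus's qualifying variants with
#'   `variant_id`, `pos`, `p`.
#' @param ld_lookup square r^2 matrix with variant ids as dimnames (e.g.
#'   from [panel_r2()]); missing LD for a candidate lead errors rather than
#'   assuming independence.
#' @param r2_independent independence threshold (default 0.01).
#' @return list of signals: `lead` (variant_id), `lead_row`, `members`
#'   (`data.frame` of variant_id + r2 to lead).
#' @export
ld_clump <- function(locus_rows, ld_lookup, r2_independent = 0.01) {
  rows <- locus_rows[order(locus_rows$p, locus_rows$pos), , drop = FALSE]
  signals <- list()
  while (nrow(rows) > 0) {
    lead <- rows[1, ]
    if (!lead$variant_id %in% rownames(ld_lookup)) {
      stop(sprintf("missing LD for candidate lead %s", lead$variant_id),
           call. = FALSE)
    }
    have <- rows$variant_id %in% colnames(ld_lookup)
    r2 <- rep(NA_real_, nrow(rows))
    r2[have] <- ld_lookup[lead$variant_id, rows$variant_id[have]]
    absorb <- which(!is.na(r2) & r2 >= r2_independent | rows$variant_id == lead$variant_id)
    signals[[length(signals) + 1L]] <- list(
      lead = lead$variant_id, lead_row = lead,
      members = data.frame(variant_id = rows$variant_id[absorb],
                           r2 = r2[absorb], stringsAsFactors = FALSE)
    )
    rows <- rows[-absorb, , drop = FALSE]
  }
  signals
}

#' Sex-bias filtering of clumped signals
#'
#' A signal is retained when its lead reaches genome-wide significance
#' (p < `p_gw`) in one sex with nominal sex heterogeneity
#' (p_het < `p_het_max`), or when the heterogeneity test itself reaches
#' p_het < `p_gw` (het-GWAS route). Signals whose lead is in LD
#' (r^2 > `r2_known`, MAF > `maf_known`) with a known catalog variant that
#' is more significant in the same sex but not sex-heterogeneous are
#' dropped; per locus only the most significant surviving signal is kept.
#' Retained leads with cross-sex effect ratio below `ratio_min` are
#' warned about (optionally dropped with `ratio_hard = TRUE`).
#'
#' @param loci output of [window_cluster()].
#' @param merged sex-merged table ([merge_sexes()] columns).
#' @param ld_lookup r^2 matrix covering leads and catalog variants.
#' @param catalog optional known-variant catalog: `data.frame` with
#'   `variant_id`, `chrom`, `pos`, `p_f`, `p_m`, `p_sexhet`, `maf`.
#' @param p_gw,p_het_max,r2_clump,r2_known,maf_known,ratio_min thresholds.
#' @param ratio_hard drop (not just warn) on ratio violations.
#' @return list with `loci` (retained: one signal each, with
#'   `discovery_sex`) and `exclusion_log` (`data.frame` with reason codes
#'   `not_gw`, `not_het`, `known_variant_ld`, `secondary_signal`,
#'   `ratio_below_min`).
#' @export
sex_bias_filter <- function(loci, merged, ld_lookup, catalog = NULL,
                            p_gw = 5e-8, p_het_max = 0.05,
                            r2_clump = 0.01, r2_known = 0.01,
                            maf_known = 0.01, ratio_min = 1.5,
                            ratio_hard = FALSE) {
  log_rows <- list()
  note <- function(id, reason) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      variant_id = id, reason = reason, stringsAsFactors = FALSE)
  }
  retained <- list()
  for (loc in loci) {
    rows <- merged[loc$variants, , drop = FALSE]
    signals <- ld_clump(
      data.frame(variant_id = rows$variant_id, pos = rows$pos,
                 p = pmin(rows$p_f, rows$p_m), stringsAsFactors = FALSE),
      ld_lookup, r2_independent = r2_clump)
    survivors <- list()
    for (sig in signals) {
      rec <- merged[merged$variant_id == sig$lead, ]
      best_p <- min(rec$p_f, rec$p_m)
      sex <- if (rec$p_f <= rec$p_m) "female" else "male"
      het_route <- rec$p_het < p_gw
      if (best_p >= p_gw && !het_route) { note(sig$lead, "not_gw"); next }
      if (rec$p_het >= p_het_max && !het_route) { note(sig$lead, "not_het"); next }
      # known-variant exclusion
      killed <- FALSE
      if (!is.null(catalog) && nrow(catalog) > 0) {
        for (ci in seq_len(nrow(catalog))) {
          cat_row <- catalog[ci, ]
          if (is.na(cat_row$p_sexhet)) next
          if (!is.na(cat_row$maf) && cat_row$maf <= maf_known) next
          if (!(cat_row$variant_id %in% colnames(ld_lookup)) ||
              !(sig$lead %in% rownames(ld_lookup))) next
          r2 <- ld_lookup[sig$lead, cat_row$variant_id]
          cat_p <- if (sex == "female") cat_row$p_f else cat_row$p_m
          if (!is.na(r2) && r2 > r2_known && !is.na(cat_p) &&
              cat_p < best_p && cat_row$p_sexhet > p_het_max) {
            note(sig$lead, "known_variant_ld"); killed <- TRUE; break
          }
        }
      }
      if (killed) next
      survivors[[length(survivors) + 1L]] <- list(
        signal = sig, rec = rec, p = if (het_route && best_p >= p_gw) rec$p_het else best_p,
        discovery_sex = if (het_route && best_p >= p_gw) "het_gwas" else sex)
    }
    if (!length(survivors)) next
    ps <- vapply(survivors, `[[`, 0, "p")
    keep_i <- which.min(ps)
    for (i in seq_along(survivors)) {
      if (i != keep_i) note(survivors[[i]]$signal$lead, "secondary_signal")
    }
    top <- survivors[[keep_i]]
    ratio <- top$rec$effect_ratio
    if (!is.na(ratio) && ratio < ratio_min) {
      if (ratio_hard) { note(top$signal$lead, "ratio_below_min"); next }
      warning(sprintf("retained lead %s has cross-sex effect ratio %.2f < %.2f",
                      top$signal$lead, ratio, ratio_min), call. = FALSE)
    }
    retained[[length(retained) + 1L]] <- list(
      chrom = loc$chrom, span = loc$span, lead = top$signal$lead,
      lead_rec = top$rec, members = top$signal$members,
      discovery_sex = top$discovery_sex
    )
  }
  excl <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(variant_id = character(), reason = character())
  list(loci = retained, exclusion_log = excl)
}

#' Classify a retained lead's novelty against a known-variant catalog
#'
#' Distance-then-LD rule: leads more than `dist` bp from every catalog
#' variant are "novel_locus_novel_variant"; within `dist` but r^2 below
#' `r2_known` to all nearby catalog variants, "known_locus_novel_variant";
#' otherwise "known_locus_known_variant". Ids in `overrides` are forced to
#' "known_locus_novel_variant" (independent-signal exceptions).
#'
#' @param lead_rec one merged row (needs `variant_id`, `chrom`, `pos`).
#' @param catalog known-variant catalog (`variant_id`, `chrom`, `pos`).
#' @param ld_lookup r^2 matrix covering lead and nearby catalog variants.
#' @param dist proximity threshold in bp (default 1 Mb).
#' @param r2_known LD threshold (default 0.01).
#' @param overrides variant ids forced to the novel-variant class.
#' @return one of the three novelty strings.
#' @export
classify_novelty <- function(lead_rec, catalog, ld_lookup,
                             dist = 1e6, r2_known = 0.01,
                             overrides = character()) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    stop("novelty classification requires a nonempty catalog", call. = FALSE)
  }
  near <- catalog[catalog$chrom == lead_rec$chrom &
                    abs(catalog$pos - lead_rec$pos) <= dist, , drop = FALSE]
  if (nrow(near) == 0) return("novel_locus_novel_variant")
  if (lead_rec$variant_id %in% overrides) return("known_locus_novel_variant")
  for (ci in seq_len(nrow(near))) {
    cid <- near$variant_id[ci]
    if (identical(cid, lead_rec$variant_id)) return("known_locus_known_variant")
    if (!(cid %in% colnames(ld_lookup)) ||
        !(lead_rec$variant_id %in% rownames(ld_lookup))) {
      stop(sprintf("missing LD between %s and catalog variant %s",
                   lead_rec$variant_id, cid), call. = FALSE)
    }
    if (ld_lookup[lead_rec$variant_id, cid] >= r2_known) {
      return("known_locus_known_variant")
    }
  }
  "known_locus_novel_variant"
}

#' Cross-ancestry consistency of a sex-heterogeneous lead
#'
#' Per sex, the European and African-ancestry estimates are combined by
#' fixed-effects meta-analysis and the sex-heterogeneity p recomputed;
#' consistency is "yes" when the combined p_het improves on the
#' European-only p_het, "no" when it does not, and "eur_only" when the
#' variant is absent from the African-ancestry results.
#'
#' @param eur_pair,afr_pair lists with `female` and `male` one-row records
#'   (beta/se); `afr_pair` may be `NULL`.
#' @param rho passed to [sex_heterogeneity_test()].
#' @return list with `status` ("yes"/"no"/"eur_only"), `p_het_eur`,
#'   `p_het_combined`.
#' @export
afr_consistency <- function(eur_pair, afr_pair, rho = 0) {
  het_eur <- sex_heterogeneity_test(eur_pair$female, eur_pair$male, rho)
  if (is.null(afr_pair)) {
    return(list(status = "eur_only", p_het_eur = het_eur$p_het,
                p_het_combined = NA_real_))
  }
  comb <- function(e, a) {
    w <- c(1 / e$se^2, 1 / a$se^2)
    b <- sum(w * c(e$beta, a$beta)) / sum(w)
    list(beta = b, se = sqrt(1 / sum(w)))
  }
  het_all <- sex_heterogeneity_test(comb(eur_pair$female, afr_pair$female),
                                    comb(eur_pair$male, afr_pair$male), rho)
  list(status = if (het_all$p_het < het_eur$p_het) "yes" else "no",
       p_het_eur = het_eur$p_het, p_het_combined = het_all$p_het)
}

#' Full locus-discovery pass over a sex-merged table
#'
#' Convenience wrapper: [window_cluster()] (with optional APOE-region
#' mask) on the per-variant best sex p, then [sex_bias_filter()], then
#' optional novelty classification.
#'
#' @inheritParams window_cluster
#' @inheritParams sex_bias_filter
#' @param merged sex-merged table from [merge_sexes()].
#' @param apoe_region optional mask list (`chrom`, `start`, `end`).
#' @param novelty_catalog optional catalog for [classify_novelty()].
#' @return as [sex_bias_filter()], each retained locus gaining `novelty`
#'   when a catalog was supplied.
#' @export
discover_loci <- function(merged, ld_lookup, catalog = NULL,
                          p_enter = 1e-5, window = 1e6,
                          apoe_region = NULL, novelty_catalog = NULL, ...) {
  work <- merged
  work$p <- pmin(work$p_f, work$p_m)
  cand <- window_cluster(work, p_enter = p_enter, window = window,
                         mask = apoe_region)
  res <- sex_bias_filter(cand, merged, ld_lookup, catalog = catalog, ...)
  if (!is.null(novelty_catalog) && length(res$loci)) {
    for (i in seq_along(res$loci)) {
      res$loci[[i]]$novelty <- classify_novelty(res$loci[[i]]$lead_rec,
                                                novelty_catalog, ld_lookup)
    }
  }
  res
}
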