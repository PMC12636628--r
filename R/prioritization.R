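# Rule-based 1/2/3 gene priority scoring from colocalization, PWAS and
# differential-abundance evidence, plus the final per-sex gene lists.

GENE_SPECIFIC_QTL <- c("eQTL", "sQTL", "pQTL")

#' Assemble a gene's evidence ledger
#'
#' @param gene_id,locus_id identifiers.
#' @param origin `"gwas_locus"` or `"pwas_locus"` (which discovery route
#'   the locus came from — selects the scoring rule set).
#' @param pwas_hit for PWAS-discovered genes: list with `tissue` and
#'   `matched_pqtl_pp4` (PP4 in the matching pQTL tissue; NA when the gene
#'   is unavailable there); `NULL` otherwise.
#' @param xqtl_hits `data.frame` with `qtl_type` (eQTL/sQTL/pQTL/mQTL/
#'   haQTL/caQTL), `dataset` and `pp4`; may be empty.
#' @param da_sex_p,da_interaction_p differential-abundance p-values
#'   (optional).
#' @return an `evidence_ledger` list.
#' @export
evidence_ledger <- function(gene_id, locus_id,
                            origin = c("gwas_locus", "pwas_locus"),
                            pwas_hit = NULL,
                            xqtl_hits = data.frame(qtl_type = character(),
                                                   dataset = character(),
                                                   pp4 = numeric()),
                            da_sex_p = NA_real_, da_interaction_p = NA_real_) {
  origin <- match.arg(origin)
  if (nrow(xqtl_hits) && any(xqtl_hits$pp4 < 0 | xqtl_hits$pp4 > 1)) {
    stop("pp4 values must lie in [0,1]", call. = FALSE)
  }
  structure(list(gene_id = gene_id, locus_id = locus_id, origin = origin,
                 pwas_hit = pwas_hit, xqtl_hits = xqtl_hits,
                 da_sex_p = da_sex_p, da_interaction_p = da_interaction_p),
            class = "evidence_ledger")
}

# count strong gene-specific colocalizations over distinct (qtl_type, dataset)
.n_strong_specific <- function(ledger, thr = 0.7) {
  h <- ledger$xqtl_hits
  h <- h[h$qtl_type %in% GENE_SPECIFIC_QTL & h$pp4 >= thr, , drop = FALSE]
  nrow(unique(h[, c("qtl_type", "dataset")]))
}

#' Priority score for a gene at a GWAS-discovered locus
#'
#' Score 1: more than one strong (PP4 >= 0.7) gene-specific QTL
#' colocalization across distinct tissue/dataset pairs, or a PWAS
#' discovery with strong matching-tissue pQTL colocalization. Score 2:
#' exactly one strong gene-specific colocalization. Score 3 otherwise.
#'
#' @param ledger an [evidence_ledger()] with `origin = "gwas_locus"`.
#' @return a `gene_score` list: `gene_id`, `score`, `rule_fired`.
#' @export
score_gwas_locus_gene <- function(ledger) {
  stopifnot(ledger$origin == "gwas_locus")
  n_strong <- .n_strong_specific(ledger)
  pwas_strong <- !is.null(ledger$pwas_hit) &&
    !is.na(ledger$pwas_hit$matched_pqtl_pp4) &&
    ledger$pwas_hit$matched_pqtl_pp4 >= 0.7
  if (n_strong > 1) return(.gene_score(ledger, 1L, "gwas_multi_strong"))
  if (pwas_strong) return(.gene_score(ledger, 1L, "gwas_pwas_matched_strong"))
  if (n_strong == 1) return(.gene_score(ledger, 2L, "gwas_single_strong"))
  .gene_score(ledger, 3L, "gwas_no_strong")
}

.gene_score <- function(ledger, score, rule, overrides = character()) {
  structure(list(gene_id = ledger$gene_id, locus_id = ledger$locus_id,
                 score = score, rule_fired = rule, overrides = overrides),
            class = "gene_score")
}

#' Priority score for a gene at a PWAS-discovered locus
#'
#' Score 1: PWAS-discovered with strong matching-tissue pQTL
#' colocalization; or a same-locus gene strong in the non-matching pQTL
#' tissue while unavailable in the matching one; or a same-locus gene with
#' more than one strong gene-specific colocalization. Score 2:
#' matching-tissue suggestive colocalization (upgraded to 1 when any other
#' gene-specific strong hit exists); or exactly one strong gene-specific
#' colocalization. Score 3 otherwise.
#'
#' @param ledger an [evidence_ledger()] with `origin = "pwas_locus"`. For
#'   non-PWAS genes at the locus, `pwas_hit` may carry
#'   `nonmatching_pp4`/`matched_unavailable` fields.
#' @return a `gene_score`.
#' @export
score_pwas_locus_gene <- function(ledger) {
  stopifnot(ledger$origin == "pwas_locus")
  n_strong <- .n_strong_specific(ledger)
  ph <- ledger$pwas_hit
  matched <- if (!is.null(ph)) ph$matched_pqtl_pp4 else NA_real_
  if (!is.null(ph) && !is.na(matched) && matched >= 0.7) {
    return(.gene_score(ledger, 1L, "pwas_matched_strong"))
  }
  if (!is.null(ph) && isTRUE(ph$matched_unavailable) &&
      !is.null(ph$nonmatching_pp4) && !is.na(ph$nonmatching_pp4) &&
      ph$nonmatching_pp4 >= 0.7) {
    return(.gene_score(ledger, 1L, "pwas_nonmatching_strong_unavailable"))
  }
  if (n_strong > 1) return(.gene_score(ledger, 1L, "pwas_multi_strong"))
  if (!is.null(ph) && !is.na(matched) && matched >= 0.4 && matched < 0.7) {
    if (n_strong >= 1) return(.gene_score(ledger, 1L, "pwas_suggestive_upgraded"))
    return(.gene_score(ledger, 2L, "pwas_matched_suggestive"))
  }
  if (n_strong == 1) return(.gene_score(ledger, 2L, "pwas_single_strong"))
  .gene_score(ledger, 3L, "pwas_no_support")
}

#' Sex and sex-by-status differential abundance of proteins
#'
#' Per protein, `da_sex_p` is the sex main effect from
#' `protein ~ sex + diagnosis + covariates` over all subjects, and
#' `da_interaction_p` the sex x status interaction from
#' `protein ~ sex * status + covariates` restricted to biomarker-defined
#' controls (A-T-) and cases (A+T+).
#'
#' @param abundance proteins x samples numeric matrix (or samples in
#'   rows with `samples_in_rows = TRUE`).
#' @param sex factor-like, length = samples.
#' @param diagnosis factor-like diagnosis adjustment.
#' @param at_status per-sample "A-T-"/"A+T+" labels (others excluded
#'   from the interaction analysis; NA allowed).
#' @param covariates optional covariate data.frame.
#' @param min_cell minimum subjects per sex x status cell for the
#'   interaction analysis (default 10).
#' @param samples_in_rows orientation flag.
#' @return `data.frame` per protein: `protein`, `da_sex_p`,
#'   `da_interaction_p` (NA when skipped), `skipped_reason`.
#' @export
differential_abundance <- function(abundance, sex, diagnosis, at_status,
                                   covariates = NULL, min_cell = 10,
                                   samples_in_rows = FALSE) {
  if (samples_in_rows) abundance <- t(abundance)
  proteins <- rownames(abundance) %||% paste0("p", seq_len(nrow(abundance)))
  sex <- factor(sex)
  diagnosis <- factor(diagnosis)
  base <- data.frame(sex = sex, diagnosis = diagnosis)
  if (!is.null(covariates)) base <- cbind(base, covariates)
  cc <- !is.na(at_status) & at_status %in% c("A-T-", "A+T+")
  status <- factor(at_status[cc], levels = c("A-T-", "A+T+"))
  cells_ok <- sum(cc) > 0 && all(table(sex[cc], status) >= min_cell)
  cov_terms <- if (is.null(covariates)) character() else names(covariates)
  f_main <- stats::as.formula(paste(c("y ~ sex + diagnosis", cov_terms),
                                    collapse = " + "))
  f_int <- stats::as.formula(paste(c("y ~ sex * status", cov_terms),
                                   collapse = " + "))
  base_cc <- base[cc, , drop = FALSE]
  base_cc$status <- status
  out <- lapply(seq_len(nrow(abundance)), function(i) {
    d <- base
    d$y <- abundance[i, ]
    sm <- summary(stats::lm(f_main, data = d))$coefficients
    sex_row <- grep("^sex", rownames(sm))
    da_sex <- if (length(sex_row)) sm[sex_row[1], 4] else NA_real_
    if (cells_ok) {
      dcc <- base_cc
      dcc$y <- abundance[i, cc]
      sm2 <- summary(stats::lm(f_int, data = dcc))$coefficients
      int_row <- grep(":", rownames(sm2))
      da_int <- if (length(int_row)) sm2[int_row[1], 4] else NA_real_
      reason <- ""
    } else {
      da_int <- NA_real_
      reason <- "cell_below_min"
    }
    data.frame(protein = proteins[i], da_sex_p = da_sex,
               da_interaction_p = da_int, skipped_reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Upgrade score-3 genes with nominal differential-abundance support
#'
#' @param score a `gene_score`.
#' @param ledger the gene's [evidence_ledger()].
#' @return the (possibly upgraded) `gene_score`; score-3 genes with
#'   `da_sex_p < 0.05` or `da_interaction_p < 0.05` become score 2 with
#'   rule id `"da_upgrade"`.
#' @export
apply_da_upgrade <- function(score, ledger) {
  if (score$score != 3L) return(score)
  hit <- (!is.na(ledger$da_sex_p) && ledger$da_sex_p < 0.05) ||
    (!is.na(ledger$da_interaction_p) && ledger$da_interaction_p < 0.05)
  if (hit) return(.gene_score(ledger, 2L, "da_upgrade"))
  score
}

#' Score a list of evidence ledgers (with DA upgrade)
#'
#' @param ledgers list of [evidence_ledger()]s.
#' @return `data.frame` with `gene_id`, `locus_id`, `score`, `rule_fired`.
#' @export
score_genes <- function(ledgers) {
  rows <- lapply(ledgers, function(led) {
    s <- if (led$origin == "gwas_locus") score_gwas_locus_gene(led)
    else score_pwas_locus_gene(led)
    s <- apply_da_upgrade(s, led)
    data.frame(gene_id = s$gene_id, locus_id = s$locus_id, score = s$score,
               rule_fired = s$rule_fired, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the final per-sex prioritized gene lists
#'
#' Literature/missense overrides force score 1 (provenance recorded);
#' excluded loci are dropped entirely; output is sorted by (score,
#' locus).
#'
#' @param scores `data.frame` from [score_genes()] plus a `sex` column.
#' @param literature_overrides named character vector: gene_id ->
#'   provenance (`"literature"` or `"missense_cadd"`).
#' @param excluded_loci locus ids to drop.
#' @return named list of per-sex `data.frame`s with `provenance`.
#' @export
assemble_final_lists <- function(scores, literature_overrides = character(),
                                 excluded_loci = character()) {
  if (length(literature_overrides)) {
    unknown <- setdiff(names(literature_overrides), scores$gene_id)
    if (length(unknown)) {
      stop(sprintf("override for unknown gene(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  scores$provenance <- "evidence"
  hit <- scores$gene_id %in% names(literature_overrides)
  scores$score[hit] <- 1L
  scores$rule_fired[hit] <- "override"
  scores$provenance[hit] <- literature_overrides[scores$gene_id[hit]]
  scores <- scores[!scores$locus_id %in% excluded_loci, , drop = FALSE]
  scores <- scores[order(scores$score, scores$locus_id), , drop = FALSE]
  split(scores, scores$sex)
}
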