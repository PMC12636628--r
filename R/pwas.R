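# Proteome-wide association: variant-weight model training, the
# summary-statistic weighted-burden test, grouped FDR, and the
# sex-specificity / consistency classification rules.

#' Construct a variant weight model
#'
#' @param gene_id gene / protein identifier.
#' @param variants,weights aligned variant ids and signed weights (at
#'   least one nonzero).
#' @param window cis window (start, end) in bp.
#' @param model_name one of `"top1"`, `"lasso"`, `"enet"`, `"ridge_blup"`
#'   (or `"truth"` for generator ground truth).
#' @param cv_r2 cross-validated predictive r^2 of the chosen model.
#' @param herit_p heritability screening p-value.
#' @param tissue,stratum metadata labels.
#' @return a `weight_model` list.
#' @export
weight_model <- function(gene_id, variants, weights, window,
                         model_name, cv_r2, herit_p,
                         tissue = "brain", stratum = "combined") {
  if (length(variants) != length(weights)) {
    stop("variants and weights must align", call. = FALSE)
  }
  if (!any(weights != 0)) stop("model needs >= 1 nonzero weight", call. = FALSE)
  structure(list(gene_id = gene_id, variants = variants, weights = weights,
                 window = window, model_name = model_name, cv_r2 = cv_r2,
                 herit_p = herit_p, tissue = tissue, stratum = stratum),
            class = "weight_model")
}

#' Serialize / restore weight models as JSON
#' @param model a `weight_model`; `path` file path.
#' @return `path` invisibly (writer); a `weight_model` (reader).
#' @export
write_weight_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weight_model
#' @export
read_weight_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(weight_model, x)
}

# residualize a vector on a covariate matrix (with intercept)
.residualize <- function(y, covariates) {
  if (is.null(covariates) || NCOL(covariates) == 0) return(y - mean(y))
  stats::lm.fit(cbind(1, as.matrix(covariates)), y)$residuals
}

# out-of-fold CV r^2 of the single-best-marginal-variant ("top1") model
.top1_cv_r2 <- function(g, y, folds) {
  yhat <- numeric(length(y))
  for (f in unique(folds)) {
    tr <- folds != f
    gt <- g[tr, , drop = FALSE]
    cv <- as.numeric(crossprod(scale(gt, scale = FALSE), y[tr] - mean(y[tr])))
    vv <- colSums(scale(gt, scale = FALSE)^2)
    vv[vv == 0] <- Inf
    b <- cv / vv
    j <- which.max(abs(b) * sqrt(vv))  # max |t| ~ max marginal evidence
    yhat[!tr] <- mean(y[tr]) + b[j] * (g[!tr, j] - mean(gt[, j]))
  }
  r <- suppressWarnings(stats::cor(yhat, y))
  if (is.na(r)) 0 else max(0, r)^2
}

#' Train a cis variant-weight model for protein abundance
#'
#' Abundance is residualized on covariates, screened for SNP-based
#' signal by a permutation p-value of cross-validated predictive r^2
#' (genes failing `herit_p_max` return a herit-fail), then fit with
#' top1, lasso, elastic net and ridge (the dense BLUP-like model);
#' the model with the best 5-fold CV r^2 wins.
#'
#' @param genotypes n x m dosage matrix, columns named by variant id.
#' @param abundance length-n protein abundance vector.
#' @param covariates optional n x c covariate matrix.
#' @param window cis window (start, end) recorded on the model.
#' @param stratum `"female"`, `"male"` or `"combined"`.
#' @param seed integer seed (folds and permutations).
#' @param n_perm permutations for the heritability screen (default 200).
#' @param herit_p_max screening threshold (default 0.01).
#' @param tissue tissue label.
#' @return a `weight_model`, or a list with `herit_fail = TRUE` and
#'   `reason`/`herit_p` when the gene fails the screen.
#' @export
train_weights <- function(genotypes, abundance, covariates = NULL,
                          window = c(NA_real_, NA_real_),
                          stratum = "combined", seed = 1L,
                          n_perm = 200, herit_p_max = 0.01,
                          tissue = "brain") {
  g <- as.matrix(genotypes)
  poly <- apply(g, 2, stats::var) > 0
  if (!any(poly)) {
    return(list(herit_fail = TRUE, reason = "no_polymorphic_variants",
                herit_p = NA_real_))
  }
  g <- g[, poly, drop = FALSE]
  y <- .residualize(abundance, covariates)
  set.seed(as.integer(seed))
  n <- length(y)
  folds <- sample(rep(seq_len(5), length.out = n))
  obs <- .top1_cv_r2(g, y, folds)
  perm <- vapply(seq_len(n_perm), function(i) {
    .top1_cv_r2(g, sample(y), folds)
  }, 0)
  herit_p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  if (herit_p >= herit_p_max) {
    return(list(herit_fail = TRUE, reason = "heritability_screen",
                herit_p = herit_p))
  }
  # candidate models, 5-fold CV r^2 each
  cand <- list()
  cand$top1 <- local({
    cv <- as.numeric(crossprod(scale(g, scale = FALSE), y - mean(y)))
    vv <- colSums(scale(g, scale = FALSE)^2); vv[vv == 0] <- Inf
    b <- cv / vv
    j <- which.max(abs(b) * sqrt(vv))
    w <- numeric(ncol(g)); w[j] <- b[j]
    list(weights = w, cv_r2 = obs)
  })
  vy <- stats::var(y)
  alphas <- c(lasso = 1, enet = 0.5, ridge_blup = 0)
  for (nm in names(alphas)) {
    fit <- tryCatch(
      glmnet::cv.glmnet(g, y, alpha = alphas[[nm]], nfolds = 5,
                        foldid = folds, standardize = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) next
    w <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
    if (!any(w != 0)) next
    cand[[nm]] <- list(weights = w,
                       cv_r2 = max(0, 1 - min(fit$cvm) / vy))
  }
  best <- names(cand)[which.max(vapply(cand, `[[`, 0, "cv_r2"))]
  weight_model(gene_id = attr(genotypes, "gene_id") %||% "gene",
               variants = colnames(g), weights = cand[[best]]$weights,
               window = window, model_name = best,
               cv_r2 = cand[[best]]$cv_r2, herit_p = herit_p,
               tissue = tissue, stratum = stratum)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed allele-scale correlation between panel variants
#' @inheritParams panel_r2
#' @return square correlation matrix (signed r).
#' @export
panel_cor <- function(panel, ids = NULL) {
  j <- if (is.null(ids)) seq_along(panel$variant_ids) else
    match(ids, panel$variant_ids)
  r <- suppressWarnings(stats::cor(panel$haplotypes[, j, drop = FALSE]))
  r[is.na(r)] <- 0
  dimnames(r) <- list(panel$variant_ids[j], panel$variant_ids[j])
  r
}

#' Weighted-burden PWAS association from GWAS summary statistics
#'
#' z = w'z_gwas / sqrt(w' R w) over the variants shared between the weight
#' model and the GWAS, with R the signed LD correlation matrix shrunk
#' toward identity (`lambda`) and eigenvalue-floored to positive definite.
#' Coverage is the fraction of absolute weight mass retained after
#' intersection; genes below `coverage_floor` are refused.
#'
#' @param model a `weight_model`.
#' @param gwas_records GWAS table with `variant_id`, `beta`, `se`.
#' @param ld_lookup signed correlation matrix (e.g. [panel_cor()]).
#' @param coverage_floor minimum retained weight mass (default 0.5).
#' @param lambda shrinkage toward identity (default 0.1).
#' @return list with `z`, `p`, `coverage`, `n_variants`.
#' @export
pwas_assoc <- function(model, gwas_records, ld_lookup,
                       coverage_floor = 0.5, lambda = 0.1) {
  keep <- model$variants %in% gwas_records$variant_id
  coverage <- sum(abs(model$weights[keep])) / sum(abs(model$weights))
  if (!any(keep)) stop("no model variant present in GWAS", call. = FALSE)
  if (coverage < coverage_floor) {
    stop(sprintf("weight coverage %.2f below floor %.2f", coverage,
                 coverage_floor), call. = FALSE)
  }
  v <- model$variants[keep]
  w <- model$weights[keep]
  nz <- w != 0
  v <- v[nz]; w <- w[nz]
  gi <- match(v, gwas_records$variant_id)
  z <- gwas_records$beta[gi] / gwas_records$se[gi]
  if (!all(v %in% rownames(ld_lookup))) {
    stop("LD lookup does not cover all model variants", call. = FALSE)
  }
  R <- ld_lookup[v, v, drop = FALSE]
  R <- (1 - lambda) * R + lambda * diag(length(v))
  ev <- eigen(R, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-8)
  R <- ev$vectors %*% (vals * t(ev$vectors))
  denom <- as.numeric(t(w) %*% R %*% w)
  if (denom <= 0 || !is.finite(denom)) stop("singular LD after regularization",
                                            call. = FALSE)
  zb <- sum(w * z) / sqrt(denom)
  list(z = zb, p = z_to_p(zb)$p, coverage = coverage, n_variants = length(v))
}

#' Benjamini-Hochberg FDR within analysis groups
#'
#' @param pvalues p-values in (0,1].
#' @param grouping factor-like; BH is applied within each level (e.g. each
#'   GWAS x weights x tissue combination).
#' @return vector of q-values aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, grouping = rep(1L, length(pvalues))) {
  if (!length(pvalues)) return(numeric())
  as.numeric(stats::ave(pvalues, grouping,
                        FUN = function(p) stats::p.adjust(p, "BH")))
}

#' Classify proteins as sex-biased from the full grid of PWAS runs
#'
#' A protein is female-biased when it is FDR-significant in the
#' female-GWAS x female-weights run (primary discovery) or the
#' female-GWAS x combined-weights run (secondary), and every available
#' male-GWAS run (male, female or combined weights) is either discordant
#' in effect direction or above nominal significance (p > 0.05);
#' symmetric for male. Loci whose most significant associated protein is
#' not sex-biased have all their proteins demoted to not sex-biased.
#'
#' @param results `data.frame` with `gene_id`, `gwas_sex`
#'   ("female"/"male"), `weight_stratum` ("female"/"male"/"combined"),
#'   `tissue`, `z`, `p`, `p_fdr`.
#' @param locus_map optional `data.frame` (`gene_id`, `locus_id`) enabling
#'   the locus demotion rule.
#' @param alpha_fdr,alpha_nominal thresholds (0.05, 0.05).
#' @return `data.frame`: `gene_id`, `sex_bias` ("female"/"male"/"none"),
#'   `discovery` ("primary"/"secondary"/"both"/"none"), `best_p`.
#' @export
classify_sex_specific <- function(results, locus_map = NULL,
                                  alpha_fdr = 0.05, alpha_nominal = 0.05) {
  genes <- sort(unique(results$gene_id))
  out <- lapply(genes, function(g) {
    rg <- results[results$gene_id == g, , drop = FALSE]
    judge <- function(sex) {
      opp <- setdiff(c("female", "male"), sex)
      prim <- rg[rg$gwas_sex == sex & rg$weight_stratum == sex, , drop = FALSE]
      seco <- rg[rg$gwas_sex == sex & rg$weight_stratum == "combined", , drop = FALSE]
      hit_p <- nrow(prim) > 0 && any(prim$p_fdr < alpha_fdr)
      hit_s <- nrow(seco) > 0 && any(seco$p_fdr < alpha_fdr)
      if (!hit_p && !hit_s) return(NULL)
      disc_rows <- rbind(if (hit_p) prim[prim$p_fdr < alpha_fdr, ],
                         if (hit_s) seco[seco$p_fdr < alpha_fdr, ])
      disc_sign <- sign(disc_rows$z[which.min(disc_rows$p)])
      oppo <- rg[rg$gwas_sex == opp, , drop = FALSE]
      ok <- nrow(oppo) == 0 ||
        all(sign(oppo$z) != disc_sign | oppo$p > alpha_nominal)
      if (!ok) return(NULL)
      list(sex = sex,
           discovery = if (hit_p && hit_s) "both" else if (hit_p) "primary" else "secondary",
           best_p = min(disc_rows$p))
    }
    f <- judge("female"); m <- judge("male")
    hit <- if (!is.null(f)) f else m
    data.frame(gene_id = g,
               sex_bias = if (is.null(hit)) "none" else hit$sex,
               discovery = if (is.null(hit)) "none" else hit$discovery,
               best_p = if (is.null(hit))
                 suppressWarnings(min(rg$p)) else hit$best_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(locus_map)) {
    sig_gene <- vapply(out$gene_id, function(g) {
      rg <- results[results$gene_id == g, ]
      any(rg$p_fdr < alpha_fdr &
            ((rg$gwas_sex == rg$weight_stratum) | rg$weight_stratum == "combined"))
    }, TRUE)
    out$locus_id <- locus_map$locus_id[match(out$gene_id, locus_map$gene_id)]
    for (loc in unique(stats::na.omit(out$locus_id))) {
      at <- which(out$locus_id == loc & sig_gene)
      if (length(at) < 2) next
      top <- at[which.min(out$best_p[at])]
      if (out$sex_bias[top] == "none") {
        out$sex_bias[at] <- "none"
        out$discovery[at] <- "none"
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Cross-ancestry consistency of a sex-biased PWAS protein
#'
#' Consistent when the sample-size-weighted meta z of the discovery sex
#' gives a smaller p than the European-only result while the opposite
#' sex's meta p stays above 0.05.
#'
#' @param z_disc_eur,z_disc_afr discovery-sex z per ancestry.
#' @param z_opp_eur,z_opp_afr opposite-sex z per ancestry.
#' @param n_eur,n_afr (effective) sample sizes.
#' @return logical.
#' @export
afr_consistency_pwas <- function(z_disc_eur, z_disc_afr,
                                 z_opp_eur, z_opp_afr, n_eur, n_afr) {
  zd <- meta_z_samplesize(z_disc_eur, n_eur, z_disc_afr, n_afr)
  zo <- meta_z_samplesize(z_opp_eur, n_eur, z_opp_afr, n_afr)
  z_to_p(zd)$p < z_to_p(z_disc_eur)$p && z_to_p(zo)$p > 0.05
}

#' Proxy-exclusion sensitivity consistency
#'
#' Consistent when the no-proxy rerun keeps the discovery sex's effect
#' direction with p < 0.05 while the opposite sex stays above 0.05.
#'
#' @param full,noproxy lists with `z_disc`, `p_disc`, `p_opp` from the
#'   full and proxy-excluded analyses.
#' @return logical.
#' @export
sensitivity_consistency <- function(full, noproxy) {
  sign(noproxy$z_disc) == sign(full$z_disc) &&
    noproxy$p_disc < 0.05 && noproxy$p_opp > 0.05
}

#' Drop variants inside a masked genomic region (e.g. the MHC)
#'
#' @param table `data.frame` with `chrom` and `pos`.
#' @param chrom,start,end region to remove (1-based inclusive).
#' @return filtered table.
#' @export
mask_region <- function(table, chrom, start, end) {
  drop <- table$chrom == chrom & table$pos >= start & table$pos <= end
  table[!drop, , drop = FALSE]
}
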