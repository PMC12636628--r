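# Structural-variant-aware locus dissection: two-locus LD from unphased
# genotypes via the cubic (Hill) haplotype-frequency equation, tag-panel
# selection, SV genotype imputation with repeated-split evaluation,
# conditional / stratified association and a locus pheWAS.

#' Cross-tabulate two dosage vectors into a 3x3 genotype table
#'
#' @param g1,g2 dosage vectors in \{0,1,2\} (NA pairs dropped).
#' @return 3x3 integer matrix n_ij, i = dosage at locus 1 + 1.
#' @export
two_locus_table <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  t0 <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  matrix(as.integer(t0), 3, 3)
}

# EM for the AB haplotype frequency from a 3x3 genotype table
.em_fab <- function(tab, tol = 1e-12, max_iter = 5000) {
  n <- sum(tab)
  p <- sum(tab * matrix(0:2, 3, 3, byrow = FALSE)) / (2 * n)  # allele 1 at locus 1
  q <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  ndh <- tab[2, 2]
  # counts of unambiguous AB haplotypes
  cAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  f <- p * q
  for (it in seq_len(max_iter)) {
    f12 <- p - f; f21 <- q - f; f22 <- 1 - p - q + f
    num <- f * f22
    den <- f * f22 + f12 * f21
    a <- if (den <= 0) 0 else num / den
    f_new <- (cAB + ndh * a) / (2 * n)
    if (abs(f_new - f) < tol) { f <- f_new; break }
    f <- f_new
  }
  f
}

# multinomial log-likelihood of a 3x3 table given haplotype freq f_AB
.ll_fab <- function(tab, p, q, f) {
  f11 <- f; f12 <- p - f; f21 <- q - f; f22 <- 1 - p - q + f
  h <- c(f11, f12, f21, f22)
  if (any(h < -1e-12)) return(-Inf)
  h <- pmax(h, 0)
  gp <- matrix(0, 3, 3)
  # genotype probabilities under HWE on haplotypes
  # dosage at locus1 = copies of allele A (freq p) etc.
  gp[3, 3] <- f11^2;              gp[3, 2] <- 2 * f11 * f12;      gp[3, 1] <- f12^2
  gp[2, 3] <- 2 * f11 * f21
  gp[2, 2] <- 2 * f11 * f22 + 2 * f12 * f21
  gp[2, 1] <- 2 * f12 * f22
  gp[1, 3] <- f21^2;              gp[1, 2] <- 2 * f21 * f22;      gp[1, 1] <- f22^2
  sel <- tab > 0
  sum(tab[sel] * log(pmax(gp[sel], 1e-300)))
}

#' Two-locus LD from unphased genotypes via the cubic Hill equation
#'
#' The EM stationarity condition for the AB haplotype frequency under
#' Hardy-Weinberg reduces to a cubic; all real roots inside the
#' admissible interval \[max(0, p+q-1), min(p,q)\] are evaluated and the
#' root maximizing the multinomial likelihood is returned (the number of
#' valid roots is recorded). When no valid root is found numerically, an
#' EM fallback is used. D, D' and r^2 follow from f_AB.
#'
#' @param tab 3x3 genotype count table ([two_locus_table()]).
#' @return list with `f_AB`, `p`, `q`, `D`, `D_prime`, `r2`,
#'   `n_valid_roots`.
#' @export
cubex_ld <- function(tab) {
  tab <- matrix(as.numeric(tab), 3, 3)
  n <- sum(tab)
  if (n == 0) stop("empty genotype table", call. = FALSE)
  p <- sum(tab * matrix(0:2, 3, 3, byrow = FALSE)) / (2 * n)
  q <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) {
    stop("both loci must be polymorphic", call. = FALSE)
  }
  ndh <- tab[2, 2]
  cAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  # stationary equation: (2n f - cAB) (f f22 + f12 f21) = ndh f f22,
  # a cubic in f; coefficients recovered exactly by interpolation.
  g <- function(f) {
    f12 <- p - f; f21 <- q - f; f22 <- 1 - p - q + f
    (2 * n * f - cAB) * (f * f22 + f12 * f21) - ndh * f * f22
  }
  xs <- c(0, 1 / 3, 2 / 3, 1)
  V <- outer(xs, 0:3, `^`)
  coefs <- solve(V, vapply(xs, g, 0))
  roots <- polyroot(coefs)
  lo <- max(0, p + q - 1); hi <- min(p, q)
  real <- Re(roots)[abs(Im(roots)) < 1e-8]
  eps <- 1e-9
  valid <- unique(pmin(pmax(real[real >= lo - 1e-6 & real <= hi + 1e-6], lo + 0), hi))
  valid <- valid[valid >= lo - eps & valid <= hi + eps]
  if (!length(valid)) {
    f <- .em_fab(tab)
    n_valid <- 0L
  } else {
    ll <- vapply(valid, function(f) .ll_fab(tab, p, q, f), 0)
    f <- valid[which.max(ll)]
    n_valid <- length(valid)
  }
  D <- f - p * q
  dmax <- if (D >= 0) min(p * (1 - q), q * (1 - p)) else min(p * q, (1 - p) * (1 - q))
  list(f_AB = f, p = p, q = q, D = D,
       D_prime = if (dmax > 0) D / dmax else 0,
       r2 = D^2 / (p * (1 - p) * q * (1 - q)),
       n_valid_roots = n_valid)
}

#' EM estimate of two-locus LD (reference fixed point)
#'
#' @inheritParams cubex_ld
#' @return list as [cubex_ld()] (without root count).
#' @export
em_ld <- function(tab) {
  tab <- matrix(as.numeric(tab), 3, 3)
  n <- sum(tab)
  p <- sum(tab * matrix(0:2, 3, 3, byrow = FALSE)) / (2 * n)
  q <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  f <- .em_fab(tab)
  D <- f - p * q
  dmax <- if (D >= 0) min(p * (1 - q), q * (1 - p)) else min(p * q, (1 - p) * (1 - q))
  list(f_AB = f, p = p, q = q, D = D,
       D_prime = if (dmax > 0) D / dmax else 0,
       r2 = D^2 / (p * (1 - p) * q * (1 - q)))
}

#' Select tag SNVs for SV imputation by cubic-Hill r-squared
#'
#' @param sv_genotypes SV dosage vector.
#' @param snv_genotypes sample x SNV dosage matrix (named columns).
#' @param r2_min retention threshold (default 0.1).
#' @return `data.frame` with `snv`, `r2`, ordered by descending r^2
#'   (position/name order breaks ties); errors when no SNV qualifies.
#' @export
select_tag_panel <- function(sv_genotypes, snv_genotypes, r2_min = 0.1) {
  ids <- colnames(snv_genotypes) %||% paste0("snv", seq_len(ncol(snv_genotypes)))
  r2 <- vapply(seq_len(ncol(snv_genotypes)), function(j) {
    tryCatch(cubex_ld(two_locus_table(sv_genotypes, snv_genotypes[, j]))$r2,
             error = function(e) 0)
  }, 0)
  keep <- which(r2 > r2_min)
  if (!length(keep)) stop("no tag SNVs with r2 above threshold", call. = FALSE)
  out <- data.frame(snv = ids[keep], r2 = r2[keep], stringsAsFactors = FALSE)
  out[order(-out$r2, out$snv), , drop = FALSE]
}

#' Train an SV genotype imputer on a tag-SNV panel
#'
#' A support-vector classifier with polynomial kernel (degree 3) is
#' evaluated over repeated stratified 70/30 train/test splits (accuracy
#' distribution recorded), then refit on all samples. Missing tag
#' dosages are mean-imputed.
#'
#' @param panel_genotypes sample x tag dosage matrix.
#' @param sv_genotypes SV dosages in \{0,1,2\}.
#' @param n_splits repeated splits (default 100).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return an `sv_imputation_model`: `snv_panel`, `fit`,
#'   `accuracy_distribution`, `mean_accuracy`, `class_prior_baseline`.
#' @export
train_sv_imputer <- function(panel_genotypes, sv_genotypes,
                             n_splits = 100, train_frac = 0.7, seed = 1L) {
  x <- as.matrix(panel_genotypes)
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- mean(x[, j], na.rm = TRUE)
  }
  y <- factor(sv_genotypes, levels = sort(unique(sv_genotypes)))
  n <- length(y)
  set.seed(as.integer(seed))
  accs <- vapply(seq_len(n_splits), function(s) {
    # stratified split so every class is seen in training
    tr <- unlist(lapply(split(seq_len(n), y), function(ix) {
      sample(ix, max(1, round(train_frac * length(ix))))
    }), use.names = FALSE)
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "polynomial",
                      degree = 3, scale = FALSE)
    mean(stats::predict(fit, x[-tr, , drop = FALSE]) == y[-tr])
  }, 0)
  final <- e1071::svm(x, y, kernel = "polynomial", degree = 3,
                      scale = FALSE, probability = TRUE)
  structure(list(
    snv_panel = colnames(panel_genotypes) %||% paste0("snv", seq_len(ncol(x))),
    fit = final,
    accuracy_distribution = accs,
    mean_accuracy = mean(accs),
    class_prior_baseline = max(prop.table(table(y)))
  ), class = "sv_imputation_model")
}

#' Impute SV genotypes on new samples
#'
#' @param model an `sv_imputation_model`.
#' @param genotype_matrix sample x SNV dosage matrix containing every
#'   panel SNV (missing columns error, listing the absentees).
#' @return `data.frame` with `call` (dosage) and per-class probability
#'   columns.
#' @export
impute_sv <- function(model, genotype_matrix) {
  if (NROW(genotype_matrix) == 0) {
    return(data.frame(call = numeric()))
  }
  cols <- colnames(genotype_matrix)
  absent <- setdiff(model$snv_panel, cols)
  if (length(absent)) {
    stop(sprintf("panel SNVs absent from input: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(genotype_matrix[, model$snv_panel, drop = FALSE])
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- mean(x[, j], na.rm = TRUE)
  }
  pred <- stats::predict(model$fit, x, probability = TRUE)
  probs <- attr(pred, "probabilities")
  out <- data.frame(call = as.numeric(as.character(pred)))
  if (!is.null(probs)) out <- cbind(out, as.data.frame(probs))
  out
}

#' Association of a variant with an outcome, optionally conditioned
#'
#' Logistic (binary y) or linear regression of y on the variant dosage,
#' covariates and — when supplied — a conditioning dosage (e.g. imputed
#' SV genotype). Near-collinear variant/condition pairs (r^2 > 0.99) are
#' reported non-estimable rather than silently dropped.
#'
#' @param y outcome (binary 0/1 or continuous).
#' @param g_variant dosage of the variant under test.
#' @param covariates optional covariate data.frame/matrix.
#' @param g_condition optional conditioning dosage.
#' @return one-row `data.frame` with `beta`, `se`, `p`, `n`,
#'   `conditioned`, `estimable`.
#' @export
conditional_assoc <- function(y, g_variant, covariates = NULL,
                              g_condition = NULL) {
  d <- data.frame(y = y, g = g_variant)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  if (!is.null(g_condition)) {
    r2 <- .pair_r2(g_variant, g_condition)
    if (!is.na(r2) && r2 > 0.99) {
      return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                        n = length(y), conditioned = TRUE, estimable = FALSE))
    }
    d$g_cond <- g_condition
  }
  binary <- all(stats::na.omit(y) %in% c(0, 1))
  fit <- if (binary) {
    stats::glm(y ~ ., data = d, family = stats::binomial())
  } else {
    stats::lm(y ~ ., data = d)
  }
  co <- summary(fit)$coefficients
  if (!"g" %in% rownames(co)) {
    return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                      n = length(y), conditioned = !is.null(g_condition),
                      estimable = FALSE))
  }
  data.frame(beta = co["g", 1], se = co["g", 2], p = co["g", 4],
             n = nrow(d), conditioned = !is.null(g_condition),
             estimable = TRUE)
}

#' Per-stratum association with a shared covariate specification
#'
#' @inheritParams conditional_assoc
#' @param strata_labels factor-like stratum labels partitioning samples.
#' @param min_n strata smaller than this are flagged underpowered
#'   (default 30); empty strata are skipped.
#' @return `data.frame`, one row per stratum, with `stratum`,
#'   association columns and `underpowered`.
#' @export
stratified_assoc <- function(y, g, covariates = NULL, strata_labels,
                             min_n = 30) {
  strata <- unique(strata_labels)
  rows <- lapply(strata, function(s) {
    ix <- which(strata_labels == s)
    if (!length(ix)) return(NULL)
    res <- conditional_assoc(y[ix], g[ix],
                             if (is.null(covariates)) NULL else
                               covariates[ix, , drop = FALSE])
    cbind(data.frame(stratum = s, stringsAsFactors = FALSE), res,
          underpowered = length(ix) < min_n)
  })
  do.call(rbind, rows)
}

#' Proteome-wide scan of variants of interest at a locus
#'
#' Per (variant, aptamer) linear regression of abundance on dosage and
#' covariates, with MAC and missingness filters and a per-tissue
#' Bonferroni threshold of 0.05 / number of aptamers.
#'
#' @param genotypes sample x variant dosage matrix (named columns).
#' @param protein_matrix sample x aptamer abundance matrix (named).
#' @param covariates optional covariate data.frame.
#' @param mac_min minimum minor allele count (default 10).
#' @param miss_max maximum genotype missingness (default 0.1).
#' @param alpha family-wise level before Bonferroni (default 0.05).
#' @return list with `significant` (`data.frame` variant/protein/beta/
#'   se/p), `threshold`, `excluded_variants` (id + reason).
#' @export
locus_phewas <- function(genotypes, protein_matrix, covariates = NULL,
                         mac_min = 10, miss_max = 0.1, alpha = 0.05) {
  vids <- colnames(genotypes) %||% paste0("v", seq_len(ncol(genotypes)))
  pids <- colnames(protein_matrix) %||% paste0("p", seq_len(ncol(protein_matrix)))
  n_apt <- ncol(protein_matrix)
  thr <- alpha / n_apt
  excluded <- list()
  rows <- list()
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    miss <- mean(is.na(g))
    mac <- sum(pmin(g, 2 - g), na.rm = TRUE)
    if (miss > miss_max) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        variant = vids[j], reason = "missingness", stringsAsFactors = FALSE)
      next
    }
    if (mac < mac_min) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        variant = vids[j], reason = "mac", stringsAsFactors = FALSE)
      next
    }
    for (k in seq_len(n_apt)) {
      res <- conditional_assoc(protein_matrix[, k], g, covariates)
      if (isTRUE(res$estimable) && !is.na(res$p) && res$p < thr) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant = vids[j], protein = pids[k], beta = res$beta,
          se = res$se, p = res$p, stringsAsFactors = FALSE)
      }
    }
  }
  list(
    significant = if (length(rows)) do.call(rbind, rows) else
      data.frame(variant = character(), protein = character(),
                 beta = numeric(), se = numeric(), p = numeric()),
    threshold = thr,
    excluded_variants = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(variant = character(), reason = character())
  )
}
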