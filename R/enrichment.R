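# Hypergeometric gene-set enrichment with BH correction, sex-specificity
# fold filtering, brain cell-type specificity, and the drug-network
# expansion + drug enrichment procedure. All resources arrive as files
# (GMT, TSV); there are no live database queries.

#' Read / write GMT gene-set files
#'
#' @param path GMT file (set name, description, tab-separated genes).
#' @return named list of character vectors (reader).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Hypergeometric (upper-tail) gene-set enrichment
#'
#' For each set, the overlap k between the query and the set within the
#' universe is tested with P(X >= k) under the hypergeometric null;
#' Benjamini-Hochberg is applied across sets. Query genes outside the
#' universe are dropped (and counted in `n_dropped`). The gene ratio k/n
#' uses the number of mapped query genes as denominator.
#'
#' @param query_genes character vector of query genes.
#' @param sets named list of gene sets.
#' @param universe background gene vector; set members outside it are
#'   ignored.
#' @return `data.frame` per set: `set_name`, `k_overlap`, `n_query`,
#'   `K_set`, `N_universe`, `gene_ratio`, `fold`, `p`, `p_fdr`; attribute
#'   `n_dropped`.
#' @export
hypergeom_enrich <- function(query_genes, sets, universe) {
  q <- unique(query_genes)
  dropped <- setdiff(q, universe)
  q <- intersect(q, universe)
  n <- length(q)
  N <- length(unique(universe))
  if (n == 0) {
    warning("empty query after restriction to universe", call. = FALSE)
    out <- data.frame(set_name = character(), k_overlap = integer(),
                      n_query = integer(), K_set = integer(),
                      N_universe = integer(), gene_ratio = numeric(),
                      fold = numeric(), p = numeric(), p_fdr = numeric())
    attr(out, "n_dropped") <- length(dropped)
    return(out)
  }
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    k <- length(intersect(q, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k_overlap = k, n_query = n, K_set = K,
               N_universe = N, gene_ratio = k / n,
               fold = (k / n) / (K / N), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, "BH")
  attr(out, "n_dropped") <- length(dropped)
  out
}

#' Sex-specificity fold filter over paired enrichment tables
#'
#' Keeps a female row when FDR-significant and its gene ratio is at least
#' `fold` times the male ratio for the same set (sets absent from the
#' other sex count as ratio 0, so they pass the fold test); symmetric for
#' male. By construction no set is retained for both sexes.
#'
#' @param rows_f,rows_m [hypergeom_enrich()] outputs keyed by `set_name`.
#' @param fold minimum ratio multiple (default 1.5).
#' @param alpha_fdr FDR threshold (default 0.05).
#' @return list with `female` and `male` filtered tables.
#' @export
sex_specificity_filter <- function(rows_f, rows_m, fold = 1.5,
                                   alpha_fdr = 0.05) {
  ratio_of <- function(rows, set) {
    i <- match(set, rows$set_name)
    ifelse(is.na(i), 0, rows$gene_ratio[i])
  }
  keep_f <- rows_f$p_fdr < alpha_fdr &
    rows_f$gene_ratio >= fold * ratio_of(rows_m, rows_f$set_name)
  keep_m <- rows_m$p_fdr < alpha_fdr &
    rows_m$gene_ratio >= fold * ratio_of(rows_f, rows_m$set_name)
  # a set can in principle satisfy both inequalities only when both
  # ratios are 0; those rows are never significant, but guard anyway
  both <- intersect(rows_f$set_name[keep_f], rows_m$set_name[keep_m])
  keep_f[rows_f$set_name %in% both] <- FALSE
  keep_m[rows_m$set_name %in% both] <- FALSE
  list(female = rows_f[keep_f, , drop = FALSE],
       male = rows_m[keep_m, , drop = FALSE])
}

#' Cell-type specificity from mean expression shares
#'
#' Per gene, mean expression per cell type is converted to a share of the
#' summed expression; the gene is assigned the predominant type when its
#' share is at least `fold` times the second-largest share.
#'
#' @param expression genes x cell-types matrix of nonnegative mean
#'   expression (canonically endothelial, oligodendrocyte, astrocyte,
#'   neuron, microglia_macrophage).
#' @param fold dominance multiple (default 1.5).
#' @return `data.frame` with `gene`, `cell_type` (NA when not specific or
#'   all-zero), `top_share`, `second_share`.
#' @export
cell_type_specificity <- function(expression, fold = 1.5) {
  if (any(expression < 0)) stop("expression must be nonnegative", call. = FALSE)
  genes <- rownames(expression) %||% paste0("g", seq_len(nrow(expression)))
  rows <- lapply(seq_len(nrow(expression)), function(i) {
    x <- expression[i, ]
    tot <- sum(x)
    if (tot == 0) {
      return(data.frame(gene = genes[i], cell_type = NA_character_,
                        top_share = NA_real_, second_share = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sh <- sort(x / tot, decreasing = TRUE)
    ct <- if (length(sh) == 1 || sh[2] == 0 || sh[1] >= fold * sh[2]) {
      names(sh)[1]
    } else NA_character_
    data.frame(gene = genes[i], cell_type = ct, top_share = sh[1],
               second_share = if (length(sh) > 1) sh[2] else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type enrichment of a sex-biased gene list
#'
#' Hypergeometric test per cell type of the overlap between the query
#' and the type-specific genes within the background; types with fewer
#' than `min_annotated` annotated genes across the two sex lists are
#' flagged unreliable and excluded from the headline table.
#'
#' @param sex_genes query gene vector for one sex.
#' @param ct_map `data.frame` from [cell_type_specificity()] restricted to
#'   the background.
#' @param background background gene vector.
#' @param other_sex_genes the other sex's list (enters the reliability
#'   count only).
#' @param min_annotated reliability floor (default 10).
#' @return list with `table` (reliable types) and `unreliable`
#'   (excluded type names).
#' @export
cell_type_enrichment <- function(sex_genes, ct_map, background,
                                 other_sex_genes = character(),
                                 min_annotated = 10) {
  types <- unique(stats::na.omit(ct_map$cell_type))
  sets <- lapply(types, function(ct) ct_map$gene[!is.na(ct_map$cell_type) &
                                                   ct_map$cell_type == ct])
  names(sets) <- types
  tab <- hypergeom_enrich(sex_genes, sets, background)
  annotated <- vapply(types, function(ct) {
    length(intersect(sets[[ct]], union(sex_genes, other_sex_genes)))
  }, 0L)
  unreliable <- types[annotated < min_annotated]
  list(table = tab[!tab$set_name %in% unreliable, , drop = FALSE],
       unreliable = unreliable)
}

#' Expand prioritized genes into a druggable disease-gene network
#'
#' expanded = seeds plus PPI neighbors of seeds that are both
#' literature-flagged disease genes and tier-1 druggable. Every added
#' gene records the seed(s) and edge(s) that qualified it; seeds absent
#' from the PPI table are kept as isolated seeds and logged.
#'
#' @param seed_genes prioritized genes (one sex).
#' @param ppi_edges `data.frame` with `gene_a`, `gene_b` (undirected).
#' @param ad_literature_genes disease-literature gene vector.
#' @param druggable_tiers `data.frame` with `gene`, `tier`; tier 1
#'   qualifies.
#' @return list with `genes` (expanded vector), `provenance`
#'   (`data.frame` gene/seed/via), `isolated_seeds`.
#' @export
expand_drug_gene_network <- function(seed_genes, ppi_edges,
                                     ad_literature_genes, druggable_tiers) {
  tier1 <- druggable_tiers$gene[druggable_tiers$tier == 1]
  prov <- list()
  isolated <- character()
  for (s in seed_genes) {
    nb <- c(ppi_edges$gene_b[ppi_edges$gene_a == s],
            ppi_edges$gene_a[ppi_edges$gene_b == s])
    if (!length(nb)) { isolated <- c(isolated, s); next }
    keep <- nb[nb %in% ad_literature_genes & nb %in% tier1]
    for (g in unique(keep)) {
      prov[[length(prov) + 1L]] <- data.frame(
        gene = g, seed = s, via = "ppi+literature+tier1",
        stringsAsFactors = FALSE)
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene = character(), seed = character(), via = character())
  list(genes = unique(c(seed_genes, prov$gene)), provenance = prov,
       isolated_seeds = isolated)
}

#' Sex-specific drug enrichment over expanded gene networks
#'
#' Hypergeometric enrichment of each sex's expanded gene set against drug
#' target sets, restricted to FDA-approved drugs, FDR-filtered and passed
#' through the sex-specificity fold filter.
#'
#' @param expanded_f,expanded_m expanded gene vectors per sex.
#' @param drug_sets named list of drug target-gene sets (GMT-style).
#' @param fda_list names of FDA-approved drugs.
#' @param universe background gene vector.
#' @param fold,alpha_fdr filter parameters.
#' @return list with `female`, `male` drug tables.
#' @export
drug_enrichment <- function(expanded_f, expanded_m, drug_sets, fda_list,
                            universe, fold = 1.5, alpha_fdr = 0.05) {
  rf <- hypergeom_enrich(expanded_f, drug_sets, universe)
  rm_ <- hypergeom_enrich(expanded_m, drug_sets, universe)
  rf <- rf[rf$set_name %in% fda_list, , drop = FALSE]
  rm_ <- rm_[rm_$set_name %in% fda_list, , drop = FALSE]
  sex_specificity_filter(rf, rm_, fold = fold, alpha_fdr = alpha_fdr)
}
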