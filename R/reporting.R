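# Deterministic plot-ready data for Miami and multi-tag locus plots,
# and the reproducible results bundle.

#' Multi-tag locus plot data
#'
#' Each variant's dot size is its maximum r^2 with the three tagging
#' variants; its color class is the single tag it reaches r^2 >= 0.2
#' with, a blend (with weights = per-tag r^2 normalized over qualifying
#' tags) when several qualify, or gray when none do.
#'
#' @param variants `data.frame` with `variant_id`, `pos`, `p`.
#' @param tags exactly three variant ids.
#' @param ld_lookup r^2 matrix covering variants and tags.
#' @param r2_color color-qualification threshold (default 0.2).
#' @return `data.frame` with `variant_id`, `pos`, `neglog10p`,
#'   `size_r2`, `color_class` and `w_tag1..w_tag3` blend weights.
#' @export
multitag_plot_data <- function(variants, tags, ld_lookup, r2_color = 0.2) {
  if (length(tags) != 3) stop("exactly 3 tagging variants required",
                              call. = FALSE)
  if (!all(tags %in% colnames(ld_lookup))) {
    stop("LD unavailable for a tagging variant", call. = FALSE)
  }
  r2 <- sapply(tags, function(tg) {
    ifelse(variants$variant_id %in% rownames(ld_lookup),
           ld_lookup[variants$variant_id, tg], NA_real_)
  })
  r2 <- matrix(r2, ncol = 3)
  r2[is.na(r2)] <- 0
  qual <- r2 >= r2_color
  nq <- rowSums(qual)
  cls <- ifelse(nq == 0, "gray",
                ifelse(nq > 1, "blend",
                       c("tag1", "tag2", "tag3")[max.col(qual, "first")]))
  w <- r2 * qual
  rs <- rowSums(w)
  w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  w[rs == 0, ] <- 0
  data.frame(
    variant_id = variants$variant_id, pos = variants$pos,
    neglog10p = -log10(variants$p),
    size_r2 = apply(r2, 1, max),
    color_class = cls,
    w_tag1 = w[, 1], w_tag2 = w[, 2], w_tag3 = w[, 3],
    stringsAsFactors = FALSE
  )
}

#' Miami (mirrored Manhattan) plot data
#'
#' -log10 p is capped at `-log10(truncate_p)`; the female stratum plots
#' upward, the male stratum downward (signed y).
#'
#' @param female_table,male_table tables with `variant_id`, `chrom`,
#'   `pos` and `p` (or `neglog10_p`).
#' @param truncate_p truncation (default 1e-30).
#' @param gw_line genome-wide significance line (default 5e-8).
#' @return `data.frame` with `variant_id`, `chrom`, `pos`, `stratum`,
#'   `y` (signed, capped); attributes `gw_line_y` and `cap`.
#' @export
miami_plot_data <- function(female_table, male_table,
                            truncate_p = 1e-30, gw_line = 5e-8) {
  cap <- -log10(truncate_p)
  one <- function(tab, sign_, label) {
    if (is.null(tab) || nrow(tab) == 0) {
      warning(sprintf("empty %s table: one-sided frame", label),
              call. = FALSE)
      return(NULL)
    }
    nl <- if ("neglog10_p" %in% names(tab)) tab$neglog10_p else -log10(tab$p)
    data.frame(variant_id = tab$variant_id, chrom = tab$chrom,
               pos = tab$pos, stratum = label,
               y = sign_ * pmin(nl, cap), stringsAsFactors = FALSE)
  }
  out <- rbind(one(female_table, 1, "female"), one(male_table, -1, "male"))
  attr(out, "gw_line_y") <- -log10(gw_line)
  attr(out, "cap") <- cap
  out
}

#' Write a reproducible results bundle
#'
#' Writes every stage output as TSV (data.frames) or JSON (lists) into a
#' directory together with a config snapshot, seed registry and per-file
#' MD5 checksums. Re-running with the same inputs reproduces
#' byte-identical files.
#'
#' @param outputs named list of stage outputs (each a `data.frame` or
#'   list); `NULL` entries are a dependency error.
#' @param dir output directory (created).
#' @param config list snapshot of the run configuration.
#' @param seeds named list/vector of seeds used.
#' @return invisible `data.frame` of file checksums (also written as
#'   `checksums.tsv`).
#' @export
results_bundle <- function(outputs, dir, config = list(), seeds = list()) {
  missing <- names(outputs)[vapply(outputs, is.null, TRUE)]
  if (length(missing)) {
    stop(sprintf("missing stage output(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(outputs)) {
    x <- outputs[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    files <- c(files, f)
  }
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(seeds, file.path(dir, "seeds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(dir, c("config.json", "seeds.json")))
  sums <- data.frame(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE)
  utils::write.table(sums, file.path(dir, "checksums.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sums)
}

#' Verify a results bundle against its recorded checksums
#'
#' @param dir bundle directory.
#' @return logical: do all files match `checksums.tsv`?
#' @export
verify_bundle <- function(dir) {
  sums <- utils::read.table(file.path(dir, "checksums.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  now <- unname(tools::md5sum(file.path(dir, sums$file)))
  all(now == sums$md5)
}
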