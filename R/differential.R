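#' Per-sample median pseudocount
#'
#' The pseudocount added to both terms of the expression ratio is the
#' median RPKM of the sample's *nonzero* genes. Taking the median over all
#' annotated genes would give zero in a typical library (roughly half the
#' genes are silent), which would leave ratios of silent genes undefined;
#' restricting to nonzero genes yields a strictly positive stabiliser on
#' the scale of typical expression.
#'
#' @param x A `thermo_expression` tibble or a numeric RPKM vector.
#' @return The pseudocount (positive scalar).
#' @export
median_pseudocount <- function(x) {
  v <- if (is.data.frame(x)) x$rpkm else x
  v <- v[v > 0]
  if (length(v) == 0) {
    abort("cannot compute a median pseudocount: all RPKM values are zero")
  }
  stats::median(v)
}

#' Pseudocount-adjusted fold change
#'
#' `fldchg = (rpkm_30 + m_30) / (rpkm_25 + m_25)`: values below 1 mean
#' higher expression at 25 degrees. Vectorised over genes.
#'
#' @param rpkm_25,rpkm_30 Per-gene RPKM in the 25 and 30 degree samples.
#' @param m_25,m_30 Positive pseudocounts for each sample.
#' @return A tibble with columns `fldchg`, `log2fc`.
#' @export
fold_change <- function(rpkm_25, rpkm_30, m_25, m_30) {
  if (any(m_25 <= 0) || any(m_30 <= 0)) abort("pseudocounts must be > 0")
  if (any(rpkm_25 < 0) || any(rpkm_30 < 0)) abort("negative RPKM input")
  f <- (rpkm_30 + m_30) / (rpkm_25 + m_25)
  tibble(fldchg = f, log2fc = log2(f))
}

reg_class_labels <- c("up25_ge3", "up25_2to3", "up25_1p5to2", "unchanged",
                      "dn25_1p5to2", "dn25_2to3", "dn25_ge3")

#' Classify genes into regulation bins
#'
#' With `r = max(fldchg, 1/fldchg)`: `r >= 3` is the `ge3` bin, `2 <= r <
#' 3` the `2to3` bin, `1.5 <= r < 2` the `1p5to2` bin and `r < 1.5` is
#' `unchanged`. Direction `up25` (upregulated at 25 degrees) corresponds
#' to `fldchg < 1`. All edges are configurable and closed on the left so
#' the bins partition the fold-change axis.
#'
#' @param fldchg Positive fold-change vector.
#' @param edges Strictly increasing bin edges, default `c(1.5, 2, 3)`.
#' @return Factor with levels `up25_ge3`, `up25_2to3`, `up25_1p5to2`,
#'   `unchanged`, `dn25_1p5to2`, `dn25_2to3`, `dn25_ge3`.
#' @export
classify_regulation <- function(fldchg, edges = c(1.5, 2, 3)) {
  if (any(fldchg <= 0)) abort("fold changes must be > 0")
  stopifnot(length(edges) == 3, !is.unsorted(edges, strictly = TRUE), edges[1] > 1)
  r <- pmax(fldchg, 1 / fldchg)
  mag <- cut(r, breaks = c(-Inf, edges, Inf), right = FALSE,
             labels = c("unchanged", "1p5to2", "2to3", "ge3"))
  dir <- ifelse(fldchg < 1, "up25", "dn25")
  out <- ifelse(mag == "unchanged", "unchanged", paste0(dir, "_", mag))
  factor(out, levels = reg_class_labels)
}

#' Build the per-gene fold-change table for two samples
#'
#' Combines the 25 and 30 degree expression profiles into one table with
#' pseudocount-adjusted expression, fold change and regulation class for
#' every annotated gene (not only the expressed ones — the adjusted ratio
#' is defined everywhere thanks to the pseudocount floor).
#'
#' @param profile_25,profile_30 `thermo_expression` tibbles for the 25 and
#'   30 degree samples.
#' @param edges Regulation-bin edges, see [classify_regulation()].
#' @return A `thermo_foldchange` tibble: `gene_id`, `rpkm_25`, `rpkm_30`,
#'   `adj_25`, `adj_30`, `fldchg`, `log2fc`, `reg_class`; attributes
#'   `m_25`, `m_30` hold the pseudocounts.
#' @export
fold_change_table <- function(profile_25, profile_30, edges = c(1.5, 2, 3)) {
  if (!setequal(profile_25$gene_id, profile_30$gene_id)) {
    abort("the two profiles must cover the same gene set")
  }
  m_25 <- median_pseudocount(profile_25)
  m_30 <- median_pseudocount(profile_30)
  tab <- tibble(gene_id = profile_25$gene_id, rpkm_25 = profile_25$rpkm) |>
    left_join(tibble(gene_id = profile_30$gene_id, rpkm_30 = profile_30$rpkm),
              by = "gene_id") |>
    mutate(
      adj_25 = .data$rpkm_25 + m_25,
      adj_30 = .data$rpkm_30 + m_30,
      fold_change(.data$rpkm_25, .data$rpkm_30, m_25, m_30),
      reg_class = classify_regulation(.data$fldchg, edges)
    )
  structure(tab, m_25 = m_25, m_30 = m_30, edges = edges,
            class = c("thermo_foldchange", "tbl_df", "tbl", "data.frame"))
}

#' Select regulated genes
#'
#' Genes whose fold change reaches `fold` in either direction:
#' `max(fldchg, 1/fldchg) >= fold`. This set is the enrichment foreground.
#'
#' @param table A `thermo_foldchange` tibble.
#' @param fold Fold threshold (>= 1), default 2.
#' @return Tibble `gene_id`, `fldchg`, `direction` (`up25` for `fldchg <
#'   1`, else `dn25`).
#' @export
select_regulated <- function(table, fold = 2) {
  if (fold < 1) abort("fold threshold must be >= 1")
  r <- pmax(table$fldchg, 1 / table$fldchg)
  sel <- table[r >= fold, c("gene_id", "fldchg")]
  sel$direction <- ifelse(sel$fldchg < 1, "up25", "dn25")
  as_tibble(sel)
}

#' Histogram of log2 fold changes
#'
#' @param table A `thermo_foldchange` tibble.
#' @param bin_width Width of the log2 fold-change bins.
#' @return Tibble `bin_left`, `bin_right`, `frequency`; frequencies sum to
#'   the number of genes in the table.
#' @export
fold_change_histogram <- function(table, bin_width = 0.25) {
  log2_histogram(tibble(rpkm = table$fldchg), bin_width = bin_width)
}

#' Write the per-gene fold-change report
#'
#' Mirrors the supplementary per-gene table layout: `Gene`, `Exon-length`,
#' `Location`, `Description`, `RPKM(25)`, `RPKM(30)`, `RPKM+median(25)`,
#' `RPKM+median(30)`, `fldchg`, `reg_class`.
#'
#' @param table A `thermo_foldchange` tibble.
#' @param genes Gene-model tibble supplying length/location/description.
#' @param path Output path.
#' @param header Optional comment line(s) written before the table.
#' @return `path`, invisibly.
#' @export
write_fold_change_table <- function(table, genes, path, header = NULL) {
  out <- table |>
    left_join(select(genes, "gene_id", "exon_length", "chrom", "start",
                     "end", "strand", "description"),
              by = "gene_id") |>
    mutate(location = format_location(.data$chrom, .data$start, .data$end,
                                      .data$strand))
  out <- tibble(
    "Gene" = out$gene_id,
    "Exon-length" = out$exon_length,
    "Location" = out$location,
    "Description" = out$description,
    "RPKM(25)" = out$rpkm_25,
    "RPKM(30)" = out$rpkm_30,
    "RPKM+median(25)" = out$adj_25,
    "RPKM+median(30)" = out$adj_30,
    "fldchg" = out$fldchg,
    "reg_class" = as.character(out$reg_class)
  )
  write_tsv_with_header(out, path, header)
  invisible(path)
}

write_tsv_with_header <- function(x, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("#", header), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
  invisible(path)
}
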