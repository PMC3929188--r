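#' Read a minimal SAM alignment stream
#'
#' Parses the plain-text SAM subset the counting step needs: `QNAME`,
#' `FLAG` (bit 0x4 = unmapped, bit 0x1 = paired), `RNAME`, `POS`, `CIGAR`
#' and the optional `NH:i:` tag (number of reported alignments for the
#' read). The reference span of each alignment is derived from the CIGAR
#' string (`M`, `D`, `N`, `=`, `X` consume reference; `I`, `S`, `H`, `P`
#' do not). Records without an NH tag are treated as uniquely mapped
#' (`n_hits = 1`) with one warning per file.
#'
#' @param path Path to a SAM text file.
#' @return A tibble with one row per record: `read_id`, `flag`, `mapped`,
#'   `paired`, `chrom`, `pos`, `span`, `n_hits`.
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("SAM file does not exist: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), flag = integer(), mapped = logical(),
                  paired = logical(), chrom = character(), pos = integer(),
                  span = integer(), n_hits = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 11L
  if (any(short)) abort("SAM record with fewer than 11 fields")

  flag <- as.integer(vapply(fields, `[`, "", 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- vapply(fields, `[`, "", 6L)
  span <- rep(NA_integer_, length(lines))
  span[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[mapped])

  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0) NA_integer_ else as.integer(sub("^NH:i:", "", tag[1]))
  }, 1L)
  if (anyNA(nh[mapped])) {
    warn(sprintf("%d mapped record(s) lack an NH tag; treated as uniquely mapped",
                 sum(is.na(nh[mapped]))))
  }
  nh[is.na(nh)] <- 1L
  if (any(nh < 1L)) abort("NH tag must be >= 1")

  tibble(
    read_id = vapply(fields, `[`, "", 1L),
    flag = flag,
    mapped = mapped,
    paired = bitwAnd(flag, 1L) == 1L,
    chrom = ifelse(mapped, vapply(fields, `[`, "", 3L), NA_character_),
    pos = ifelse(mapped, as.integer(vapply(fields, `[`, "", 4L)), NA_integer_),
    span = span,
    n_hits = nh
  )
}

# one interval row per gene (or several, when exon structure is known)
gene_intervals <- function(genes) {
  if ("exons" %in% names(genes)) {
    tidyr::unnest(
      select(genes, "gene_id", "chrom", exon = "exons"),
      "exon"
    )
  } else {
    select(genes, "gene_id", "chrom", "start", "end")
  }
}

#' Count reads per gene with multimapper weighting
#'
#' Each mapped alignment record contributes weight `1 / n_hits` (the
#' reciprocal of its number of reported genome locations, from the SAM NH
#' tag). The weight is assigned to the single gene whose exon union the
#' aligned span overlaps by at least one base; an alignment overlapping two
#' or more genes is ambiguous and assigned to none. Every mapped record —
#' assigned, ambiguous or intergenic — contributes its weight to the
#' library total, so RPKM denominators reflect all mapped reads. Unmapped
#' records contribute nothing. In `mate_handling = "fragments"` mode each
#' paired record additionally carries weight 1/2, so a mate pair counts as
#' one fragment; the default counts each mate as an independent read.
#'
#' @param alignments Alignment tibble from [read_sam_alignments()].
#' @param genes Gene-model tibble.
#' @param mate_handling `"reads"` (default) or `"fragments"`.
#' @return A count table: tibble with columns `gene_id`, `weighted_count`
#'   (one row per annotated gene, zeros included), carrying the summed
#'   weight of all mapped records in attribute `total_mapped_reads`.
#' @export
weighted_gene_counts <- function(alignments, genes,
                                 mate_handling = c("reads", "fragments")) {
  mate_handling <- match.arg(mate_handling)
  aln <- alignments[alignments$mapped, ]
  w <- 1 / aln$n_hits
  if (mate_handling == "fragments") w <- w * ifelse(aln$paired, 0.5, 1)

  counts <- setNames(numeric(nrow(genes)), genes$gene_id)
  total <- sum(w)

  if (nrow(aln) > 0) {
    iv <- gene_intervals(genes)
    q <- GenomicRanges::GRanges(aln$chrom,
                                IRanges::IRanges(start = aln$pos, width = aln$span))
    s <- GenomicRanges::GRanges(iv$chrom,
                                IRanges::IRanges(start = iv$start, end = iv$end))
    hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
    hit_gene <- iv$gene_id[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    # distinct genes per record; ambiguous records (>= 2 genes) are dropped
    per_rec <- rowsum(
      x = as.numeric(!duplicated(paste0(qh, "\r", hit_gene))),
      group = qh
    )
    n_genes_per_rec <- setNames(per_rec[, 1], rownames(per_rec))
    keep <- !duplicated(paste0(qh, "\r", hit_gene)) &
      n_genes_per_rec[as.character(qh)] == 1
    assigned <- rowsum(w[qh[keep]], hit_gene[keep])
    counts[rownames(assigned)] <- assigned[, 1]
  }

  structure(
    tibble(gene_id = genes$gene_id, weighted_count = unname(counts[genes$gene_id])),
    total_mapped_reads = total,
    class = c("thermo_counts", "tbl_df", "tbl", "data.frame")
  )
}

#' Total mapped-read weight of a count table
#' @param counts A count table from [weighted_gene_counts()] or
#'   [read_count_table()].
#' @return The summed per-read weight over all mapped reads.
#' @export
total_mapped_reads <- function(counts) {
  tot <- attr(counts, "total_mapped_reads")
  if (is.null(tot)) abort("count table has no total_mapped_reads attribute")
  tot
}

#' Read / write a weighted count table
#'
#' The dialect is a TSV with columns `gene_id`, `weighted_count`, preceded
#' by a `#total_mapped_reads=<value>` comment line carrying the library
#' total (which includes reads not assigned to any gene, so it cannot be
#' recomputed from the per-gene rows).
#'
#' @param path File path.
#' @return For the reader, a count-table tibble with the
#'   `total_mapped_reads` attribute; the writer returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(paste0("count table does not exist: ", path))
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  if (!grepl("^#total_mapped_reads=", first)) {
    abort("count table must start with a '#total_mapped_reads=' header line")
  }
  total <- as.numeric(sub("^#total_mapped_reads=", "", first))
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    gene_id = readr::col_character(),
    weighted_count = readr::col_double()
  ), progress = FALSE)
  if (any(tab$weighted_count < 0)) abort("negative weighted_count in count table")
  structure(tab, total_mapped_reads = total,
            class = c("thermo_counts", "tbl_df", "tbl", "data.frame"))
}

#' @rdname read_count_table
#' @param counts Count-table tibble.
#' @export
write_count_table <- function(counts, path) {
  writeLines(sprintf("#total_mapped_reads=%.10g", total_mapped_reads(counts)), path)
  readr::write_tsv(counts, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' RPKM and RPB normalisation
#'
#' `rpkm()` is reads per kilobase of exon model per million mapped reads:
#' `count / ((exon_length/1000) * (total/1e6))`. `rpb()` is the
#' intermediate reads-per-billion value `1e9 * count / total`. Both are
#' vectorised over genes.
#'
#' @param weighted_count Non-negative per-gene weighted read count.
#' @param exon_length Exon-union length in bp (>= 1).
#' @param total Total mapped-read weight of the library (> 0).
#' @return Numeric vector of normalised expression values.
#' @export
rpkm <- function(weighted_count, exon_length, total) {
  if (any(total <= 0)) abort("total mapped reads must be > 0 for RPKM")
  if (any(exon_length < 1)) abort("exon_length must be >= 1 for RPKM")
  if (any(weighted_count < 0)) abort("weighted_count must be non-negative")
  weighted_count / ((exon_length / 1000) * (total / 1e6))
}

#' @rdname rpkm
#' @export
rpb <- function(weighted_count, total) {
  if (any(total <= 0)) abort("total mapped reads must be > 0 for RPB")
  1e9 * weighted_count / total
}

#' Call a gene expressed
#'
#' A gene is expressed when its RPKM is strictly greater than the
#' threshold (default 1 RPKM).
#'
#' @param rpkm_value Numeric RPKM vector.
#' @param threshold Positive RPKM threshold.
#' @return Logical vector.
#' @export
call_expressed <- function(rpkm_value, threshold = 1) {
  if (threshold <= 0) abort("expressed threshold must be > 0")
  rpkm_value > threshold
}

level_bin_labels <- c("not_detected", "low", "modest", "high", "extreme")

#' Build a per-sample expression profile
#'
#' Joins a weighted count table to the gene models and computes RPB, RPKM,
#' the expressed call and the expression-level bin. Bins are left-closed,
#' right-open: `low` = (threshold, 10), `modest` = [10, 100), `high` =
#' [100, 1000), `extreme` = [1000, Inf); genes not called expressed are
#' `not_detected`.
#'
#' @param counts Count table (tibble `gene_id`, `weighted_count` with the
#'   `total_mapped_reads` attribute).
#' @param genes Gene-model tibble.
#' @param sample Sample label stored in the `sample` column.
#' @param threshold Expressed-call RPKM threshold (strict), default 1.
#' @param level_edges Bin edges for low/modest/high/extreme, default
#'   `c(10, 100, 1000)`.
#' @return A `thermo_expression` tibble: `gene_id`, `sample`,
#'   `weighted_count`, `rpb`, `rpkm`, `expressed`, `level_bin`; attributes
#'   `total_mapped_reads`, `threshold`.
#' @export
expression_profile <- function(counts, genes, sample = "sample_1",
                               threshold = 1, level_edges = c(10, 100, 1000)) {
  total <- total_mapped_reads(counts)
  missing <- setdiff(counts$gene_id, genes$gene_id)
  if (length(missing) > 0) {
    abort(paste0("count table contains gene ids absent from the annotation: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  prof <- genes |>
    select("gene_id", "exon_length") |>
    left_join(counts, by = "gene_id") |>
    mutate(
      weighted_count = ifelse(is.na(.data$weighted_count), 0, .data$weighted_count),
      sample = sample,
      rpb = rpb(.data$weighted_count, total),
      rpkm = rpkm(.data$weighted_count, .data$exon_length, total),
      expressed = call_expressed(.data$rpkm, threshold),
      level_bin = bin_levels(.data$rpkm, .data$expressed, level_edges)
    ) |>
    select("gene_id", "sample", "weighted_count", "rpb", "rpkm",
           "expressed", "level_bin")
  structure(prof, total_mapped_reads = total, threshold = threshold,
            level_edges = level_edges,
            class = c("thermo_expression", "tbl_df", "tbl", "data.frame"))
}

bin_levels <- function(rpkm_value, expressed, edges = c(10, 100, 1000)) {
  stopifnot(length(edges) == 3, !is.unsorted(edges, strictly = TRUE))
  out <- factor(rep("not_detected", length(rpkm_value)), levels = level_bin_labels)
  out[expressed & rpkm_value < edges[1]] <- "low"
  out[expressed & rpkm_value >= edges[1] & rpkm_value < edges[2]] <- "modest"
  out[expressed & rpkm_value >= edges[2] & rpkm_value < edges[3]] <- "high"
  out[expressed & rpkm_value >= edges[3]] <- "extreme"
  out
}

#' Count genes per expression-level bin
#'
#' @param profile A `thermo_expression` tibble.
#' @return A tibble `level_bin`, `n_genes` with one row per bin (zeros
#'   included); the counts sum to the number of genes in the profile.
#' @export
bin_expression_levels <- function(profile) {
  tab <- table(factor(profile$level_bin, levels = level_bin_labels))
  tibble(level_bin = factor(level_bin_labels, levels = level_bin_labels),
         n_genes = as.integer(tab))
}

#' Histogram of log2 expression
#'
#' Only genes with RPKM > 0 are included (log2 of zero is undefined); the
#' frequencies sum to the number of included genes.
#'
#' @param profile A `thermo_expression` tibble (or any tibble with an
#'   `rpkm` column).
#' @param bin_width Width of the log2 bins.
#' @return A tibble `bin_left`, `bin_right`, `frequency`.
#' @export
log2_histogram <- function(profile, bin_width = 0.5) {
  x <- log2(profile$rpkm[profile$rpkm > 0])
  if (length(x) == 0) {
    return(tibble(bin_left = numeric(), bin_right = numeric(), frequency = integer()))
  }
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling((max(x) + 1e-9) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 2) edges <- c(lo, lo + bin_width)
  idx <- pmin(findInterval(x, edges), length(edges) - 1L)
  tab <- tabulate(idx, nbins = length(edges) - 1L)
  tibble(bin_left = edges[-length(edges)], bin_right = edges[-1],
         frequency = as.integer(tab))
}
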