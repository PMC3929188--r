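# small in-code fixtures shared across the suite

make_genes <- function(ids, lengths, chrom = "Chr1", starts = NULL,
                       strand = "+") {
  n <- length(ids)
  if (is.null(starts)) starts <- cumsum(c(1L, head(lengths, -1L) + 1000L))
  tibble::tibble(
    gene_id = ids,
    exon_length = as.integer(lengths),
    chrom = rep_len(chrom, n),
    start = as.integer(starts),
    end = as.integer(starts + lengths - 1L),
    strand = rep_len(strand, n),
    description = paste("gene", ids)
  )
}

write_gene_tsv <- function(genes, path = tempfile(fileext = ".tsv")) {
  thermoseq::write_gene_models(genes, path)
  path
}

# minimal GFF3 with gene -> mRNA -> exon features
write_gff3 <- function(gene_exons, path = tempfile(fileext = ".gff3"),
                       chrom = "Chr1") {
  lines <- "##gff-version 3"
  for (gid in names(gene_exons)) {
    ex <- gene_exons[[gid]]
    gstart <- min(ex[, 1]); gend <- max(ex[, 2])
    lines <- c(
      lines,
      sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s", chrom, gstart, gend, gid),
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.1;Parent=%s",
              chrom, gstart, gend, gid, gid),
      sprintf("%s\ttest\texon\t%d\t%d\t.\t+\t.\tID=%s.1.e%d;Parent=%s.1",
              chrom, ex[, 1], ex[, 2], gid, seq_len(nrow(ex)), gid)
    )
  }
  writeLines(lines, path)
  path
}

write_category_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

# SAM text from a record table (read_id, flag, chrom, pos, cigar, nh)
write_sam <- function(records, path = tempfile(fileext = ".sam"),
                      chroms = "Chr1", with_nh = TRUE) {
  lines <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:100000000", chroms))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    opt <- if (with_nh && !is.na(r$nh)) sprintf("\tNH:i:%d", r$nh) else ""
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*%s",
                              r$read_id, r$flag, r$chrom, r$pos, r$cigar, opt))
  }
  writeLines(lines, path)
  path
}

sam_record <- function(read_id, chrom, pos, cigar = "90M", nh = 1L, flag = 0L) {
  tibble::tibble(read_id = read_id, flag = as.integer(flag), chrom = chrom,
                 pos = as.integer(pos), cigar = cigar, nh = as.integer(nh))
}

# category layout scaled for very small simulated universes
small_category_spec <- function(planted_size = 25, null_sizes = c(10, 20, 30),
                                factor = 3) {
  purrr::map(c("GO", "KEGG", "TF"), function(ns) {
    tibble::tibble(namespace = ns,
                   size = c(null_sizes, planted_size),
                   planted = c(rep(FALSE, length(null_sizes)), TRUE),
                   enrichment_factor = c(rep(1, length(null_sizes)), factor))
  }) |> dplyr::bind_rows()
}

# one tiny expression profile straight from rpkm values
profile_from_rpkm <- function(rpkm_values, sample = "s", threshold = 1) {
  n <- length(rpkm_values)
  structure(
    tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n)),
      sample = sample,
      weighted_count = rpkm_values,
      rpb = rpkm_values,
      rpkm = rpkm_values,
      expressed = rpkm_values > threshold,
      level_bin = thermoseq:::bin_levels(rpkm_values, rpkm_values > threshold)
    ),
    total_mapped_reads = 1e6, threshold = threshold,
    class = c("thermo_expression", "tbl_df", "tbl", "data.frame")
  )
}
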