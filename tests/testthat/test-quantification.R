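test_that("an empty alignment stream yields zero counts and zero total", {
  genes <- make_genes(c("gA", "gB"), c(1000L, 1000L))
  sam <- write_sam(sam_record(character(), character(), integer())[0, ])
  counts <- weighted_gene_counts(read_sam_alignments(sam), genes)
  expect_equal(counts$weighted_count, c(0, 0))
  expect_equal(total_mapped_reads(counts), 0)
})

test_that("a two-location multimapper contributes 1/NH to each gene", {
  genes <- make_genes(c("gA", "gB"), c(1000L, 1000L),
                      starts = c(1000L, 50000L))
  rec <- rbind(sam_record("r1", "Chr1", 1100L, nh = 2L),
               sam_record("r1", "Chr1", 50100L, nh = 2L))
  counts <- weighted_gene_counts(read_sam_alignments(write_sam(rec)), genes)
  expect_equal(counts$weighted_count, c(0.5, 0.5))
  expect_equal(total_mapped_reads(counts), 1.0)
})

test_that("unique gene reads count fully; intergenic reads only in the total", {
  genes <- make_genes("gA", 1000L, starts = 1000L)
  rec <- rbind(sam_record(c("r1", "r2", "r3"), "Chr1", c(1100L, 1200L, 1300L)),
               sam_record("r4", "Chr1", 90000L))
  counts <- weighted_gene_counts(read_sam_alignments(write_sam(rec)), genes)
  expect_equal(counts$weighted_count, 3.0)
  expect_equal(total_mapped_reads(counts), 4.0)
})

test_that("ambiguous overlap with two genes is dropped from gene counts", {
  genes <- make_genes(c("gA", "gB"), c(1000L, 1000L), starts = c(1000L, 1950L))
  rec <- sam_record("r1", "Chr1", 1940L)  # spans the gA/gB junction
  counts <- weighted_gene_counts(read_sam_alignments(write_sam(rec)), genes)
  expect_equal(counts$weighted_count, c(0, 0))
  expect_equal(total_mapped_reads(counts), 1.0)
})

test_that("missing NH tags warn and count as uniquely mapped; unmapped are ignored", {
  genes <- make_genes("gA", 1000L, starts = 1000L)
  rec <- rbind(sam_record("r1", "Chr1", 1100L, nh = NA),
               sam_record("r2", "*", 0L, cigar = "*", flag = 4L))
  expect_warning(aln <- read_sam_alignments(write_sam(rec)), "NH")
  expect_equal(aln$n_hits, c(1L, 1L))
  counts <- weighted_gene_counts(aln, genes)
  expect_equal(counts$weighted_count, 1.0)
  expect_equal(total_mapped_reads(counts), 1.0)
})

test_that("CIGAR reference span drives the overlap test", {
  # 50M100N40M spans 190 reference bases; soft clips consume none
  genes <- make_genes("gA", 200L, starts = 1000L)
  rec <- rbind(sam_record("r1", "Chr1", 900L, cigar = "50M100N40M"),
               sam_record("r2", "Chr1", 880L, cigar = "10S90M"))
  aln <- read_sam_alignments(write_sam(rec))
  expect_equal(aln$span, c(190L, 90L))
  counts <- weighted_gene_counts(aln, genes)
  expect_equal(counts$weighted_count, 1.0)  # r1 reaches into gA, r2 ends at 969
  expect_equal(total_mapped_reads(counts), 2.0)
})

test_that("rpkm implements count / (kb * millions) and rpb is reads per billion", {
  expect_equal(rpkm(250, 2000, 25e6), 5.0)
  expect_equal(rpkm(1, 1000, 1e6), 1.0)
  expect_equal(rpkm(0, 1234, 5e6), 0)
  expect_equal(rpb(1, 1e9), 1)
  expect_error(rpkm(1, 1000, 0), "must be > 0")
  # scale invariance: scaling counts and total together leaves RPKM fixed
  expect_equal(rpkm(37 * 8, 1700, 3e6 * 8), rpkm(37, 1700, 3e6))
})

test_that("the expressed call is strictly greater than the threshold", {
  expect_false(call_expressed(1.0, 1))
  expect_true(call_expressed(1.01, 1))
  expect_false(call_expressed(0, 1))
  expect_error(call_expressed(1, 0), "> 0")
})

test_that("level bins partition genes with left-closed edges", {
  prof <- profile_from_rpkm(c(0.5, 5, 50, 500, 5000, 0, 100))
  bins <- bin_expression_levels(prof)
  expect_equal(sum(bins$n_genes), 7L)
  expect_equal(bins$n_genes[bins$level_bin == "not_detected"], 2L)  # 0.5 and 0
  expect_equal(bins$n_genes[bins$level_bin == "low"], 1L)
  expect_equal(bins$n_genes[bins$level_bin == "modest"], 1L)
  expect_equal(bins$n_genes[bins$level_bin == "high"], 2L)  # 500 and boundary 100
  expect_equal(bins$n_genes[bins$level_bin == "extreme"], 1L)
  # all-zero profile: everything not detected
  zeros <- bin_expression_levels(profile_from_rpkm(c(0, 0, 0)))
  expect_equal(zeros$n_genes[zeros$level_bin == "not_detected"], 3L)
})

test_that("log2 histograms cover only positive rpkm and conserve gene counts", {
  one <- log2_histogram(profile_from_rpkm(8), bin_width = 1)
  expect_equal(sum(one$frequency), 1L)
  hit <- one[one$frequency > 0, ]
  expect_true(hit$bin_left <= 3 && 3 < hit$bin_right)

  two <- log2_histogram(profile_from_rpkm(c(1, 2)), bin_width = 1)
  expect_equal(two$frequency, c(1L, 1L))
  expect_equal(two$bin_left, c(0, 1))

  empty <- log2_histogram(profile_from_rpkm(c(0, 0)))
  expect_equal(nrow(empty), 0)

  set.seed(41)
  prof <- profile_from_rpkm(rlnorm(500, 1, 2))
  expect_equal(sum(log2_histogram(prof, 0.5)$frequency), 500L)
})

test_that("read mass is conserved and counts match the enumeration oracle", {
  set.seed(11)
  for (rep in 1:5) {
    genes <- make_genes(sprintf("g%d", 1:8),
                        sample(200:2000, 8),
                        starts = cumsum(sample(500:5000, 8)))
    n <- 40
    pos <- sample(max(genes$end) + 5000, n)
    inside <- sample(nrow(genes), n, replace = TRUE)
    use_inside <- runif(n) < 0.7
    pos[use_inside] <- as.integer(
      genes$start[inside[use_inside]] +
        floor(runif(sum(use_inside)) * pmax(1, genes$exon_length[inside[use_inside]] - 90)))
    nh <- sample(c(1L, 1L, 2L), n, replace = TRUE)
    rec <- sam_record(sprintf("r%03d", 1:n), "Chr1", pos, nh = nh)
    aln <- read_sam_alignments(write_sam(rec))
    counts <- weighted_gene_counts(aln, genes)
    oracle <- enum_weighted_counts(aln, genes)
    expect_equal(setNames(counts$weighted_count, counts$gene_id), oracle$counts)
    expect_equal(total_mapped_reads(counts), oracle$total)
    expect_lte(sum(counts$weighted_count), total_mapped_reads(counts) + 1e-12)
  }
})

test_that("count tables round-trip through the TSV dialect with their total", {
  genes <- make_genes(c("gA", "gB"), c(1000L, 1000L))
  counts <- structure(
    tibble::tibble(gene_id = c("gA", "gB"), weighted_count = c(2.5, 0)),
    total_mapped_reads = 4.5,
    class = c("thermo_counts", "tbl_df", "tbl", "data.frame"))
  path <- tempfile(fileext = ".tsv")
  write_count_table(counts, path)
  back <- read_count_table(path)
  expect_equal(back$weighted_count, counts$weighted_count)
  expect_equal(total_mapped_reads(back), 4.5)
  expect_error(read_count_table(tempfile()), "does not exist")
})

test_that("expression profiles join counts to genes and respect the threshold", {
  genes <- make_genes(c("gA", "gB", "gC"), c(1000L, 2000L, 500L))
  counts <- structure(
    tibble::tibble(gene_id = c("gA", "gB", "gC"),
                   weighted_count = c(10, 10, 0)),
    total_mapped_reads = 1e6,
    class = c("thermo_counts", "tbl_df", "tbl", "data.frame"))
  prof <- expression_profile(counts, genes, sample = "25C")
  expect_equal(prof$rpkm, c(10, 5, 0))
  expect_equal(prof$rpb, c(1e4, 1e4, 0))
  expect_equal(prof$expressed, c(TRUE, TRUE, FALSE))
  expect_equal(attr(prof, "total_mapped_reads"), 1e6)
})
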