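#' Configuration for a synthetic two-temperature study
#'
#' Defines the generative model the test fixtures come from: ~half the
#' genes expressed with a long-tailed log-normal expression law, planted
#' fold-change regulation between the two conditions, and categories with
#' planted over-representation among the regulated genes. Defaults are
#' desk scale (10,000 genes, 1e6 reads per sample) so a full pipeline plus
#' recovery run takes seconds; [paper_scale_config()] gives the full-size
#' preset.
#'
#' @param n_genes Number of annotated genes.
#' @param frac_expressed Fraction of genes with nonzero true expression.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of the expression
#'   shape of expressed genes. The default `sdlog = 1.6` reproduces, at
#'   full scale, the canonical structure of a leaf transcriptome: ~3% of
#'   expressed genes above 100 RPKM and about two thirds below 10 RPKM.
#' @param library_size Expected mapped reads per sample.
#' @param n_up25,n_dn25 Number of genes planted up- / down-regulated at 25
#'   degrees (i.e. higher at 25, resp. higher at 30).
#' @param fold Planted fold change (>= 1) applied to one condition.
#' @param dispersion Negative-binomial size parameter for counts; `Inf`
#'   (default) gives Poisson counts.
#' @param exon_length_range Uniform range (bp) for exon-union lengths.
#' @param planted_pool_quantiles Regulated genes are drawn from expressed
#'   genes between these expression quantiles (default the 50th-90th
#'   percentile): the median pseudocount intentionally shrinks ratios of
#'   genes below the typical expression level, and excluding the extreme
#'   top decile keeps planting from shifting a large share of the library
#'   mass.
#' @param categories Tibble with one row per category: `namespace`,
#'   `size`, `planted` (logical), `enrichment_factor` (planted members are
#'   regulated with probability `enrichment_factor * R / n_genes`).
#' @param seed Integer seed; every artifact (annotation, expression,
#'   counts per sample, categories) draws from its own stream derived from
#'   it, so artifacts can be regenerated independently.
#' @return A validated `thermo_simconfig` list.
#' @export
simulation_config <- function(n_genes = 10000,
                              frac_expressed = 0.5,
                              expr_meanlog = log(5),
                              expr_sdlog = 1.6,
                              library_size = 1e6,
                              n_up25 = 250,
                              n_dn25 = 150,
                              fold = 8,
                              dispersion = Inf,
                              exon_length_range = c(500, 5000),
                              planted_pool_quantiles = c(0.5, 0.9),
                              categories = default_category_spec(),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), frac_expressed = frac_expressed,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              library_size = library_size, n_up25 = as.integer(n_up25),
              n_dn25 = as.integer(n_dn25), fold = fold,
              dispersion = dispersion, exon_length_range = exon_length_range,
              planted_pool_quantiles = planted_pool_quantiles,
              categories = categories, seed = as.integer(seed))
  if (cfg$frac_expressed <= 0 || cfg$frac_expressed > 1) {
    abort("frac_expressed must lie in (0, 1]")
  }
  if (cfg$fold < 1) abort("planted fold must be >= 1")
  if (cfg$n_up25 + cfg$n_dn25 > cfg$n_genes) abort("more regulated genes than genes")
  if (any(cfg$categories$size > cfg$n_genes)) abort("category larger than the gene set")
  if (any(cfg$categories$enrichment_factor < 1)) {
    abort("planted_enrichment_factor must be >= 1")
  }
  structure(cfg, class = "thermo_simconfig")
}

#' @rdname simulation_config
#' @export
default_category_spec <- function() {
  purrr::map(c("GO", "KEGG", "TF"), function(ns) {
    tibble(
      namespace = ns,
      size = c(round(seq(20, 200, length.out = 10)), 120L, 120L),
      planted = c(rep(FALSE, 10), TRUE, TRUE),
      enrichment_factor = c(rep(1, 10), 5, 5)
    )
  }) |> bind_rows()
}

#' @rdname simulation_config
#' @export
paper_scale_config <- function(seed = 1L) {
  simulation_config(n_genes = 56143, library_size = 25e6,
                    n_up25 = 821, n_dn25 = 553, seed = seed)
}

# independent RNG streams, one per artifact
derive_subseeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 5L),
           c("annotation", "expression", "counts_25", "counts_30", "categories"))
}

#' Simulate a complete two-temperature study with known ground truth
#'
#' Draws gene models, true expression, planted regulation, per-condition
#' counts and category maps from the generative model described in
#' [simulation_config()]. True RPKM per condition is normalised so that
#' `sum(rpkm * length_kb) = 1e6` — the identity every genuine RPKM vector
#' satisfies — which makes empirical RPKM an unbiased estimate of the
#' recorded truth. Counts are negative binomial with mean
#' `rpkm * length_kb * library_size / 1e6` (Poisson in the default
#' infinite-dispersion limit). Fully reproducible from the seed.
#'
#' @param config A `thermo_simconfig` from [simulation_config()].
#' @return A list of class `thermo_simulation`: `genes` (gene-model
#'   tibble), `categories` (membership tibble), `counts_25`, `counts_30`
#'   (count tables), and `truth` (class `thermo_truth`: `regulated`,
#'   `planted_categories`, `true_rpkm`, the derived sub-seeds and the
#'   config).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "thermo_simconfig"))
  seeds <- derive_subseeds(config$seed)

  genes <- simulate_gene_models(config, seeds[["annotation"]])
  len_kb <- genes$exon_length / 1000

  # --- true expression and planted regulation ------------------------------
  set.seed(seeds[["expression"]])
  n_expr <- round(config$frac_expressed * config$n_genes)
  expressed_idx <- sort(sample.int(config$n_genes, n_expr))
  shape <- numeric(config$n_genes)
  shape[expressed_idx] <- rlnorm(n_expr, config$expr_meanlog, config$expr_sdlog)

  qs <- quantile(shape[expressed_idx], config$planted_pool_quantiles, names = FALSE)
  pool <- expressed_idx[shape[expressed_idx] >= qs[1] & shape[expressed_idx] <= qs[2]]
  n_reg <- config$n_up25 + config$n_dn25
  if (length(pool) < n_reg) {
    abort(sprintf("infeasible planting: %d regulated genes requested but only %d genes in the planted pool",
                  n_reg, length(pool)))
  }
  reg_idx <- sample(pool, n_reg)
  up_idx <- reg_idx[seq_len(config$n_up25)]
  dn_idx <- setdiff(reg_idx, up_idx)

  shape_25 <- shape
  shape_30 <- shape
  shape_25[up_idx] <- shape[up_idx] * config$fold   # higher at 25C
  shape_30[dn_idx] <- shape[dn_idx] * config$fold   # higher at 30C

  true_rpkm_25 <- shape_25 * 1e6 / sum(shape_25 * len_kb)
  true_rpkm_30 <- shape_30 * 1e6 / sum(shape_30 * len_kb)

  counts_25 <- simulate_counts(genes, true_rpkm_25, config, seeds[["counts_25"]])
  counts_30 <- simulate_counts(genes, true_rpkm_30, config, seeds[["counts_30"]])

  regulated <- tibble(
    gene_id = genes$gene_id[c(up_idx, dn_idx)],
    direction = rep(c("up25", "dn25"), c(length(up_idx), length(dn_idx))),
    planted_fold = config$fold
  )
  categories <- simulate_categories(genes, regulated$gene_id, config,
                                    seeds[["categories"]])

  truth <- structure(list(
    regulated = regulated,
    planted_categories = filter(categories$spec, .data$planted) |>
      select("category_id", "namespace", "enrichment_factor"),
    true_rpkm = tibble(gene_id = genes$gene_id,
                       true_rpkm_25 = true_rpkm_25,
                       true_rpkm_30 = true_rpkm_30),
    sub_seeds = seeds,
    config = config
  ), class = "thermo_truth")

  structure(list(genes = genes, categories = categories$members,
                 counts_25 = counts_25, counts_30 = counts_30, truth = truth),
            class = "thermo_simulation")
}

simulate_gene_models <- function(config, seed) {
  set.seed(seed)
  n <- config$n_genes
  chrom_n <- 12L
  chrom <- sort(rep_len(seq_len(chrom_n), n))
  exon_length <- as.integer(round(runif(n, config$exon_length_range[1],
                                        config$exon_length_range[2])))
  gap <- as.integer(round(runif(n, 200, 2000)))
  start <- integer(n)
  for (ch in seq_len(chrom_n)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(gap[i] + c(0L, head(exon_length[i], -1L))) + 1L
  }
  idx_in_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  tibble(
    gene_id = sprintf("SYN_Os%02dg%06d", chrom, idx_in_chrom * 10L),
    exon_length = exon_length,
    chrom = paste0("Chr", chrom),
    start = start,
    end = start + exon_length - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    description = "synthetic gene"
  )
}

simulate_counts <- function(genes, true_rpkm, config, seed) {
  set.seed(seed)
  mu <- true_rpkm * (genes$exon_length / 1000) * config$library_size / 1e6
  counts <- if (is.infinite(config$dispersion)) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), size = config$dispersion, mu = mu)
  }
  structure(
    tibble(gene_id = genes$gene_id, weighted_count = as.numeric(counts)),
    total_mapped_reads = sum(counts),
    class = c("thermo_counts", "tbl_df", "tbl", "data.frame")
  )
}

simulate_categories <- function(genes, regulated_ids, config, seed) {
  set.seed(seed)
  N <- nrow(genes)
  R <- length(regulated_ids)
  non_reg <- setdiff(genes$gene_id, regulated_ids)
  spec <- config$categories |>
    group_by(.data$namespace) |>
    mutate(category_id = sprintf("SYN:%s:%03d", .data$namespace, row_number()),
           label = sprintf("synthetic %s category %d%s", .data$namespace,
                           row_number(), ifelse(.data$planted, " (planted)", ""))) |>
    ungroup()
  members <- purrr::pmap(spec, function(namespace, size, planted,
                                        enrichment_factor, category_id, label) {
    if (planted) {
      p_reg <- enrichment_factor * R / N
      if (p_reg > 1) {
        abort("infeasible planting: enrichment_factor * R / N exceeds 1")
      }
      if (size * p_reg > R) {
        abort("infeasible planting: more planted members than regulated genes")
      }
      # cap the stochastic draw at R so small universes stay feasible
      n_from_reg <- min(rbinom(1, size, p_reg), R)
      ids <- c(sample(regulated_ids, n_from_reg),
               sample(non_reg, size - n_from_reg))
    } else {
      ids <- sample(genes$gene_id, size)
    }
    tibble(category_id = category_id, label = label, namespace = namespace,
           gene_id = ids)
  }) |> bind_rows()
  list(members = members, spec = spec)
}

#' Write the simulated study to the pipeline's file dialects
#'
#' Emits the annotation TSV, one category TSV per namespace, the two count
#' tables, and the ground truth (TSVs plus a JSON sidecar).
#'
#' @param sim A `thermo_simulation` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "annotation.tsv"),
             counts_25 = file.path(dir, "counts_25C.tsv"),
             counts_30 = file.path(dir, "counts_30C.tsv"))
  write_gene_models(sim$genes, paths[["annotation"]])
  write_count_table(sim$counts_25, paths[["counts_25"]])
  write_count_table(sim$counts_30, paths[["counts_30"]])
  for (ns in unique(sim$categories$namespace)) {
    p <- file.path(dir, paste0("categories_", ns, ".tsv"))
    readr::write_tsv(
      filter(sim$categories, .data$namespace == ns) |>
        select("category_id", "label", "gene_id"),
      p, progress = FALSE)
    paths[paste0("categories_", ns)] <- p
  }
  paths["truth_regulated"] <- file.path(dir, "truth_regulated.tsv")
  readr::write_tsv(sim$truth$regulated, paths[["truth_regulated"]], progress = FALSE)
  paths["truth_rpkm"] <- file.path(dir, "truth_rpkm.tsv")
  readr::write_tsv(sim$truth$true_rpkm, paths[["truth_rpkm"]], progress = FALSE)
  paths["truth_json"] <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    planted_categories = sim$truth$planted_categories,
    sub_seeds = as.list(sim$truth$sub_seeds),
    n_regulated = nrow(sim$truth$regulated)
  ), paths[["truth_json"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Emit a small SAM fixture with known expected counts
#'
#' Writes a minimal SAM text stream exercising the NH-weighted counting
#' rules: unique reads inside exon unions, a configurable fraction of
#' multimappers reported at two loci with `NH:i:2`, intergenic and
#' optionally unmapped reads. The expected count table returned alongside
#' is computed by an independent per-read enumeration (simple linear
#' interval scans, no shared code with the production counter).
#'
#' @param genes Gene-model tibble (synthetic genes from
#'   [simulate_study()] work; spans are treated as exon unions).
#' @param n_reads Number of reads (<= 10,000).
#' @param frac_multi Fraction of reads reported at two loci with NH=2 (the
#'   second locus falls in a different gene).
#' @param frac_intergenic Fraction of reads placed outside every gene.
#' @param frac_unmapped Fraction of unmapped records.
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @param path Optional path to also write the SAM text to.
#' @return List with `sam` (character vector of SAM lines),
#'   `expected_counts` (count-table tibble with the `total_mapped_reads`
#'   attribute) and `records` (the per-read placement tibble).
#' @export
emit_sam_fixture <- function(genes, n_reads = 100, frac_multi = 0.2,
                             frac_intergenic = 0.1, frac_unmapped = 0,
                             read_len = 90L, seed = 1L, path = NULL) {
  if (n_reads > 10000) abort("SAM fixtures are capped at 10,000 reads")
  set.seed(seed)
  eligible <- which(genes$end - genes$start + 1L >= read_len)
  if (length(eligible) < 2) abort("need at least two genes longer than the read length")

  n_un <- round(frac_unmapped * n_reads)
  n_ig <- round(frac_intergenic * n_reads)
  n_mu <- round(frac_multi * n_reads)
  n_uq <- n_reads - n_un - n_ig - n_mu
  if (n_uq < 0) abort("read-class fractions exceed 1")

  place_in <- function(gi) {
    as.integer(round(runif(length(gi), genes$start[gi],
                           genes$end[gi] - read_len + 1L)))
  }
  max_end <- max(genes$end)

  rec <- list()
  if (n_uq > 0) {
    gi <- sample(eligible, n_uq, replace = TRUE)
    rec$unique <- tibble(read_id = sprintf("uniq_%04d", seq_len(n_uq)),
                         chrom = genes$chrom[gi], pos = place_in(gi),
                         n_hits = 1L, mapped = TRUE)
  }
  if (n_mu > 0) {
    g1 <- sample(eligible, n_mu, replace = TRUE)
    g2 <- vapply(g1, function(g) sample(setdiff(eligible, g), 1L), 1L)
    rec$multi <- tibble(
      read_id = rep(sprintf("multi_%04d", seq_len(n_mu)), 2L),
      chrom = genes$chrom[c(g1, g2)], pos = c(place_in(g1), place_in(g2)),
      n_hits = 2L, mapped = TRUE)
  }
  if (n_ig > 0) {
    rec$intergenic <- tibble(
      read_id = sprintf("intergenic_%04d", seq_len(n_ig)),
      chrom = sample(unique(genes$chrom), n_ig, replace = TRUE),
      pos = max_end + 10000L + as.integer(seq_len(n_ig)) * 200L,
      n_hits = 1L, mapped = TRUE)
  }
  if (n_un > 0) {
    rec$unmapped <- tibble(read_id = sprintf("unmapped_%04d", seq_len(n_un)),
                           chrom = NA_character_, pos = NA_integer_,
                           n_hits = 1L, mapped = FALSE)
  }
  records <- bind_rows(rec)

  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", unique(genes$chrom), max_end + 1000000L),
    ifelse(records$mapped,
           sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                   records$read_id, records$chrom, records$pos, read_len,
                   strrep("A", read_len), records$n_hits),
           sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                   records$read_id, strrep("A", read_len)))
  )
  if (!is.null(path)) writeLines(sam, path)

  list(sam = sam,
       expected_counts = enumerate_expected_counts(records, genes, read_len),
       records = records)
}

# independent per-read enumeration oracle: plain loops and comparisons
enumerate_expected_counts <- function(records, genes, read_len) {
  counts <- setNames(numeric(nrow(genes)), genes$gene_id)
  total <- 0
  for (i in seq_len(nrow(records))) {
    if (!records$mapped[i]) next
    w <- 1 / records$n_hits[i]
    total <- total + w
    r_start <- records$pos[i]
    r_end <- r_start + read_len - 1L
    hit <- which(genes$chrom == records$chrom[i] &
                   genes$start <= r_end & genes$end >= r_start)
    if (length(hit) == 1) counts[hit] <- counts[hit] + w
  }
  structure(
    tibble(gene_id = genes$gene_id, weighted_count = unname(counts)),
    total_mapped_reads = total,
    class = c("thermo_counts", "tbl_df", "tbl", "data.frame")
  )
}

#' Compare pipeline calls against the planted ground truth
#'
#' Direct set comparison of the called regulated genes and the enrichment
#' ranking against what the generator planted.
#'
#' @param regulated_called Called regulated genes (character vector or the
#'   tibble from [select_regulated()]).
#' @param enrichment A `thermo_enrichment` tibble covering all simulated
#'   categories (any mix of namespaces).
#' @param truth The `thermo_truth` from [simulate_study()].
#' @param n_genes Universe size used for specificity (defaults to the
#'   truth's config).
#' @return One-row tibble: `n_true_regulated`, `n_called`, `sensitivity`,
#'   `specificity`, `false_positive_rate`, `n_planted_categories`,
#'   `median_planted_rank`, `all_planted_top` (every planted category
#'   ranked above every non-planted one, globally) and
#'   `all_planted_top_namespace` (same, within each namespace).
#' @export
recovery_report <- function(regulated_called, enrichment, truth,
                            n_genes = truth$config$n_genes) {
  if (is.data.frame(regulated_called)) regulated_called <- regulated_called$gene_id
  called <- unique(regulated_called)
  true_reg <- truth$regulated$gene_id
  tp <- length(intersect(called, true_reg))
  fp <- length(setdiff(called, true_reg))
  tn <- n_genes - length(true_reg) - fp
  sens <- if (length(true_reg) == 0) NA_real_ else tp / length(true_reg)
  spec <- tn / (tn + fp)

  planted <- truth$planted_categories$category_id
  is_pl <- enrichment$category_id %in% planted
  top_global <- if (any(is_pl) && any(!is_pl)) {
    max(enrichment$p_value[is_pl]) < min(enrichment$p_value[!is_pl])
  } else NA
  top_ns <- if (any(is_pl) && any(!is_pl)) {
    all(vapply(unique(enrichment$namespace), function(ns) {
      e <- enrichment[enrichment$namespace == ns, ]
      pl <- e$category_id %in% planted
      if (!any(pl) || !any(!pl)) return(TRUE)
      max(e$p_value[pl]) < min(e$p_value[!pl])
    }, TRUE))
  } else NA

  tibble(
    n_true_regulated = length(true_reg),
    n_called = length(called),
    sensitivity = sens,
    specificity = spec,
    false_positive_rate = 1 - spec,
    n_planted_categories = length(planted),
    median_planted_rank = if (any(is_pl)) median(enrichment$rank[is_pl]) else NA_real_,
    all_planted_top = top_global,
    all_planted_top_namespace = top_ns
  )
}
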