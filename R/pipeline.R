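#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline so none is a literal in
#' code: the strict >1 RPKM expressed call, the 2-fold regulated
#' selection, the 1.5/2/3 regulation-bin edges, the pseudocount rule, the
#' enrichment universe and the binomial parameterisation.
#'
#' @param expressed_rpkm_threshold Strict RPKM threshold for the expressed
#'   call (default 1).
#' @param de_fold_threshold Fold threshold defining the regulated set
#'   (default 2).
#' @param class_edges Regulation-bin edges (default `c(1.5, 2, 3)`).
#' @param level_edges Expression-level bin edges (default
#'   `c(10, 100, 1000)`).
#' @param pseudocount_mode Only `"median_nonzero_rpkm"` is implemented.
#' @param universe_mode `"all_annotated"` (default) or `"expressed"`
#'   (genes expressed in at least one sample).
#' @param binomial_parameterisation `"pathway_n"` (default) or
#'   `"regulated_n"`, see [enrich_categories()].
#' @param adjustment `"none"` (default) or `"BH"`.
#' @param seed Integer seed recorded with the run.
#' @return A validated `thermo_config` list.
#' @export
analysis_config <- function(expressed_rpkm_threshold = 1,
                            de_fold_threshold = 2,
                            class_edges = c(1.5, 2, 3),
                            level_edges = c(10, 100, 1000),
                            pseudocount_mode = "median_nonzero_rpkm",
                            universe_mode = c("all_annotated", "expressed"),
                            binomial_parameterisation = c("pathway_n", "regulated_n"),
                            adjustment = c("none", "BH"),
                            seed = 1L) {
  universe_mode <- match.arg(universe_mode)
  binomial_parameterisation <- match.arg(binomial_parameterisation)
  adjustment <- match.arg(adjustment)
  pseudocount_mode <- match.arg(pseudocount_mode, "median_nonzero_rpkm")
  if (expressed_rpkm_threshold <= 0) abort("expressed_rpkm_threshold must be > 0")
  if (de_fold_threshold < 1) abort("de_fold_threshold must be >= 1")
  if (length(class_edges) != 3 || is.unsorted(class_edges, strictly = TRUE)) {
    abort("class_edges must be three strictly increasing values")
  }
  if (length(level_edges) != 3 || is.unsorted(level_edges, strictly = TRUE)) {
    abort("level_edges must be three strictly increasing values")
  }
  structure(list(
    expressed_rpkm_threshold = expressed_rpkm_threshold,
    de_fold_threshold = de_fold_threshold,
    class_edges = as.numeric(class_edges),
    level_edges = as.numeric(level_edges),
    pseudocount_mode = pseudocount_mode,
    universe_mode = universe_mode,
    binomial_parameterisation = binomial_parameterisation,
    adjustment = adjustment,
    seed = as.integer(seed)
  ), class = "thermo_config")
}

#' @rdname analysis_config
#' @param path File path for the YAML serialisation.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "thermo_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file does not exist: ", path))
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname analysis_config
#' @param config A `thermo_config`.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage ", stage, ": ", conditionMessage(e)))
  })
}

resolve_counts <- function(x, genes, stage) {
  with_stage(stage, {
    if (inherits(x, "thermo_counts")) return(x)
    if (is.character(x) && length(x) == 1) {
      if (grepl("\\.sam$", x, ignore.case = TRUE)) {
        return(weighted_gene_counts(read_sam_alignments(x), genes))
      }
      return(read_count_table(x))
    }
    abort("counts must be a thermo_counts table or a path to a count/SAM file")
  })
}

#' Run the full two-temperature analysis pipeline
#'
#' Orchestrates the stages end to end: annotation, per-sample counting or
#' count loading, RPKM profiles, the pseudocount fold-change table,
#' regulated-gene selection and per-namespace binomial enrichment.
#' Deterministic given inputs and config; every output file starts with a
#' comment header recording the package version and the config hash.
#'
#' @param annotation Gene-model tibble or path (GFF3/TSV).
#' @param counts_25,counts_30 Count tables, count-table paths, or SAM
#'   paths for the 25 and 30 degree samples.
#' @param categories Named list `list(GO = path_or_tibble, ...)`, or a
#'   single membership tibble with a `namespace` column.
#' @param config A `thermo_config` from [analysis_config()].
#' @param out_dir Output directory; created if needed. The bundle writes
#'   `expression.tsv`, `fold_change.tsv`, one `enrichment_<NS>.tsv` per
#'   namespace, `expression_histogram.tsv`, `fold_change_histogram.tsv`
#'   and `run_log.txt`.
#' @return A `thermo_bundle` list: `genes`, `profiles` (list with
#'   elements `t25`, `t30`), `fold_change`, `regulated`, `enrichment`
#'   (one `thermo_enrichment` per namespace, `NULL` when the regulated
#'   set is empty), `universe`, `files`, `config`, `log`.
#' @export
run_pipeline <- function(annotation, counts_25, counts_30, categories,
                         config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(config, "thermo_config"))
  log <- character()
  note <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    inform(line)
  }

  genes <- with_stage("annotation", {
    if (is.character(annotation)) read_gene_models(annotation) else {
      validate_gene_models(annotation)
    }
  })
  note("annotation: %d gene models", nrow(genes))

  c25 <- resolve_counts(counts_25, genes, "counts_25")
  c30 <- resolve_counts(counts_30, genes, "counts_30")
  note("counts: totals %.1f (25C) / %.1f (30C)",
       total_mapped_reads(c25), total_mapped_reads(c30))

  prof <- with_stage("quantification", list(
    t25 = expression_profile(c25, genes, sample = "25C",
                             threshold = config$expressed_rpkm_threshold,
                             level_edges = config$level_edges),
    t30 = expression_profile(c30, genes, sample = "30C",
                             threshold = config$expressed_rpkm_threshold,
                             level_edges = config$level_edges)
  ))
  note("quantification: %d / %d genes expressed (25C / 30C)",
       sum(prof$t25$expressed), sum(prof$t30$expressed))

  fc <- with_stage("differential",
                   fold_change_table(prof$t25, prof$t30, config$class_edges))
  regulated <- with_stage("differential",
                          select_regulated(fc, config$de_fold_threshold))
  note("differential: %d regulated genes at fold >= %g (pseudocounts %.3g / %.3g)",
       nrow(regulated), config$de_fold_threshold,
       attr(fc, "m_25"), attr(fc, "m_30"))

  universe <- with_stage("enrichment", {
    if (config$universe_mode == "all_annotated") {
      make_universe(genes)
    } else {
      make_universe(union(prof$t25$gene_id[prof$t25$expressed],
                          prof$t30$gene_id[prof$t30$expressed]))
    }
  })

  cat_map <- with_stage("categories", {
    if (is.data.frame(categories)) categories else {
      purrr::imap(categories, function(x, ns) {
        if (is.character(x)) read_category_map(x, namespace = ns,
                                               universe = universe) else x
      }) |> bind_rows()
    }
  })
  note("categories: %d memberships in %d categories",
       nrow(cat_map), n_distinct(cat_map$category_id))

  enr <- NULL
  if (nrow(regulated) == 0) {
    note("enrichment: skipped, the regulated set is empty")
  } else {
    enr <- with_stage("enrichment", {
      ns_list <- split(cat_map, cat_map$namespace)
      purrr::map(ns_list, function(m) {
        enrich_categories(regulated, m, universe,
                          parameterisation = config$binomial_parameterisation,
                          adjust = config$adjustment)
      })
    })
    note("enrichment: R = %d, N = %d, namespaces: %s",
         nrow(regulated), universe$N, paste(names(enr), collapse = ", "))
  }

  files <- character()
  if (!is.null(out_dir)) {
    files <- with_stage("report", write_bundle_files(
      out_dir, genes, prof, fc, enr, config))
    note("report: %d data files written", length(files))
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(log, sprintf("log: written to %s", "run_log.txt")), log_path)
    files["run_log"] <- log_path
  }

  structure(list(genes = genes, profiles = prof, fold_change = fc,
                 regulated = regulated, enrichment = enr,
                 universe = universe, files = files, config = config,
                 log = log),
            class = "thermo_bundle")
}

write_bundle_files <- function(out_dir, genes, prof, fc, enr, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("thermoseq %s config=%s",
                 as.character(packageVersion("thermoseq")), config_hash(config))
  files <- c(expression = file.path(out_dir, "expression.tsv"),
             fold_change = file.path(out_dir, "fold_change.tsv"),
             expression_histogram = file.path(out_dir, "expression_histogram.tsv"),
             fold_change_histogram = file.path(out_dir, "fold_change_histogram.tsv"))

  expr <- bind_rows(as_tibble(prof$t25), as_tibble(prof$t30)) |>
    mutate(level_bin = as.character(.data$level_bin))
  write_tsv_with_header(expr, files[["expression"]], hdr)
  write_fold_change_table(fc, genes, files[["fold_change"]], hdr)

  eh <- bind_rows(
    mutate(log2_histogram(prof$t25), sample = "25C"),
    mutate(log2_histogram(prof$t30), sample = "30C")
  )
  write_tsv_with_header(eh, files[["expression_histogram"]], hdr)
  write_tsv_with_header(fold_change_histogram(fc),
                        files[["fold_change_histogram"]], hdr)

  for (ns in names(enr)) {
    p <- file.path(out_dir, paste0("enrichment_", ns, ".tsv"))
    write_enrichment_table(enr[[ns]], p,
                           digits_ratio = if (ns == "TF") 3 else 2,
                           header = hdr)
    files[paste0("enrichment_", ns)] <- p
  }
  files
}

#' Summarise a pipeline run
#'
#' Per-class gene counts, expressed-gene counts per sample, and the
#' top-ranked enrichment rows per namespace (12 by default, the printed
#' tables' length), with the regulated-set and universe sizes used.
#'
#' @param bundle A `thermo_bundle` from [run_pipeline()].
#' @param top_n Number of top enrichment rows kept per namespace.
#' @return A `thermo_summary` list: `reg_class_counts`,
#'   `expressed_counts`, `top_enrichment` (with a `percent` column),
#'   `R`, `N`, `enrichment_skipped`.
#' @export
summarize_run <- function(bundle, top_n = 12) {
  stopifnot(inherits(bundle, "thermo_bundle"))
  reg_counts <- bundle$fold_change |>
    count(.data$reg_class, name = "n_genes", .drop = FALSE) |>
    as_tibble()
  expressed <- tibble(
    sample = c("25C", "30C"),
    n_expressed = c(sum(bundle$profiles$t25$expressed),
                    sum(bundle$profiles$t30$expressed)),
    total_mapped_reads = c(attr(bundle$profiles$t25, "total_mapped_reads"),
                           attr(bundle$profiles$t30, "total_mapped_reads"))
  )
  skipped <- is.null(bundle$enrichment)
  if (skipped) {
    inform("enrichment was skipped for this run (empty regulated set)")
    top <- NULL
  } else {
    top <- purrr::map(bundle$enrichment, function(e) {
      head(as_tibble(e), top_n) |>
        mutate(percent = round(100 * .data$k / .data$n, 1))
    })
  }
  structure(list(
    reg_class_counts = reg_counts,
    expressed_counts = expressed,
    top_enrichment = top,
    R = nrow(bundle$regulated),
    N = bundle$universe$N,
    enrichment_skipped = skipped
  ), class = "thermo_summary")
}

#' @export
print.thermo_summary <- function(x, ...) {
  cat("Two-temperature transcriptome run summary\n")
  cat(sprintf("  universe N = %d, regulated R = %d\n", x$N, x$R))
  cat("  expressed genes:\n")
  print(x$expressed_counts)
  cat("  regulation classes:\n")
  print(x$reg_class_counts)
  if (x$enrichment_skipped) {
    cat("  enrichment: skipped (empty regulated set)\n")
  } else {
    for (ns in names(x$top_enrichment)) {
      cat(sprintf("  top %s categories:\n", ns))
      print(select(x$top_enrichment[[ns]], "rank", "category_id", "n", "k",
                   "ratio", "percent", "p_value"))
    }
  }
  invisible(x)
}

#' @export
print.thermo_bundle <- function(x, ...) {
  cat("<thermo_bundle>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
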