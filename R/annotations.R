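#' Read gene models from a GFF3 or TSV annotation file
#'
#' Builds the per-gene annotation table the rest of the pipeline works from.
#' For GFF3 input the exon length of a gene is the total length of the
#' *union* of the exon intervals of all of its transcripts (overlapping exons
#' are merged), so the value does not depend on how many isoforms are
#' annotated. For TSV input the file supplies the exon length directly; the
#' expected header is `gene_id  exon_length  location  description`, with
#' `location` in `chrom:start-end(strand)` form (strand optional).
#'
#' Coordinates are 1-based inclusive on input and output; all interval
#' arithmetic inside the package is 0-based half-open, converted only at the
#' file boundary.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A tibble of gene models with columns `gene_id`, `exon_length`,
#'   `chrom`, `start`, `end`, `strand`, `description`, one row per gene.
#'   GFF3 input additionally carries the merged exon intervals in a
#'   list-column `exons` (tibbles with `start`, `end`), which the read
#'   counter uses for overlap tests when present.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\texon_length\tlocation\tdescription",
#'              "LOC_Os01g01010\t1200\tChr1:2903-10817(+)\texpressed protein"),
#'            tsv)
#' read_gene_models(tsv)
read_gene_models <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("annotation file does not exist: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  genes <- if (format == "gff3") read_gene_models_gff3(path) else read_gene_models_tsv(path)
  validate_gene_models(genes)
  genes
}

read_gene_models_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    exon_length = readr::col_integer(),
    location = readr::col_character(),
    description = readr::col_character()
  ), progress = FALSE)
  loc <- parse_location(raw$location)
  tibble(
    gene_id = raw$gene_id,
    exon_length = raw$exon_length,
    chrom = loc$chrom,
    start = loc$start,
    end = loc$end,
    strand = loc$strand,
    description = raw$description
  )
}

parse_location <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)(\\(([+.-])\\))?$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    abort(paste0("malformed location field: ", x[bad][1]))
  }
  tibble(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = ifelse(vapply(m, `[`, "", 6L) == "", ".", vapply(m, `[`, "", 6L))
  )
}

format_location <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d(%s)", chrom, start, end, strand)
}

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  if (!"Parent" %in% names(df)) df$Parent <- list(character(0))
  df$parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, "")

  genes <- df[df$type == "gene", ]
  if (nrow(genes) == 0) abort("no gene features found in GFF3")
  mrna <- df[df$type %in% c("mRNA", "transcript"), ]
  exons <- df[df$type == "exon", ]

  # exon Parent may point at an mRNA or directly at the gene
  mrna_to_gene <- setNames(mrna$parent, mrna$ID)
  exon_gene <- ifelse(exons$parent %in% names(mrna_to_gene),
                      unname(mrna_to_gene[exons$parent]), exons$parent)

  merged <- purrr::map(genes$ID, function(gid) {
    ex <- exons[exon_gene == gid, c("start", "end")]
    if (nrow(ex) == 0) {
      abort(paste0("gene with no exons in GFF3: ", gid))
    }
    ir <- IRanges::reduce(IRanges::IRanges(start = ex$start, end = ex$end))
    tibble(start = IRanges::start(ir), end = IRanges::end(ir))
  })

  tibble(
    gene_id = genes$ID,
    exon_length = vapply(merged, function(ex) sum(ex$end - ex$start + 1L), 1L),
    chrom = genes$seqnames,
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
    description = if ("Note" %in% names(genes)) {
      vapply(genes$Note, function(x) if (length(x)) as.character(x[[1]]) else NA_character_, "")
    } else NA_character_,
    exons = merged
  )
}

validate_gene_models <- function(genes) {
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id in annotation: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(genes$exon_length < 1L, na.rm = TRUE)) {
    abort("exon_length must be >= 1 for every gene")
  }
  if (any(genes$start > genes$end)) {
    abort("gene with start > end in annotation")
  }
  invisible(genes)
}

#' Write gene models to the tab-separated annotation dialect
#'
#' Inverse of [read_gene_models()] for the TSV dialect: columns `gene_id`,
#' `exon_length`, `location`, `description`. Re-reading the file reproduces
#' the input records (the `exons` list-column, present only for GFF3 input,
#' is not representable in this dialect and is dropped).
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  out <- tibble(
    gene_id = genes$gene_id,
    exon_length = genes$exon_length,
    location = format_location(genes$chrom, genes$start, genes$end, genes$strand),
    description = genes$description
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a category membership map (GO, KEGG or TF families)
#'
#' The file is a headered TSV with columns `category_id`, `label`,
#' `gene_id`, one row per (category, member) pair. Duplicate pairs are
#' collapsed. When a gene universe is supplied, members outside it are
#' dropped with a warning (and counted in the `n_dropped` attribute), and
#' categories left empty after the restriction are removed.
#'
#' @param path Path to the TSV file.
#' @param namespace One of `"GO"`, `"KEGG"`, `"TF"` — recorded in the
#'   `namespace` column.
#' @param universe Optional universe from [make_universe()] (or a character
#'   vector of gene ids) used to restrict memberships.
#' @return A tibble with columns `category_id`, `label`, `namespace`,
#'   `gene_id`, one row per membership; attribute `n_dropped` counts
#'   memberships removed by the universe restriction.
#' @export
read_category_map <- function(path, namespace = c("GO", "KEGG", "TF"), universe = NULL) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) {
    abort(paste0("category file does not exist: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    category_id = readr::col_character(),
    label = readr::col_character(),
    gene_id = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0) {
    warn(paste0("empty category file: ", path))
    return(structure(
      tibble(category_id = character(), label = character(),
             namespace = character(), gene_id = character()),
      n_dropped = 0L
    ))
  }
  cat_map <- raw |>
    mutate(namespace = namespace) |>
    distinct(.data$category_id, .data$label, .data$namespace, .data$gene_id)

  n_dropped <- 0L
  if (!is.null(universe)) {
    ids <- universe_ids(universe)
    outside <- !(cat_map$gene_id %in% ids)
    n_dropped <- sum(outside)
    if (n_dropped > 0) {
      warn(sprintf("%d membership row(s) referenced genes outside the universe and were dropped", n_dropped))
      cat_map <- cat_map[!outside, ]
    }
    gone <- setdiff(unique(raw$category_id), unique(cat_map$category_id))
    if (length(gone) > 0) {
      warn(paste0("categories with no members inside the universe dropped: ",
                  paste(gone, collapse = ", ")))
    }
  }
  structure(cat_map[, c("category_id", "label", "namespace", "gene_id")],
            n_dropped = n_dropped)
}

#' Define the background gene universe
#'
#' The universe is the gene set within which every enrichment count (pathway
#' size `n`, observed `k`, regulated-set size `R`, background size `N`) is
#' taken — by default all annotated genes.
#'
#' @param genes Gene-model tibble from [read_gene_models()], or a character
#'   vector of gene ids.
#' @return An object of class `thermo_universe`: the vector of gene ids with
#'   size `N = length(gene_ids)`.
#' @export
make_universe <- function(genes) {
  ids <- if (is.character(genes)) genes else genes$gene_id
  if (length(ids) == 0) {
    abort("cannot build a universe from an empty gene set")
  }
  if (anyDuplicated(ids)) {
    abort("duplicate gene ids in universe input")
  }
  structure(list(gene_ids = ids, N = length(ids)), class = "thermo_universe")
}

universe_ids <- function(universe) {
  if (inherits(universe, "thermo_universe")) universe$gene_ids else universe
}

universe_size <- function(universe) {
  if (inherits(universe, "thermo_universe")) universe$N else length(universe)
}

#' @export
print.thermo_universe <- function(x, ...) {
  cat("<thermo_universe> N =", x$N, "genes\n")
  invisible(x)
}
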