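#' One-sided binomial tail probability
#'
#' Exact upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p)`,
#' computed by summing binomial log-probabilities (log-sum-exp), with no
#' normal approximation. This is the enrichment statistic: with `n` the
#' pathway size and `p = R/N` the background regulated rate, it is the
#' probability of observing at least `k` regulated members by chance.
#' Vectorised over `k`, `n`, `p`.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of trials (>= 0).
#' @param p Success probability, strictly inside (0, 1).
#' @param lower Return the lower tail `P(X <= k)` instead (used by the
#'   optional depletion score); default `FALSE`.
#' @return Probability in (0, 1].
#' @export
binomial_tail <- function(k, n, p, lower = FALSE) {
  if (any(p <= 0 | p >= 1)) abort("binomial p must be strictly inside (0, 1)")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  if (any(n != floor(n)) || any(k != floor(k))) abort("k and n must be integers")
  m <- max(length(k), length(n), length(p))
  k <- rep_len(k, m); n <- rep_len(n, m); p <- rep_len(p, m)
  vapply(seq_len(m), function(i) {
    j <- if (lower) 0:k[i] else k[i]:n[i]
    logsumexp(stats::dbinom(j, n[i], p[i], log = TRUE))
  }, 1)
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(exp(m))
  min(exp(m + log(sum(exp(lx - m)))), 1)
}

#' Score category over-representation among regulated genes
#'
#' For each category: pathway size `n` = members inside the universe,
#' observed `k` = members in the regulated set, `ratio = k/n`, and a
#' one-sided exact binomial tail p-value. The default parameterisation
#' treats the pathway as the sample — `P(X >= k)` for `X ~ Binomial(n,
#' R/N)` — matching a background in which a fraction `R/N` of all genes is
#' regulated; the alternative `"regulated_n"` treats the regulated set as
#' the sample, `X ~ Binomial(R, n/N)`. Results are ranked by ascending
#' p-value (ties: larger `k` first, then category id).
#'
#' @param regulated Character vector of regulated gene ids (or the tibble
#'   from [select_regulated()]), the foreground `R`.
#' @param categories Category-membership tibble from [read_category_map()]
#'   (columns `category_id`, `label`, `namespace`, `gene_id`).
#' @param universe Universe from [make_universe()] (or character vector):
#'   the background `N`. Regulated genes must lie inside it.
#' @param parameterisation `"pathway_n"` (default) or `"regulated_n"`.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values in `p_adjusted`.
#' @param depletion Also report the lower-tail (depletion) p-value in
#'   `p_depletion`; off by default, over-representation is what is ranked.
#' @return A `thermo_enrichment` tibble: `rank`, `category_id`, `label`,
#'   `namespace`, `n`, `k`, `ratio`, `p_value` (plus `p_adjusted` /
#'   `p_depletion` when requested); attributes `R`, `N`,
#'   `parameterisation`.
#' @export
enrich_categories <- function(regulated, categories, universe,
                              parameterisation = c("pathway_n", "regulated_n"),
                              adjust = c("none", "BH"),
                              depletion = FALSE) {
  parameterisation <- match.arg(parameterisation)
  adjust <- match.arg(adjust)
  if (is.data.frame(regulated)) regulated <- regulated$gene_id
  regulated <- unique(regulated)
  ids <- universe_ids(universe)
  N <- universe_size(universe)
  if (length(regulated) == 0) abort("the regulated set is empty; nothing to enrich")
  outside <- setdiff(regulated, ids)
  if (length(outside) > 0) {
    abort(paste0("regulated genes outside the universe: ",
                 paste(head(outside, 3), collapse = ", ")))
  }
  R <- length(regulated)

  per_cat <- categories |>
    distinct(.data$category_id, .data$label, .data$namespace, .data$gene_id) |>
    group_by(.data$category_id, .data$label, .data$namespace) |>
    summarise(
      n = sum(.data$gene_id %in% ids),
      k = sum(.data$gene_id %in% ids & .data$gene_id %in% regulated),
      .groups = "drop"
    )
  empty <- per_cat$n == 0
  if (any(empty)) {
    warn(paste0("categories with no members in the universe skipped: ",
                paste(per_cat$category_id[empty], collapse = ", ")))
    per_cat <- per_cat[!empty, ]
  }
  if (nrow(per_cat) == 0) {
    abort("no category has members inside the universe")
  }

  res <- per_cat |>
    mutate(
      ratio = .data$k / .data$n,
      p_value = if (parameterisation == "pathway_n") {
        binomial_tail(.data$k, .data$n, R / N)
      } else {
        binomial_tail(.data$k, R, .data$n / N)
      }
    )
  if (depletion) {
    res$p_depletion <- if (parameterisation == "pathway_n") {
      binomial_tail(res$k, res$n, R / N, lower = TRUE)
    } else {
      binomial_tail(res$k, R, res$n / N, lower = TRUE)
    }
  }
  if (adjust == "BH") res$p_adjusted <- bh_adjust(res$p_value)

  res <- rank_results(res)
  structure(res, R = R, N = N, parameterisation = parameterisation,
            class = c("thermo_enrichment", "tbl_df", "tbl", "data.frame"))
}

#' Rank enrichment results
#'
#' Ascending p-value; ties broken by descending observed count `k`, then
#' lexicographic category id. Ranks are a permutation of 1..#categories.
#'
#' @param results Tibble with columns `p_value`, `k`, `category_id`.
#' @return The tibble sorted with a `rank` column first.
#' @export
rank_results <- function(results) {
  ord <- order(results$p_value, -results$k, results$category_id)
  out <- results[ord, ]
  out$rank <- seq_len(nrow(out))
  select(out, "rank", dplyr::everything())
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wrapper around `stats::p.adjust(method = "BH")` with input validation;
#' adjusted values are monotone, at least the raw p-value and at most 1.
#'
#' @param p_values Raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Regulated fraction of a gene family
#'
#' Convenience summary for one category (e.g. a transcription-factor
#' family): the observed count `k`, the family size `n`, the percentage
#' `100 k/n` and the ratio `k/n`, rounded to report precision. Percent
#' defaults to one decimal and ratio to two (three for small ratios keeps
#' the printed style of family tables — pass `digits_ratio = 3`).
#'
#' @param k Number of regulated members (or a membership tibble for one
#'   category, in which case supply `regulated`).
#' @param n Family size.
#' @param regulated Regulated gene ids, used when `k` is a membership
#'   tibble.
#' @param digits_percent,digits_ratio Rounding for the two report columns.
#' @return Tibble `k`, `n`, `ratio`, `percent`.
#' @export
family_regulation_fraction <- function(k, n = NULL, regulated = NULL,
                                       digits_percent = 1, digits_ratio = 2) {
  if (is.data.frame(k)) {
    members <- unique(k$gene_id)
    n <- length(members)
    k <- length(intersect(members, unique(regulated)))
  }
  if (n < 1) abort("family size n must be >= 1")
  tibble(k = as.integer(k), n = as.integer(n),
         ratio = round(k / n, digits_ratio),
         percent = round(100 * k / n, digits_percent))
}

#' Write an enrichment report table
#'
#' Columns in the printed order `Rank`, `Pathway`, `Pathway annotation`,
#' `Pathway size`, `Observed`, `Ratio`, `P value`, with the ratio rounded
#' to report precision, followed by full-precision `ratio_full` and
#' `p_value_full` columns.
#'
#' @param results A `thermo_enrichment` tibble.
#' @param path Output path.
#' @param digits_ratio Rounding for the printed ratio column.
#' @param header Optional comment line written before the table.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(results, path, digits_ratio = 2, header = NULL) {
  out <- tibble(
    "Rank" = results$rank,
    "Pathway" = results$label,
    "Pathway annotation" = results$category_id,
    "Pathway size" = results$n,
    "Observed" = results$k,
    "Ratio" = round(results$ratio, digits_ratio),
    "P value" = signif(results$p_value, 3),
    "ratio_full" = results$ratio,
    "p_value_full" = results$p_value
  )
  write_tsv_with_header(out, path, header)
  invisible(path)
}

#' Per-gene scatter data for expression comparison plots
#'
#' Exports the data behind a two-sample expression scatter: log2 RPKM in
#' each sample for genes expressed in both (RPKM > 0), with an optional
#' family/category label for highlighting.
#'
#' @param table A `thermo_foldchange` tibble.
#' @param categories Optional membership tibble; genes get the `label` of
#'   the first category that contains them, others `"other"`.
#' @return Tibble `gene_id`, `log2_rpkm_25`, `log2_rpkm_30`, `family`.
#' @export
scatter_data <- function(table, categories = NULL) {
  dat <- table |>
    filter(.data$rpkm_25 > 0, .data$rpkm_30 > 0) |>
    mutate(log2_rpkm_25 = log2(.data$rpkm_25),
           log2_rpkm_30 = log2(.data$rpkm_30)) |>
    select("gene_id", "log2_rpkm_25", "log2_rpkm_30")
  if (is.null(categories)) {
    dat$family <- "other"
  } else {
    lab <- categories |> distinct(.data$gene_id, .keep_all = TRUE) |>
      select("gene_id", family = "label")
    dat <- left_join(dat, lab, by = "gene_id") |>
      mutate(family = ifelse(is.na(.data$family), "other", .data$family))
  }
  dat
}
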