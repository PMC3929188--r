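#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()`
#' returns the per-row observations as a plain tibble, `glance()` a
#' one-row summary of the object.
#'
#' @param x A `thermo_expression`, `thermo_foldchange` or
#'   `thermo_enrichment` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name thermoseq-tidiers
NULL

#' @rdname thermoseq-tidiers
#' @export
tidy.thermo_expression <- function(x, ...) {
  as_tibble(x)
}

#' @rdname thermoseq-tidiers
#' @export
glance.thermo_expression <- function(x, ...) {
  tibble(
    sample = x$sample[1],
    n_genes = nrow(x),
    n_expressed = sum(x$expressed),
    total_mapped_reads = attr(x, "total_mapped_reads"),
    threshold = attr(x, "threshold"),
    median_nonzero_rpkm = median_pseudocount(x)
  )
}

#' @rdname thermoseq-tidiers
#' @export
tidy.thermo_foldchange <- function(x, ...) {
  as_tibble(x)
}

#' @rdname thermoseq-tidiers
#' @export
glance.thermo_foldchange <- function(x, ...) {
  r <- pmax(x$fldchg, 1 / x$fldchg)
  tibble(
    n_genes = nrow(x),
    m_25 = attr(x, "m_25"),
    m_30 = attr(x, "m_30"),
    n_regulated_2fold = sum(r >= 2),
    n_up25_2fold = sum(r >= 2 & x$fldchg < 1),
    n_dn25_2fold = sum(r >= 2 & x$fldchg >= 1)
  )
}

#' @rdname thermoseq-tidiers
#' @export
tidy.thermo_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @rdname thermoseq-tidiers
#' @export
glance.thermo_enrichment <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    R = attr(x, "R"),
    N = attr(x, "N"),
    parameterisation = attr(x, "parameterisation"),
    n_p_below_05 = sum(x$p_value < 0.05),
    min_p_value = min(x$p_value)
  )
}
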