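test_that("binomial_tail matches small closed forms and the full distribution", {
  expect_equal(binomial_tail(0, 5, 0.3), 1.0)
  expect_equal(binomial_tail(2, 5, 0.5), 0.8125)  # 26/32 outcomes
  expect_equal(binomial_tail(10, 10, 0.1), 1e-10)
  expect_error(binomial_tail(2, 5, 0), "inside")
  expect_error(binomial_tail(6, 5, 0.5), "0 <= k <= n")
})

test_that("binomial_tail agrees with exhaustive enumeration and pbinom", {
  for (n in c(3, 7, 10)) {
    for (p in c(0.1, 0.5, 0.9)) {
      for (k in 0:n) {
        expected <- enum_binomial_tail(k, n, p)
        expect_equal(binomial_tail(k, n, p), expected, tolerance = 1e-12)
      }
    }
  }
  # independent library cross-check at realistic enrichment sizes
  ks <- c(0, 3, 15, 57, 241)
  ns <- c(10, 95, 107, 362, 3620)
  p0 <- 1374 / 56143
  expect_equal(binomial_tail(ks, ns, p0),
               pbinom(ks - 1, ns, p0, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("binomial_tail is non-increasing in k", {
  p <- 0.07
  tails <- binomial_tail(0:40, 40, p)
  expect_true(all(diff(tails) <= 1e-15))
})

test_that("category enrichment computes n, k, ratio and the tail p-value", {
  universe <- make_universe(sprintf("g%04d", 1:1000))
  regulated <- sprintf("g%04d", 1:100)
  cats <- tibble::tibble(
    category_id = rep(c("full", "disjoint"), each = 10),
    label = rep(c("all regulated", "none regulated"), each = 10),
    namespace = "GO",
    gene_id = c(sprintf("g%04d", 1:10), sprintf("g%04d", 901:910))
  )
  res <- enrich_categories(regulated, cats, universe)
  full <- res[res$category_id == "full", ]
  expect_equal(full$n, 10L)
  expect_equal(full$k, 10L)
  expect_equal(full$ratio, 1)
  expect_equal(full$p_value, 0.1^10, tolerance = 1e-9)
  disjoint <- res[res$category_id == "disjoint", ]
  expect_equal(disjoint$k, 0L)
  expect_equal(disjoint$p_value, 1.0)
  expect_equal(disjoint$ratio, 0)
  expect_equal(attr(res, "R"), 100L)
  expect_equal(attr(res, "N"), 1000L)
})

test_that("the observed counts sum to the membership of regulated genes", {
  set.seed(21)
  ids <- sprintf("g%04d", 1:500)
  universe <- make_universe(ids)
  regulated <- sample(ids, 60)
  cats <- tibble::tibble(
    category_id = rep(sprintf("c%02d", 1:8), each = 25),
    label = "cat", namespace = "KEGG",
    gene_id = sample(ids, 200, replace = TRUE)
  )
  res <- enrich_categories(regulated, cats, universe)
  direct <- cats |>
    dplyr::distinct(category_id, gene_id) |>
    dplyr::filter(gene_id %in% regulated) |>
    nrow()
  expect_equal(sum(res$k), direct)
})

test_that("empty-in-universe categories are skipped with a warning", {
  universe <- make_universe(c("gA", "gB"))
  cats <- tibble::tibble(
    category_id = c("in", "out"), label = c("in", "out"),
    namespace = "GO", gene_id = c("gA", "gZ"))
  expect_warning(res <- enrich_categories("gA", cats, universe), "skipped")
  expect_equal(res$category_id, "in")
  expect_error(
    suppressWarnings(enrich_categories("gA", cats[2, ], universe)),
    "no category")
})

test_that("the alternative parameterisation swaps the binomial margins", {
  universe <- make_universe(sprintf("g%03d", 1:200))
  regulated <- sprintf("g%03d", 1:40)
  cats <- tibble::tibble(category_id = "c1", label = "c1", namespace = "GO",
                         gene_id = sprintf("g%03d", seq(1, 60, by = 3)))
  a <- enrich_categories(regulated, cats, universe, "pathway_n")
  b <- enrich_categories(regulated, cats, universe, "regulated_n")
  expect_equal(a$p_value, binomial_tail(a$k, a$n, 40 / 200))
  expect_equal(b$p_value, binomial_tail(b$k, 40, a$n / 200))
})

test_that("ranking is by p, then larger k, then category id", {
  res <- tibble::tibble(
    category_id = c("b", "a", "c", "d"),
    k = c(5L, 9L, 9L, 2L),
    p_value = c(1e-5, 1e-5, 1e-5, 1e-7))
  ranked <- rank_results(res)
  expect_equal(ranked$category_id, c("d", "a", "c", "b"))
  expect_equal(ranked$rank, 1:4)
  single <- rank_results(res[1, ])
  expect_equal(single$rank, 1L)
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  # hand-computed step-up: p * m / rank with running minimum from the top
  p <- c(0.005, 0.04, 0.02, 0.9)
  expect_equal(bh_adjust(p), c(0.02, 0.0533333333333333, 0.04, 0.9),
               tolerance = 1e-10)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("family fractions round to report precision", {
  bzip <- family_regulation_fraction(9, 95)
  expect_equal(bzip$percent, 9.5)
  wrky <- family_regulation_fraction(15, 107)
  expect_equal(wrky$ratio, 0.14)
  expect_equal(family_regulation_fraction(0, 50)$percent, 0)
  members <- tibble::tibble(gene_id = sprintf("g%02d", 1:20))
  got <- family_regulation_fraction(members, regulated = sprintf("g%02d", 1:5))
  expect_equal(got$k, 5L)
  expect_equal(got$n, 20L)
  expect_equal(got$percent, 25)
})

test_that("a planted category scores the smallest p-value in a simulated study", {
  sim <- simulate_study(simulation_config(n_genes = 4000, n_up25 = 100,
                                          n_dn25 = 60, seed = 303))
  res <- enrich_categories(sim$truth$regulated$gene_id, sim$categories,
                           make_universe(sim$genes))
  top <- res$category_id[res$rank == 1]
  expect_true(top %in% sim$truth$planted_categories$category_id)
})

test_that("enrichment reports print the table layout with full precision kept", {
  universe <- make_universe(sprintf("g%03d", 1:300))
  cats <- tibble::tibble(category_id = rep(c("c1", "c2"), each = 15),
                         label = rep(c("one", "two"), each = 15),
                         namespace = "TF",
                         gene_id = sprintf("g%03d", c(1:15, 101:115)))
  res <- enrich_categories(sprintf("g%03d", 1:30), cats, universe)
  path <- tempfile(fileext = ".tsv")
  write_enrichment_table(res, path, digits_ratio = 3)
  got <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(got)[1:7],
               c("Rank", "Pathway", "Pathway annotation", "Pathway size",
                 "Observed", "Ratio", "P value"))
  expect_equal(got$ratio_full, res$ratio)
  expect_equal(got$p_value_full, res$p_value)
})

test_that("scatter export pairs log2 expression with family labels", {
  p25 <- profile_from_rpkm(c(2, 4, 0, 16), sample = "25C")
  p30 <- profile_from_rpkm(c(2, 8, 5, 16), sample = "30C")
  fc <- fold_change_table(p25, p30)
  fams <- tibble::tibble(category_id = "TF:X", label = "famX",
                         namespace = "TF", gene_id = "g002")
  dat <- scatter_data(fc, fams)
  expect_equal(nrow(dat), 3)  # the rpkm_25 == 0 gene is excluded
  expect_equal(dat$family[dat$gene_id == "g002"], "famX")
  expect_equal(dat$log2_rpkm_25[dat$gene_id == "g001"], 1)
  expect_equal(dat$log2_rpkm_30[dat$gene_id == "g002"], 3)
})
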