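# brute-force oracles, deliberately independent of the implementation paths

# upper-tail binomial probability by explicit enumeration of all 2^n
# outcome vectors (feasible for n <= 12)
enum_binomial_tail <- function(k, n, p) {
  outcomes <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  successes <- rowSums(outcomes)
  probs <- apply(outcomes, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  sum(probs[successes >= k])
}

# per-read assignment enumeration: nested loops, linear interval scans
enum_weighted_counts <- function(alignments, genes) {
  counts <- setNames(numeric(nrow(genes)), genes$gene_id)
  total <- 0
  for (i in seq_len(nrow(alignments))) {
    if (!alignments$mapped[i]) next
    w <- 1 / alignments$n_hits[i]
    total <- total + w
    a_start <- alignments$pos[i]
    a_end <- a_start + alignments$span[i] - 1L
    hits <- character()
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] == alignments$chrom[i] &&
          genes$start[g] <= a_end && genes$end[g] >= a_start) {
        hits <- c(hits, genes$gene_id[g])
      }
    }
    if (length(unique(hits)) == 1) {
      counts[hits[1]] <- counts[hits[1]] + w
    }
  }
  list(counts = counts, total = total)
}
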