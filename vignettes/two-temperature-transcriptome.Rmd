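---
title: "Methods: two-temperature transcriptome analysis without replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-temperature transcriptome analysis without replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoseq)
```

## The analysis problem

thermoseq implements a complete analysis chain for a common but awkward
experimental design: bulk RNA-seq of one library per condition, here rice
seedling leaf blades grown at 25°C and 30°C against the MSU release-7 rice
annotation (~56,000 gene models). With no replicates there is no
within-condition variance to estimate, so replicate-aware tools (DESeq2,
edgeR dispersion models) do not apply. The chain instead uses three simple,
transparent statistics:

1. **RPKM quantification** with multimapper down-weighting,
2. **median-pseudocount fold changes** between the two samples,
3. **exact one-sided binomial tests** for category (GO / KEGG /
   transcription-factor family) over-representation among regulated genes.

Each stage is an exported, pipe-friendly function over tibbles; the
`run_pipeline()` orchestrator, `analysis_config()` and `summarize_run()`
form the end-to-end interface, and a synthetic-study generator provides
ground-truth data for every stage.

## Quantification

Expression for gene $g$ in a sample with total mapped-read weight $T$ is

$$\mathrm{RPKM}_g = \frac{c_g}{(L_g/10^3)\,(T/10^6)},
\qquad
\mathrm{RPB}_g = 10^9\,\frac{c_g}{T},$$

where $L_g$ is the length of the union of the gene's annotated exons (so
the value does not depend on how many isoforms are annotated) and $c_g$ is
the weighted read count. Each mapped alignment contributes weight $1/\mathrm{NH}$
(the reciprocal of its number of reported genome locations, from the SAM NH
tag) to the single gene whose exon union it overlaps by at least one base.
Three deliberate conventions:

* **Ambiguous alignments** overlapping two or more genes are assigned to
  none — the dominant convention (htseq-count's `union`-mode "ambiguous"),
  chosen over fractional splitting to avoid double counting. They still
  count in $T$, as do intergenic alignments: $T$ is the total mapped mass,
  not the assigned mass, which makes read-mass conservation
  ($\sum_g c_g \le T$) a checkable invariant.
* **Mates of a pair are counted as two reads** by default (the library
  totals are read counts, not fragment counts); `mate_handling =
  "fragments"` halves paired-record weights instead.
* **Strand is carried but ignored** in counting; the protocol is treated
  as unstranded.

A gene is **expressed** when RPKM is *strictly* greater than the threshold
(default 1 RPKM). Expressed genes are binned left-closed at 10/100/1000
RPKM into low / modest / high / extreme levels; together with
`not_detected` the bins partition the annotation, another tested
invariant. The boundary placement at exactly 10 (rather than "9") and the
strictness of the expressed call are configurable in `analysis_config()`
because published descriptions of such cut-offs are often ambiguous; the
defaults are the package's fixed reading.

Whether the RPKM denominator should be all reads or mapped reads is a
genuine ambiguity in the field; the package uses **mapped** reads, the
only total observable from its inputs.

## Fold changes without replicates

With one library per condition the only usable stabiliser is a
pseudocount. For each sample the package adds the **median RPKM over that
sample's nonzero genes** ($m_{25}$, $m_{30}$) to both terms:

$$\mathrm{fldchg}_g=\frac{\mathrm{RPKM}_{30,g}+m_{30}}{\mathrm{RPKM}_{25,g}+m_{25}},$$

so values below 1 mean higher expression at 25°C. The median is taken over
*nonzero* genes because the median over all annotated genes is zero
whenever at least half the annotation is silent — which is the case in any
real leaf library — and a zero pseudocount would leave silent genes'
ratios undefined. Computing the ratio for **all** annotated genes (not
just expressed ones) is intentional: with the pseudocount floor the ratio
is defined everywhere, and downstream category counts are then taken
against the full-annotation universe.

Genes are classified by the fold magnitude $r=\max(f, 1/f)$ into seven
bins: unchanged ($r<1.5$), 1.5–2, 2–3, and $\ge 3$, each split by
direction. All edges are closed on the left ($\ge$), so "twofold or
higher" selects $r \ge 2$ exactly and the bins partition the axis. The
regulated set $R$ for enrichment is $r \ge 2$ by default.

Three properties pin the arithmetic down and are tested directly:
swapping the samples maps $f \mapsto 1/f$ and mirrors the direction
labels exactly; $f$ is strictly monotone in each sample's RPKM; and as
the pseudocount grows every ratio collapses to 1 (the pseudocount's
damping of low-expression fold changes, taken to its limit).

## Binomial enrichment

For a category with $n$ members inside the universe (size $N$) of which
$k$ are regulated (regulated-set size $R$), the score is the exact
one-sided binomial tail

$$P = \Pr(X \ge k), \qquad X \sim \mathrm{Binomial}\!\left(n, \frac{R}{N}\right),$$

summed in log space with no normal approximation (`binomial_tail()`,
authored in-package and cross-checked in the tests against both
`stats::pbinom` and exhaustive enumeration of all $2^n$ outcomes for
$n \le 12$). Results carry pathway size, observed count, ratio $k/n$ and
rank (ascending $P$, ties by larger $k$, then category id).

Design choices that were genuinely open:

* **Parameterisation.** Treating the pathway as the sample
  ($n$ draws at rate $R/N$) is the default; the transpose (the regulated
  set as $R$ draws at rate $n/N$) is available as
  `binomial_parameterisation = "regulated_n"`. At $N = 56{,}143$,
  $R = 1{,}374$ the default reproduces the order of magnitude of every
  family-table probability (e.g. WRKY $k=15$, $n=107$ gives
  $6.1\times10^{-8}$), which is the precision the package claims for this
  statistic: published tables of this kind rarely state the exact
  convention, so digit-exact agreement is not a meaningful target.
* **Universe.** All annotated genes by default (`universe_mode =
  "expressed"` restricts to genes detected in either sample).
* **No multiple-testing adjustment by default**; Benjamini–Hochberg
  (`stats::p.adjust`) is available by flag.
* **Depletion is not ranked**; a lower-tail column is available by flag.

Because the binomial count is discrete, the exact tail test is
*conservative*: under a random-regulated-set null with category sizes
20–200 the analytic rejection rate at $\alpha=0.05$ is ≈0.036–0.038
regardless of $R/N$, not 0.05. The calibration test asserts the empirical
rate falls within three binomial standard errors of the nominal level
over 1000 replicates, which this conservatism satisfies; it is a property
of discrete exact tests, not a defect of the implementation.

## The synthetic-study generator

`simulate_study()` emulates the structure of the real study so that every
stage can be validated against known truth:

* ~56k-style annotation scaled to 10,000 genes by default (uniform
  500–5000 bp exon unions on 12 chromosomes), 1e6 reads per sample;
  `paper_scale_config()` gives the 56,143-gene / 25M-read preset.
* Half the genes expressed; expressed genes draw a log-normal expression
  shape with $\sigma_{\log} = 1.6$. At full scale this reproduces the
  canonical leaf-transcriptome profile (median ≈ 5 RPKM, ≈3% of expressed
  genes above 100 RPKM, about two thirds below 10 RPKM).
* True RPKM is normalised per condition so that
  $\sum_g \mathrm{RPKM}_g L_g/10^3 = 10^6$ — the identity every genuine
  RPKM vector satisfies. A consequence worth knowing: absolute per-gene
  RPKM scales inversely with the number of expressed genes, so the
  desk-scale default (5,000 expressed genes sharing a million reads) sits
  ≈4× above the full-scale levels while preserving the distribution's
  shape.
* 250 genes planted up at 25°C and 150 down (the real study's ~1.5:1
  direction ratio), at a fixed 8-fold change, drawn from expressed genes
  between the 50th and 90th expression percentile. Two reasons: the
  median pseudocount *deliberately* shrinks ratios of genes below the
  typical expression level, so planting regulation there would test the
  method against behaviour it is designed to suppress; and excluding the
  extreme top decile keeps the planted genes from shifting a large share
  of the library mass between conditions.
* Counts are negative binomial with mean
  $\mathrm{RPKM}\times L_\mathrm{kb} \times \mathrm{lib}/10^6$
  (Poisson in the default infinite-dispersion limit — the single-library
  design gives no dispersion information, but the knob lets tests probe
  robustness).
* 12 categories per namespace (GO/KEGG/TF); two per namespace are planted
  at enrichment factor 5, i.e. each member is a regulated gene with
  probability $5R/N$; planted sizes (120) were chosen by a power analysis
  of the ranking statistic so that all six planted categories outrank all
  thirty null categories in ≈99.8% of seeds. When a draw would need more
  regulated members than exist the generator caps it; a configuration
  whose *expected* planting is infeasible is a hard error.
* Every artifact (annotation, expression, each sample's counts,
  categories) draws from its own RNG stream derived from the single seed,
  so fixtures regenerate independently and byte-identically; the recorded
  ground truth is exact, which the suite verifies by regenerating counts
  from the stored per-gene parameters.

What the generator does **not** emulate: sequence content and alignment
error (no FASTQ, no aligner in the loop), 3'/5' coverage bias, isoform
structure (one expression value per gene), and library-composition biases
beyond those induced by planting. Tests passing on synthetic data
therefore validate the *arithmetic and the statistics*, not robustness to
alignment artefacts.

`emit_sam_fixture()` additionally writes miniature SAM streams (unique
reads, NH=2 multimappers split across two loci, intergenic and unmapped
records) together with expected counts computed by an independent
per-read enumeration, which is the oracle the counting tests compare
against.

## Numerical and interface choices

* GFF3 coordinates are 1-based inclusive; interval arithmetic happens in
  IRanges/GenomicRanges; conversions occur only at file boundaries.
  Exon-union lengths are invariant to exon order and to splitting an exon
  into adjacent pieces (tested).
* `binomial_tail()` clamps its log-sum-exp at 1 so a $k=0$ tail is
  exactly 1; p-values are computed per category, never approximated.
* Report tables round ratios to two decimals (three for family tables)
  and percentages to one decimal, matching common journal style, while
  always writing full-precision companion columns.
* Every thermoseq output file begins with a `#thermoseq <version>
  config=<hash>` header; reruns with identical inputs and config are
  byte-identical (tested), and the run log records per-stage record
  counts so the partition invariants can be audited from logs alone.
* Problem sizes in the test suite are desk scale by design: the default
  simulated study (10,000 genes, 1e6 reads) runs the full pipeline in
  well under a second, the recovery check spans 100 seeds, and the null
  calibration uses 1000 replicates of five categories each.

## Known limitations

* No per-gene significance: with one library per condition the fold
  change is descriptive; the package deliberately offers no gene-level
  p-values.
* The pseudocount makes fold changes conservative for weakly expressed
  genes; sensitivity claims from the synthetic study apply to genes
  expressed at or above typical levels.
* KEGG "pathway size" is counted in genes, not transcripts; flat category
  lists only (no GO-graph propagation, no pathway topology).
* The binomial model treats regulated membership as independent draws;
  hypergeometric-style finite-population corrections are not offered
  beyond the two binomial parameterisations.
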