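---
title: "Methods: ChIRP-seq downstream analysis in chirpflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ChIRP-seq downstream analysis in chirpflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpflow)
```

## The analytical model

ChIRP-seq recovers the DNA contacted by a target RNA. After alignment and
MACS peak calling, each peak carries a genomic interval, a fold-enrichment
over the input track, and an FDR. `chirpflow` operates entirely on these
called peaks; read-level processing is out of scope. The pipeline is a
fixed composition of five stages, each an exported function with no hidden
state, so running `run_pipeline()` is provably equivalent to running the
stages by hand on the intermediate files (and a test asserts this).

All coordinates are normalized on read to 0-based half-open (BED)
intervals; GTF input (1-based inclusive) is converted once at the boundary.
Every windowed criterion uses one distance notion, `gap_distance()`: the
number of bases strictly separating two intervals, 0 when they overlap
*or abut* (adjacency is maximal proximity under a "same genomic region"
reading), and infinite across chromosomes.

### Stage parameters

| parameter            | default | units | meaning                                   |
|----------------------|--------:|-------|-------------------------------------------|
| `max_fdr`            | 0.05    | —     | peak FDR must be strictly below this      |
| `min_fold`           | 20      | ratio | fold-enrichment strictly above this       |
| `replication_window` | 10000   | bp    | gap for a peak to count as replicated     |
| `control_window`     | 10000   | bp    | gap to a pooled control peak to be flagged|
| `gene_max_dist`      | 2000    | bp    | peak-to-gene-body gap for assignment      |
| `de_alpha`           | 0.05    | —     | q-value cutoff for DE significance        |

The defaults are the published operating point of the analysis this
package reimplements. All inequalities are strict, following the source's
parenthetical "(<5%)", "(>20)" and "(q-value of <0.05)" wording; peaks
missing either quality statistic fail the filter (conservative).

### Replicate consensus

A replicate-A peak is *replicated* if any replicate-B peak lies within the
window. Consensus peaks are **anchored on replicate A**: one consensus
record per replicated A peak, carrying A's interval as the representative,
the ids of all matching B peaks, and the minimal partner gap. The source
study counts "peaks replicated between the two samples" without describing
a merge, so anchoring is the weakest-assumption reading; a `"union"`
representative (span of A with all partners) is available, and the anchor
asymmetry is tested. Window semantics are interval-gap by default; a
summit-to-summit mode exists because the original criterion could have
been either (the publication does not say).

Matching is done per chromosome with `GenomicRanges::findOverlaps(maxgap =
window)`; the tests verify exact agreement with a quadratic all-pairs
brute force over seeded random instances, so the interval-index path never
silently diverges from the definition.

### Control screening

Control peak sets are pooled; every consensus peak records its gap to the
nearest control peak (infinite when no control shares the chromosome) and
is flagged when the gap is at most the control window. The source reports
control proximity but never states that proximal peaks were removed; since
the downstream gene list is described as "RNA-specific", the pipeline
computes both and, by default, carries only the non-proximal subset into
gene assignment (`exclude_control_proximal = FALSE` switches this off).

### Gene association and TSS profile

"Closest gene within 2 kb" is measured from peak edge to gene-body edge,
so peaks inside genes get distance 0 — the reading consistent with the
observation that most peaks lie *within* genes. A midpoint-to-TSS mode is
provided for sensitivity analysis. Ties on the primary distance are broken
by the smaller |peak midpoint − TSS|, then lexicographic gene id, and the
tie is recorded. The TSS profile is a separate computation with **no
cutoff**: each peak's signed distance to the nearest TSS on its
chromosome, sign flipped for minus-strand genes so negative always means
upstream, binned into GREAT-style left-open/right-closed kb bins; a peak
exactly on a TSS (distance 0) falls in (−5,0] by the ≤ rule, which is
unit-tested as the fixed boundary convention.

### Overlap enrichment

The gene universe for the 2×2 table is the intersection of annotated genes
and DE-tested genes — the source never states its universe, so the choice
is explicit in the report (universe size, ChIRP genes inside/outside it)
rather than hidden. The Pearson statistic is computed as Σ(O−E)²/E and
cross-checked in tests against the margin form N(ad−bc)²/(row and column
products) to 1e−9; no continuity correction by default (the source names
only "the chi-squared test"), with a Yates flag available. p-values are
reported as computed, never floored at 2.2 × 10⁻¹⁶ — that printed value is
a software display floor, not a statistic.

## What the synthetic generator emulates

`synthetic_config()` describes a desk-scale world whose defaults mirror
the structure (not the scale) of the source experiment:

* 5 chromosomes × 10 Mb, 2000 genes of 2–20 kb placed uniformly with
  ≥ 1 kb spacing;
* 500 true binding sites; each yields a peak in each replicate
  independently with reproducibility r = 0.9, jittered ≤ 200 bp, width
  200–800 bp (the sonication fragment range), fold/FDR drawn from ranges
  strictly on the passing side of the filter;
* 500 noise peaks per replicate and 200 sub-threshold peaks per replicate
  (fold-fail, FDR-fail, or both, cycling) to exercise the filter;
* 3 control sets of 300 peaks; 12% of each set is planted within half the
  control window of a true site (≈ the source's 985-of-8300 proportion),
  the rest far from every site;
* a DE table over the annotation's genes with overall significance rate
  0.3, planted odds ratio 2.0 for ChIRP genes (back-of-envelope from the
  published 50%-of-2403 overlap against a ~32% genome-wide rate), and
  94.2% of significant genes up-regulated — the published fraction.

**Placement guarantee.** True sites and noise positions are drawn from a
lattice with spacing `noise_min_separation + 2·jitter` (default 25 kb +
4 kb), so *every* pair of planted positions — true–true, true–noise, and
noise–noise across replicates — is at least 25 kb apart, which exceeds
twice the replication window. Consequences: a noise peak can never find a
partner, and a true site is recovered iff both of its replicate peaks
exist. Recovery is therefore *exactly* Binomial(n_sites, r²), which is
what the planted-truth acceptance test asserts with an exact binomial 99%
interval aggregated over 100 seeds (a per-seed 99% check over 100 seeds
would be designed to fail about once). The generator warns when the
separation is set at or below 2× the window; truth labels stay exact
either way.

q-values are sampled uniformly inside (significant) or outside
(non-significant) the significance band: the pipeline consumes only the
threshold crossing, so distributional realism beyond the cutoff would add
nothing testable. What a green suite does **not** establish: realistic
peak-width/fold correlation, chromatin-driven clustering of binding
sites, correlated noise between replicates, or q-value calibration of a
real DE engine — none of which the downstream logic consumes.

Determinism: one master seed drives a named arithmetic substream per
generator operation (annotation, site placement, peak sampling, controls,
DE), so changing DE parameters cannot perturb peak placement; regenerated
datasets are byte-identical, which the suite checks at file level.

## Numerical and design choices

* Internal coordinates 0-based half-open everywhere; conversion happens
  only in `read_gtf()`/`write_gtf()`, and a round-trip test pins the
  identity.
* narrowPeak's −log10(q) column is linearized to `fdr = 10^(−q)` at read
  time so the 5% threshold compares on the printed scale; `−1` sentinels
  in columns 8–10 become `NA`, and `NA` fails the filter.
* The planted ChIRP gene set used for DE generation is "genes within
  `gene_max_dist` of a true site". The pipeline's recovered set differs
  slightly (it sees jittered, finite-width peaks at the ~r² recovered
  subset of sites); tests that compare planted versus realized enrichment
  use the planted set on both sides, so the difference is not a source of
  flakiness.
* `report.json` contains a config echo and package version but no
  timestamps: rerunning on identical inputs must produce byte-identical
  reports. Timestamped progress goes to stderr.
* Configuration files are JSON (not YAML): the declared dependency set
  guarantees `jsonlite` but no YAML parser, and the config is a flat
  paths-plus-thresholds block either way.
* Degenerate inputs: empty peak sets flow through every stage (empty
  consensus, empty gene set); a chi-squared margin of zero is an error
  naming the degenerate margin rather than a NaN; an empty peak set's row
  in the pairwise-overlap matrix is `NA` and flagged, never 0.

## Known limitations

* The consensus count is A-anchored; if the original 8105 was B-anchored
  or merged-region counted, absolute counts would differ (the source does
  not specify). Both the union mode and the documented asymmetry exist so
  the choice is visible, not buried.
* The published genomic headline counts (8105, 2403, 985, 6467/3140)
  derive from unreleased sequencing intermediates and cannot be
  regenerated at desk scale; the acceptance machinery therefore checks
  the one reproducible printed quantity (the 50% overlap arithmetic) plus
  structural properties with planted truth.
* GO enrichment, IDR-style reproducibility modeling, motif discovery and
  the GREAT regulatory-domain model are out of scope by design.
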