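# chirpflow

Downstream analysis of **ChIRP-seq** (chromatin isolation by RNA
purification sequencing) peak sets in R. ChIRP-seq maps the genomic loci
contacted by a target RNA — for example a nuclear long non-coding RNA such
as a snoRNA host-gene transcript — by pulling the RNA down with antisense
oligos and sequencing the recovered DNA. After read alignment and peak
calling (MACS), the analytical questions are downstream of the peak caller,
and that is the part `chirpflow` implements as a reusable, tested pipeline:

1. **Quality filtering** — keep peaks with FDR < 5% and fold-enrichment
   over input > 20 (both strict).
2. **Replicate consensus** — a peak is *replicated* when a peak of the
   second biological replicate lies within a 10 kb window of it (gap
   distance between intervals; summit-to-summit mode available).
3. **Control specificity** — consensus peaks within 10 kb of any pooled
   negative-control peak (non-specific oligos, deletion tissue) are
   flagged; the complement is the RNA-specific peak set.
4. **Gene association** — each specific peak is assigned to its closest
   gene within 2 kb (distance 0 for peaks inside gene bodies), and peak
   positions are profiled as signed distances to the nearest TSS in
   GREAT-style kb bins: (−∞,−500], (−500,−50], (−50,−5], (−5,0], (0,5],
   (5,50], (50,500], (500,∞).
5. **Expression overlap** — a differential-expression table (gene id,
   log2 fold change, q-value) is summarized at q < 0.05, and the overlap
   between ChIRP-associated genes *A* and significantly changed genes *B*
   over the gene universe *U* is tested with Pearson's chi-squared on the
   2×2 table

   |            | in *B* | not in *B* |
   |------------|--------|------------|
   | in *A*     | a      | b          |
   | not in *A* | c      | d          |

   with X² = N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d)), df = 1, odds ratio
   ad/bc, no continuity correction by default.

Because the sequencing intermediates behind published ChIRP analyses are
rarely deposited, `chirpflow` ships a **synthetic-data generator with
planted ground truth** (true binding sites with tunable reproducibility
*r*, non-replicating noise peaks, sub-threshold peaks straddling the
filter, control sets with a tunable fraction planted near true sites, and
a DE table with a planted odds ratio and up-regulated fraction), so every
stage is testable end-to-end: consensus sensitivity is exactly
Binomial(*r*²) by construction, and noise must never replicate.

## Worked example

Simulate a dataset (5 × 10 Mb chromosomes, 2000 genes, 500 true sites,
r = 0.9, 500 noise + 200 sub-threshold peaks per replicate, 3 × 300
control peaks) and run the pipeline:

```sh
Rscript -e 'chirpflow::chirp_cli(commandArgs(TRUE))' \
    simulate --seed 7 --outdir demo
Rscript -e 'chirpflow::chirp_cli(commandArgs(TRUE))' \
    run --config demo/pipeline_config.json
Rscript -e 'chirpflow::chirp_cli(commandArgs(TRUE))' \
    report --json demo/results/report.json
```

prints (actual output):

```
filter_peaks[repA]: 1147 -> 947 peaks
filter_peaks[repB]: 1158 -> 958 peaks
...
replicate_consensus: 409 replicated peaks
flag_control_proximity: 84 control-proximal, 325 specific
assign_closest_gene: 194/325 peaks assigned, 194 genes
de_summary: 587/2000 significant (96.1% up)
enrichment: a=83 chi2=18.7 p=1.53e-05; overlap 42.8% of ChIRP genes
```

Reading it: of 500 planted sites, 409 replicated — matching the expected
r² = 0.81 recovery; the 200 injected sub-threshold peaks per replicate
were removed by the filter (947 = 1147 − 200); 84 consensus peaks sat
within 10 kb of a control peak, leaving 325 RNA-specific peaks, 194 of
which lie within 2 kb of a gene; and those genes are over-represented
among significantly changed genes (odds ratio 1.93, p ≈ 1.5 × 10⁻⁵ —
the generator planted an odds ratio of 2).

The same analysis is available programmatically:

```r
library(chirpflow)
cfg  <- read_pipeline_config("demo/pipeline_config.json")
rep  <- run_pipeline(cfg)            # writes BED/TSV/JSON into demo/results
rep$n_replicated                     # 409
rep$enrichment$odds_ratio            # 1.93
```

and stage by stage via `read_narrowpeak()`, `filter_peaks()`,
`replicate_consensus()`, `flag_control_proximity()`,
`assign_closest_gene()`, `tss_distance_profile()`, `de_summary()`,
`overlap_counts()`, `chi_squared_2x2()`.

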