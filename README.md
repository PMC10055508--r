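# spcenrich

Tissue-enriched protein discovery from label-free spectral counts by
**in silico reference subtraction**.

## The problem

Shotgun MS/MS profiling of a tissue identifies thousands of proteins, and
ranking them by absolute abundance surfaces mostly housekeeping and
structural proteins (actins, tubulins, Gapdh, ...).  The candidates that
matter for a tissue's development and disease are often modestly
expressed but *tissue-restricted*.  `spcenrich` prioritizes them by
comparing the tissue's spectral-count profile against a whole-body
reference proteome and calling proteins **enriched** rather than merely
abundant.

The package implements the full pipeline from search-engine PSM output
to enrichment calls, for a two-group replicated design (tissue vs
reference):

* **PSM error control** — target/decoy FDR filtering of
  peptide-spectrum matches with conditional (charge x modification x
  delta-mass) score histograms, per-subclass thresholds for an
  experiment-wide FDR (default 1%), and a minimum peptide length of 7.
* **Protein inference** — parsimony grouping (indistinguishable
  proteins merged, minimal explanatory set selected, shared peptides
  razor-assigned), extended grouping of homologs with insufficient
  distinguishing evidence, the two-distinct-peptide rule, and
  decoy-based protein FDR.
* **Quantification** — spectral-count (SpC) tallies per protein group,
  scaling of every sample to the average total SpC, and the > 2.5
  mean-SpC abundance filter.
* **Enrichment statistics** — TMM normalization; negative-binomial
  model SpC<sub>gs</sub> ~ NB(mu<sub>g</sub>, phi) with qCML common
  dispersion; the conditional exact test of group sums given their
  total; Benjamini–Hochberg adjustment; and the call
  *enriched* = (FDR < 0.01) AND (fold change >= 2 toward the tissue),
  with medium/low confidence bands at FDR < 0.05 / < 0.1 for MA-plot
  classification.
* **Reporting** — QC (boxplot stats, pairwise correlations,
  leading-log-fold-change MDS), expression- vs enrichment-ranked
  candidate tables, MA-plot data, and UCSC custom heat-map tracks
  (BED9 + itemRgb).

A seeded synthetic-data module (reversed-decoy databases, PSM score
mixtures, NB count matrices with planted enrichment) makes every stage
testable end to end with known ground truth.

## Worked example

Simulate the emulated study design — 2,675 quantifiable proteins, 5 vs 5
replicates, 90 proteins planted at a true log2 fold change of 1.5 — and
run the subtraction pipeline with the published thresholds:

```r
library(spcenrich)

sim <- simulate_counts(n_proteins = 2675, n_per_group = 5, n_enriched = 90,
                       log2fc = 1.5, dispersion = 0.05, seed = 42)
res <- run_wb_subtraction(sim$counts, min_avg = 2.5)
rec <- res$records

nrow(rec)                      # 2615 proteins pass the >2.5 mean-SpC filter
attr(rec, "dispersion")        # 0.0488 -- qCML estimate of the true 0.05
sum(rec$enriched)              # 74 proteins called enriched

rank_table(rec, mode = "enriched", top_n = 5)[,
  c("rank", "group_id", "avg_spc", "log2fc", "fdr")]
#>   rank group_id avg_spc log2fc      fdr
#> 1    1   P00293    6.38   3.13 1.75e-07
#> 2    2   P02209   24.30   2.69 3.92e-14
#> 3    3   P01766    7.27   2.56 2.10e-06
#> 4    4   P00642    8.19   2.34 4.23e-06
#> 5    5   P02065    5.48   2.26 2.92e-04
```

Of the 74 calls, 73 are planted proteins (recovering 73/90 = 81% of the
planted set with a single false call) — the enriched list is dominated
by genuinely tissue-elevated proteins, not by the most abundant ones:
note the top candidates average only 5–25 SpC.  The same `rec` table
feeds `ma_data()` (MA plot with high/medium/low/none bands),
`qc_summary()` and `export_tracks()`, and the PSM-level front end is
available via `make_database()`, `simulate_psms()`, `filter_psms_fdr()`,
`parsimony_infer()` and `tally_spc()`.

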