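---
title: "Methods: spectral-count enrichment by in silico reference subtraction"
author: "spcenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count enrichment by in silico reference subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcenrich)
```

## The problem and the approach

Shotgun proteomics of a tissue yields thousands of identified proteins, and
ranking them by absolute abundance surfaces mostly housekeeping and
structural proteins.  `spcenrich` implements the alternative prioritization
this package is built around: compare the tissue's spectral-count profile
against a whole-body reference proteome and rank proteins by *enrichment*
over that reference ("in silico subtraction").  Regulatory proteins that
are modestly expressed but tissue-restricted rise to the top; ubiquitous
high-abundance proteins drop out.

The pipeline covers five stages, each usable on its own:

1. **PSM error control** (`filter_psms_fdr`): target/decoy filtering of
   peptide-spectrum matches to an experiment-wide FDR using conditional
   score histograms.
2. **Protein inference** (`parsimony_infer`, `extended_group`,
   `two_peptide_filter`): parsimony grouping with decoy-based
   protein-level FDR (`protein_fdr_percent`).
3. **Quantification** (`tally_spc`, `scale_to_average_total`,
   `abundance_filter`): spectral-count tallies under a razor policy,
   scaling, and the mean-abundance filter.
4. **Enrichment statistics** (`wb_enrich`): TMM normalization, qCML
   common dispersion, the conditional negative-binomial exact test,
   Benjamini-Hochberg adjustment, and the banded enrichment call.
5. **Reporting** (`qc_summary`, `rank_table`, `ma_data`,
   `export_tracks`): QC, ranked candidate tables, MA-plot data, and
   UCSC custom heat-map tracks.

A seeded synthetic-data module (`make_database`, `simulate_psms`,
`simulate_counts`) generates inputs with known ground truth so every stage
is testable without raw mass-spectrometry data.

## PSM error control

Each spectrum's best match carries a discriminant score; by default the
synthetic tables supply it directly (`disc`), and for Comet-style raw
scores the conventional combination `ln(xcorr) + 4 deltaCn` is available
through `discriminant_score(weights, log_transform)`.  The correctness of
downstream error control never depends on the particular combination: the
target/decoy estimator only uses score *ranks* within subclasses.

PSMs are partitioned into (charge 2-4) x (unmodified/oxidized) x
(delta-mass window) subclasses and binned (default bin width 0.1
discriminant units).  For the accepted set at threshold $t$ the FDR is
estimated as $\widehat{\mathrm{FDR}}(t) = D(t)/T(t)$, the decoy/target
ratio above $t$, capped at 1.  Raw curves are monotonized q-value style
(the value at $t$ is the smallest estimate at any threshold at or below
$t$), so estimated FDR is non-increasing in the threshold.

Per-subclass thresholds start at the most permissive value whose
conditional FDR meets the experiment-wide target (default 1%); since
every subclass then satisfies the bound, so does the pooled set.  A
greedy relaxation then lowers thresholds one bin at a time wherever that
adds accepted targets without pushing the pooled estimate over the
target.  Two numerical choices matter here:

* **Ties** between thresholds that accept the same number of targets are
  resolved toward the *higher* threshold, so no decoys are admitted
  gratuitously (an all-decoys-below-all-targets configuration yields an
  estimated FDR of exactly 0).
* **Sparse subclasses** (fewer than 50 decoys by default) take their
  threshold from the pooled histogram; their conditional estimates are
  too unstable to stand alone.

Peptides shorter than 7 residues are removed regardless of score.  The
estimator is the plain decoy/target ratio rather than the
$(2D)/(T+D)$ variant; the same convention is used at the protein level,
where 37 decoy groups among 3,963 detected give 0.9% to one decimal.

## Protein inference

A distinct peptide is a (sequence, modification-state) pair.  Inference
proceeds in three steps:

1. Accessions with identical accepted-peptide sets merge into one group
   of indistinguishable proteins.
2. A minimal set of groups explaining every peptide is selected.  The
   incidence graph is split into connected components; components with at
   most 20 candidate groups are solved *exactly* for the minimum cover by
   size-ordered enumeration bounded by the greedy solution, and larger
   components fall back to deterministic greedy selection (descending
   peptide count, ties by accession).  Pure greedy cover can exceed the
   optimum even on small inputs, which would silently inflate protein
   counts; exact-within-components removes that failure mode wherever
   enumeration is affordable, and real peptide-protein graphs decompose
   into small components, so the greedy fallback is rarely exercised.
3. Peptides still shared between surviving groups are razor-assigned to
   the group with more unique distinct peptides, ties broken
   lexicographically by first accession -- deterministic and simple.

The extended grouping step merges homolog pairs whose evidence cannot
distinguish them: each group must share at least `share_min` (default
0.9) of *its own* peptide set with the other and hold at most
`unique_max` (default 1) peptides the other lacks, applied transitively.
The share is computed per group rather than against the union: two
10-peptide homologs sharing 9 peptides each carry a 9/10 = 0.9 share and
merge at the default, which is the configuration the rule is meant to
catch (on the union scale the same pair would score 9/11 and never
merge at 0.9).  Both parameters are exposed because the merge criterion
used by any particular lab pipeline is a matter of configuration, not of
principle.

Groups lacking two distinct peptides in every sample are removed.  A
group is a decoy group only if *all* members are decoys (mixed groups
count as target -- conservative for FDR), and a contaminant group if it
contains a contaminant and no target.

## Quantification

Spectral counts are tallied per group per sample under the razor policy;
decoy and contaminant groups are excluded from the quantitative matrix
before scaling.  Each sample is scaled to the *average total spectral
count per sample* -- every column is multiplied by (grand mean of column
totals)/(its own total) -- computed over all samples of both groups
pooled.  A per-tissue variant of the question (scale within each group
separately) is not implemented as a default because the pooled form is
the one the downstream matrix invariant (all column totals equal) relies
on; scaled values are kept as reals.  Rows whose pooled mean is
*strictly* greater than 2.5 scaled counts enter the differential
analysis.

## Enrichment statistics

**TMM.**  Normalization factors are the classical doubly trimmed,
precision-weighted means of library-size-adjusted log2 ratios against a
reference sample (trim 30% of M values and 5% of A values from each
tail, inverse delta-method variances as weights, rows positive in both
samples only), renormalized to geometric mean 1.  The automatic
reference is the sample whose upper-quartile-normalized value is closest
to the mean.  The implementation is written here and cross-checked in
the test suite against edgeR's `calcNormFactors` to 1e-8.

**Pseudo-counts.**  The conditional test assumes equal library sizes, so
counts are first rescaled linearly, column by column, to the geometric
mean of the effective library sizes (library size x TMM factor).  This
mean-preserving rescaling keeps within-column structure intact;
group sums are rounded to integers only where the conditional law needs
integer support.

**Common dispersion.**  The NB dispersion $\varphi$
(var $= \mu + \varphi\mu^2$) is estimated by maximizing the conditional
log-likelihood given per-group totals (qCML) on the pseudo-counts, by
bounded one-dimensional search over $\log\varphi \in [\log 10^{-8},
\log 5]$; when the boundary value is no worse than the interior optimum
the estimate is 0 (Poisson).  Tagwise shrinkage is deliberately not the
default: a study of this design (5 vs 5, a single tissue contrast)
states its defaults without printing per-protein dispersions, and the
common-dispersion exact test is the canonical matching workflow.

**Exact test.**  For each protein the two group sums $(a, b)$ of rounded
pseudo-counts are compared conditionally on their total: under the null
the group-A sum given $a+b=N$ follows the NB-convolution law with sizes
$n_A/\varphi$ and $n_B/\varphi$ (binomial when $\varphi = 0$).  The
two-sided p-value sums the probabilities of all outcomes no more
probable than the observed one ("small-p"); tail doubling is available
via `rejection = "doubletail"`.  Ties in outcome probability are
resolved with a relative tolerance of 1e-10.  The implementation is
verified against exhaustive enumeration of the joint law for all totals
up to 30 at $\varphi \in \{0, 0.1, 0.5\}$ and against edgeR's
`exactTestBySmallP` on matrices.

**Calibration note.**  An exact test on discrete counts is conservative:
at the count scale of this design (a dozen spectral counts per protein
per sample), the achieved $P(p \le 0.05)$ under the null sits near
0.04 rather than 0.05, for this implementation and for edgeR alike --
the achievable p-values are spaced too coarsely to exhaust the nominal
level.  The test suite therefore estimates the null rejection rate by
pooling several simulations and judges it against the binomial 99%
interval around 0.05 at the single-simulation size; mild conservatism is
the expected and accepted behavior of the method, whereas type-I
*inflation* would be a defect.

**Fold change and call.**  M and A coordinates come from
prior-augmented (default prior 0.125 counts) group means of the
pseudo-counts, so zero rows stay finite.  BH adjustment is the standard
step-up rule.  Bands follow the MA classification: high (FDR < 0.01),
medium (< 0.05), low (< 0.1), none; the *enriched* call requires the
high band plus at least 2-fold change toward the tissue group
(log2fc >= 1).

## What the generator emulates -- and what it does not

`simulate_counts` draws per-protein baseline means from a lognormal
(meanlog `log(8)`, sdlog 1), left-truncated at 2.5: the simulated rows
stand for the proteins that enter the differential analysis, all of
which passed the abundance filter, and the scale reproduces roughly 35K
total counts per sample across ~2,700 quantifiable proteins.  Planted
proteins keep their baseline mean in the reference group and are
elevated 2^log2fc-fold in the tissue group -- the structure the
subtraction is meant to recover.  Counts are NB with a single shared
dispersion.

`simulate_psms` draws discriminants from a two-Gaussian mixture (null:
mean 0, sd 1; correct: mean 3, configurable), with per-charge shifts so
conditional histograms genuinely differ, 0/1-Da delta-mass windows, and
planted shared-peptide families (identical pairs, strict subsets,
homologs sharing a configurable fraction).  Decoy databases are
whole-sequence reversals, making decoy generation a testable involution.

Real data differ in ways the generator does not model: per-protein
dispersion heterogeneity, correlated peptides within a protein,
intensity- and retention-time structure, fragment spectra, and score
distributions that are only approximately Gaussian.  Passing tests
demonstrate that the *algorithms* behave according to their contracts
under a controlled NB/Gaussian world -- they do not certify biological
conclusions on any particular real dataset.

## Problem sizes and determinism

Every stochastic routine takes a `seed` and is fully reproducible from
it.  The validation suite exercises the dataset-scale identities exactly
as printed (a 44,932-entry database; 37/3,963 protein FDR), the
exact-test oracle on all totals up to 30, null calibration on five
2,000-protein simulations, dispersion recovery on 2,000 rows, parsimony
against exhaustive set-cover search on 200 random instances up to 10
proteins x 15 peptides, PSM calibration on 20,000 spectra, and
end-to-end recovery on twenty replicates of the emulated design (2,675
proteins, 90 planted at log2fc 1.5, 5 vs 5, dispersion 0.05) -- sizes
chosen so the whole suite completes in about a minute while keeping
Monte-Carlo error well inside the asserted bounds.

## Known limitations

* Exactly two groups; no GLM or multi-factor designs.
* Spectral counting only -- no NSAF/emPAI or intensity quantification.
* The razor policy and extended-grouping criterion are one defensible
  convention each, exposed as configuration rather than claimed as the
  only correct choice.
* Protein-level FDR uses the non-decoy group count as denominator;
  at realistic decoy rates the alternative reading (decoys included in
  the denominator) differs by far less than the estimate's own noise.
* The exact test's conservatism at low counts (see above) means the
  nominal FDR bound is honored but not tight.
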