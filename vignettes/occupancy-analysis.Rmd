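---
title: "Tiling-array occupancy analysis: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiling-array occupancy analysis: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilingchip)
```

## The analysis problem

ChIP-chip experiments on high-density tiling microarrays produce, per
probe, a pair of intensities: immunoprecipitate (IP) and supernatant
(SUP). The log2 IP/SUP ratio along the chromosome is a noisy readout of
protein occupancy. `tilingchip` implements the full analysis chain for
such data in compact genomes: per-probe signal and significance
estimation, detection of *binding clusters* (contiguous occupied
ranges), mapping of clusters onto annotated features, strand-aware
metagene profiles, gene ranking by windowed signal, and integration with
gene-level expression data (differential-expression calling, gene-set
overlap and structural statistics).

Two biological signal architectures motivate the design and are planted
by the bundled simulator:

* an mRNA-export-factor-like protein ("TREX2-like" in the generator)
  whose ORF occupancy rises from the 5' to the 3' end, with amplitude
  increasing with the gene's expression level; and
* a replicative-helicase-like protein ("Rrm3-like") that accumulates in
  discrete blocks around ORF 3' ends, marking replication-obstacle
  sites; in a mutant condition the blocks are more numerous, longer and
  more biased toward highly expressed genes.

## Per-probe signal estimation

At each probe position, all replicate log2 ratios from probes within a
half-bandwidth `bandwidth_bp` (default 150 bp, i.e. a ~300 bp window —
the working resolution of the tiling design) are pooled. The estimated
signal is the Hodges–Lehmann pseudo-median of the pooled values (the
median of all pairwise Walsh averages \((x_i + x_j)/2,\ i \le j\)), and
the change P-value is a one-sided Wilcoxon signed-rank test of
"pseudo-median > 0". The pair is the classical robust location
estimate / test duo: the pseudo-median is the Wilcoxon test's associated
estimator, resistant to the heavy-tailed outliers common on arrays.

Numerical conventions, all deliberate and tested:

* **Zeros** are dropped before ranking and **ties** of absolute values
  receive midranks, the standard Wilcoxon conventions.
* For windows of up to 25 values the P-value is **exact**. Tie-free
  samples use the closed-form signed-rank distribution; tied samples use
  a convolution over the doubled midranks, which is arithmetically
  identical to enumerating all \(2^n\) sign assignments (the test suite
  verifies this against literal enumeration up to \(n = 12\)). Beyond 25
  values the normal approximation with tie correction and a 0.5
  continuity correction is used; at \(n = 20\text{–}25\) it agrees with
  the exact tail to within 0.01.
* A window holding a single value is reported as `p_value = 1` with a
  warning: one observation carries no sign-rank evidence.
* One-sidedness is a choice: occupancy enrichment is directional
  (IP over SUP), and cluster calling only consumes evidence for positive
  signal.

Smoothing is translation-equivariant and shift-covariant (shifting all
positions, or adding a constant to all ratios, shifts the output
identically); both properties are tested.

## Quantile normalization of replicates

Replicate tracks on a common probe grid are normalized by the quantile
method: the value of rank *r* in every replicate is replaced by the mean
of the rank-*r* values across replicates. Ties are broken by probe
order, which makes every output column carry exactly the same sorted
multiset and makes the transform idempotent — both properties are part
of the acceptance suite. On tie-free data the result matches
`limma::normalizeQuantiles` to machine precision (cross-checked in the
tests).

## Binding clusters

A probe *qualifies* when its estimated signal is positive and its change
P-value is below `p_threshold` (default 0.01). Qualifying probes are
chained while the genomic gap between consecutive qualifying probes is
at most `max_gap_bp` (default 250) **and** no intervening probe has
signal ≤ 0, so the estimated signal is positive over the whole range.
Chains whose genomic span is below `min_run_bp` (default 100) are
discarded.

Design decisions, each exposed or flagged:

* The cluster span is `[first qualifying probe, last qualifying probe + 1)`
  — no padding by half the probe spacing; unambiguous and conservative.
* "Minimum run" is a genomic span in bp, not a probe count, because bp
  is the natural unit of the rule.
* The positivity requirement applies to **all** probes inside the span,
  including non-significant ones; this literal reading prevents chains
  from bridging across negative dips. `require_positive_gap = FALSE`
  switches to the laxer gap-only rule for comparison.
* The peak is the leftmost probe of maximal signal — a deterministic
  tie-break.
* No multiple-testing correction is applied across probes: the cluster
  definition is a raw per-probe P < 0.01 rule by design, and the run/gap
  constraints are what control spurious calls.

`call_clusters()` is verified against an independently coded
sequential-scan enumeration of maximal qualifying chains on hundreds of
random tracks.

## Metagene profiles

Each ORF is cut into 10 genomic segments of equal length independently
of ORF size; remainder base pairs are assigned one each to the 3'-most
segments (a deterministic choice biased by less than one probe spacing).
Flanking segments of the same unit length (`floor(length/10)`) are added
upstream and downstream, clipped at chromosome edges. Bins are ordered by
transcription, so for minus-strand genes they run right-to-left
genomically; mirroring the genome end-for-end leaves profiles exactly
unchanged (tested).

Two profile modes:

* **cluster_percent** — every (cluster, gene-bin) pair sharing ≥ 1 bp
  counts one incidence; a cluster spanning *k* bins contributes *k*
  incidences. Percentages are over incidences, which is the simplest
  reading that makes the 12 bins sum to exactly 100 while clusters can
  span bins.
* **signal_mean** — the mean smoothed signal of the probes in each bin,
  pooled over genes; probe-free bins are reported `NA` with a message.

`stratify_by_length()` cuts genes into equal-count length strata (ties
broken by id) so the gradient claim can be checked within each stratum.

## Expression analysis

Expression values are gene-level, linear-scale arbitrary units. Before
any comparison, genes below an expression floor (default 600 A.U.) in at
least half of **all** samples are removed. A gene is called up- (down-)
regulated when three conditions hold simultaneously: linear fold-change
of replicate means ≥ 1.5 (≤ 1/1.5), absolute difference of means
> 100 A.U., and P < 0.05 from a two-sided Welch t-test on log2 replicate
values. The Welch test is this package's explicit stand-in for a
"difference P-value": it is robust, standard for triplicate arrays, and
applied to log2 values where array noise is closest to Gaussian.
Fold-changes are computed from replicate means (not model-based
confidence bounds) and thresholds are symmetric in direction. No
multiple-testing correction is applied: the three-way filter is the
decision rule itself.

Profile clustering for heatmaps keeps the half of genes with the largest
maximum |log2 fold-change| across profiles and agglomerates profiles by
complete linkage on the `1 - Pearson r` distance. Gene-set overlaps are
tested with the upper-tail hypergeometric distribution, and qPCR-style
relative quantitation divides target by normalizer per sample, scales to
the reference-condition mean and reports mean ± SEM.

## Structural statistics and ranking

Gene sets are compared to the genome by a two-sided Mann–Whitney U test
on ORF length, G+C fraction or expression level — set versus all
retained genes, the test named in the figure legends this style of
analysis comes from, rather than a one-sample test against the median
value. The exact distribution is used when the smaller group has at most
8 tie-free observations; otherwise the normal approximation with tie and
continuity corrections.

Top-N ranking scores each gene by the maximum mean smoothed signal over
windows of `window_bp` (default 200) fully inside the ORF. Windows are
anchored at probe positions: on piecewise-constant probe data this finds
the identical extrema as per-bp anchoring at a fraction of the cost.
ORFs shorter than the window are scored over their whole span; ties are
broken by gene id.

## What the simulator emulates — and what it does not

The generator is the package's validation substrate: every downstream
claim is tested as recovery of a structure the generator planted.
Defaults describe a compact yeast-like genome:

| parameter | default | rationale |
|---|---|---|
| `probe_spacing_bp` | 50 | with the 150 bp bandwidth this reproduces a ~300 bp effective resolution |
| `n_chroms` × `chrom_length_bp` | 4 × 250 kb | ~1 Mb toy genome; ~63% genic like a dense microbial genome |
| `orf_length` | log-normal, median 1.2 kb, range 0.3–8 kb | yeast-like ORF lengths |
| `expr` | log-normal, median 1000 A.U., sdlog 1 | wide dynamic range; ~30% of genes fall below the 600 A.U. floor |
| `gc_fraction` | Beta(38, 62) | mean 0.38, yeast-like |
| `noise_sd` | 0.25 | per-replicate log2 ratio noise typical of two-channel arrays |
| `gradient_strength` | 1 | pure 5'→3' ramp; 0 gives a flat profile |
| `amplitude_scale` | 0.6 | occupancy amplitude `0.6·log2(1 + e/1000)`, a monotone expression link |
| `signal_taper_bp` | 200 | planted signal decays linearly past the 3' end, emulating ChIP fragment-size spread beyond feature boundaries |
| `rrm3_block_width_bp` | 500 (log-normal) | discrete obstacle blocks at ORF 3' ends |
| `mutant_cluster_elongation` | 1.6 | mutant blocks are longer, at more genes, with stronger expression bias |
| `expr_noise_sdlog` | 0.15 | tight replicate noise of model-based array summaries |
| `de_fraction_up/down`, `de_fold_range` | 0.05/0.10, 2–4× | planted de-regulation with structural bias `de_bias` on (length, G+C, expression) z-scores |

Two modelling choices deserve emphasis. First, planted ratios are
globally mean-centred before noise: array normalization forces the
genome-wide average log2 ratio to zero, so when part of the genome is
occupied the unbound remainder sits slightly below zero. Without this,
unbound baseline would be exactly zero and the one-sided P < 0.01 rule
would generate a steady trickle of minimum-length chance clusters — a
property of an idealized zero baseline, not of normalized array data.
Second, the 3' taper: truncating the planted gradient exactly at the
stop codon would create an artificial 3'-edge attenuation in smoothed
signal (half of each boundary window would be empty), depressing the
final metagene bin; real ChIP signal spreads past boundaries by the
chromatin fragment size.

The generator does **not** model probe-level cross-hybridization, array
spatial artifacts, probe-sequence (G+C) response, copy-number structure,
or the probe-level summarization that produces model-based expression
values — expression enters at the gene level. Passing the recovery
suite therefore demonstrates that the statistics and rules are
implemented correctly and recover the planted architectures under
realistic noise; it does not certify performance on raw array data with
those additional artifact layers.

## Validation problem sizes and seeds

The acceptance suite (and `scripts/acceptance.R`) uses simulations of
500–2 000 genes on 1–4 Mb toy genomes: large enough that stratified
trend tests and median comparisons are well-powered, small enough to run
in seconds. Cluster-caller equivalence is checked on ≥ 500 random tracks
of up to 200 probes against a brute-force chain enumeration; all exact
statistics are checked against literal enumeration at small *n*. All
randomness flows through explicit seeds; every simulation output is a
pure function of its configuration.

## Known limitations

* The smoothing estimator is the Hodges–Lehmann/Wilcoxon pair in a fixed
  bandwidth; it is the documented equivalent of the classical
  tiling-array suite approach, but other monotone-equivalent estimators
  would shift cluster boundaries slightly.
* Enrichment of a gene requires ≥ 1 bp of cluster–ORF overlap, with no
  minimum-fraction rule and no flank allowance; both are deliberate,
  simple readings and can be tightened by filtering the cluster table
  before the call.
* The expression floor counts all samples pooled across strains; with
  strongly down-regulated genes near the floor this removes true
  positives (the recovery metrics are therefore computed over
  floor-surviving genes).
* `compare_to_genome()` tests set-vs-genome with the set included in the
  genome sample; for small genomes this is slightly conservative.
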