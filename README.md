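# tilingchip

Analysis of two-channel tiling-microarray ChIP (ChIP-chip) data in
compact genomes, for researchers studying where chromatin-bound proteins
sit along genes and how that occupancy relates to transcription.
The package covers the whole chain from replicate probe tracks to
gene-level biology: per-probe occupancy estimation, binding-cluster
detection, cluster-to-feature mapping, strand-aware metagene profiles,
sliding-window gene ranking, and differential-expression analysis with
gene-set overlap and structural statistics — plus a seeded synthetic-data
generator that plants all of these signal structures so every stage is
validated end-to-end without any external download.

## The statistics at the core

**Per-probe signal.** For probe position $p$, all replicate log2 IP/SUP
ratios at probes within a bandwidth $h$ (default 150 bp) are pooled into
a window sample $x_1,\dots,x_n$. The estimated signal is the
Hodges–Lehmann pseudo-median

$$\hat\theta(p) = \mathrm{median}\left\{\tfrac{x_i + x_j}{2} : i \le j\right\},$$

and the change P-value is the one-sided Wilcoxon signed-rank test of
$\theta > 0$ (zeros dropped, midranks for ties; exact for $n \le 25$,
normal approximation with tie and continuity corrections beyond).
Replicates are first quantile-normalized (rank-wise across-replicate
means).

**Binding clusters.** A probe qualifies when $\hat\theta > 0$ and
$P < 0.01$; qualifying probes are chained while consecutive gaps are
≤ 250 bp and the estimated signal stays positive over the whole range,
and chains spanning < 100 bp are discarded.

**Metagene profiles.** Each ORF is split into 10 equal segments plus
upstream/downstream flanks of the same unit length, ordered 5'→3' by
transcription; profiles report either the percentage of cluster
incidences per segment (summing to 100) or the mean smoothed signal per
segment.

**Expression.** Genes below 600 A.U. in ≥ 50% of samples are floored
out; a gene is de-regulated when fold-change ≥ 1.5 (either direction),
|difference| > 100 A.U. and Welch-t $P < 0.05$ on log2 replicate values.
Gene sets are compared structurally (length, G+C, expression) to the
genome by Mann–Whitney U, and set overlaps by the hypergeometric
upper tail.

## Worked example

Simulate a small two-chromosome genome, run the full pipeline, and look
at the results:

```r
library(tilingchip)
cfg <- pipeline_config(seed = 1,
                       sim = sim_config(seed = 1, n_chroms = 2,
                                        chrom_length_bp = 150000,
                                        n_orfs = 120),
                       top_n = 20)
res <- run_pipeline(cfg)
res
#> pipeline_result (seed 1)
#>   TREX2-like: 43 clusters (mean 987 bp, 14.1% coverage), 47 enriched genes
#>   Rrm3-like: mean cluster 451 bp (wt) vs 724 bp (mutant), MW P = 1.8e-06
#>   DE: 2 up, 7 down, 33 floor-filtered; sensitivity 1.00, FPR 0.000
```

The export-factor-like track yields 43 binding clusters covering 14.1%
of the toy genome, all peaking inside ORFs, which call 47 of 120 genes
enriched. The helicase-like clusters are markedly longer in the mutant
condition (724 vs 451 bp; Mann–Whitney P = 1.8e-06), the planted
analogue of replication-obstacle spreading. The DE stage recovers every
planted ≥2-fold change that survives the expression floor, with no false
positives.

The planted 3' occupancy gradient shows up directly in the metagene
profile — segment means rise monotonically from the 5' to the 3' end:

```r
res$trex2$profile_signal_mean
#> metagene_profile (signal_mean, 120 genes):
#>   upstream         s1         s2         s3         s4         s5         s6
#>     -0.045     -0.087     -0.062     -0.014      0.011      0.049      0.100
#>         s7         s8         s9        s10 downstream
#>      0.144      0.175      0.220      0.229      0.153
```

(Unbound regions sit slightly below zero because array normalization
centres the genome-wide mean ratio at zero.) Per-stage tables are in the
result bundle — e.g. `res$trex2$feature_table` counts features of each
annotation class overlapped by clusters:

```r
res$trex2$feature_table
#>   feature_class n_mapped n_total
#> 1           ORF       47     120
#> 2    centromere        0       2
#> 3      telomere        0       4
#> 4           ARS        0       4
#> 5        intron        2      12
#> 6  snRNA_snoRNA        0       4
#> 7       RNAPIII        0       4
```

Setting `out_dir` in `pipeline_config()` additionally writes BED,
bedGraph and TSV files for every stage plus a YAML summary, all byte
reproducible from (configuration, seed).

## Package layout

* `R/annotation.R`, `R/io.R` — typed genome annotation, interval
  arithmetic, GFF3/BED/bedGraph/TSV readers and writers (internal
  coordinates are 0-based half-open everywhere).
* `R/tiling_signal.R` — probe tracks, quantile normalization,
  Hodges–Lehmann/Wilcoxon smoothing.
* `R/clusters.R`, `R/feature_mapping.R` — cluster calling, cluster-set
  statistics, feature mapping, enriched genes, overlap tests.
* `R/metagene.R` — gene segmentation, profiles, length stratification.
* `R/expression.R`, `R/gene_stats.R` — DE calling, profile clustering,
  relative quantitation, structural comparisons, sliding-window ranking.
* `R/simulate.R`, `R/recovery.R` — the synthetic-data generator and
  recovery metrics against its planted ground truth.
* `R/pipeline.R` — configuration and end-to-end orchestration.
* `vignettes/occupancy-analysis.Rmd` — models, conventions, generator
  design and validation rationale.
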