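## Binding-cluster detection by run/gap rules and cluster-level statistics.

#' Call binding clusters from a smoothed track
#'
#' A probe qualifies when its estimated signal is positive and its change
#' P-value is below `p_threshold`. Qualifying probes are chained along the
#' chromosome while (i) the genomic gap between consecutive qualifying
#' probes does not exceed `max_gap_bp` and (ii) no intervening probe has
#' signal <= 0, so the estimated signal is positive over the whole range
#' (relax (ii) with `require_positive_gap = FALSE`). Chains whose genomic
#' span is shorter than `min_run_bp` are discarded. Defaults mirror the
#' standard tiling-array rule set: P < 0.01, minimum run 100 bp, maximum
#' gap 250 bp.
#'
#' @param smoothed A [smooth_track()] result.
#' @param p_threshold Change P-value cut-off for a qualifying probe.
#' @param min_run_bp Minimum genomic span of a cluster.
#' @param max_gap_bp Maximum genomic gap between consecutive qualifying
#'   probes in a cluster.
#' @param require_positive_gap Enforce signal > 0 on every probe inside
#'   the chain span, including non-significant ones.
#' @return `data.frame` of class `binding_clusters`: `id`, `chrom`,
#'   `start`, `end` (half-open, first to last qualifying probe + 1),
#'   `peak_pos` (leftmost probe of maximal signal), `mean_signal` (mean
#'   over qualifying member probes) and `n_probes`.
#' @export
call_clusters <- function(smoothed, p_threshold = 0.01, min_run_bp = 100,
                          max_gap_bp = 250, require_positive_gap = TRUE) {
  stopifnot(is.data.frame(smoothed),
            all(c("chrom", "pos", "signal", "p_value") %in% names(smoothed)))
  res <- list()
  for (c_ in unique(smoothed$chrom)) {
    d <- smoothed[smoothed$chrom == c_, , drop = FALSE]
    q <- which(d$signal > 0 & d$p_value < p_threshold)
    if (!length(q)) next
    if (length(q) > 1) {
      a <- q[-length(q)]
      b <- q[-1]
      gap_break <- d$pos[b] - d$pos[a] > max_gap_bp
      if (require_positive_gap) {
        nonpos <- cumsum(d$signal <= 0)
        neg_between <- nonpos[b - 1] - nonpos[a] > 0
        brk <- gap_break | neg_between
      } else brk <- gap_break
      grp <- cumsum(c(TRUE, brk))
    } else grp <- 1L
    for (g in split(q, grp)) {
      start <- d$pos[g[1]]
      end <- d$pos[g[length(g)]] + 1L
      if (end - start < min_run_bp) next
      peak <- g[which.max(d$signal[g])]   # which.max: leftmost tie
      res[[length(res) + 1]] <- data.frame(
        chrom = c_, start = start, end = end,
        peak_pos = d$pos[peak],
        mean_signal = mean(d$signal[g]),
        n_probes = length(g), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(chrom = character(), start = integer(),
                         end = integer(), peak_pos = integer(),
                         mean_signal = numeric(), n_probes = integer(),
                         stringsAsFactors = FALSE)
  out <- cbind(id = if (nrow(out)) sprintf("cluster_%04d", seq_len(nrow(out)))
                    else character(), out, stringsAsFactors = FALSE)
  class(out) <- c("binding_clusters", "data.frame")
  out
}

#' Summary statistics of a cluster set
#'
#' @param clusters A [call_clusters()] table.
#' @param annotation A [genome_annotation()] supplying chromosome lengths
#'   and ORF spans.
#' @return List of class `cluster_set_stats`: `n_clusters`,
#'   `mean_length_bp`, `genome_coverage_fraction` (distinct covered bp
#'   over total genome bp) and `fraction_peaks_in_ORFs`. All but
#'   `n_clusters` are `NA` for an empty cluster set.
#' @export
cluster_set_stats <- function(clusters, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!nrow(clusters)) {
    return(structure(list(n_clusters = 0L, mean_length_bp = NA_real_,
                          genome_coverage_fraction = NA_real_,
                          fraction_peaks_in_ORFs = NA_real_),
                     class = "cluster_set_stats"))
  }
  lens <- clusters$end - clusters$start
  covered <- sum(IRanges::width(GenomicRanges::reduce(
    .to_granges(clusters, strand = "*"))))
  orfs <- orf_features(annotation)
  in_orf <- if (nrow(orfs)) {
    peaks <- GenomicRanges::GRanges(clusters$chrom,
      IRanges::IRanges(clusters$peak_pos + 1L, clusters$peak_pos + 1L))
    IRanges::overlapsAny(peaks, .to_granges(orfs, strand = "*"))
  } else rep(FALSE, nrow(clusters))
  structure(list(
    n_clusters = nrow(clusters),
    mean_length_bp = mean(lens),
    genome_coverage_fraction = covered / sum(annotation$chromosomes),
    fraction_peaks_in_ORFs = mean(in_orf)), class = "cluster_set_stats")
}

#' @export
print.cluster_set_stats <- function(x, ...) {
  cat("clusters:", x$n_clusters,
      "| mean length:", round(x$mean_length_bp, 1), "bp",
      "| genome coverage:",
      sprintf("%.1f%%", 100 * x$genome_coverage_fraction),
      "| peaks in ORFs:",
      sprintf("%.1f%%", 100 * x$fraction_peaks_in_ORFs), "\n")
  invisible(x)
}

#' Compare cluster length distributions between two sets
#'
#' Two-sided Mann-Whitney U test on cluster lengths, as used to contrast
#' replication-obstacle cluster sizes between strains.
#'
#' @param a,b [call_clusters()] tables, both non-empty.
#' @return Two-sided P-value.
#' @export
compare_cluster_lengths <- function(a, b) {
  if (!nrow(a) || !nrow(b))
    stop("both cluster sets must be non-empty")
  suppressWarnings(
    wilcox.test(a$end - a$start, b$end - b$start,
                alternative = "two.sided")$p.value)
}
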