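## Strand-aware 12-bin metagene profiles: 10 equal ORF segments plus one
## upstream and one downstream flank of the same unit length, ordered by
## transcription (5' -> 3'), not genome coordinates.

.METAGENE_BINS <- c("upstream", paste0("s", 1:10), "downstream")

#' Split a gene into 12 metagene segments
#'
#' The ORF is cut into 10 genomic intervals of equal length independently
#' of ORF size (remainder bp are given one each to the 3'-most segments),
#' and flanking segments of the same unit length (`floor(length/10)`) are
#' appended upstream of the 5' end and downstream of the 3' end. For
#' minus-strand genes the ordered bins run right-to-left genomically.
#' Flanks are clipped at chromosome edges and may come back empty
#' (`start == end`).
#'
#' @param gene One-row ORF `data.frame` (or list) with `chrom`, `start`,
#'   `end`, `strand` in `{"+","-"}`.
#' @param chrom_length Chromosome length used to clip flanks (default:
#'   no right clipping).
#' @return `data.frame` with 12 rows in transcription order: `bin` (1-12),
#'   `label`, `start`, `end`.
#' @export
segment_gene <- function(gene, chrom_length = Inf) {
  len <- gene$end - gene$start
  if (len < 10) stop("ORF '", gene$id, "' is shorter than 10 bp")
  if (!gene$strand %in% c("+", "-"))
    stop("metagene segmentation requires a stranded ORF")
  base <- len %/% 10
  rem <- len %% 10
  sizes <- rep(base, 10)                       # transcription order 5'->3'
  if (rem > 0) sizes[(10 - rem + 1):10] <- base + 1
  if (gene$strand == "+") {
    bounds <- gene$start + cumsum(c(0, sizes))
    starts <- c(gene$start - base, bounds[-11])
    ends <- c(gene$start, bounds[-1])
    starts <- c(starts, gene$end)
    ends <- c(ends, gene$end + base)
  } else {
    ## minus strand: upstream flank sits to the genomic right of the ORF
    ## and the segments walk right-to-left in transcription order.
    bounds <- gene$end - cumsum(c(0, sizes))
    starts <- c(gene$end, bounds[-1], gene$start - base)
    ends <- c(gene$end + base, bounds[-11], gene$start)
  }
  starts <- pmin(pmax(starts, 0), chrom_length)
  ends <- pmin(pmax(ends, 0), chrom_length)
  data.frame(bin = 1:12, label = .METAGENE_BINS,
             start = as.integer(starts), end = as.integer(ends),
             stringsAsFactors = FALSE)
}

## All 12 segments for every gene, as one table with gene index attached.
.all_segments <- function(genes, annotation) {
  stopifnot(nrow(genes) > 0)
  clen <- annotation$chromosomes
  segs <- lapply(seq_len(nrow(genes)), function(i) {
    s <- segment_gene(genes[i, ], chrom_length = clen[[genes$chrom[i]]])
    s$chrom <- genes$chrom[i]
    s$gene <- i
    s
  })
  do.call(rbind, segs)
}

.new_profile <- function(values, mode, n_genes) {
  structure(setNames(values, .METAGENE_BINS),
            mode = mode, n_genes = n_genes,
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile (", attr(x, "mode"), ", ",
      attr(x, "n_genes"), " genes):\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Percentage-of-clusters metagene profile
#'
#' Counts one incidence for every (cluster, gene-bin) pair sharing at
#' least 1 bp; a cluster spanning k bins of a gene contributes k
#' incidences, so the 12 bin percentages always sum to 100.
#'
#' @param clusters A [call_clusters()] table.
#' @param genes Stranded ORF `data.frame` (e.g. [orf_features()]).
#' @param annotation A [genome_annotation()] (for chromosome lengths).
#' @return A `metagene_profile` (mode `"cluster_percent"`).
#' @export
cluster_distribution_profile <- function(clusters, genes, annotation) {
  segs <- .all_segments(genes, annotation)
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  counts <- numeric(12)
  if (nrow(clusters) && nrow(segs)) {
    hits <- IRanges::countOverlaps(
      .to_granges(segs, strand = "*"),
      .to_granges(clusters, strand = "*"))
    counts <- vapply(1:12, function(b) sum(hits[segs$bin == b]), numeric(1))
  }
  total <- sum(counts)
  if (total == 0)
    stop("no cluster-segment incidences: cannot form a percentage profile")
  .new_profile(100 * counts / total, "cluster_percent", nrow(genes))
}

#' Mean-signal metagene profile
#'
#' Bin value = mean of the smoothed probe signals falling inside that bin,
#' pooled over all genes. Bins containing no probe anywhere come back
#' `NA` with a message.
#'
#' @param smoothed A [smooth_track()] result.
#' @param genes Stranded ORF `data.frame`.
#' @param annotation A [genome_annotation()].
#' @return A `metagene_profile` (mode `"signal_mean"`).
#' @export
signal_mean_profile <- function(smoothed, genes, annotation) {
  if (!nrow(genes)) stop("empty gene list")
  segs <- .all_segments(genes, annotation)
  sums <- numeric(12)
  ns <- numeric(12)
  for (c_ in unique(segs$chrom)) {
    probes <- smoothed[smoothed$chrom == c_, , drop = FALSE]
    if (!nrow(probes)) next
    ss <- segs[segs$chrom == c_, , drop = FALSE]
    cs0 <- c(0, cumsum(probes$signal))   # cs0[i+1] = sum of first i
    lo <- findInterval(ss$start - 0.5, probes$pos) + 1L
    hi <- findInterval(ss$end - 0.5, probes$pos)
    ok <- hi >= lo
    binsum <- (cs0[hi[ok] + 1] - cs0[lo[ok]])
    for (b in 1:12) {
      bsel <- ss$bin[ok] == b
      sums[b] <- sums[b] + sum(binsum[bsel])
      ns[b] <- ns[b] + sum((hi[ok] - lo[ok] + 1)[bsel])
    }
  }
  if (any(ns == 0))
    message("metagene bins without probes: ",
            paste(.METAGENE_BINS[ns == 0], collapse = ", "))
  vals <- ifelse(ns > 0, sums / ns, NA_real_)
  .new_profile(vals, "signal_mean", nrow(genes))
}

#' Split genes into equal-count length strata
#'
#' Genes are ordered by ORF length (ties broken by id for stability) and
#' cut into `n_strata` groups of near-equal size, shortest first.
#'
#' @param genes ORF `data.frame`.
#' @param n_strata Number of strata, >= 2.
#' @return Named list of gene `data.frame`s (`"L1"` shortest ... ).
#' @export
stratify_by_length <- function(genes, n_strata) {
  if (n_strata < 2) stop("n_strata must be >= 2")
  if (nrow(genes) < n_strata) stop("fewer genes than strata")
  ord <- order(genes$end - genes$start, genes$id)
  stratum <- ceiling(seq_along(ord) * n_strata / length(ord))
  out <- lapply(seq_len(n_strata), function(s)
    genes[ord[stratum == s], , drop = FALSE])
  names(out) <- paste0("L", seq_len(n_strata))
  out
}

#' Metagene profiles per gene-length stratum
#'
#' Convenience wrapper: stratify genes by length and compute one profile
#' per stratum, either from clusters (`cluster_percent`) or from a
#' smoothed track (`signal_mean`).
#'
#' @param x A [call_clusters()] table or a [smooth_track()] result,
#'   matching `mode`.
#' @param genes ORF `data.frame`.
#' @param annotation A [genome_annotation()].
#' @param n_strata Number of length strata.
#' @param mode `"cluster_percent"` or `"signal_mean"`.
#' @return Named list of `metagene_profile`s.
#' @export
profile_by_length_stratum <- function(x, genes, annotation, n_strata = 3,
                                      mode = c("cluster_percent",
                                               "signal_mean")) {
  mode <- match.arg(mode)
  strata <- stratify_by_length(genes, n_strata)
  lapply(strata, function(g) {
    if (mode == "cluster_percent")
      cluster_distribution_profile(x, g, annotation)
    else signal_mean_profile(x, g, annotation)
  })
}
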