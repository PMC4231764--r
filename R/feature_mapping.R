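## Mapping binding clusters onto annotated features, enriched-gene calls
## and gene-set overlap statistics.

#' Count features of each class overlapped by binding clusters
#'
#' A feature is "mapped" when it shares at least 1 bp with any cluster;
#' nested features (e.g. an intron inside an ORF) are counted
#' independently in their own class.
#'
#' @param clusters A [call_clusters()] table.
#' @param annotation A [genome_annotation()].
#' @return `data.frame` with `feature_class`, `n_mapped` and `n_total`,
#'   one row per feature class present in the annotation.
#' @export
map_clusters_to_features <- function(clusters, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  feats <- annotation$features
  classes <- FEATURE_CLASSES[FEATURE_CLASSES %in% feats$feature_class]
  hit <- if (nrow(clusters) && nrow(feats)) {
    IRanges::overlapsAny(.to_granges(feats, strand = "*"),
                         .to_granges(clusters, strand = "*"))
  } else rep(FALSE, nrow(feats))
  data.frame(
    feature_class = classes,
    n_mapped = vapply(classes, function(cl)
      sum(hit[feats$feature_class == cl]), integer(1)),
    n_total = vapply(classes, function(cl)
      sum(feats$feature_class == cl), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Call cluster-enriched genes and per-gene enrichment levels
#'
#' A gene is enriched when its ORF is overlapped by at least one binding
#' cluster (>= 1 bp). The enrichment level is the mean smoothed signal
#' over the probes inside the ORF span, computed for every gene
#' regardless of the enrichment call (`NA` when no probe falls inside).
#'
#' @param clusters A [call_clusters()] table.
#' @param smoothed The [smooth_track()] result the clusters came from.
#' @param annotation A [genome_annotation()].
#' @return `data.frame` with `gene_id`, `enriched`, `enrichment_level`
#'   and `n_probes`.
#' @export
call_enriched_genes <- function(clusters, smoothed, annotation) {
  orfs <- orf_features(annotation)
  if (!nrow(orfs))
    return(data.frame(gene_id = character(), enriched = logical(),
                      enrichment_level = numeric(), n_probes = integer()))
  enriched <- if (nrow(clusters)) {
    IRanges::overlapsAny(.to_granges(orfs, strand = "*"),
                         .to_granges(clusters, strand = "*"))
  } else rep(FALSE, nrow(orfs))
  level <- rep(NA_real_, nrow(orfs))
  nprobe <- integer(nrow(orfs))
  for (c_ in unique(orfs$chrom)) {
    probes <- smoothed[smoothed$chrom == c_, , drop = FALSE]
    gi <- which(orfs$chrom == c_)
    if (!nrow(probes)) next
    cs0 <- c(0, cumsum(probes$signal))   # cs0[i+1] = sum of first i
    lo <- findInterval(orfs$start[gi] - 0.5, probes$pos) + 1L
    hi <- findInterval(orfs$end[gi] - 0.5, probes$pos)
    ok <- hi >= lo
    nprobe[gi] <- pmax(0L, hi - lo + 1L)
    level[gi[ok]] <- (cs0[hi[ok] + 1] - cs0[lo[ok]]) /
      (hi[ok] - lo[ok] + 1)
  }
  data.frame(gene_id = orfs$id, enriched = enriched,
             enrichment_level = level, n_probes = nprobe,
             stringsAsFactors = FALSE)
}

#' Hypergeometric overlap test for two gene sets
#'
#' Upper-tail hypergeometric probability of observing an intersection at
#' least as large as `|A` \eqn{\cap} `B|` when `|B|` genes are drawn at
#' random from the universe — the standard Venn-diagram significance
#' test.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector of all eligible gene ids (typically
#'   the expression-floor-passing ORFs).
#' @return List with `overlap`, `fraction_a`, `fraction_b` (overlap as a
#'   fraction of each set) and `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe)) stop("set_a is not a subset of universe")
  if (!all(set_b %in% universe)) stop("set_b is not a subset of universe")
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  list(overlap = k,
       fraction_a = if (length(set_a)) k / length(set_a) else NA_real_,
       fraction_b = if (length(set_b)) k / length(set_b) else NA_real_,
       p_value = min(p, 1))
}
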