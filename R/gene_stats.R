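## Structural/functional statistics of gene sets and top-N sliding-window
## ranking.

#' Two-sided Mann-Whitney U P-value
#'
#' Exact when `min(n, m) <= exact_max` and the pooled sample is tie-free,
#' otherwise the normal approximation with tie and continuity
#' corrections. This is the rank test used for all set-vs-set structural
#' comparisons in the package.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for which the exact distribution
#'   is used.
#' @return Two-sided P-value.
#' @export
mann_whitney_p <- function(x, y, exact_max = 8) {
  use_exact <- min(length(x), length(y)) <= exact_max &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = use_exact, correct = TRUE)$p.value)
}

#' Compare a gene set's attribute to the genome distribution
#'
#' Two-sided Mann-Whitney U test of the set's attribute values (ORF
#' length, G+C fraction or expression level) against all retained genome
#' genes. When `expression_floor` is given, genes whose annotation-level
#' expression lies below it are removed from both samples first,
#' mirroring the pre-filtering used for structural comparisons.
#'
#' @param set Character vector of gene ids.
#' @param annotation A [genome_annotation()] carrying the attribute.
#' @param attribute `"length"`, `"gc_fraction"` or `"expression_level"`.
#' @param expression_floor Optional linear-scale floor (e.g. 600 A.U.).
#' @return List of class `gene_set_comparison`: `attribute`,
#'   `set_median`, `genome_median`, `p_value`, `n_set`, `n_genome`.
#' @export
compare_to_genome <- function(set, annotation,
                              attribute = c("length", "gc_fraction",
                                            "expression_level"),
                              expression_floor = NULL) {
  attribute <- match.arg(attribute)
  orfs <- orf_features(annotation)
  if (!is.null(expression_floor))
    orfs <- orfs[!is.na(orfs$expression_level) &
                   orfs$expression_level >= expression_floor, , drop = FALSE]
  vals <- switch(attribute,
                 length = orfs$end - orfs$start,
                 gc_fraction = orfs$gc_fraction,
                 expression_level = orfs$expression_level)
  in_set <- orfs$id %in% set
  x <- vals[in_set]
  x <- x[!is.na(x)]
  y <- vals[!is.na(vals)]
  if (!length(x))
    stop("gene set is empty after filtering")
  structure(list(attribute = attribute,
                 set_median = median(x),
                 genome_median = median(y),
                 p_value = mann_whitney_p(x, y),
                 n_set = length(x), n_genome = length(y)),
            class = "gene_set_comparison")
}

#' @export
print.gene_set_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: set median %.4g (n=%d) vs genome median %.4g (n=%d), MW P = %.3g\n",
    x$attribute, x$set_median, x$n_set, x$genome_median, x$n_genome,
    x$p_value))
  invisible(x)
}

#' Rank genes by maximal sliding-window signal
#'
#' Per gene, the score is the maximum over all windows of `window_bp`
#' fully inside the ORF of the mean smoothed probe signal within the
#' window; windows are anchored at probe positions (identical extrema on
#' piecewise-constant probe data at a fraction of the cost of per-bp
#' anchoring). ORFs shorter than the window, or without an eligible
#' anchor, are scored over the whole ORF. Genes without probes are
#' dropped with a message. Ties are broken by gene id.
#'
#' @param smoothed A [smooth_track()] result.
#' @param genes ORF `data.frame` (e.g. [orf_features()]).
#' @param window_bp Sliding-window width in bp.
#' @param n Number of top genes to return (clamped to the gene count).
#' @return `data.frame` with `gene_id`, `score`, `rank`, best first.
#' @export
top_n_by_sliding_window <- function(smoothed, genes, window_bp = 200,
                                    n = 500) {
  stopifnot(window_bp > 0)
  scores <- rep(NA_real_, nrow(genes))
  for (c_ in unique(genes$chrom)) {
    probes <- smoothed[smoothed$chrom == c_, , drop = FALSE]
    gi <- which(genes$chrom == c_)
    if (!nrow(probes)) next
    pos <- as.numeric(probes$pos)
    cs0 <- c(0, cumsum(probes$signal))   # cs0[i+1] = sum of first i
    wsum <- function(lo, hi) cs0[hi + 1] - cs0[lo]
    for (g in gi) {
      lo <- findInterval(genes$start[g] - 0.5, pos) + 1L
      hi <- findInterval(genes$end[g] - 0.5, pos)
      if (hi < lo) next
      anchors <- lo:hi
      anchors <- anchors[pos[anchors] + window_bp <= genes$end[g]]
      if (genes$end[g] - genes$start[g] < window_bp || !length(anchors)) {
        scores[g] <- wsum(lo, hi) / (hi - lo + 1)
        next
      }
      his <- findInterval(pos[anchors] + window_bp - 0.5, pos)
      means <- (cs0[his + 1] - cs0[anchors]) / (his - anchors + 1)
      scores[g] <- max(means)
    }
  }
  if (anyNA(scores))
    message(sum(is.na(scores)), " gene(s) without probes dropped from ranking")
  keep <- which(!is.na(scores))
  ord <- keep[order(-scores[keep], genes$id[keep])]
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(gene_id = genes$id[ord], score = scores[ord],
             rank = seq_along(ord), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Correlation between per-gene enrichment and expression
#'
#' Pearson correlation of ChIP enrichment levels against log2 expression
#' over the supplied genes.
#'
#' @param enrichment `data.frame` with `gene_id` and `enrichment_level`
#'   (e.g. from [call_enriched_genes()]).
#' @param annotation A [genome_annotation()] carrying expression levels.
#' @return List with `r`, `p_value` and `n`.
#' @export
enrichment_expression_correlation <- function(enrichment, annotation) {
  orfs <- orf_features(annotation)
  expr <- orfs$expression_level[match(enrichment$gene_id, orfs$id)]
  ok <- !is.na(expr) & !is.na(enrichment$enrichment_level)
  if (sum(ok) < 3) stop("need >= 3 genes with enrichment and expression")
  x <- enrichment$enrichment_level[ok]
  y <- log2(expr[ok])
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
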