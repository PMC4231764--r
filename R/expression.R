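## Gene-level expression analysis: floor filtering, differential-expression
## calling with fold/difference/P rules, profile correlation and
## clustering, and qPCR-style relative quantitation.

#' Construct an expression matrix
#'
#' Gene-level model-based expression values in linear arbitrary units,
#' with per-sample strain and replicate metadata.
#'
#' @param values Numeric matrix, genes x samples, strictly positive,
#'   with gene ids as rownames.
#' @param strain Character vector, one strain label per column.
#' @param replicate Integer replicate index per column.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, strain, replicate) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (any(values <= 0)) stop("expression values must be strictly positive")
  if (length(strain) != ncol(values) || length(replicate) != ncol(values))
    stop("strain and replicate must have one entry per sample column")
  structure(list(values = values,
                 samples = data.frame(strain = as.character(strain),
                                      replicate = as.integer(replicate),
                                      stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x",
      ncol(x$values), "samples (",
      paste(unique(x$samples$strain), collapse = ", "), ")\n")
  invisible(x)
}

#' Partition genes by the expression floor
#'
#' A gene is `filtered_low` when its value lies below `floor` in at least
#' `fraction` of all samples (both strains pooled); such genes are
#' removed before any differential comparison to limit false positives.
#'
#' @param em An [expression_matrix()].
#' @param floor Linear-scale expression cut-off (default 600 A.U.).
#' @param fraction Minimum fraction of samples below the floor.
#' @return List with `retained` and `filtered_low` gene-id vectors.
#' @export
apply_expression_floor <- function(em, floor = 600, fraction = 0.5) {
  stopifnot(inherits(em, "expression_matrix"))
  frac_below <- rowMeans(em$values < floor)
  low <- frac_below >= fraction
  list(retained = rownames(em$values)[!low],
       filtered_low = rownames(em$values)[low])
}

## Vectorized Welch t-test on log2 values, rows = genes.
.welch_p_log2 <- function(a, b) {
  la <- log2(a); lb <- log2(b)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  ## degenerate zero-variance rows: identical means -> 1, else -> ~0
  zero <- se2 == 0
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, .Machine$double.xmin)
  p
}

#' Call differentially expressed genes
#'
#' Applies the expression floor, then calls a gene `up` (or `down`) when
#' the linear fold-change of replicate means is at least `fold_threshold`
#' (at most `1/fold_threshold`), the absolute difference of means exceeds
#' `min_difference` A.U., and a two-sided Welch t-test on log2 replicate
#' values gives P below `alpha`. Defaults: 1.5-fold, difference > 100,
#' P < 0.05, floor 600 in >= 50% of samples.
#'
#' @param em An [expression_matrix()] containing both strains.
#' @param wild_type,mutant Strain labels to compare (>= 2 replicates
#'   each).
#' @param fold_threshold,min_difference,alpha DE thresholds (see above).
#' @param floor,floor_fraction Passed to [apply_expression_floor()];
#'   `floor = NULL` skips the filter.
#' @return `data.frame` of class `de_records`: `gene_id`, `wt_mean`,
#'   `mut_mean`, `fold_change` (mutant/wild-type, linear),
#'   `log2_fold_change`, `abs_difference`, `p_value` and `call` in
#'   `{up, down, unchanged, filtered_low}`.
#' @export
call_de <- function(em, wild_type, mutant, fold_threshold = 1.5,
                    min_difference = 100, alpha = 0.05,
                    floor = 600, floor_fraction = 0.5) {
  stopifnot(inherits(em, "expression_matrix"))
  wt_cols <- which(em$samples$strain == wild_type)
  mut_cols <- which(em$samples$strain == mutant)
  if (length(wt_cols) < 2 || length(mut_cols) < 2)
    stop("need >= 2 replicates per strain (found ", length(wt_cols),
         " wild-type, ", length(mut_cols), " mutant)")
  wt <- em$values[, wt_cols, drop = FALSE]
  mut <- em$values[, mut_cols, drop = FALSE]
  wt_mean <- rowMeans(wt)
  mut_mean <- rowMeans(mut)
  fc <- mut_mean / wt_mean
  diff <- abs(mut_mean - wt_mean)
  p <- .welch_p_log2(wt, mut)
  call <- rep("unchanged", nrow(em$values))
  sig <- diff > min_difference & p < alpha
  call[sig & fc >= fold_threshold] <- "up"
  call[sig & fc <= 1 / fold_threshold] <- "down"
  if (!is.null(floor)) {
    low <- apply_expression_floor(em, floor, floor_fraction)$filtered_low
    call[rownames(em$values) %in% low] <- "filtered_low"
  }
  out <- data.frame(gene_id = rownames(em$values),
                    wt_mean = wt_mean, mut_mean = mut_mean,
                    fold_change = fc, log2_fold_change = log2(fc),
                    abs_difference = diff, p_value = p, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_records", "data.frame")
  out
}

#' Pearson correlation between two fold-change profiles
#'
#' Correlates log2 fold-changes over the genes shared by two DE result
#' tables, excluding floor-filtered genes in either.
#'
#' @param de_a,de_b [call_de()] results.
#' @return Pearson r.
#' @export
profile_correlation <- function(de_a, de_b) {
  keep_a <- de_a[de_a$call != "filtered_low", c("gene_id", "log2_fold_change")]
  keep_b <- de_b[de_b$call != "filtered_low", c("gene_id", "log2_fold_change")]
  shared <- intersect(keep_a$gene_id, keep_b$gene_id)
  if (length(shared) < 3)
    stop("need >= 3 shared genes after floor filtering, found ",
         length(shared))
  cor(keep_a$log2_fold_change[match(shared, keep_a$gene_id)],
      keep_b$log2_fold_change[match(shared, keep_b$gene_id)])
}

#' Hierarchical clustering of expression profiles
#'
#' Genes are ranked by their maximum absolute log2 fold-change across
#' profiles and the top fraction retained (heatmap gene selection);
#' profiles are then agglomerated by complete linkage on the
#' `1 - Pearson r` distance.
#'
#' @param fc Numeric matrix of log2 fold-changes, genes x profiles, with
#'   dimnames.
#' @param top_fraction Fraction of genes (by max |log2 FC|) to keep.
#' @return List of class `profile_clustering`: `hclust` (profile tree),
#'   `leaf_order`, `merge_heights`, and `genes` (retained ids in heatmap
#'   order, largest fold-change first).
#' @export
cluster_profiles <- function(fc, top_fraction = 0.5) {
  fc <- as.matrix(fc)
  if (ncol(fc) < 2) stop("need >= 2 profiles")
  if (is.null(rownames(fc))) rownames(fc) <- seq_len(nrow(fc))
  score <- apply(abs(fc), 1, max)
  keep_n <- max(2, ceiling(top_fraction * nrow(fc)))
  ord <- order(-score, rownames(fc))
  kept <- fc[ord[seq_len(min(keep_n, nrow(fc)))], , drop = FALSE]
  sds <- apply(kept, 2, sd)
  if (any(sds == 0))
    stop("zero-variance profile: ", colnames(kept)[which(sds == 0)[1]])
  d <- as.dist(1 - cor(kept))
  hc <- hclust(d, method = "complete")
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 merge_heights = hc$height,
                 genes = rownames(kept)),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat("profile_clustering:", length(x$leaf_order), "profiles,",
      length(x$genes), "genes; leaf order:",
      paste(x$leaf_order, collapse = " "), "\n")
  invisible(x)
}

#' qPCR-style relative quantitation
#'
#' Per sample, the target measurement is divided by the normalizer gene's
#' measurement; all ratios are then scaled to the mean ratio of the
#' reference condition, and mean +/- SEM is reported per condition.
#'
#' @param target,normalizer Numeric vectors of per-sample measurements
#'   (same length); normalizer values must be positive.
#' @param condition Character vector of condition labels per sample.
#' @param reference Condition whose mean ratio defines level 1.
#' @return `data.frame` with `condition`, `mean`, `sem`, `n`.
#' @export
relative_quantitation <- function(target, normalizer, condition,
                                  reference = "wild_type") {
  if (length(target) != length(normalizer) ||
      length(target) != length(condition))
    stop("target, normalizer and condition must have equal length")
  if (any(!is.finite(normalizer)) || any(normalizer <= 0))
    stop("normalizer measurements must be positive and finite")
  if (!reference %in% condition)
    stop("no samples in reference condition '", reference, "'")
  ratio <- target / normalizer
  ref_mean <- mean(ratio[condition == reference])
  if (ref_mean == 0) stop("reference condition has zero mean ratio")
  norm <- ratio / ref_mean
  conds <- unique(condition)
  data.frame(
    condition = conds,
    mean = vapply(conds, function(cc) mean(norm[condition == cc]), 1),
    sem = vapply(conds, function(cc) {
      v <- norm[condition == cc]
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }, 1),
    n = vapply(conds, function(cc) sum(condition == cc), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}
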