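## Evaluation of called results against planted ground truth from the
## synthetic-data generator.

#' Precision and recall of planted-span recovery
#'
#' A planted span counts as recovered when some called cluster overlaps
#' it reciprocally: the overlap covers at least `min_reciprocal` of the
#' planted span AND of the cluster. Precision applies the same rule from
#' the cluster side.
#'
#' @param clusters A [call_clusters()] table.
#' @param truth Planted spans (`chrom`, `start`, `end`), e.g. the `truth`
#'   component of [simulate_chip_tracks()].
#' @param min_reciprocal Minimum reciprocal overlap fraction.
#' @return List with `recall`, `precision`, `n_truth`, `n_clusters`.
#' @export
planted_span_recovery <- function(clusters, truth, min_reciprocal = 0.5) {
  if (!nrow(truth)) stop("no planted spans to recover")
  if (!nrow(clusters))
    return(list(recall = 0, precision = NA_real_,
                n_truth = nrow(truth), n_clusters = 0L))
  tg <- .to_granges(truth, strand = "*")
  cg <- .to_granges(clusters, strand = "*")
  hits <- GenomicRanges::findOverlaps(tg, cg)
  ti <- S4Vectors::queryHits(hits)
  ci <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(tg)[ti],
                                           IRanges::ranges(cg)[ci]))
  good <- ov >= min_reciprocal * (truth$end - truth$start)[ti] &
    ov >= min_reciprocal * (clusters$end - clusters$start)[ci]
  list(recall = mean(seq_len(nrow(truth)) %in% ti[good]),
       precision = mean(seq_len(nrow(clusters)) %in% ci[good]),
       n_truth = nrow(truth), n_clusters = nrow(clusters))
}

#' Sensitivity and false-positive rate of DE recovery
#'
#' Sensitivity is computed over planted genes with fold at least
#' `min_fold` that survive the expression floor (i.e. were not
#' `filtered_low`), requiring the call to match the planted direction.
#' The false-positive rate is the fraction of planted-unchanged,
#' floor-surviving genes called up or down.
#'
#' @param de A [call_de()] result.
#' @param truth Planted labels (`gene_id`, `label`, `fold`) from
#'   [simulate_expression()].
#' @param min_fold Minimum planted fold for the sensitivity denominator.
#' @return List with `sensitivity`, `fpr`, `n_positive`, `n_negative`.
#' @export
de_recovery <- function(de, truth, min_fold = 2) {
  m <- merge(de, truth, by = "gene_id")
  eligible <- m$call != "filtered_low"
  pos <- eligible & m$label %in% c("up", "down") & m$fold >= min_fold
  neg <- eligible & m$label == "unchanged"
  list(sensitivity = if (any(pos)) mean(m$call[pos] == m$label[pos])
                     else NA_real_,
       fpr = if (any(neg)) mean(m$call[neg] %in% c("up", "down"))
             else NA_real_,
       n_positive = sum(pos), n_negative = sum(neg))
}
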