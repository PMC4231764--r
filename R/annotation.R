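## Domain containers: genome annotation, typed features, intervals.
## Coordinates are 0-based half-open throughout.

#' Recognized genomic feature classes
#'
#' The typed feature vocabulary used by [genome_annotation()]:
#' protein-coding ORFs, centromeres, telomeres, autonomously replicating
#' sequences (ARS), introns, sn/snoRNA genes and RNA-polymerase-III
#' transcribed genes.
#'
#' @format Character vector of class names.
#' @export
FEATURE_CLASSES <- c("ORF", "centromere", "telomere", "ARS", "intron",
                     "snRNA_snoRNA", "RNAPIII")

## classes for which strand "." is legal
.unstranded_classes <- c("centromere", "telomere", "ARS")

#' Construct a genome annotation
#'
#' Bundles chromosome lengths with a typed feature table. Every feature
#' span must lie within its chromosome and identifiers must be unique
#' within a feature class.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param features `data.frame` with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open bp), `strand` (`"+"`, `"-"` or `"."`),
#'   `feature_class` (one of [FEATURE_CLASSES]), and optionally
#'   `expression_level` (linear A.U.) and `gc_fraction` (in `[0,1]`).
#' @return An object of class `genome_annotation`.
#' @examples
#' ann <- genome_annotation(
#'   c(chrI = 10000),
#'   data.frame(id = "YAL001C", chrom = "chrI", start = 200, end = 800,
#'              strand = "+", feature_class = "ORF"))
#' ann
#' @export
genome_annotation <- function(chromosomes, features) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("'chromosomes' must be a named vector of lengths")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be positive")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("id", "chrom", "start", "end", "strand", "feature_class")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols))
    stop("'features' lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"expression_level" %in% names(features))
    features$expression_level <- NA_real_
  if (!"gc_fraction" %in% names(features)) features$gc_fraction <- NA_real_
  features <- features[, c(needed, "expression_level", "gc_fraction")]
  if (nrow(features)) {
    bad <- !features$feature_class %in% FEATURE_CLASSES
    if (any(bad))
      stop("unknown feature_class: ",
           paste(unique(features$feature_class[bad]), collapse = ", "))
    unknown <- !features$chrom %in% names(chromosomes)
    if (any(unknown))
      stop("feature '", features$id[which(unknown)[1]],
           "' lies on unknown chromosome '",
           features$chrom[which(unknown)[1]], "'")
    if (any(features$start >= features$end))
      stop("feature '", features$id[which(features$start >= features$end)[1]],
           "' has start >= end")
    len <- unname(chromosomes[features$chrom])
    out_of_range <- features$start < 0 | features$end > len
    if (any(out_of_range))
      stop("feature '", features$id[which(out_of_range)[1]],
           "' extends beyond its chromosome")
    dot <- features$strand == "."
    if (any(dot & !features$feature_class %in% .unstranded_classes))
      stop("strand '.' is only allowed for unstranded classes (",
           paste(.unstranded_classes, collapse = ", "), ")")
    if (!all(features$strand %in% c("+", "-", ".")))
      stop("strand must be '+', '-' or '.'")
    dup <- duplicated(features[, c("feature_class", "id")])
    if (any(dup))
      stop("duplicated feature id within class: ", features$id[which(dup)[1]])
    gc_bad <- !is.na(features$gc_fraction) &
      (features$gc_fraction < 0 | features$gc_fraction > 1)
    if (any(gc_bad)) stop("gc_fraction must lie in [0,1]")
  }
  structure(list(chromosomes = chromosomes, features = features),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chromosomes), "chromosome(s),",
      format(sum(x$chromosomes), big.mark = ","), "bp total\n")
  if (nrow(x$features)) {
    tab <- table(factor(x$features$feature_class, levels = FEATURE_CLASSES))
    tab <- tab[tab > 0]
    for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], "\n", sep = "")
  } else cat("  (no features)\n")
  invisible(x)
}

#' Extract the ORF features of an annotation
#'
#' @param annotation A [genome_annotation()].
#' @return `data.frame` of ORF features.
#' @export
orf_features <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  annotation$features[annotation$features$feature_class == "ORF", ,
                      drop = FALSE]
}

#' Genomic interval
#'
#' A minimal 0-based half-open interval on a named chromosome.
#'
#' @param chrom Chromosome name.
#' @param start,end Coordinates in bp, `start < end`.
#' @return A list of class `interval`.
#' @export
interval <- function(chrom, start, end) {
  if (start >= end) stop("interval requires start < end")
  structure(list(chrom = chrom, start = start, end = end),
            class = "interval")
}

#' Overlap between two intervals in bp
#'
#' Returns `max(0, min(end) - max(start))` when the chromosomes match and
#' 0 otherwise. Half-open convention: abutting intervals overlap by 0.
#'
#' @param a,b Objects with `chrom`, `start`, `end` (e.g. [interval()] or a
#'   one-row feature).
#' @return Non-negative integer overlap in bp.
#' @examples
#' overlap_bp(interval("chrI", 100, 400), interval("chrI", 200, 800))  # 200
#' @export
overlap_bp <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}
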