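## I/O boundary: GFF3/BED6 annotation readers, BED/bedGraph writers,
## chrom.sizes and expression tables. External conventions (1-based closed
## GFF3) are converted here; everything internal is 0-based half-open.

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length in bp.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  if (any(duplicated(tab$chrom))) stop("duplicated chromosome in ", path)
  setNames(tab$length, tab$chrom)
}

#' Default mapping from GFF3 type to feature class
#'
#' Table-driven and overridable in [read_annotation()]: SGD-style GFF type
#' vocabularies vary between releases, so users can extend or replace the
#' mapping. Types absent from the map are skipped with a message.
#'
#' @return Named character vector: GFF type -> feature class.
#' @export
default_gff_class_map <- function() {
  c(gene = "ORF", ORF = "ORF", CDS = "ORF", mRNA = "ORF",
    centromere = "centromere", telomere = "telomere",
    ARS = "ARS", origin_of_replication = "ARS",
    intron = "intron",
    snRNA = "snRNA_snoRNA", snoRNA = "snRNA_snoRNA",
    snRNA_gene = "snRNA_snoRNA", snoRNA_gene = "snRNA_snoRNA",
    tRNA = "RNAPIII", tRNA_gene = "RNAPIII", rRNA_5S = "RNAPIII",
    RNase_P_RNA = "RNAPIII")
}

## Cheap structural validation so malformed lines are reported with their
## line number before the heavyweight parser sees the file.
.validate_columns <- function(path, min_fields, label) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser"))
      next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf < min_fields)
      stop("malformed ", label, " line ", i, " in ", path,
           ": expected >= ", min_fields, " tab-separated fields, found ", nf)
  }
  invisible(TRUE)
}

#' Read a genome annotation from GFF3 or BED6
#'
#' GFF3 coordinates (1-based closed) are converted to the internal 0-based
#' half-open convention; BED is already half-open. Feature classes come
#' from the GFF `type` column via `class_map`, or from `feature_class` for
#' BED input (BED carries no type column).
#'
#' @param path GFF3 or BED6 file.
#' @param chrom_sizes Named length vector (from [read_chrom_sizes()]) or a
#'   path to a chrom.sizes file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param class_map Named vector mapping GFF types to [FEATURE_CLASSES].
#' @param feature_class Class assigned to every BED feature.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, chrom_sizes,
                            format = c("auto", "gff3", "bed"),
                            class_map = default_gff_class_map(),
                            feature_class = "ORF") {
  format <- match.arg(format)
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  if (format == "gff3") {
    .validate_columns(path, 9, "GFF3")
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    cls <- unname(class_map[type])
    if (any(is.na(cls))) {
      message("skipping ", sum(is.na(cls)), " feature(s) with unmapped GFF type: ",
              paste(unique(type[is.na(cls)]), collapse = ", "))
      gr <- gr[!is.na(cls)]
      cls <- cls[!is.na(cls)]
    }
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
    if (!is.null(gr$Name)) {
      nm <- as.character(gr$Name)
      id <- ifelse(is.na(id), nm, id)
    }
    id[is.na(id)] <- paste0(cls[is.na(id)], "_", which(is.na(id)))
    feats <- data.frame(
      id = id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> half-open
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      feature_class = cls,
      stringsAsFactors = FALSE)
    for (col in c("expression_level", "gc_fraction")) {
      v <- S4Vectors::mcols(gr)[[col]]
      feats[[col]] <- if (is.null(v)) NA_real_ else as.numeric(v)
    }
  } else {
    .validate_columns(path, 6, "BED6")
    gr <- rtracklayer::import(path, format = "bed")
    feats <- data.frame(
      id = if (!is.null(gr$name)) as.character(gr$name)
           else paste0(feature_class, "_", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # GRanges is 1-based
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      feature_class = feature_class,
      stringsAsFactors = FALSE)
  }
  genome_annotation(chrom_sizes, feats)
}

## features (or clusters) data.frame -> GRanges, internal half-open to 1-based
.to_granges <- function(df, strand = NULL) {
  if (is.null(strand)) {
    strand <- if ("strand" %in% names(df)) sub("\\.", "*", df$strand) else "*"
  }
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

#' Write features as BED6
#'
#' Coordinates are written 0-based half-open; a round trip through
#' [read_annotation()] reproduces them exactly.
#'
#' @param features Feature `data.frame` (e.g. from a [genome_annotation()]).
#' @param path Output BED path.
#' @export
write_features_bed <- function(features, path) {
  gr <- .to_granges(features)
  gr$name <- features$id
  gr$score <- 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write binding clusters as BED6
#'
#' The BED score is `1000 * mean_signal`, clipped to `[0, 1000]`.
#'
#' @param clusters Cluster table from [call_clusters()].
#' @param path Output BED path.
#' @export
write_clusters_bed <- function(clusters, path) {
  gr <- .to_granges(clusters, strand = "*")
  gr$name <- clusters$id
  gr$score <- pmin(1000, pmax(0, round(1000 * clusters$mean_signal)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a per-position value track as bedGraph
#'
#' Each probe becomes a 1-bp half-open record at its position.
#'
#' @param chrom,pos,value Parallel vectors (position 0-based bp).
#' @param path Output path.
#' @export
write_bedgraph <- function(chrom, pos, value, path) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L),
                               score = value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file as a per-position table
#'
#' @param path bedGraph path.
#' @return `data.frame` with `chrom`, `pos` (0-based start) and `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr) - 1L,
             value = gr$score, stringsAsFactors = FALSE)
}

#' Write a probe track as one bedGraph per replicate
#'
#' @param track A [probe_track()].
#' @param prefix Path prefix; files are `<prefix>_rep<k>.bedGraph`.
#' @return Character vector of file paths.
#' @export
write_probe_track <- function(track, prefix) {
  stopifnot(inherits(track, "probe_track"))
  paths <- character(ncol(track$values))
  for (r in seq_len(ncol(track$values))) {
    paths[r] <- paste0(prefix, "_rep", r, ".bedGraph")
    write_bedgraph(track$chrom, track$pos, track$values[, r], paths[r])
  }
  paths
}

#' Read replicate bedGraphs into a probe track
#'
#' @param paths bedGraph files, one per replicate, on identical probe grids.
#' @return A [probe_track()].
#' @export
read_probe_track <- function(paths) {
  reps <- lapply(paths, read_bedgraph)
  first <- reps[[1]]
  for (r in seq_along(reps)[-1]) {
    if (!identical(reps[[r]]$chrom, first$chrom) ||
        !identical(reps[[r]]$pos, first$pos)) {
      bad <- which(reps[[r]]$chrom != first$chrom |
                     reps[[r]]$pos != first$pos)[1]
      stop("replicate ", r, " probe grid differs from replicate 1 ",
           "starting at record ", bad)
    }
  }
  probe_track(first$chrom, first$pos,
              do.call(cbind, lapply(reps, `[[`, "value")))
}

#' Write an expression matrix as TSV
#'
#' Columns are named `<strain>_<replicate>`; [read_expression_tsv()]
#' recovers the sample metadata from these names.
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  out <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0(em$samples$strain, "_", em$samples$replicate)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#'
#' @param path TSV path.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab$gene_id
  nm <- colnames(vals)
  if (any(!grepl("_[0-9]+$", nm)))
    stop("expression column names must look like <strain>_<replicate>")
  expression_matrix(vals,
                    strain = sub("_[0-9]+$", "", nm),
                    replicate = as.integer(sub("^.*_", "", nm)))
}
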