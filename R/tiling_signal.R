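## Per-probe tiling signal estimation: replicate tracks, quantile
## normalization, and bandwidth-windowed Hodges-Lehmann / Wilcoxon
## signed-rank smoothing.

#' Construct a probe track
#'
#' An ordered set of tiling-array probes with one log2(IP/SUP) ratio per
#' replicate. Positions must be strictly increasing within each
#' chromosome.
#'
#' @param chrom Character vector of chromosome names (one per probe).
#' @param pos Integer probe positions (bp, 0-based), strictly increasing
#'   within chromosome.
#' @param values Numeric matrix, probes x replicates, of log2 ratios; a
#'   vector is treated as a single replicate.
#' @return Object of class `probe_track`.
#' @seealso [probe_track_from_intensities()] for raw IP/SUP channels.
#' @export
probe_track <- function(chrom, pos, values) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != length(pos) || nrow(values) != length(pos))
    stop("chrom, pos and values must have one entry per probe")
  if (is.unsorted(match(chrom, unique(chrom))))
    stop("probes must be grouped by chromosome")
  for (c_ in unique(chrom)) {
    p <- pos[chrom == c_]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within ", c_)
  }
  structure(list(chrom = chrom, pos = pos, values = values),
            class = "probe_track")
}

#' Build a probe track from IP and SUP intensities
#'
#' Forms `log2(IP) - log2(SUP)` per probe and replicate. Intensities must
#' be strictly positive.
#'
#' @param chrom,pos As in [probe_track()].
#' @param ip,sup Intensity matrices (probes x replicates), same shape.
#' @return A [probe_track()] of log2 ratios.
#' @export
probe_track_from_intensities <- function(chrom, pos, ip, sup) {
  ip <- as.matrix(ip); sup <- as.matrix(sup)
  if (!identical(dim(ip), dim(sup)))
    stop("ip and sup must have identical dimensions")
  if (any(ip <= 0) || any(sup <= 0))
    stop("intensities must be strictly positive to form log ratios")
  probe_track(chrom, pos, log2(ip) - log2(sup))
}

#' @export
print.probe_track <- function(x, ...) {
  cat("probe_track:", length(x$pos), "probes on",
      length(unique(x$chrom)), "chromosome(s),",
      ncol(x$values), "replicate(s)\n")
  invisible(x)
}

## Core quantile normalization on a probes x replicates matrix.
## Ties are broken by row order so every output column carries exactly the
## reference multiset (the across-replicate means of rank-matched values);
## this also makes the transform idempotent.
.quantile_normalize_matrix <- function(m) {
  ord <- apply(m, 2, order)
  ref <- rowMeans(vapply(seq_len(ncol(m)),
                         function(j) m[ord[, j], j],
                         numeric(nrow(m))))
  out <- m
  for (j in seq_len(ncol(m))) out[ord[, j], j] <- ref
  dimnames(out) <- dimnames(m)
  out
}

#' Quantile-normalize replicate probe tracks
#'
#' Replaces each replicate's value at a given rank by the across-replicate
#' mean of the rank-matched values, so all replicates end up with an
#' identical sorted value multiset. Accepts a multi-replicate
#' [probe_track()] or a list of single-replicate tracks on identical
#' probe grids.
#'
#' @param tracks A [probe_track()] with >= 2 replicate columns, or a list
#'   of [probe_track()] objects.
#' @return Same shape as the input, normalized.
#' @export
quantile_normalize <- function(tracks) {
  if (inherits(tracks, "probe_track")) {
    if (ncol(tracks$values) == 1) {
      warning("single replicate: quantile normalization is the identity")
      return(tracks)
    }
    tracks$values <- .quantile_normalize_matrix(tracks$values)
    return(tracks)
  }
  stopifnot(is.list(tracks), all(vapply(tracks, inherits, TRUE, "probe_track")))
  if (length(tracks) == 1) {
    warning("single replicate: quantile normalization is the identity")
    return(tracks)
  }
  first <- tracks[[1]]
  for (r in seq_along(tracks)[-1]) {
    if (!identical(tracks[[r]]$chrom, first$chrom) ||
        !identical(tracks[[r]]$pos, first$pos)) {
      bad <- which(tracks[[r]]$chrom != first$chrom |
                     tracks[[r]]$pos != first$pos)[1]
      stop("probe grids differ between replicates 1 and ", r,
           " starting at probe ", bad)
    }
  }
  m <- do.call(cbind, lapply(tracks, function(t) t$values[, 1]))
  m <- .quantile_normalize_matrix(m)
  lapply(seq_along(tracks), function(r)
    probe_track(first$chrom, first$pos, m[, r]))
}

#' Hodges-Lehmann pseudo-median
#'
#' Median of all `n(n+1)/2` pairwise Walsh averages `(x_i + x_j)/2`,
#' `i <= j`. The location estimate paired with the Wilcoxon signed-rank
#' test.
#'
#' @param x Numeric vector.
#' @return The pseudo-median (NA for empty input).
#' @examples
#' hodges_lehmann(c(1, 2, 3))  # 2
#' @export
hodges_lehmann <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n == 1) return(x)
  w <- outer(x, x, "+") / 2
  median(w[upper.tri(w, diag = TRUE)])
}

#' One-sided Wilcoxon signed-rank P-value for median > 0
#'
#' Zeros are dropped and ties of absolute values receive midranks. For
#' `n <= exact_max` remaining values the P-value is exact: tie-free
#' samples use the closed-form signed-rank distribution, tied samples a
#' convolution over the doubled midranks (equivalent to enumerating all
#' `2^n` sign assignments). Larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x Numeric sample (e.g. log2 ratios in a smoothing window).
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return P-value in `(0, 1]` for the alternative "pseudo-median > 0".
#' @examples
#' signed_rank_p(c(1, 2, 3))  # 1/8: all three signs positive
#' @export
signed_rank_p <- function(x, exact_max = 25) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_max) {
    if (!anyDuplicated(r)) {
      ## distinct ranks: standard exact signed-rank distribution
      p <- psignrank(w - 1, n, lower.tail = FALSE)
    } else {
      ## midranks: exact tail by convolution over doubled ranks
      d <- as.integer(round(2 * r))
      counts <- c(1, numeric(sum(d)))
      for (di in d) {
        shifted <- c(numeric(di), counts[seq_len(length(counts) - di)])
        counts <- counts + shifted
      }
      sums <- seq_along(counts) - 1
      p <- sum(counts[sums >= round(2 * w)]) / 2^n
    }
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p <- pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Smooth a probe track into per-probe signal and change P-value
#'
#' At every probe position, all replicate log2 ratios from probes within
#' `bandwidth_bp` on either side are pooled; the estimated signal is their
#' Hodges-Lehmann pseudo-median and the change P-value a one-sided
#' Wilcoxon signed-rank test of "pseudo-median > 0" ([signed_rank_p()]).
#' The default half-bandwidth of 150 bp gives an effective window of
#' about 300 bp, the working resolution of the tiling design.
#'
#' @param track A [probe_track()] (replicates are pooled; normalize first
#'   with [quantile_normalize()] if desired).
#' @param bandwidth_bp Half-width of the smoothing window in bp.
#' @return Object of class `smoothed_track`: a `data.frame` with `chrom`,
#'   `pos`, `signal`, `p_value`, and attribute `bandwidth_bp`.
#' @export
smooth_track <- function(track, bandwidth_bp = 150) {
  stopifnot(inherits(track, "probe_track"), bandwidth_bp >= 0)
  n <- length(track$pos)
  signal <- numeric(n)
  pval <- numeric(n)
  warned_single <- FALSE
  for (c_ in unique(track$chrom)) {
    sel <- which(track$chrom == c_)
    pos <- as.numeric(track$pos[sel])
    vals <- track$values[sel, , drop = FALSE]
    ## window index bounds: probes with |pos_j - pos_i| <= bandwidth
    lo <- findInterval(pos - bandwidth_bp - 0.5, pos) + 1L
    hi <- findInterval(pos + bandwidth_bp + 0.5, pos)
    for (i in seq_along(sel)) {
      x <- as.vector(vals[lo[i]:hi[i], , drop = FALSE])
      signal[sel[i]] <- hodges_lehmann(x)
      if (length(x) == 1) {
        if (!warned_single) {
          warning("window with a single value: p_value set to 1")
          warned_single <- TRUE
        }
        pval[sel[i]] <- 1
      } else {
        pval[sel[i]] <- signed_rank_p(x)
      }
    }
  }
  out <- data.frame(chrom = track$chrom, pos = track$pos,
                    signal = signal, p_value = pval,
                    stringsAsFactors = FALSE)
  attr(out, "bandwidth_bp") <- bandwidth_bp
  class(out) <- c("smoothed_track", "data.frame")
  out
}

#' @export
print.smoothed_track <- function(x, ...) {
  cat("smoothed_track:", nrow(x), "probes, bandwidth",
      attr(x, "bandwidth_bp"), "bp\n")
  print(head(as.data.frame(x)), ...)
  invisible(x)
}
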