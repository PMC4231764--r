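# Independent brute-force oracles used to freeze expected values and to
# check the package's statistics by enumeration on small inputs.

# Hodges-Lehmann by explicit double loop over Walsh averages.
oracle_hl <- function(x) {
  n <- length(x)
  w <- c()
  for (i in seq_len(n)) for (j in i:n) w <- c(w, (x[i] + x[j]) / 2)
  w <- sort(w)
  m <- length(w)
  if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
}

# One-sided signed-rank P by enumerating all 2^n sign assignments of the
# midranks (zeros dropped first, as in the implementation's convention).
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  count <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    if (sum(r[signs]) >= w_obs) count <- count + 1
  }
  count / 2^n
}

# Upper-tail hypergeometric by enumerating every possible draw of |B|
# elements from the universe.
oracle_hyper_p <- function(n_universe, set_a, n_b, k_obs) {
  draws <- combn(n_universe, n_b)
  mean(apply(draws, 2, function(d) sum(d %in% set_a) >= k_obs))
}

# Two-sided Mann-Whitney P by enumerating all group assignments of the
# pooled (tie-free) sample; doubled smaller tail, capped at 1, matching
# the standard exact convention.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  picks <- combn(length(pooled), n)
  ws <- apply(picks, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(p, 1)
}

# Maximal qualifying-chain enumeration by a sequential per-probe scan --
# an intentionally different control flow from call_clusters().
oracle_clusters <- function(sm, p_threshold = 0.01, min_run_bp = 100,
                            max_gap_bp = 250) {
  out <- list()
  for (c_ in unique(sm$chrom)) {
    d <- sm[sm$chrom == c_, , drop = FALSE]
    chain <- integer()
    dirty <- FALSE   # nonpositive probe seen since last qualifying probe
    flush <- function(chain) {
      if (!length(chain)) return()
      span_start <- d$pos[chain[1]]
      span_end <- d$pos[chain[length(chain)]] + 1
      if (span_end - span_start < min_run_bp) return()
      sig <- d$signal[chain]
      out[[length(out) + 1]] <<- data.frame(
        chrom = c_, start = span_start, end = span_end,
        peak_pos = d$pos[chain[which(sig == max(sig))[1]]],
        mean_signal = mean(sig), n_probes = length(chain))
    }
    for (i in seq_len(nrow(d))) {
      qual <- d$signal[i] > 0 && d$p_value[i] < p_threshold
      if (qual) {
        if (length(chain) &&
            (d$pos[i] - d$pos[chain[length(chain)]] > max_gap_bp || dirty)) {
          flush(chain)
          chain <- integer()
        }
        chain <- c(chain, i)
        dirty <- FALSE
      } else if (d$signal[i] <= 0) dirty <- TRUE
    }
    flush(chain)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), start = integer(), end = integer(),
                  peak_pos = integer(), mean_signal = numeric(),
                  n_probes = integer())
}

# Random smoothed-track fixture for cluster property tests.
random_smoothed <- function(n, spacing_range = c(20, 120)) {
  pos <- cumsum(sample(spacing_range[1]:spacing_range[2], n, replace = TRUE))
  d <- data.frame(chrom = "chrS", pos = as.integer(pos),
                  signal = round(rnorm(n, 0.2, 1), 2),
                  p_value = round(runif(n)^2, 4))
  d$p_value <- pmax(d$p_value, 1e-4)
  d
}

# Minimal annotation fixture: two chromosomes, a handful of typed features.
tiny_annotation <- function() {
  genome_annotation(
    c(chrA = 10000, chrB = 8000),
    data.frame(
      id = c("g1", "g2", "g3", "g4", "cenA", "telA", "arsA", "int_g1",
             "sno1", "t1"),
      chrom = c("chrA", "chrA", "chrA", "chrB", "chrA", "chrA", "chrA",
                "chrA", "chrB", "chrB"),
      start = c(1000, 3000, 6000, 2000, 4900, 0, 4500, 1100, 500, 4000),
      end = c(2000, 4500, 7000, 3500, 5020, 300, 4700, 1350, 650, 4120),
      strand = c("+", "-", "+", "+", ".", ".", ".", "+", "+", "-"),
      feature_class = c("ORF", "ORF", "ORF", "ORF", "centromere",
                        "telomere", "ARS", "intron", "snRNA_snoRNA",
                        "RNAPIII"),
      expression_level = c(1200, 800, 3000, 500, NA, NA, NA, NA, NA, NA),
      gc_fraction = c(0.38, 0.42, 0.45, 0.35, NA, NA, NA, NA, NA, NA),
      stringsAsFactors = FALSE))
}

# Mirror a set of intervals / genes / probes through x -> L - x.
mirror_features <- function(genes, L) {
  out <- genes
  out$start <- L - genes$end
  out$end <- L - genes$start
  out$strand <- ifelse(genes$strand == "+", "-",
                       ifelse(genes$strand == "-", "+", "."))
  out[order(out$chrom, out$start), , drop = FALSE]
}
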