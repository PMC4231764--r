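test_that("Mann-Whitney exact P equals permutation enumeration", {
  set.seed(151)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    x <- rnorm(n)
    y <- rnorm(m)
    expect_equal(mann_whitney_p(x, y), oracle_mw_p(x, y))
  }
  # separated samples with n = m = 3 give the extreme tail
  expect_equal(mann_whitney_p(c(100, 110, 120), c(500, 510, 520)), 0.1)
})

test_that("gene-set structural comparisons contrast set against genome", {
  set.seed(161)
  cfg <- sim_config(seed = 13, n_chroms = 4, chrom_length_bp = 500000,
                    n_orfs = 1000)
  ann <- simulate_genome(cfg)
  orfs <- orf_features(ann)
  len <- orfs$end - orfs$start
  # top decile by length: strongly significant, median above genome
  top <- orfs$id[order(-len)][1:100]
  cmp <- compare_to_genome(top, ann, "length")
  expect_gt(cmp$set_median, cmp$genome_median)
  expect_lt(cmp$p_value, 0.001)
  # the whole genome against itself is null
  cmp_all <- compare_to_genome(orfs$id, ann, "length")
  expect_gt(cmp_all$p_value, 0.99)
  # uniform random sets: P should not be systematically extreme
  ps <- replicate(30, {
    compare_to_genome(sample(orfs$id, 80), ann, "length")$p_value
  })
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(min(ps), 1e-4)
  # the expression floor trims both samples
  cmp_floor <- compare_to_genome(top, ann, "expression_level",
                                 expression_floor = 600)
  expect_lt(cmp_floor$n_genome, nrow(orfs))
  expect_error(compare_to_genome(character(), ann, "length"), "empty")
})

test_that("sliding-window scores equal a brute-force window maximum", {
  ann <- genome_annotation(c(c1 = 20000), data.frame(
    id = c("flat", "peaked", "short"), chrom = "c1",
    start = c(1000, 5000, 9000), end = c(3000, 7000, 9100),
    strand = "+", feature_class = "ORF"))
  pos <- seq(0, 19950, 50)
  signal <- rep(1, length(pos))
  # one 200-bp stretch at 3.0 inside "peaked"
  hot <- pos >= 5600 & pos < 5800
  signal[hot] <- 3
  signal[pos >= 1000 & pos < 3000] <- 2
  sm <- data.frame(chrom = "c1", pos = pos, signal = signal,
                   p_value = 0.5, stringsAsFactors = FALSE)
  res <- suppressMessages(
    top_n_by_sliding_window(sm, orf_features(ann), 200, 10))
  expect_equal(res$score[res$gene_id == "flat"], 2)     # constant field
  expect_equal(res$score[res$gene_id == "peaked"], 3)   # window finds peak
  # ORF shorter than the window is scored over its whole span
  expect_equal(res$score[res$gene_id == "short"], 1)
  expect_equal(res$gene_id, c("peaked", "flat", "short"))
})

test_that("probe-anchored window maxima match all-anchor enumeration", {
  set.seed(171)
  for (i in 1:25) {
    n <- sample(20:120, 1)
    pos <- sort(sample(0:6000, n))
    sig <- rnorm(n)
    sm <- data.frame(chrom = "c1", pos = pos, signal = sig,
                     p_value = 0.5, stringsAsFactors = FALSE)
    g_start <- sample(0:1000, 1)
    g_end <- g_start + sample(600:4000, 1)
    ann <- genome_annotation(c(c1 = 10000), data.frame(
      id = "g", chrom = "c1", start = g_start, end = g_end, strand = "+",
      feature_class = "ORF"))
    res <- suppressMessages(
      top_n_by_sliding_window(sm, orf_features(ann), 200, 1))
    if (!nrow(res)) next
    # oracle: every probe anchor, means recomputed naively
    inside <- which(pos >= g_start & pos < g_end)
    anchors <- inside[pos[inside] + 200 <= g_end]
    want <- if (length(anchors)) {
      max(vapply(anchors, function(a) {
        win <- inside[pos[inside] >= pos[a] & pos[inside] < pos[a] + 200]
        mean(sig[win])
      }, numeric(1)))
    } else mean(sig[inside])
    expect_equal(res$score, want)
  }
})

test_that("top-N ranking clamps n and breaks ties by gene id", {
  ann <- genome_annotation(c(c1 = 10000), data.frame(
    id = c("b", "a"), chrom = "c1", start = c(1000, 5000),
    end = c(2000, 6000), strand = "+", feature_class = "ORF"))
  pos <- seq(0, 9950, 50)
  sm <- data.frame(chrom = "c1", pos = pos, signal = rep(1, length(pos)),
                   p_value = 0.5, stringsAsFactors = FALSE)
  res <- top_n_by_sliding_window(sm, orf_features(ann), 200, 500)
  expect_equal(nrow(res), 2)               # n clamped to the gene count
  expect_equal(res$gene_id, c("a", "b"))   # equal scores: id order
})

test_that("enrichment-expression correlation behaves at its extremes", {
  ann <- tiny_annotation()
  orfs <- orf_features(ann)
  enr <- data.frame(gene_id = orfs$id,
                    enrichment_level = log2(orfs$expression_level))
  res <- enrichment_expression_correlation(enr, ann)
  expect_equal(res$r, 1)
  expect_equal(res$n, 4)
  enr0 <- data.frame(gene_id = orfs$id, enrichment_level = 1)
  expect_error(enrichment_expression_correlation(enr0, ann),
               "zero-variance")
  # shuffled pairing decorrelates
  set.seed(181)
  cfg <- sim_config(seed = 19, n_chroms = 4, chrom_length_bp = 500000,
                    n_orfs = 1000)
  ann2 <- simulate_genome(cfg)
  orfs2 <- orf_features(ann2)
  enr2 <- data.frame(gene_id = orfs2$id,
                     enrichment_level =
                       log2(orfs2$expression_level)[sample(nrow(orfs2))])
  expect_lt(abs(enrichment_expression_correlation(enr2, ann2)$r), 0.1)
})
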