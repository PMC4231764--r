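test_that("plus-strand gene splits into 10 segments plus equal flanks", {
  g <- list(id = "g", chrom = "c", start = 0, end = 1000, strand = "+")
  segs <- segment_gene(g, chrom_length = 5000)
  expect_equal(nrow(segs), 12)
  s <- segs[segs$label == "s1", ]
  expect_equal(c(s$start, s$end), c(0, 100))
  s10 <- segs[segs$label == "s10", ]
  expect_equal(c(s10$start, s10$end), c(900, 1000))
  up <- segs[segs$label == "upstream", ]
  expect_equal(c(up$start, up$end), c(0, 0))   # clipped at chromosome start
  down <- segs[segs$label == "downstream", ]
  expect_equal(c(down$start, down$end), c(1000, 1100))
})

test_that("minus-strand bins run right-to-left genomically", {
  g <- list(id = "g", chrom = "c", start = 0, end = 1000, strand = "-")
  segs <- segment_gene(g, chrom_length = 5000)
  s1 <- segs[segs$label == "s1", ]
  expect_equal(c(s1$start, s1$end), c(900, 1000))
  up <- segs[segs$label == "upstream", ]
  expect_equal(c(up$start, up$end), c(1000, 1100))
})

test_that("remainder base pairs go to the 3'-most segments", {
  g <- list(id = "g", chrom = "c", start = 0, end = 1003, strand = "+")
  segs <- segment_gene(g, chrom_length = 5000)
  widths <- segs$end - segs$start
  orf_w <- widths[segs$label %in% paste0("s", 1:10)]
  expect_equal(orf_w, c(rep(100, 7), rep(101, 3)))
  expect_equal(sum(orf_w), 1003)
  # same gene on the minus strand: the 101-bp segments sit genomically left
  gm <- list(id = "g", chrom = "c", start = 0, end = 1003, strand = "-")
  sm <- segment_gene(gm, chrom_length = 5000)
  s10 <- sm[sm$label == "s10", ]
  expect_equal(s10$end - s10$start, 101)
  expect_equal(s10$start, 0)
  expect_error(segment_gene(list(id = "t", chrom = "c", start = 0, end = 8,
                                 strand = "+")), "shorter than 10")
})

test_that("cluster-percent profile counts per-bin incidences summing to 100", {
  ann <- genome_annotation(c(c1 = 20000), data.frame(
    id = "g1", chrom = "c1", start = 5000, end = 6000, strand = "+",
    feature_class = "ORF"))
  genes <- orf_features(ann)
  # single cluster wholly inside bin 10 ([5900,6000))
  cl <- data.frame(id = "c", chrom = "c1", start = 5910, end = 5980,
                   peak_pos = 5910, mean_signal = 1, n_probes = 2)
  prof <- cluster_distribution_profile(cl, genes, ann)
  expect_equal(as.numeric(prof), c(rep(0, 10), 100, 0),
               ignore_attr = TRUE)
  expect_equal(sum(prof), 100)
  # cluster spanning bins 9 and 10 -> two incidences, 50/50
  cl2 <- data.frame(id = "c", chrom = "c1", start = 5850, end = 5950,
                    peak_pos = 5850, mean_signal = 1, n_probes = 2)
  prof2 <- cluster_distribution_profile(cl2, genes, ann)
  expect_equal(unname(prof2[c("s9", "s10")]), c(50, 50), ignore_attr = TRUE)
  # no incidences is an error
  far <- data.frame(id = "c", chrom = "c1", start = 100, end = 300,
                    peak_pos = 100, mean_signal = 1, n_probes = 2)
  expect_error(cluster_distribution_profile(far, genes, ann), "incidence")
})

test_that("signal-mean profile averages probe signals per bin", {
  ann <- genome_annotation(c(c1 = 20000), data.frame(
    id = "g1", chrom = "c1", start = 5000, end = 6000, strand = "+",
    feature_class = "ORF"))
  genes <- orf_features(ann)
  pos <- seq(0, 19950, 50)
  sm <- data.frame(chrom = "c1", pos = pos, signal = rep(2, length(pos)),
                   p_value = 0.5, stringsAsFactors = FALSE)
  prof <- signal_mean_profile(sm, genes, ann)
  expect_equal(as.numeric(prof), rep(2, 12), ignore_attr = TRUE)
  # planted noise-free linear gradient: strictly increasing ORF bins
  smg <- sm
  inside <- smg$pos >= 5000 & smg$pos < 6000
  smg$signal <- ifelse(inside, (smg$pos - 5000) / 1000, 0)
  pg <- signal_mean_profile(smg, genes, ann)
  orfbins <- as.numeric(pg)[2:11]
  expect_true(all(diff(orfbins) > 0))
  expect_error(signal_mean_profile(sm, genes[0, ], ann), "empty gene list")
})

test_that("metagene profiles are invariant under strand mirroring", {
  set.seed(101)
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length_bp = 100000,
                    n_orfs = 40)
  ann <- simulate_genome(cfg)
  genes <- orf_features(ann)
  s <- simulate_chip_tracks(ann, cfg, "TREX2")
  sm <- smooth_track(quantile_normalize(s$track))
  cl <- call_clusters(sm)
  L <- ann$chromosomes[[1]]
  prof <- cluster_distribution_profile(cl, genes, ann)
  m_genes <- mirror_features(genes, L)
  m_cl <- cl
  m_cl$start <- L - cl$end
  m_cl$end <- L - cl$start
  m_prof <- cluster_distribution_profile(m_cl, m_genes, ann)
  expect_equal(as.numeric(m_prof), as.numeric(prof))
  # mirrored signal-mean profile: probes at L-1-pos, re-sorted
  sm2 <- sm
  sm2$pos <- L - 1 - sm$pos
  sm2 <- sm2[order(sm2$pos), ]
  m_sig <- signal_mean_profile(sm2, m_genes, ann)
  sig <- signal_mean_profile(sm, genes, ann)
  expect_equal(as.numeric(m_sig), as.numeric(sig))
})

test_that("length stratification is balanced, stable and validated", {
  genes <- data.frame(id = sprintf("g%02d", 1:9), chrom = "c",
                      start = 0, end = rep(c(500, 500, 1500), 3),
                      strand = "+", feature_class = "ORF",
                      stringsAsFactors = FALSE)
  strata <- stratify_by_length(genes, 3)
  expect_equal(lengths(lapply(strata, `[[`, "id")), c(L1 = 3, L2 = 3, L3 = 3))
  # ties broken by id: deterministic membership
  again <- stratify_by_length(genes[sample(9), ], 3)
  expect_equal(sort(strata$L1$id), sort(again$L1$id))
  expect_error(stratify_by_length(genes, 1), "n_strata")
  expect_error(stratify_by_length(genes[1:2, ], 3), "fewer genes")
})
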