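small_cfg <- function(seed = 3, n_orfs = 60, ...) {
  sim_config(seed = seed, n_chroms = 2, chrom_length_bp = 80000,
             n_orfs = n_orfs, ...)
}

test_that("the generator is a pure function of the configuration", {
  cfg <- small_cfg()
  a1 <- simulate_genome(cfg)
  a2 <- simulate_genome(cfg)
  expect_identical(a1, a2)
  t1 <- simulate_chip_tracks(a1, cfg, "TREX2")
  t2 <- simulate_chip_tracks(a2, cfg, "TREX2")
  expect_identical(t1, t2)
  e1 <- simulate_expression(a1, cfg)
  e2 <- simulate_expression(a1, cfg)
  expect_identical(e1, e2)
  # a different seed changes the draw
  expect_false(identical(simulate_genome(small_cfg(seed = 4)), a1))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(simulate_genome(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("simulated ORFs never overlap and respect chromosome bounds", {
  ann <- simulate_genome(small_cfg())
  orfs <- orf_features(ann)
  expect_equal(nrow(orfs), 60)
  for (c_ in unique(orfs$chrom)) {
    o <- orfs[orfs$chrom == c_, ]
    o <- o[order(o$start), ]
    if (nrow(o) > 1) {
      for (i in seq_len(nrow(o) - 1))
        expect_equal(overlap_bp(o[i, ], o[i + 1, ]), 0)
    }
  }
  expect_true(all(orfs$start >= 0 &
                    orfs$end <= ann$chromosomes[orfs$chrom]))
  # all feature classes are represented
  expect_setequal(unique(ann$features$feature_class), FEATURE_CLASSES)
})

test_that("n_orfs = 0 yields an annotation with only non-ORF features", {
  ann <- simulate_genome(small_cfg(n_orfs = 0))
  expect_equal(nrow(orf_features(ann)), 0)
  expect_gt(nrow(ann$features), 0)
})

test_that("an over-full genome is rejected with advice", {
  cfg <- sim_config(seed = 1, n_chroms = 1, chrom_length_bp = 30000,
                    n_orfs = 500)
  expect_error(simulate_genome(cfg), "increase chrom_length_bp")
})

test_that("zero gradient plants a flat expected profile", {
  cfg <- small_cfg(gradient_strength = 0, noise_sd = 0.05)
  ann <- simulate_genome(cfg)
  s <- simulate_chip_tracks(ann, cfg, "TREX2")
  sm <- smooth_track(quantile_normalize(s$track))
  prof <- signal_mean_profile(sm, orf_features(ann)[
    orf_features(ann)$id %in% s$truth$gene_id, ], ann)
  orfbins <- as.numeric(prof)[2:11]
  # no systematic 5'->3' trend (bin-to-bin wobble reflects which genes
  # contribute probes to which bin, not position along the gene)
  trend <- suppressWarnings(cor.test(1:10, orfbins, method = "spearman"))
  expect_gt(trend$p.value, 0.05)
})

test_that("the planted gradient is strand-aware", {
  cfg <- small_cfg(noise_sd = 0)
  ann <- simulate_genome(cfg)
  s <- simulate_chip_tracks(ann, cfg, "TREX2")
  orfs <- orf_features(ann)
  minus <- orfs[orfs$strand == "-" & orfs$id %in% s$truth$gene_id, ][1, ]
  tr <- s$track
  idx <- which(tr$chrom == minus$chrom & tr$pos >= minus$start &
                 tr$pos < minus$end)
  v <- tr$values[idx, 1]
  # minus-strand 3' end is the genomic left: signal decreases left->right
  expect_gt(v[1], v[length(v)])
  plus <- orfs[orfs$strand == "+" & orfs$id %in% s$truth$gene_id, ][1, ]
  idxp <- which(tr$chrom == plus$chrom & tr$pos >= plus$start &
                  tr$pos < plus$end)
  vp <- tr$values[idxp, 1]
  expect_lt(vp[1], vp[length(vp)])
})

test_that("occupancy amplitude increases with expression tercile", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length_bp = 200000,
                    n_orfs = 150)
  ann <- simulate_genome(cfg)
  s <- simulate_chip_tracks(ann, cfg, "TREX2")
  orfs <- orf_features(ann)
  tr <- s$truth
  tr$expr <- orfs$expression_level[match(tr$gene_id, orfs$id)]
  terc <- cut(rank(tr$expr), 3, labels = c("low", "mid", "high"))
  expect_gt(mean(tr$amplitude[terc == "high"]),
            mean(tr$amplitude[terc == "low"]))
})

test_that("mutant Rrm3-like planting elongates and extends the spans", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  wt <- simulate_chip_tracks(ann, cfg, "Rrm3", "wild_type")
  mut <- simulate_chip_tracks(ann, cfg, "Rrm3", "mutant")
  expect_gt(nrow(mut$truth), nrow(wt$truth))
  expect_gt(mean(mut$truth$end - mut$truth$start),
            mean(wt$truth$end - wt$truth$start))
})

test_that("planted DE labels follow the configured fractions and folds", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  se <- simulate_expression(ann, cfg)
  tab <- table(se$truth$label)
  expect_equal(unname(tab[["down"]]), round(0.10 * 60))
  expect_equal(unname(tab[["up"]]), round(0.05 * 60))
  expect_true(all(se$truth$fold[se$truth$label != "unchanged"] >= 2))
  # a planted down gene's mutant mean tracks wt/fold within noise
  g <- se$truth[se$truth$label == "down", ][1, ]
  em <- se$expression
  wt_m <- mean(em$values[g$gene_id, em$samples$strain == "wild_type"])
  mut_m <- mean(em$values[g$gene_id, em$samples$strain == "mutant"])
  expect_equal(mut_m / wt_m, 1 / g$fold, tolerance = 0.35)
  # de fractions of zero yield all-unchanged labels
  cfg0 <- small_cfg(de_fraction_up = 0, de_fraction_down = 0)
  se0 <- simulate_expression(simulate_genome(cfg0), cfg0)
  expect_true(all(se0$truth$label == "unchanged"))
})

test_that("unbiased DE planting leaves the length distribution unshifted", {
  cfg <- sim_config(seed = 17, n_chroms = 4, chrom_length_bp = 1000000,
                    n_orfs = 2000, de_bias = c(0, 0, 0),
                    de_fraction_down = 0.1, de_fraction_up = 0.05)
  ann <- simulate_genome(cfg)
  se <- simulate_expression(ann, cfg)
  orfs <- orf_features(ann)
  len <- orfs$end - orfs$start
  de_len <- len[orfs$id %in%
                  se$truth$gene_id[se$truth$label != "unchanged"]]
  p <- mann_whitney_p(de_len, len)
  expect_gt(p, 0.001)   # only sampling-level deviation from the genome
})

test_that("probe tracks survive a bedGraph round trip", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  s <- simulate_chip_tracks(ann, cfg, "TREX2")
  prefix <- tempfile()
  paths <- write_probe_track(s$track, prefix)
  expect_length(paths, 2)
  back <- read_probe_track(paths)
  expect_equal(back$chrom, s$track$chrom)
  expect_equal(back$pos, s$track$pos)
  expect_equal(unname(back$values), unname(s$track$values),
               tolerance = 1e-6)
})
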