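mk_em <- function(wt, mut, ids = sprintf("g%02d", seq_len(nrow(wt)))) {
  vals <- cbind(wt, mut)
  rownames(vals) <- ids
  expression_matrix(vals,
                    strain = rep(c("wild_type", "mutant"),
                                 c(ncol(wt), ncol(mut))),
                    replicate = c(seq_len(ncol(wt)), seq_len(ncol(mut))))
}

test_that("expression floor removes genes low in at least half the samples", {
  wt <- rbind(c(500, 500, 500), c(700, 700, 700), c(500, 500, 700))
  mut <- rbind(c(500, 500, 500), c(700, 700, 700), c(700, 700, 500))
  em <- mk_em(wt, mut)
  part <- apply_expression_floor(em, floor = 600, fraction = 0.5)
  expect_equal(part$filtered_low, c("g01", "g03"))  # g03: 3 of 6 below
  expect_equal(part$retained, "g02")
})

test_that("DE calls require fold, difference and P simultaneously", {
  # up: FC 1.6, diff 600, tight replicates
  wt <- rbind(c(995, 1000, 1005), c(995, 1000, 1005), c(995, 1000, 1005))
  mut <- rbind(c(1590, 1600, 1610), c(1085, 1090, 1095), c(1100, 2800, 950))
  em <- mk_em(wt, mut)
  de <- call_de(em, "wild_type", "mutant", floor = NULL)
  expect_equal(de$call[1], "up")
  expect_equal(round(de$fold_change[1], 2), 1.6)
  expect_gt(de$abs_difference[1], 100)
  # FC 1.09 < 1.5: unchanged even though P is small
  expect_equal(de$call[2], "unchanged")
  # mean ratio passes but replicate variance kills the t-test
  expect_gte(de$p_value[3], 0.05)
  expect_equal(de$call[3], "unchanged")
})

test_that("DE calling is column-order invariant and direction-symmetric", {
  set.seed(111)
  n <- 60
  wt <- matrix(rlnorm(3 * n, log(1000), 0.1), n)
  mut <- wt * rep(sample(c(1, 2, 0.5), n, replace = TRUE), 3) *
    matrix(rlnorm(3 * n, 0, 0.1), n)
  em <- mk_em(wt, mut)
  de <- call_de(em, "wild_type", "mutant")
  # shuffle sample columns
  perm <- sample(6)
  em2 <- expression_matrix(em$values[, perm],
                           em$samples$strain[perm],
                           em$samples$replicate[perm])
  de2 <- call_de(em2, "wild_type", "mutant")
  expect_equal(de$call, de2$call)
  expect_equal(de$p_value, de2$p_value)
  # swap roles: up and down exchange exactly
  de_swap <- call_de(em, "mutant", "wild_type")
  expect_equal(de_swap$call[de$call == "up"],
               rep("down", sum(de$call == "up")))
  expect_equal(de_swap$call[de$call == "down"],
               rep("up", sum(de$call == "down")))
  expect_equal(de_swap$call[de$call == "unchanged"],
               rep("unchanged", sum(de$call == "unchanged")))
})

test_that("profile correlation works over the shared floor-passing genes", {
  set.seed(121)
  n <- 40
  wt <- matrix(rlnorm(3 * n, log(2000), 0.05), n)
  fold <- rep(c(2, 1, 0.5, 1), each = 10)
  mut <- wt * fold * matrix(rlnorm(3 * n, 0, 0.05), n)
  em <- mk_em(wt, mut)
  de <- call_de(em, "wild_type", "mutant")
  expect_equal(profile_correlation(de, de), 1)
  de_neg <- de
  de_neg$log2_fold_change <- -de$log2_fold_change
  expect_equal(profile_correlation(de, de_neg), -1)
  expect_error(profile_correlation(de[1:2, ], de[1:2, ]), ">= 3")
})

test_that("profile clustering merges identical profiles first", {
  set.seed(131)
  a <- rnorm(30)
  fc <- cbind(A = a, Acopy = a, negA = -a)
  rownames(fc) <- sprintf("g%02d", 1:30)
  res <- cluster_profiles(fc, top_fraction = 1)
  expect_equal(res$merge_heights, c(0, 2), tolerance = 1e-12)
  first_pair <- sort(res$hclust$labels[-res$hclust$merge[1, ]])
  expect_equal(first_pair, c("A", "Acopy"))
  # top-fraction selection keeps the genes with largest max |log2 FC|
  res2 <- cluster_profiles(fc, top_fraction = 0.5)
  expect_equal(length(res2$genes), 15)
  kept_scores <- apply(abs(fc[res2$genes, ]), 1, max)
  dropped <- setdiff(rownames(fc), res2$genes)
  expect_gte(min(kept_scores), max(apply(abs(fc[dropped, ]), 1, max)))
  expect_error(cluster_profiles(fc[, 1, drop = FALSE]), ">= 2 profiles")
  fc0 <- fc; fc0[, 2] <- 0
  expect_error(cluster_profiles(fc0, top_fraction = 1), "Acopy")
})

test_that("relative quantitation normalizes to the reference mean ratio", {
  # target equals normalizer everywhere: all ratios 1
  rq <- relative_quantitation(c(2, 2, 3, 3), c(2, 2, 3, 3),
                              c("wild_type", "wild_type", "mut", "mut"))
  expect_equal(rq$mean, c(1, 1))
  # mutant ratio exactly twice wild type -> normalized 2.0
  rq2 <- relative_quantitation(c(1, 1, 4, 4), c(1, 1, 2, 2),
                               c("wild_type", "wild_type", "mut", "mut"))
  expect_equal(rq2$mean[rq2$condition == "mut"], 2)
  # SEM of {1,2,3} is sd/sqrt(3)
  rq3 <- relative_quantitation(c(1, 1, 2, 3), c(1, 1, 1, 1),
                               c("wild_type", "mut", "mut", "mut"))
  m <- rq3[rq3$condition == "mut", ]
  expect_equal(m$mean, 2)
  expect_equal(m$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(rq3$sem[rq3$condition == "wild_type"], NA_real_)
  expect_error(relative_quantitation(1:2, c(1, 0), c("wild_type", "m")),
               "positive")
})

test_that("expression TSV round-trips values and sample metadata", {
  set.seed(141)
  em <- mk_em(matrix(rlnorm(9, 7), 3), matrix(rlnorm(9, 7), 3))
  path <- tempfile(fileext = ".tsv")
  write_expression_tsv(em, path)
  back <- read_expression_tsv(path)
  expect_equal(unname(back$values), unname(em$values), tolerance = 1e-6)
  expect_equal(rownames(back$values), rownames(em$values))
  expect_equal(back$samples, em$samples)
})
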