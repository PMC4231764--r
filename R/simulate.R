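## Seeded synthetic-data generator: toy genome annotation, tiling probe
## tracks with planted occupancy structure, and replicate expression
## matrices with planted, structurally biased de-regulation. Every output
## is a pure function of (config, seed); ground truth is always returned
## machine-readably for downstream recovery tests.

## run expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  expr
}

## robust z-score helper (zero-variance -> zeros)
.zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulation configuration
#'
#' All tunable parameters of the synthetic genome, ChIP track and
#' expression generators, with defaults chosen to emulate a compact
#' yeast-like genome assayed at ~300-bp effective tiling resolution
#' (50-bp probe spacing, 150-bp smoothing bandwidth).
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @param n_chroms,chrom_length_bp Genome shape.
#' @param probe_spacing_bp Tiling probe spacing in bp.
#' @param n_orfs Number of non-overlapping ORFs to place.
#' @param orf_length_meanlog,orf_length_sdlog,orf_length_range Log-normal
#'   ORF length distribution (bp), truncated to the range.
#' @param gc_shape1,gc_shape2 Beta parameters of per-gene G+C fraction.
#' @param expr_meanlog,expr_sdlog Log-normal gene expression (linear A.U.).
#' @param gradient_strength Fraction of the ORF occupancy amplitude that
#'   ramps from the 5' to the 3' end (0 = flat profile, 1 = pure
#'   gradient).
#' @param amplitude_scale Scale of the monotone link between expression
#'   and occupancy amplitude, `amp = amplitude_scale * log2(1 + e/1000)`.
#' @param baseline_log2 Basal occupancy (log2) inside bound ORFs.
#' @param enriched_fraction Fraction of ORFs bound by the export-factor
#'   (TREX2-like) protein.
#' @param enrichment_expression_bias Strength of the expression bias in
#'   choosing which ORFs are bound.
#' @param noise_sd Gaussian noise SD on per-probe log2 ratios, per
#'   replicate.
#' @param n_chip_replicates,n_expr_replicates Replicate counts (ChIP
#'   default 2; expression default 3).
#' @param expr_noise_sdlog Replicate noise SD on natural-log expression.
#' @param de_fraction_up,de_fraction_down Planted DE fractions.
#' @param de_fold_range Range of planted linear fold-changes.
#' @param de_bias Length-3 vector: bias coefficients on z-scores of
#'   (log length, G+C, log expression) for planting down-regulation
#'   (negated for up-regulation).
#' @param rrm3_fraction,rrm3_fraction_mutant Fraction of ORFs carrying a
#'   planted helicase (Rrm3-like) binding block in wild type and mutant.
#' @param rrm3_expression_bias,rrm3_expression_bias_mutant Expression
#'   bias in selecting blocked ORFs.
#' @param rrm3_block_width_bp,rrm3_block_width_sdlog Log-normal planted
#'   block width (bp).
#' @param rrm3_amp_base,rrm3_amp_expr_coef Block amplitude:
#'   `base + coef * log2(1 + e/1000)`.
#' @param mutant_cluster_elongation Multiplier on planted block width in
#'   the mutant condition (> 1 elongates).
#' @param signal_taper_bp Linear decay length (bp) of the planted
#'   gradient past the ORF 3' end, emulating the spread of ChIP signal
#'   beyond feature boundaries by the chromatin fragment size.
#' @param plant_nonorf_signal Also plant blocks on telomeres and RNAPIII
#'   genes (off by default; feature-mapping recovery tests switch it on).
#' @param intergenic_gap_mean,min_gap_bp Inter-ORF gap model (bp).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 4, chrom_length_bp = 250000,
                       probe_spacing_bp = 50,
                       n_orfs = 500,
                       orf_length_meanlog = log(1200),
                       orf_length_sdlog = 0.45,
                       orf_length_range = c(300, 8000),
                       gc_shape1 = 38, gc_shape2 = 62,
                       expr_meanlog = log(1000), expr_sdlog = 1,
                       gradient_strength = 1,
                       amplitude_scale = 0.6,
                       baseline_log2 = 0,
                       enriched_fraction = 0.4,
                       enrichment_expression_bias = 1,
                       noise_sd = 0.25,
                       n_chip_replicates = 2,
                       n_expr_replicates = 3,
                       expr_noise_sdlog = 0.15,
                       de_fraction_up = 0.05,
                       de_fraction_down = 0.10,
                       de_fold_range = c(2, 4),
                       de_bias = c(length = 0.5, gc = 0.5, expression = 1),
                       rrm3_fraction = 0.30,
                       rrm3_fraction_mutant = 0.45,
                       rrm3_expression_bias = 0.5,
                       rrm3_expression_bias_mutant = 1.5,
                       rrm3_block_width_bp = 500,
                       rrm3_block_width_sdlog = 0.3,
                       rrm3_amp_base = 1.2,
                       rrm3_amp_expr_coef = 0.2,
                       mutant_cluster_elongation = 1.6,
                       signal_taper_bp = 200,
                       plant_nonorf_signal = FALSE,
                       intergenic_gap_mean = 250,
                       min_gap_bp = 60) {
  cfg <- as.list(environment())
  stopifnot(cfg$probe_spacing_bp > 0,
            cfg$gradient_strength >= 0,
            cfg$n_chroms >= 1, cfg$chrom_length_bp > 2000,
            cfg$n_orfs >= 0,
            cfg$noise_sd >= 0, cfg$expr_noise_sdlog >= 0,
            cfg$mutant_cluster_elongation > 0,
            length(cfg$de_bias) == 3, length(cfg$de_fold_range) == 2,
            all(cfg$de_fold_range >= 1))
  for (f in c("enriched_fraction", "de_fraction_up", "de_fraction_down",
              "rrm3_fraction", "rrm3_fraction_mutant")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must lie in [0,1]")
  }
  if (cfg$de_fraction_up + cfg$de_fraction_down > 1)
    stop("de fractions sum to more than 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_chroms, "x",
      x$chrom_length_bp, "bp |", x$n_orfs, "ORFs | probes every",
      x$probe_spacing_bp, "bp\n")
  invisible(x)
}

#' Simulate a toy genome annotation
#'
#' Places `n_orfs` non-overlapping ORFs on both strands with log-normal
#' lengths, Beta-distributed G+C and log-normal expression, plus
#' telomeres, a centromere per chromosome, and a few ARS, sn/snoRNA and
#' RNAPIII features in inter-ORF gaps; roughly a tenth of sufficiently
#' long ORFs receive a 5'-proximal intron. Deterministic given the
#' configuration.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()] whose ORFs carry `expression_level`
#'   and `gc_fraction`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    L <- config$chrom_length_bp
    chroms <- setNames(rep(L, config$n_chroms),
                       sprintf("chr%02d", seq_len(config$n_chroms)))
    tel_len <- 500
    cen_len <- 120
    feats <- list()
    for (cn in names(chroms)) {
      cen_start <- floor(L / 2)
      feats[[length(feats) + 1]] <- data.frame(
        id = c(paste0("tel_", cn, "_L"), paste0("tel_", cn, "_R"),
               paste0("cen_", cn)),
        chrom = cn,
        start = c(0, L - tel_len, cen_start),
        end = c(tel_len, L, cen_start + cen_len),
        strand = ".",
        feature_class = c("telomere", "telomere", "centromere"),
        stringsAsFactors = FALSE)
    }
    ## sequential ORF placement with exponential gaps, skipping the
    ## centromere and telomere reservations
    orf <- list()
    placed <- 0
    for (cn in names(chroms)) {
      if (placed >= config$n_orfs) break
      cen_start <- floor(L / 2)
      cur <- tel_len + 300
      while (placed < config$n_orfs) {
        gap <- config$min_gap_bp + round(rexp(1, 1 / config$intergenic_gap_mean))
        len <- round(rlnorm(1, config$orf_length_meanlog,
                            config$orf_length_sdlog))
        len <- min(max(len, config$orf_length_range[1]),
                   config$orf_length_range[2])
        s <- cur + gap
        e <- s + len
        if (s < cen_start + cen_len + 100 && e > cen_start - 100) {
          cur <- cen_start + cen_len + 100
          next
        }
        if (e > L - tel_len - 300) break
        placed <- placed + 1
        orf[[placed]] <- data.frame(
          id = sprintf("gene_%04d", placed), chrom = cn,
          start = s, end = e, stringsAsFactors = FALSE)
        cur <- e
      }
    }
    if (placed < config$n_orfs)
      stop("could only place ", placed, " of ", config$n_orfs,
           " ORFs; increase chrom_length_bp or n_chroms")
    if (placed > 0) {
      orf <- do.call(rbind, orf)
      orf$strand <- sample(c("+", "-"), placed, replace = TRUE)
      orf$feature_class <- "ORF"
      orf$expression_level <- rlnorm(placed, config$expr_meanlog,
                                     config$expr_sdlog)
      orf$gc_fraction <- rbeta(placed, config$gc_shape1, config$gc_shape2)
      feats[[length(feats) + 1]] <- orf
    } else orf <- NULL
    ## small non-ORF features in the largest inter-ORF gaps
    small <- data.frame(feature_class = rep(c("ARS", "snRNA_snoRNA",
                                              "RNAPIII"), each = 2),
                        len = rep(c(200, 150, 120), each = 2),
                        stringsAsFactors = FALSE)
    for (cn in names(chroms)) {
      occ <- do.call(rbind, lapply(feats, function(f)
        f[f$chrom == cn, c("start", "end")]))
      occ <- occ[order(occ$start), , drop = FALSE]
      gap_start <- c(0, occ$end)
      gap_end <- c(occ$start, L)
      w <- gap_end - gap_start
      good <- order(-w)[seq_len(min(nrow(small), sum(w >= 600)))]
      for (k in seq_along(good)) {
        g <- good[k]
        mid <- floor((gap_start[g] + gap_end[g]) / 2)
        len_k <- small$len[k]
        cls <- small$feature_class[k]
        feats[[length(feats) + 1]] <- data.frame(
          id = paste0(tolower(cls), "_", cn, "_", k), chrom = cn,
          start = mid - floor(len_k / 2), end = mid + ceiling(len_k / 2),
          strand = if (cls == "ARS") "." else sample(c("+", "-"), 1),
          feature_class = cls, stringsAsFactors = FALSE)
      }
    }
    ## 5'-proximal introns in ~10% of long ORFs
    if (!is.null(orf)) {
      eligible <- which(orf$end - orf$start >= 600)
      n_int <- round(0.1 * length(eligible))
      if (n_int > 0) {
        host <- sample(eligible, n_int)
        ilen <- sample(100:400, n_int, replace = TRUE)
        istart <- ifelse(orf$strand[host] == "+",
                         orf$start[host] + 60,
                         orf$end[host] - 60 - ilen)
        feats[[length(feats) + 1]] <- data.frame(
          id = paste0("intron_", orf$id[host]), chrom = orf$chrom[host],
          start = istart, end = istart + ilen,
          strand = orf$strand[host], feature_class = "intron",
          stringsAsFactors = FALSE)
      }
    }
    all_feats <- do.call(rbind, lapply(feats, function(f) {
      f$expression_level <- if ("expression_level" %in% names(f))
        f$expression_level else NA_real_
      f$gc_fraction <- if ("gc_fraction" %in% names(f))
        f$gc_fraction else NA_real_
      f[, c("id", "chrom", "start", "end", "strand", "feature_class",
            "expression_level", "gc_fraction")]
    }))
    genome_annotation(chroms, all_feats)
  })
}

## probe grid over all chromosomes
.probe_grid <- function(annotation, spacing) {
  grids <- lapply(names(annotation$chromosomes), function(cn)
    seq(floor(spacing / 2), annotation$chromosomes[[cn]] - 1, by = spacing))
  data.frame(
    chrom = rep(names(annotation$chromosomes), lengths(grids)),
    pos = as.integer(unlist(grids)), stringsAsFactors = FALSE)
}

#' Simulate ChIP tiling tracks with planted occupancy structure
#'
#' Two planted architectures:
#' * `factor = "TREX2"` (mRNA-export-factor-like): a fraction of ORFs,
#'   chosen with probability increasing in expression, carries occupancy
#'   `baseline + amp(e) * w(f)` where `f` is the position along the gene
#'   from 5' to 3' (strand-aware) and
#'   `w(f) = (1 - gradient_strength) + gradient_strength * f`, i.e. a
#'   3'-increasing gradient whose amplitude scales monotonically with
#'   expression. The `condition` argument does not alter this factor.
#' * `factor = "Rrm3"` (replication-obstacle-helicase-like): discrete
#'   constant-amplitude blocks centred on ORF 3' ends at a fraction of
#'   ORFs; in the `"mutant"` condition more ORFs are selected, the
#'   selection is more strongly expression-biased, and block widths are
#'   multiplied by `mutant_cluster_elongation`.
#'
#' Gaussian noise of SD `noise_sd` is added independently per replicate.
#' Planted spans are returned machine-readably as the ground truth.
#'
#' @param annotation From [simulate_genome()].
#' @param config A [sim_config()].
#' @param factor `"TREX2"` or `"Rrm3"`.
#' @param condition `"wild_type"` or `"mutant"`.
#' @return List of class `sim_chip`: `track` (a [probe_track()] with
#'   `n_chip_replicates` columns), `truth` (`data.frame` of planted spans:
#'   `chrom`, `start`, `end`, `gene_id`, `amplitude`), `factor`,
#'   `condition`.
#' @export
simulate_chip_tracks <- function(annotation, config,
                                 factor = c("TREX2", "Rrm3"),
                                 condition = c("wild_type", "mutant")) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  factor <- match.arg(factor)
  condition <- match.arg(condition)
  off <- c(TREX2 = 10, Rrm3 = 20)[[factor]] +
    c(wild_type = 1, mutant = 2)[[condition]]
  .with_seed(config$seed + off, {
    grid <- .probe_grid(annotation, config$probe_spacing_bp)
    true <- numeric(nrow(grid))
    orfs <- orf_features(annotation)
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), gene_id = character(),
                        amplitude = numeric(), stringsAsFactors = FALSE)
    if (nrow(orfs)) {
      ze <- .zscore(log(orfs$expression_level))
      amp_of <- function(e) log2(1 + e / 1000)
      if (factor == "TREX2") {
        n_sel <- round(config$enriched_fraction * nrow(orfs))
        sel <- if (n_sel > 0)
          sample(nrow(orfs), n_sel,
                 prob = exp(config$enrichment_expression_bias * ze))
          else integer()
        taper <- config$signal_taper_bp
        for (i in sel) {
          g <- orfs[i, ]
          ## planted span plus a tapered tail past the 3' end
          span <- if (g$strand == "+") c(g$start, g$end + taper)
                  else c(g$start - taper, g$end)
          idx <- which(grid$chrom == g$chrom & grid$pos >= span[1] &
                         grid$pos < span[2])
          if (!length(idx)) next
          f <- if (g$strand == "+")
            (grid$pos[idx] - g$start) / (g$end - g$start)
          else (g$end - 1 - grid$pos[idx]) / (g$end - g$start)
          w <- pmax(0, (1 - config$gradient_strength) +
                      config$gradient_strength * pmin(f, 1))
          ## downstream of the 3' end (f > 1) the signal decays linearly
          over <- f > 1
          w[over] <- w[over] *
            pmax(0, 1 - (f[over] - 1) * (g$end - g$start) / max(taper, 1))
          amp <- config$amplitude_scale * amp_of(g$expression_level)
          true[idx] <- pmax(true[idx], config$baseline_log2 + amp * w)
        }
        if (length(sel))
          truth <- data.frame(
            chrom = orfs$chrom[sel], start = orfs$start[sel],
            end = orfs$end[sel], gene_id = orfs$id[sel],
            amplitude = config$amplitude_scale *
              amp_of(orfs$expression_level[sel]),
            stringsAsFactors = FALSE)
      } else {
        frac <- if (condition == "mutant") config$rrm3_fraction_mutant
                else config$rrm3_fraction
        bias <- if (condition == "mutant")
          config$rrm3_expression_bias_mutant
          else config$rrm3_expression_bias
        elong <- if (condition == "mutant")
          config$mutant_cluster_elongation else 1
        n_sel <- round(frac * nrow(orfs))
        sel <- if (n_sel > 0)
          sample(nrow(orfs), n_sel, prob = exp(bias * ze)) else integer()
        if (length(sel)) {
          width <- rlnorm(length(sel), log(config$rrm3_block_width_bp),
                          config$rrm3_block_width_sdlog) * elong
          width <- pmin(pmax(round(width), 150), 5000)
          center <- ifelse(orfs$strand[sel] == "+", orfs$end[sel],
                           orfs$start[sel])
          clen <- annotation$chromosomes[orfs$chrom[sel]]
          bs <- pmax(0, center - floor(width / 2))
          be <- pmin(clen, center + ceiling(width / 2))
          amp <- config$rrm3_amp_base + config$rrm3_amp_expr_coef *
            amp_of(orfs$expression_level[sel])
          truth <- data.frame(chrom = orfs$chrom[sel],
                              start = as.integer(bs), end = as.integer(be),
                              gene_id = orfs$id[sel], amplitude = amp,
                              stringsAsFactors = FALSE)
        }
      }
    }
    if (factor == "Rrm3" && config$plant_nonorf_signal) {
      nf <- annotation$features
      nf <- nf[nf$feature_class %in% c("telomere", "RNAPIII"), ,
               drop = FALSE]
      if (nrow(nf)) {
        clen <- annotation$chromosomes[nf$chrom]
        truth <- rbind(truth, data.frame(
          chrom = nf$chrom,
          start = as.integer(pmax(0, nf$start - 200)),
          end = as.integer(pmin(clen, nf$end + 200)),
          gene_id = nf$id, amplitude = config$rrm3_amp_base,
          stringsAsFactors = FALSE))
      }
    }
    if (factor == "Rrm3" && nrow(truth)) {
      for (i in seq_len(nrow(truth))) {
        idx <- which(grid$chrom == truth$chrom[i] &
                       grid$pos >= truth$start[i] &
                       grid$pos < truth$end[i])
        true[idx] <- pmax(true[idx], truth$amplitude[i])
      }
    }
    ## global centering: array normalization forces the genome-wide mean
    ## log2 ratio to zero, so unbound regions sit slightly below zero
    ## when part of the genome is occupied
    true <- true - mean(true)
    vals <- true + matrix(rnorm(nrow(grid) * config$n_chip_replicates,
                                0, config$noise_sd),
                          nrow(grid), config$n_chip_replicates)
    structure(list(track = probe_track(grid$chrom, grid$pos, vals),
                   truth = truth[order(truth$chrom, truth$start), ,
                                 drop = FALSE],
                   factor = factor, condition = condition),
              class = "sim_chip")
  })
}

#' Simulate replicate expression matrices with planted de-regulation
#'
#' Wild-type means are the annotation's per-gene expression levels. A
#' configured fraction of genes is planted up- or down-regulated with
#' linear folds drawn from `de_fold_range`; down-regulated genes are
#' selected with probability increasing in gene length, G+C and
#' expression according to `de_bias` (and up-regulated genes with the
#' opposite bias), emulating the structural signature of export-factor
#' mutants. Replicate values are log-normal around the strain mean.
#'
#' @param annotation From [simulate_genome()]; ORFs must carry
#'   `expression_level`.
#' @param config A [sim_config()].
#' @return List of class `sim_expression`: `expression` (an
#'   [expression_matrix()] with strains `wild_type` and `mutant`,
#'   `n_expr_replicates` each) and `truth` (`gene_id`, `label` in
#'   `{up, down, unchanged}`, `fold`).
#' @export
simulate_expression <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(config, "sim_config"))
  orfs <- orf_features(annotation)
  if (!nrow(orfs) || anyNA(orfs$expression_level))
    stop("annotation ORFs must carry expression levels")
  .with_seed(config$seed + 30, {
    n <- nrow(orfs)
    z <- cbind(.zscore(log(orfs$end - orfs$start)),
               .zscore(orfs$gc_fraction),
               .zscore(log(orfs$expression_level)))
    b <- as.numeric(config$de_bias)
    lin <- drop(z %*% b)
    n_down <- round(config$de_fraction_down * n)
    n_up <- round(config$de_fraction_up * n)
    down <- if (n_down > 0) sample(n, n_down, prob = exp(lin)) else integer()
    rest <- setdiff(seq_len(n), down)
    up <- if (n_up > 0)
      rest[sample(length(rest), n_up, prob = exp(-lin[rest]))] else integer()
    label <- rep("unchanged", n)
    label[down] <- "down"
    label[up] <- "up"
    fold <- rep(1, n)
    fold[c(down, up)] <- runif(length(down) + length(up),
                               config$de_fold_range[1],
                               config$de_fold_range[2])
    wt_mean <- orfs$expression_level
    mut_mean <- wt_mean * ifelse(label == "up", fold,
                                 ifelse(label == "down", 1 / fold, 1))
    k <- config$n_expr_replicates
    noise <- function() exp(matrix(rnorm(n * k, 0, config$expr_noise_sdlog),
                                   n, k))
    vals <- cbind(wt_mean * noise(), mut_mean * noise())
    rownames(vals) <- orfs$id
    em <- expression_matrix(vals,
                            strain = rep(c("wild_type", "mutant"), each = k),
                            replicate = rep(seq_len(k), 2))
    structure(list(expression = em,
                   truth = data.frame(gene_id = orfs$id, label = label,
                                      fold = fold,
                                      stringsAsFactors = FALSE)),
              class = "sim_expression")
  })
}
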