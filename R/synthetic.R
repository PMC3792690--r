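# Synthetic ChIRP experiment generator with planted ground truth.
#
# Design notes:
# * One global seed drives a named substream per generator operation, so
#   changing DE parameters never perturbs peak placement.
# * True sites and noise positions are drawn from a lattice of slots spaced
#   noise_min_separation + 2 * site_jitter apart. Any two placed points are
#   therefore at least noise_min_separation apart, which (at defaults) is
#   more than twice the replication window: noise peaks can never replicate
#   and each true site's recovery is an independent Bernoulli(r^2) event.

.substream <- function(seed, name) {
  offs <- c(annotation = 11L, sites = 23L, peaks = 37L, controls = 53L,
            de = 71L)
  if (!name %in% names(offs)) stop("unknown substream: ", name)
  (as.integer(seed) %% 20000000L) * 100L + offs[[name]]
}

#' Configuration for the synthetic data generator
#'
#' Defaults describe a desk-scale genome: 5 chromosomes of 10 Mb, 2000
#' genes, 500 true RNA-binding sites with per-replicate reproducibility
#' 0.9, 500 pure-noise peaks per replicate kept >= 25 kb from everything
#' else, 200 sub-threshold peaks per replicate straddling the quality
#' filter, three 300-peak control sets with 12% of control peaks planted
#' near true sites, and a DE table whose significant genes are 94.2%
#' up-regulated and enriched for ChIRP genes at a planted odds ratio.
#'
#' @param seed Integer master seed.
#' @param chrom_lengths Named integer vector, chromosome -> length (bp).
#' @param n_genes Number of genes to place.
#' @param gene_length_range Gene length bounds (bp).
#' @param n_true_sites Number of planted binding sites.
#' @param reproducibility Probability r that a true site yields a peak in a
#'   given replicate.
#' @param n_noise_per_replicate Replicate-specific noise peaks (pass the
#'   quality filter but cannot replicate).
#' @param noise_min_separation Minimum spacing (bp) between any two planted
#'   positions; keep this above 2x the replication window.
#' @param n_subthreshold_per_replicate Peaks injected below the quality
#'   thresholds to exercise filtering.
#' @param control_n_peaks Peaks per control set (3 sets are generated).
#' @param control_near_true_frac Fraction of each control set placed within
#'   the control window of a true site.
#' @param fold_pass,fold_fail Fold-enrichment sampling bounds strictly
#'   above / not above the filter threshold.
#' @param fdr_pass,fdr_fail FDR sampling bounds strictly below / not below
#'   the filter threshold.
#' @param peak_width_range Peak width bounds in bp (sonication-scale
#'   200-800 bp fragments).
#' @param jitter_max Maximum peak-center jitter around its site (bp).
#' @param de_frac_significant Overall fraction of genes significant.
#' @param de_frac_up Fraction of significant genes up-regulated.
#' @param de_planted_odds_ratio Odds of significance for ChIRP genes
#'   relative to other genes.
#' @param lfc_meanlog,lfc_sdlog Log-normal parameters for |log2fc| of
#'   significant genes.
#' @param thresholds The [chirp_thresholds()] the generated data straddles
#'   (used for validation and for window-derived placements).
#' @return An object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(seed = 1L,
                             chrom_lengths = stats::setNames(rep(1e7, 5),
                                                             paste0("chr", 1:5)),
                             n_genes = 2000,
                             gene_length_range = c(2000, 20000),
                             n_true_sites = 500,
                             reproducibility = 0.9,
                             n_noise_per_replicate = 500,
                             noise_min_separation = 25000,
                             n_subthreshold_per_replicate = 200,
                             control_n_peaks = 300,
                             control_near_true_frac = 0.12,
                             fold_pass = c(25, 60), fold_fail = c(1, 15),
                             fdr_pass = c(1e-6, 0.04), fdr_fail = c(0.06, 0.5),
                             peak_width_range = c(200, 800),
                             jitter_max = 200,
                             de_frac_significant = 0.3,
                             de_frac_up = 0.942,
                             de_planted_odds_ratio = 2,
                             lfc_meanlog = 0, lfc_sdlog = 0.5,
                             thresholds = chirp_thresholds()) {
  cfg <- as.list(environment())
  probs <- c(reproducibility = reproducibility,
             control_near_true_frac = control_near_true_frac,
             de_frac_significant = de_frac_significant,
             de_frac_up = de_frac_up)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  counts <- c(n_genes, n_true_sites, n_noise_per_replicate,
              n_subthreshold_per_replicate, control_n_peaks)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (min(fold_pass) <= thresholds$min_fold) {
    stop("fold_pass must lie strictly above min_fold = ", thresholds$min_fold,
         call. = FALSE)
  }
  if (max(fold_fail) > thresholds$min_fold) {
    stop("fold_fail must not exceed min_fold = ", thresholds$min_fold,
         call. = FALSE)
  }
  if (max(fdr_pass) >= thresholds$max_fdr) {
    stop("fdr_pass must lie strictly below max_fdr = ", thresholds$max_fdr,
         call. = FALSE)
  }
  if (min(fdr_fail) < thresholds$max_fdr) {
    stop("fdr_fail must not lie below max_fdr = ", thresholds$max_fdr,
         call. = FALSE)
  }
  if (de_planted_odds_ratio <= 0) {
    stop("de_planted_odds_ratio must be positive", call. = FALSE)
  }
  structure(cfg, class = "SyntheticConfig")
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping genes with at least 1 kb spacing and
#' uniform random positions within each chromosome, random strand,
#' deterministic for a fixed seed. Genes are distributed across
#' chromosomes proportionally to length.
#'
#' @param config A [synthetic_config()].
#' @return A `GeneAnnotation`.
#' @export
generate_annotation <- function(config) {
  set.seed(.substream(config$seed, "annotation"))
  lens <- config$chrom_lengths
  spacing <- 1000
  chrom_of <- sample(names(lens), config$n_genes, replace = TRUE,
                     prob = lens / sum(lens))
  glen <- round(stats::runif(config$n_genes,
                             config$gene_length_range[1],
                             config$gene_length_range[2]))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  rows <- list()
  for (chrom in names(lens)) {
    idx <- which(chrom_of == chrom)
    m <- length(idx)
    if (!m) next
    free <- lens[[chrom]] - sum(glen[idx]) - (m - 1) * spacing
    if (free < 0) {
      stop("genome too small to place ", m, " genes on ", chrom,
           " with 1 kb spacing; increase chrom_lengths or reduce ",
           "n_genes/gene_length_range", call. = FALSE)
    }
    u <- sort(stats::runif(m, 0, free))
    start <- round(u) + c(0, cumsum(glen[idx][-m])) +
      (seq_len(m) - 1) * spacing
    rows[[chrom]] <- data.frame(
      chrom = chrom, start = start, end = start + glen[idx],
      strand = strand[idx], stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$start, method = "radix"), ]
  genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
  genes$gene_name <- genes$gene_id
  gene_annotation(genes)
}

# Internal: lattice of candidate positions spaced so that jittered points
# keep >= noise_min_separation between any two planted positions.
.position_lattice <- function(config, site_jitter) {
  spacing <- config$noise_min_separation + 2 * site_jitter
  slots <- list()
  for (chrom in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[chrom]]
    centers <- seq(spacing / 2, L - spacing / 2, by = spacing)
    if (length(centers)) {
      slots[[chrom]] <- data.frame(chrom = chrom, pos = round(centers),
                                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, slots)
}

# Internal: draw peaks centered (with jitter) on given positions.
.peaks_at <- function(pos_df, config, fold_range, fdr_range,
                      jitter = config$jitter_max) {
  n <- nrow(pos_df)
  width <- round(stats::runif(n, config$peak_width_range[1],
                              config$peak_width_range[2]))
  center <- pos_df$pos + round(stats::runif(n, -jitter, jitter))
  start <- pmax(0, center - floor(width / 2))
  data.frame(
    chrom = pos_df$chrom, start = start, end = start + width,
    strand = rep("*", n),
    score = rep(0, n),
    fold_enrichment = stats::runif(n, fold_range[1], fold_range[2]),
    fdr = stats::runif(n, fdr_range[1], fdr_range[2]),
    summit_offset = center - start,
    stringsAsFactors = FALSE)
}

# Internal: finalize one replicate/control sample: sort, assign ids, and
# return the PeakSet plus the provenance -> id map.
.finalize_sample <- function(df, provenance, label, role) {
  if (!nrow(df)) {
    return(list(set = peak_set(data.frame(), label = label, role = role),
                prov = character(0)))
  }
  ord <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[ord, , drop = FALSE]
  provenance <- provenance[ord]
  df$id <- sprintf("%s_peak_%05d", label, seq_len(nrow(df)))
  list(set = peak_set(df, label = label, role = role),
       prov = stats::setNames(provenance, df$id))
}

#' Generate a synthetic ChIRP experiment with planted truth
#'
#' Produces two treatment replicates, three negative-control peak sets and
#' a `GroundTruth` record. Each of the `n_true_sites` planted sites
#' independently yields a peak in each replicate with probability
#' `reproducibility`, jittered by at most `jitter_max` bp, with width in
#' `peak_width_range` and fold/FDR drawn from the pass ranges. Noise peaks
#' (pass ranges, so they survive filtering) and true sites are mutually
#' separated by at least `noise_min_separation`, so at default settings no
#' noise peak can replicate. A sub-threshold tranche (fail ranges) is
#' injected into each replicate to exercise the quality filter. Control
#' sets place `control_near_true_frac` of their peaks within half the
#' control window of a true site and the rest far from every site.
#'
#' @param config A [synthetic_config()].
#' @param annotation A `GeneAnnotation` (recorded for provenance; peak
#'   placement does not depend on it).
#' @return List with `repA`, `repB` (`PeakSet`s), `controls` (list of 3
#'   `PeakSet`s) and `truth` (class `GroundTruth`): `sites` (site_id,
#'   chrom, pos), `site_peaks` (site_id, replicate, peak_id), `noise_ids`,
#'   `subthreshold_ids`, `control_truth` (set, peak_id, near_true,
#'   site_id).
#' @export
generate_chirp_experiment <- function(config, annotation = NULL) {
  th <- config$thresholds
  if (config$noise_min_separation <= 2 * th$replication_window) {
    warning("noise_min_separation <= 2 * replication_window: noise peaks ",
            "may replicate (truth labels remain exact)")
  }
  site_jitter <- 2000
  set.seed(.substream(config$seed, "sites"))
  lattice <- .position_lattice(config, site_jitter)
  need <- config$n_true_sites + 2 * config$n_noise_per_replicate
  if (is.null(lattice) || nrow(lattice) < need) {
    stop("genome too small for ", need, " separated positions at spacing ",
         config$noise_min_separation, "; increase chrom_lengths or reduce ",
         "n_true_sites/n_noise_per_replicate", call. = FALSE)
  }
  pick <- sample(nrow(lattice), need)
  jit <- round(stats::runif(need, -site_jitter, site_jitter))
  pts <- lattice[pick, ]
  pts$pos <- pts$pos + jit
  i1 <- seq_len(config$n_true_sites)
  i2 <- config$n_true_sites + seq_len(config$n_noise_per_replicate)
  i3 <- config$n_true_sites + config$n_noise_per_replicate +
    seq_len(config$n_noise_per_replicate)
  sites <- pts[i1, , drop = FALSE]
  sites$site_id <- sprintf("site%04d", seq_len(nrow(sites)))
  noise_pos <- list(repA = pts[i2, , drop = FALSE],
                    repB = pts[i3, , drop = FALSE])

  set.seed(.substream(config$seed, "peaks"))
  reps <- list()
  site_peaks <- list()
  noise_ids <- list()
  sub_ids <- list()
  for (label in c("repA", "repB")) {
    present <- stats::runif(nrow(sites)) < config$reproducibility
    true_df <- .peaks_at(sites[present, , drop = FALSE], config,
                         config$fold_pass, config$fdr_pass)
    noise_df <- .peaks_at(noise_pos[[label]], config,
                          config$fold_pass, config$fdr_pass)
    nsub <- config$n_subthreshold_per_replicate
    sub_df <- NULL
    if (nsub > 0) {
      chrom <- sample(names(config$chrom_lengths), nsub, replace = TRUE,
                      prob = config$chrom_lengths / sum(config$chrom_lengths))
      pos <- round(stats::runif(nsub, 1000,
                                unlist(config$chrom_lengths[chrom]) - 1000))
      kind <- rep_len(c("fold", "fdr", "both"), nsub)
      sub_df <- .peaks_at(data.frame(chrom = chrom, pos = pos), config,
                          config$fold_pass, config$fdr_pass)
      fail_fold <- stats::runif(nsub, config$fold_fail[1], config$fold_fail[2])
      fail_fdr <- stats::runif(nsub, config$fdr_fail[1], config$fdr_fail[2])
      sub_df$fold_enrichment[kind != "fdr"] <- fail_fold[kind != "fdr"]
      sub_df$fdr[kind != "fold"] <- fail_fdr[kind != "fold"]
    }
    df <- rbind(true_df, noise_df, sub_df)
    prov <- c(paste0("true:", sites$site_id[present]),
              rep("noise", nrow(noise_df)),
              rep("subthreshold", if (is.null(sub_df)) 0 else nrow(sub_df)))
    fin <- .finalize_sample(df, prov, label, "treatment_replicate")
    reps[[label]] <- fin$set
    is_true <- startsWith(fin$prov, "true:")
    site_peaks[[label]] <- data.frame(
      site_id = sub("^true:", "", fin$prov[is_true]),
      replicate = label,
      peak_id = names(fin$prov)[is_true],
      stringsAsFactors = FALSE)
    noise_ids[[label]] <- names(fin$prov)[fin$prov == "noise"]
    sub_ids[[label]] <- names(fin$prov)[fin$prov == "subthreshold"]
  }

  set.seed(.substream(config$seed, "controls"))
  controls <- list()
  control_truth <- list()
  far_min <- th$control_window + 1500
  for (k in 1:3) {
    label <- paste0("ctrl", k)
    n <- config$control_n_peaks
    k_near <- round(config$control_near_true_frac * n)
    near_df <- NULL
    near_sites <- character(0)
    if (k_near > 0 && nrow(sites) > 0) {
      si <- sample(nrow(sites), k_near, replace = k_near > nrow(sites))
      off <- round(stats::runif(k_near, -th$control_window / 2,
                                th$control_window / 2))
      near_df <- .peaks_at(
        data.frame(chrom = sites$chrom[si], pos = sites$pos[si] + off),
        config, config$fold_pass, config$fdr_pass)
      near_sites <- sites$site_id[si]
    }
    k_far <- n - length(near_sites)
    far_df <- NULL
    if (k_far > 0) {
      far_df <- .peaks_at(
        .sample_far_positions(k_far, config, sites, far_min),
        config, config$fold_pass, config$fdr_pass)
    }
    df <- rbind(near_df, far_df)
    prov <- c(paste0("near:", near_sites), rep("far", k_far))
    fin <- .finalize_sample(df, prov, label, "control")
    controls[[label]] <- fin$set
    near <- startsWith(fin$prov, "near:")
    control_truth[[label]] <- data.frame(
      set = label, peak_id = names(fin$prov), near_true = near,
      site_id = ifelse(near, sub("^near:", "", fin$prov), NA_character_),
      stringsAsFactors = FALSE)
  }

  truth <- structure(list(
    sites = sites[, c("site_id", "chrom", "pos")],
    site_peaks = do.call(rbind, c(site_peaks, make.row.names = FALSE)),
    noise_ids = noise_ids,
    subthreshold_ids = sub_ids,
    control_truth = do.call(rbind, c(control_truth, make.row.names = FALSE))
  ), class = "GroundTruth")
  rownames(truth$sites) <- NULL
  list(repA = reps$repA, repB = reps$repB, controls = unname(controls),
       truth = truth)
}

# Internal: uniform positions at least `min_dist` from every true site.
.sample_far_positions <- function(n, config, sites, min_dist) {
  lens <- config$chrom_lengths
  by_chrom <- split(sites$pos, sites$chrom)
  by_chrom <- lapply(by_chrom, sort)
  out <- NULL
  guard <- 0
  while (is.null(out) || nrow(out) < n) {
    guard <- guard + 1
    if (guard > 1000) {
      stop("could not place control peaks away from true sites; the genome ",
           "is saturated", call. = FALSE)
    }
    m <- max(2 * n, 50)
    chrom <- sample(names(lens), m, replace = TRUE, prob = lens / sum(lens))
    pos <- round(stats::runif(m, 1000, unlist(lens[chrom]) - 1000))
    ok <- vapply(seq_len(m), function(i) {
      s <- by_chrom[[chrom[i]]]
      if (is.null(s)) return(TRUE)
      j <- findInterval(pos[i], s)
      d <- min(abs(pos[i] - s[pmax(j, 1)]), abs(pos[i] - s[pmin(j + 1, length(s))]))
      d >= min_dist
    }, logical(1))
    out <- rbind(out, data.frame(chrom = chrom[ok], pos = pos[ok],
                                 stringsAsFactors = FALSE))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a differential-expression table with planted enrichment
#'
#' Per-gene significance is sampled so that the odds of significance for
#' `chirp_genes` versus other genes equals `de_planted_odds_ratio` while
#' the overall significance rate is `de_frac_significant`. Significant
#' genes receive a log2 fold-change sign by `de_frac_up` and magnitude from
#' a log-normal; q-values are uniform below the significance cutoff for
#' significant genes and uniform above it otherwise (the pipeline only
#' consumes the threshold crossing).
#'
#' @param config A [synthetic_config()].
#' @param annotation A `GeneAnnotation` providing the gene universe.
#' @param chirp_genes Character vector of planted ChIRP-associated gene
#'   ids; must be a subset of the annotation.
#' @return List with `table` (data frame `gene_id`, `log2fc`, `qvalue`),
#'   `truth` (per-gene `is_chirp`, `significant`, `up`), and the solved
#'   per-class significance probabilities `p_chirp`, `p_other`.
#' @export
generate_de_table <- function(config, annotation, chirp_genes) {
  genes <- annotation$genes$gene_id
  extra <- setdiff(chirp_genes, genes)
  if (length(extra)) {
    stop("chirp_genes not in annotation: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  set.seed(.substream(config$seed, "de"))
  is_chirp <- genes %in% chirp_genes
  n1 <- sum(is_chirp); n0 <- sum(!is_chirp); N <- n1 + n0
  p <- config$de_frac_significant
  omega <- config$de_planted_odds_ratio
  p1_of <- function(p0) omega * p0 / (1 - p0 + omega * p0)
  if (p == 0 || n1 == 0) {
    p0 <- p * N / max(n0, 1)
    if (p0 > 1) stop("infeasible de_frac_significant; maximum is ", n0 / N,
                     call. = FALSE)
    p1 <- p1_of(p0)
  } else {
    f <- function(p0) (n1 * p1_of(p0) + n0 * p0) / N - p
    if (f(1) < 0) {
      stop("infeasible (de_frac_significant, de_planted_odds_ratio); ",
           "maximum overall rate is ", (n1 * p1_of(1) + n0) / N, call. = FALSE)
    }
    p0 <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
    p1 <- p1_of(p0)
  }
  prob <- ifelse(is_chirp, p1, p0)
  sig <- stats::runif(N) < prob
  up <- sig & stats::runif(N) < config$de_frac_up
  mag <- stats::rlnorm(N, config$lfc_meanlog, config$lfc_sdlog)
  log2fc <- ifelse(sig, ifelse(up, mag, -mag),
                   stats::rnorm(N, 0, 0.1))
  alpha <- config$thresholds$de_alpha
  qvalue <- ifelse(sig, stats::runif(N, 0, alpha),
                   stats::runif(N, alpha, 1))
  list(
    table = data.frame(gene_id = genes, log2fc = log2fc, qvalue = qvalue,
                       stringsAsFactors = FALSE),
    truth = data.frame(gene_id = genes, is_chirp = is_chirp,
                       significant = sig, up = up, stringsAsFactors = FALSE),
    p_chirp = p1, p_other = p0
  )
}

#' Planted ChIRP gene set: genes near true sites
#'
#' The genes within `max_dist` bp (gap distance) of any planted true site,
#' used as the planted ChIRP-associated gene set when generating the DE
#' table. The pipeline's recovered set differs slightly because it sees
#' jittered finite-width peaks at the ~r^2 recovered subset of sites.
#'
#' @param truth A `GroundTruth` from [generate_chirp_experiment()].
#' @param annotation A `GeneAnnotation`.
#' @param max_dist Distance cutoff in bp.
#' @return Sorted character vector of gene ids.
#' @export
genes_near_sites <- function(truth, annotation, max_dist = 2000) {
  s <- truth$sites
  site_iv <- data.frame(chrom = s$chrom, start = s$pos, end = s$pos + 1)
  hits <- GenomicRanges::findOverlaps(
    as_granges0(site_iv), as_granges0(annotation$genes),
    maxgap = max_dist, ignore.strand = TRUE)
  sort(unique(annotation$genes$gene_id[S4Vectors::subjectHits(hits)]))
}

#' Write a complete synthetic dataset to a directory
#'
#' Generates annotation, peak sets and DE table from `config` and writes
#' them as plain-text files: `annotation.gtf`, `repA.narrowPeak`,
#' `repB.narrowPeak`, `ctrl1..3.narrowPeak`, `de_table.tsv`, `truth.json`,
#' `config.json`, and a ready-to-run `pipeline_config.json`. Byte-identical
#' across runs for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
write_synthetic_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(config)
  exp <- generate_chirp_experiment(config, ann)
  chirp_planted <- genes_near_sites(exp$truth, ann,
                                    config$thresholds$gene_max_dist)
  de <- generate_de_table(config, ann, chirp_planted)
  paths <- list(
    gtf = file.path(outdir, "annotation.gtf"),
    repA = file.path(outdir, "repA.narrowPeak"),
    repB = file.path(outdir, "repB.narrowPeak"),
    controls = file.path(outdir, paste0("ctrl", 1:3, ".narrowPeak")),
    de_table = file.path(outdir, "de_table.tsv"),
    truth = file.path(outdir, "truth.json"),
    config = file.path(outdir, "config.json"),
    pipeline_config = file.path(outdir, "pipeline_config.json")
  )
  write_gtf(ann, paths$gtf)
  write_narrowpeak(exp$repA, paths$repA)
  write_narrowpeak(exp$repB, paths$repB)
  for (i in 1:3) write_narrowpeak(exp$controls[[i]], paths$controls[i])
  write_de_table(de$table, paths$de_table)
  truth_out <- exp$truth
  truth_out$de <- de$truth
  truth_out$planted_chirp_genes <- chirp_planted
  jsonlite::write_json(unclass(truth_out), paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  cfg_out <- unclass(config)
  cfg_out$thresholds <- unclass(cfg_out$thresholds)
  cfg_out$chrom_lengths <- as.list(cfg_out$chrom_lengths)
  jsonlite::write_json(cfg_out, paths$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  # paths relative to the dataset directory keep the config portable and
  # the emitted files byte-identical across runs in different directories
  pc <- list(repA = basename(paths$repA), repB = basename(paths$repB),
             controls = as.list(basename(paths$controls)),
             gtf = basename(paths$gtf),
             de_table = basename(paths$de_table),
             outdir = "results",
             thresholds = unclass(config$thresholds))
  jsonlite::write_json(pc, paths$pipeline_config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(annotation = ann, experiment = exp, de = de,
                 planted_chirp_genes = chirp_planted, paths = paths))
}
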