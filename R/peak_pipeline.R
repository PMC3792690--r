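# Peak quality filtering, windowed replicate consensus, and negative-control
# proximity screening.

#' Pipeline thresholds
#'
#' Collects the numeric cutoffs of the analysis. The defaults are the
#' published operating point: peaks kept at FDR < 5% and fold-enrichment
#' over input > 20 (both strict), replication and control windows of 10 kb,
#' closest-gene assignment within 2 kb, and differential-expression
#' significance at q < 0.05.
#'
#' @param max_fdr Maximum FDR (exclusive) for a peak to pass filtering.
#' @param min_fold Minimum fold-enrichment (exclusive).
#' @param replication_window Window in bp for calling a peak replicated.
#' @param control_window Window in bp for flagging control proximity.
#' @param gene_max_dist Maximum peak-to-gene gap in bp for assignment.
#' @param de_alpha q-value cutoff (exclusive) for DE significance.
#' @return An object of class `chirp_thresholds`.
#' @export
chirp_thresholds <- function(max_fdr = 0.05, min_fold = 20,
                             replication_window = 10000,
                             control_window = 10000,
                             gene_max_dist = 2000, de_alpha = 0.05) {
  th <- list(max_fdr = max_fdr, min_fold = min_fold,
             replication_window = replication_window,
             control_window = control_window,
             gene_max_dist = gene_max_dist, de_alpha = de_alpha)
  num <- vapply(th, function(x) is.numeric(x) && length(x) == 1 && x >= 0,
                logical(1))
  if (!all(num)) {
    stop("thresholds must be single non-negative numbers: ",
         paste(names(th)[!num], collapse = ", "), call. = FALSE)
  }
  if (max_fdr <= 0 || max_fdr > 1) stop("max_fdr must lie in (0,1]", call. = FALSE)
  if (de_alpha <= 0 || de_alpha > 1) stop("de_alpha must lie in (0,1]", call. = FALSE)
  structure(th, class = "chirp_thresholds")
}

#' Filter peaks on FDR and fold-enrichment
#'
#' Keeps peaks with `fdr < max_fdr` and `fold_enrichment > min_fold`, both
#' inequalities strict. Peaks missing either statistic fail the filter
#' (conservative). Input order is preserved.
#'
#' @param peakset A `PeakSet`.
#' @param thresholds A [chirp_thresholds()] object.
#' @return A `PeakSet` containing the passing subset.
#' @export
filter_peaks <- function(peakset, thresholds = chirp_thresholds()) {
  p <- peakset$peaks
  keep <- !is.na(p$fdr) & !is.na(p$fold_enrichment) &
    p$fdr < thresholds$max_fdr & p$fold_enrichment > thresholds$min_fold
  peak_set(p[keep, , drop = FALSE], label = peakset$label, role = peakset$role)
}

# Internal: GRanges used for window matching. mode "gap" uses the peak
# interval; mode "summit" collapses each peak to its summit point
# (midpoint when the summit is absent).
matching_granges <- function(df, mode) {
  if (mode == "summit") {
    pos <- ifelse(is.na(df$summit_offset),
                  interval_midpoint(df),
                  df$start + df$summit_offset)
    df <- data.frame(chrom = df$chrom, start = pos, end = pos + 1)
  }
  as_granges0(df)
}

#' Identify peaks replicated between two treatment replicates
#'
#' A peak of replicate A is called replicated when some peak of replicate B
#' lies within `window` bp of it (gap distance; 0 means overlap or
#' adjacency). One consensus peak is produced per replicated A peak: A is
#' the anchor, its interval the representative (or the union span of A with
#' all its B partners when `representative = "union"`). With
#' `mode = "summit"` the window is measured between summit points instead
#' of interval gaps.
#'
#' @param repA,repB Filtered `PeakSet`s of the two treatment replicates.
#' @param window Window in bp (>= 0).
#' @param mode Window semantics: `"gap"` (interval gap, default) or
#'   `"summit"` (summit-to-summit distance).
#' @param representative `"anchor"` (A's interval) or `"union"`.
#' @return An object of class `ConsensusResult` with elements `consensus`
#'   (data frame of consensus peaks), `n_repA_in`, `n_repB_in`,
#'   `n_replicated`, plus the control-screening fields once
#'   [flag_control_proximity()] has run.
#' @export
replicate_consensus <- function(repA, repB, window = 10000,
                                mode = c("gap", "summit"),
                                representative = c("anchor", "union")) {
  mode <- match.arg(mode)
  representative <- match.arg(representative)
  if (!is.numeric(window) || length(window) != 1 || is.na(window) || window < 0) {
    stop("window must be a single non-negative number", call. = FALSE)
  }
  a <- repA$peaks
  b <- repB$peaks
  grA <- matching_granges(a, mode)
  grB <- matching_granges(b, mode)
  hits <- GenomicRanges::findOverlaps(grA, grB, maxgap = window,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ord <- order(qh, sh)  # partners listed in replicate-B input order
  qh <- qh[ord]
  sh <- sh[ord]
  gaps <- rep(0, length(qh))
  if (length(qh)) {
    gaps <- GenomicRanges::distance(grA[qh], grB[sh], ignore.strand = TRUE)
  }
  rep_idx <- sort(unique(qh))
  consensus <- a[rep_idx, c("id", "chrom", "start", "end"), drop = FALSE]
  split_f <- factor(qh, levels = rep_idx)
  consensus$support_a <- a$id[rep_idx]
  consensus$support_b <- vapply(split(b$id[sh], split_f),
                                paste, character(1), collapse = ",")
  consensus$n_partners <- as.integer(table(split_f))
  consensus$min_partner_gap <- as.numeric(vapply(split(gaps, split_f),
                                                 min, numeric(1)))
  if (representative == "union" && nrow(consensus)) {
    bs <- split(b$start[sh], split_f)
    be <- split(b$end[sh], split_f)
    consensus$start <- pmin(consensus$start, vapply(bs, min, numeric(1)))
    consensus$end <- pmax(consensus$end, vapply(be, max, numeric(1)))
  }
  consensus$nearest_control_gap <- rep(NA_real_, nrow(consensus))
  consensus$control_proximal <- rep(NA, nrow(consensus))
  rownames(consensus) <- NULL
  structure(list(
    consensus = consensus,
    label_a = repA$label, label_b = repB$label,
    window = window, mode = mode, representative = representative,
    n_repA_in = nrow(a), n_repB_in = nrow(b),
    n_replicated = nrow(consensus),
    n_control_proximal = NA_integer_,
    n_controls_within_window = NA_integer_,
    control_window = NA_real_
  ), class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult:", x$n_replicated, "replicated peaks (",
      x$n_repA_in, "A /", x$n_repB_in, "B in, window", x$window, "bp)\n")
  if (!is.na(x$n_control_proximal)) {
    cat("  control-proximal:", x$n_control_proximal,
        "| specific:", x$n_replicated - x$n_control_proximal, "\n")
  }
  invisible(x)
}

#' Screen consensus peaks for proximity to negative-control peaks
#'
#' Pools all control peak sets and annotates every consensus peak with its
#' gap distance to the nearest control peak (`Inf` when no control peak
#' shares its chromosome). A peak is `control_proximal` when that gap is
#' <= `window`; the complement is the RNA-specific subset used downstream.
#' Also reports, from the control side, how many pooled control peaks fall
#' within `window` of any consensus peak.
#'
#' @param consensus A `ConsensusResult` from [replicate_consensus()].
#' @param controls A `PeakSet` or list of `PeakSet`s (negative controls).
#' @param window Window in bp (>= 0).
#' @return The updated `ConsensusResult`.
#' @export
flag_control_proximity <- function(consensus, controls, window = 10000) {
  if (!is.numeric(window) || length(window) != 1 || is.na(window) || window < 0) {
    stop("window must be a single non-negative number", call. = FALSE)
  }
  if (inherits(controls, "PeakSet")) controls <- list(controls)
  if (!length(controls)) stop("controls must be non-empty", call. = FALSE)
  pooled <- do.call(rbind, lapply(controls, function(s) s$peaks))
  cons <- consensus$consensus
  gap <- rep(Inf, nrow(cons))
  n_ctrl_within <- 0L
  if (nrow(pooled) && nrow(cons)) {
    grC <- as_granges0(cons)
    grX <- as_granges0(pooled)
    # suppressWarnings: disjoint seqlevels between query and subject are a
    # legitimate situation (nearest gap is Inf), not a user error
    nh <- suppressWarnings(
      GenomicRanges::distanceToNearest(grC, grX, ignore.strand = TRUE))
    gap[S4Vectors::queryHits(nh)] <- as.numeric(S4Vectors::mcols(nh)$distance)
    n_ctrl_within <- sum(suppressWarnings(GenomicRanges::countOverlaps(
      grX, grC, maxgap = window, ignore.strand = TRUE)) > 0)
  }
  cons$nearest_control_gap <- gap
  cons$control_proximal <- gap <= window
  consensus$consensus <- cons
  consensus$n_control_proximal <- sum(cons$control_proximal)
  consensus$n_controls_within_window <- as.integer(n_ctrl_within)
  consensus$control_window <- window
  consensus
}

#' Extract the control-specific consensus peaks
#'
#' @param consensus A `ConsensusResult` after [flag_control_proximity()].
#' @return Data frame of consensus peaks with `control_proximal = FALSE`.
#' @export
specific_peaks <- function(consensus) {
  cons <- consensus$consensus
  if (nrow(cons) && anyNA(cons$control_proximal)) {
    stop("run flag_control_proximity() before extracting specific peaks",
         call. = FALSE)
  }
  cons[which(!cons$control_proximal), , drop = FALSE]
}

#' Pairwise windowed overlap fractions between peak sets
#'
#' Entry (i, j) is the fraction of set i's peaks that have at least one
#' peak of set j within `window` bp (gap distance). The matrix is
#' asymmetric in general; the diagonal is 1 for non-empty sets. Rows for
#' empty sets are `NA` and flagged in the `"undefined_rows"` attribute
#' rather than reported as 0.
#'
#' @param peaksets List of two or more `PeakSet`s.
#' @param window Window in bp.
#' @return Numeric matrix with rows/columns named by set labels.
#' @export
pairwise_window_overlap <- function(peaksets, window = 10000) {
  if (length(peaksets) < 2) stop("need at least 2 peak sets", call. = FALSE)
  if (window < 0) stop("window must be non-negative", call. = FALSE)
  labels <- vapply(peaksets, function(s) s$label, character(1))
  grs <- lapply(peaksets, function(s) as_granges0(s$peaks))
  n <- length(peaksets)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  sizes <- vapply(grs, length, integer(1))
  for (i in seq_len(n)) {
    if (sizes[i] == 0) next
    for (j in seq_len(n)) {
      hit <- GenomicRanges::countOverlaps(grs[[i]], grs[[j]],
                                          maxgap = window,
                                          ignore.strand = TRUE) > 0
      m[i, j] <- mean(hit)
    }
  }
  attr(m, "undefined_rows") <- labels[sizes == 0]
  m
}
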