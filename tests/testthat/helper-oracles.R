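# Quadratic brute-force oracles and tiny fixture builders. The oracles are
# deliberately independent of the package's interval-index code paths: they
# enumerate all pairs with plain arithmetic.

bf_gap1 <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(Inf)
  max(0, s2 - e1, s1 - e2)
}

# all-pairs replicate matching: returns per-A-row list of B indices within
# window, plus the min gap
bf_replicate <- function(a, b, window) {
  lapply(seq_len(nrow(a)), function(i) {
    gaps <- vapply(seq_len(nrow(b)), function(j) {
      bf_gap1(a$chrom[i], a$start[i], a$end[i],
              b$chrom[j], b$start[j], b$end[j])
    }, numeric(1))
    hit <- which(gaps <= window)
    list(partners = b$id[hit], min_gap = if (length(hit)) min(gaps[hit]) else Inf)
  })
}

bf_nearest_gap <- function(x, y) {
  vapply(seq_len(nrow(x)), function(i) {
    if (!nrow(y)) return(Inf)
    min(vapply(seq_len(nrow(y)), function(j) {
      bf_gap1(x$chrom[i], x$start[i], x$end[i],
              y$chrom[j], y$start[j], y$end[j])
    }, numeric(1)))
  }, numeric(1))
}

# all-pairs closest-gene assignment with the documented tie rule
bf_assign <- function(peaks, genes, max_dist) {
  mid <- floor((peaks$start + peaks$end) / 2)
  do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    gaps <- vapply(seq_len(nrow(genes)), function(j) {
      bf_gap1(peaks$chrom[i], peaks$start[i], peaks$end[i],
              genes$chrom[j], genes$start[j], genes$end[j])
    }, numeric(1))
    best <- min(gaps)
    if (!is.finite(best) || best > max_dist) {
      return(data.frame(peak_id = peaks$id[i], gene_id = NA_character_,
                        distance = NA_real_, tie_broken = FALSE))
    }
    cand <- which(gaps == best)
    tie <- length(cand) > 1
    tb <- abs(mid[i] - genes$tss[cand])
    cand <- cand[order(tb, genes$gene_id[cand])]
    data.frame(peak_id = peaks$id[i], gene_id = genes$gene_id[cand[1]],
               distance = best, tie_broken = tie)
  }))
}

random_peak_df <- function(n, prefix = "p", chroms = c("chr1", "chr2"),
                           span = 2e5, max_width = 2000) {
  start <- floor(runif(n, 0, span))
  width <- 1 + floor(runif(n, 0, max_width))
  data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

random_gene_df <- function(n, chroms = c("chr1", "chr2"), span = 2e5) {
  df <- random_peak_df(n, prefix = "g", chroms = chroms, span = span,
                       max_width = 5000)
  data.frame(gene_id = df$id, gene_name = df$id, chrom = df$chrom,
             start = df$start, end = df$end,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# quick peak-set builder: intervals plus optional quality stats
mk_peaks <- function(chrom, start, end, id = NULL, fold = NA, fdr = NA,
                     label = "s", role = "treatment_replicate") {
  n <- length(start)
  if (n == 0) return(peak_set(data.frame(), label = label, role = role))
  if (is.null(id)) id <- sprintf("%s_%d", label, seq_len(n))
  peak_set(data.frame(id = id, chrom = chrom, start = start, end = end,
                      fold_enrichment = fold, fdr = fdr,
                      stringsAsFactors = FALSE),
           label = label, role = role)
}

mk_annotation <- function(...) gene_annotation(data.frame(...))
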