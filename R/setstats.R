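# Differential-expression summaries and 2x2 gene-set overlap enrichment.

#' Summarize a differential-expression table
#'
#' A gene is significant when `qvalue < alpha` (strict). Among significant
#' genes, up means `log2fc > 0` and down `log2fc < 0`; genes with
#' `log2fc == 0` are counted separately and belong to neither.
#'
#' @param records Data frame with columns `gene_id`, `log2fc`, `qvalue`
#'   (one row per gene; duplicate ids are an error).
#' @param alpha q-value cutoff.
#' @return An object of class `DESummary` with counts `n_tested`,
#'   `n_significant`, `n_up`, `n_down`, `n_zero` and `frac_up`
#'   (percentage of significant genes up-regulated; `NA` and flagged via
#'   `frac_up_defined = FALSE` when nothing is significant).
#' @export
de_summary <- function(records, alpha = 0.05) {
  if (anyDuplicated(records$gene_id)) {
    dup <- records$gene_id[duplicated(records$gene_id)][1]
    stop("duplicate gene_id in DE table: ", dup, call. = FALSE)
  }
  sig <- records$qvalue < alpha
  up <- sig & records$log2fc > 0
  down <- sig & records$log2fc < 0
  zero <- sig & records$log2fc == 0
  n_sig <- sum(sig)
  structure(list(
    n_tested = nrow(records),
    n_significant = n_sig,
    n_up = sum(up),
    n_down = sum(down),
    n_zero = sum(zero),
    frac_up = if (n_sig > 0) 100 * sum(up) / n_sig else NA_real_,
    frac_up_defined = n_sig > 0,
    alpha = alpha,
    significant_genes = records$gene_id[sig]
  ), class = "DESummary")
}

#' @export
print.DESummary <- function(x, ...) {
  cat("DESummary:", x$n_significant, "of", x$n_tested,
      "genes significant (q <", x$alpha, ")\n")
  if (x$frac_up_defined) {
    cat(sprintf("  up: %d (%.1f%%)  down: %d  log2fc==0: %d\n",
                x$n_up, x$frac_up, x$n_down, x$n_zero))
  }
  invisible(x)
}

#' Build a 2x2 contingency table of gene-set membership
#'
#' Counts, over a stated gene universe, genes in both sets (`a`), in A only
#' (`b`), in B only (`c`) and in neither (`d`).
#'
#' @param setA,setB Character vectors of gene ids; must be subsets of
#'   `universe` (violations are an error listing the offenders).
#' @param universe Character vector, the gene universe (non-empty).
#' @return An object of class `ContingencyTable2x2` with fields
#'   `a`, `b`, `c`, `d` and `n`.
#' @export
overlap_counts <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  setA <- unique(setA)
  setB <- unique(setB)
  for (nm in c("setA", "setB")) {
    s <- get(nm)
    out <- setdiff(s, universe)
    if (length(out)) {
      stop(nm, " contains ", length(out), " gene(s) outside the universe: ",
           paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
    }
  }
  inA <- universe %in% setA
  inB <- universe %in% setB
  structure(list(
    a = sum(inA & inB), b = sum(inA & !inB),
    c = sum(!inA & inB), d = sum(!inA & !inB),
    n = length(universe)
  ), class = "ContingencyTable2x2")
}

#' @export
print.ContingencyTable2x2 <- function(x, ...) {
  cat("2x2 contingency (n =", x$n, "):\n")
  cat(sprintf("  a=%d b=%d\n  c=%d d=%d\n", x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Computes the Pearson statistic sum((O - E)^2 / E) over the four cells
#' with expected counts from the margins, 1 degree of freedom, upper-tail
#' p-value, and the sample odds ratio (a*d)/(b*c) (`Inf` when `b*c = 0`
#' and `a*d > 0`). No continuity correction by default; set
#' `correct = TRUE` for the Yates-corrected statistic. Degenerate margins
#' (a row or column summing to 0) are an error. A `low_expected_warning`
#' flag is set when any expected count is below 5.
#'
#' @param table A `ContingencyTable2x2` or a list with fields `a,b,c,d`.
#' @param correct Apply the Yates continuity correction.
#' @return An object of class `EnrichmentResult` with `chi2`, `df`,
#'   `pvalue`, `odds_ratio`, `low_expected_warning`.
#' @export
chi_squared_2x2 <- function(table, correct = FALSE) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells) | cells < 0)) {
    stop("contingency counts must be non-negative", call. = FALSE)
  }
  n <- a + b + c + d
  rows <- c(a + b, c + d)
  cols <- c(a + c, b + d)
  if (any(rows == 0) || any(cols == 0)) {
    stop("degenerate margin: a row or column of the 2x2 table sums to 0",
         call. = FALSE)
  }
  expected <- outer(rows, cols) / n
  observed <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / expected)
  odds <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  structure(list(
    chi2 = chi2, df = 1L,
    pvalue = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    odds_ratio = odds,
    low_expected_warning = any(expected < 5),
    corrected = correct
  ), class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g (df = 1), p = %.3g, odds ratio = %.3g\n",
              x$chi2, x$pvalue, x$odds_ratio))
  if (x$low_expected_warning) cat("  warning: expected count < 5\n")
  invisible(x)
}

#' Overlap percentage
#'
#' `100 * n_overlap / n_total`, reported at full precision and rounded to
#' the nearest integer (halves away from zero).
#'
#' @param n_overlap Count of overlapping genes (0 <= n_overlap <= n_total).
#' @param n_total Total count (> 0).
#' @return List with `percent` and `rounded`.
#' @export
overlap_percentage <- function(n_overlap, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_overlap < 0 || n_overlap > n_total) {
    stop("need 0 <= n_overlap <= n_total", call. = FALSE)
  }
  pct <- 100 * n_overlap / n_total
  list(percent = pct, rounded = sign(pct) * floor(abs(pct) + 0.5))
}
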