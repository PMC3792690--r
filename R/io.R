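# Readers and writers for the plain-text genomic formats the pipeline
# touches: ENCODE narrowPeak / BED6 peak files, GTF annotations and
# tab-separated differential-expression tables.  All coordinates are
# normalised to 0-based half-open on read.

PEAK_COLUMNS <- c("id", "chrom", "start", "end", "strand",
                  "score", "fold_enrichment", "fdr", "summit_offset")

#' Construct a peak set
#'
#' A peak set bundles the called peaks of one sample with its label and its
#' role in the experiment (treatment replicate, negative control, or other).
#' Peaks are stored as a data frame with 0-based half-open coordinates and
#' per-peak fold-enrichment over input, FDR and summit offset (`NA` when the
#' source format does not carry them).
#'
#' @param peaks Data frame with columns `id`, `chrom`, `start`, `end` and
#'   optionally `strand`, `score`, `fold_enrichment`, `fdr`, `summit_offset`.
#' @param label Sample name.
#' @param role One of `"treatment_replicate"`, `"control"`, `"other"`.
#' @return An object of class `PeakSet`.
#' @export
peak_set <- function(peaks, label = "sample",
                     role = c("treatment_replicate", "control", "other")) {
  role <- match.arg(role)
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  for (col in PEAK_COLUMNS) {
    if (!col %in% names(peaks)) {
      peaks[[col]] <- rep(switch(col, strand = "*", NA), nrow(peaks))
    }
  }
  peaks <- peaks[, PEAK_COLUMNS, drop = FALSE]
  if (nrow(peaks)) {
    validate_intervals(peaks, what = "peak")
    if (anyDuplicated(peaks$id)) {
      dup <- peaks$id[duplicated(peaks$id)][1]
      stop("duplicate peak id in set '", label, "': ", dup, call. = FALSE)
    }
    so <- peaks$summit_offset
    bad <- which(!is.na(so) & (so < 0 | so >= peaks$end - peaks$start))
    if (length(bad)) {
      stop("peak ", peaks$id[bad[1]], ": summit_offset outside interval",
           call. = FALSE)
    }
    fe <- peaks$fold_enrichment
    if (any(!is.na(fe) & fe < 0)) stop("fold_enrichment must be >= 0", call. = FALSE)
    q <- peaks$fdr
    if (any(!is.na(q) & (q < 0 | q > 1))) stop("fdr must lie in [0,1]", call. = FALSE)
  }
  rownames(peaks) <- NULL
  structure(list(label = label, role = role, peaks = peaks),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat("PeakSet '", x$label, "' (", x$role, "): ", nrow(x$peaks),
      " peaks\n", sep = "")
  invisible(x)
}

#' Number of peaks in a set
#' @param x A `PeakSet`.
#' @return Integer count.
#' @export
n_peaks <- function(x) nrow(x$peaks)

#' Read a narrowPeak or BED6 peak file
#'
#' Accepts ENCODE narrowPeak (10 columns) or BED6 (6 columns); the two may
#' not be mixed within a file. narrowPeak column 7 becomes
#' `fold_enrichment`, column 9 (-log10 q-value) is converted to a linear
#' `fdr = 10^(-q)` so the FDR < 5% filter compares on the printed scale, and
#' column 10 becomes `summit_offset`; a value of -1 in columns 8-10 means
#' "absent" and maps to `NA`. BED6 lines yield peaks with all three absent.
#'
#' @param path Path to the file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param label Sample label; defaults to the file name without extension.
#' @param role Role of the sample (see [peak_set()]).
#' @return A `PeakSet`.
#' @export
read_narrowpeak <- function(path, label = NULL,
                            role = c("treatment_replicate", "control", "other")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("peak file not found: ", path, call. = FALSE)
  if (is.null(label)) {
    label <- sub("\\.(narrowPeak|bed|txt)$", "", basename(path))
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(peak_set(data.frame(), label = label, role = role))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(6L, 10L)))
  if (length(bad)) {
    stop("line ", lineno[bad[1]], " of ", path, ": expected 6 or 10 ",
         "tab-separated columns, found ", nf[bad[1]], call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, function(f) c(f, rep(NA, 10 - length(f)))))
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(v) & !is.na(m[, col]))
    if (length(bad)) {
      stop("line ", lineno[bad[1]], " of ", path, ": non-numeric ", what,
           " '", m[bad[1], col], "'", call. = FALSE)
    }
    v
  }
  start <- num(2, "start")
  end <- num(3, "end")
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad)) {
    stop("line ", lineno[bad[1]], " of ", path,
         ": invalid interval (need 0 <= start < end)", call. = FALSE)
  }
  strand <- m[, 6]
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad)) {
    stop("line ", lineno[bad[1]], " of ", path, ": unknown strand '",
         strand[bad[1]], "'", call. = FALSE)
  }
  strand[strand == "."] <- "*"
  absent <- function(v) ifelse(!is.na(v) & v == -1, NA, v)
  fold <- absent(num(7, "signalValue"))
  qneg <- absent(num(9, "qValue"))
  summit <- absent(num(10, "summit"))
  id <- m[, 4]
  noid <- is.na(id) | id == "." | !nzchar(id)
  id[noid] <- sprintf("%s_peak_%d", label, which(noid))
  peaks <- data.frame(
    id = id, chrom = m[, 1], start = start, end = end, strand = strand,
    score = num(5, "score"),
    fold_enrichment = fold,
    fdr = 10^(-qneg),
    summit_offset = summit,
    stringsAsFactors = FALSE
  )
  peak_set(peaks, label = label, role = role)
}

#' Write peaks as BED6
#'
#' Emits one BED6 record per peak (0-based half-open), name column set to
#' the peak id, deterministically sorted by (chrom, start, end, id),
#' tab-separated, LF-terminated, no header.
#'
#' @param peaks A `PeakSet`, a peak data frame, or a `ConsensusResult`
#'   (whose consensus peaks are written).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(peaks, path) {
  df <- peak_table(peaks)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$start, df$end, df$id, method = "radix"), ]
    score <- if ("score" %in% names(df)) ifelse(is.na(df$score), 0, df$score) else 0
    strand <- if ("strand" %in% names(df)) {
      s <- df$strand; s[is.na(s) | s == "*"] <- "."; s
    } else "."
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     df$chrom, as.integer(df$start), as.integer(df$end),
                     df$id, score, strand)
  } else {
    lines <- character(0)
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Write peaks as ENCODE narrowPeak
#'
#' Ten-column narrowPeak output, the inverse of [read_narrowpeak()]:
#' absent fold-enrichment/FDR/summit values are encoded as -1, FDR is
#' written as -log10(q). Sorted like [write_bed()].
#'
#' @inheritParams write_bed
#' @return The path, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- peak_table(peaks)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$start, df$end, df$id, method = "radix"), ]
    enc <- function(v) ifelse(is.na(v), -1, v)
    strand <- df$strand
    strand[is.na(strand) | strand == "*"] <- "."
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%s\t%d\t%s\t%d",
                     df$chrom, as.integer(df$start), as.integer(df$end),
                     df$id, enc(df$score), strand,
                     formatC(enc(df$fold_enrichment), digits = 6, format = "g"),
                     -1L,
                     formatC(ifelse(is.na(df$fdr), -1, -log10(df$fdr)),
                             digits = 6, format = "g"),
                     as.integer(enc(df$summit_offset)))
  } else {
    lines <- character(0)
  }
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

# Internal: extract a plain peak data frame from the containers write_bed
# accepts.
peak_table <- function(x) {
  if (inherits(x, "PeakSet")) return(x$peaks)
  if (inherits(x, "ConsensusResult")) return(x$consensus)
  as.data.frame(x, stringsAsFactors = FALSE)
}

#' Construct a gene annotation
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+` or `-`) and optionally `gene_name`.
#'   The transcription start site is derived from the strand: `start` for
#'   `+` genes, `end - 1` for `-` genes.
#' @return An object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(genes) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!nrow(genes)) stop("annotation has no usable gene records", call. = FALSE)
  if (!"gene_name" %in% names(genes)) genes$gene_name <- genes$gene_id
  validate_intervals(genes, what = "gene")
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1],
         call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("genes must be stranded (+ or -); unstranded records are rejected",
         call. = FALSE)
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes <- genes[, c("gene_id", "gene_name", "chrom", "start", "end",
                     "strand", "tss")]
  rownames(genes) <- NULL
  structure(list(genes = genes), class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat("GeneAnnotation:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosomes\n")
  invisible(x)
}

#' Read a gene annotation from GTF
#'
#' Gene extents are taken from feature type `"gene"` when present, otherwise
#' inferred as the span of each `gene_id`'s exons. GTF's 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#' Records without a `gene_id` attribute are skipped with a warning;
#' duplicate `gene_id` records on one chromosome and strand are merged to
#' their union span. Unstranded gene records are dropped with a warning
#' because the TSS cannot be derived for them.
#'
#' @param path Path to a GTF file.
#' @return A `GeneAnnotation`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta)) {
    stop("no usable gene records in ", path, " (no gene_id attributes)",
         call. = FALSE)
  }
  no_id <- is.na(meta$gene_id) | !nzchar(as.character(meta$gene_id))
  if (any(no_id)) {
    warning(sum(no_id), " GTF record(s) without gene_id skipped")
    gr <- gr[!no_id]
    meta <- S4Vectors::mcols(gr)
  }
  type <- as.character(meta$type)
  use <- if (any(type == "gene")) gr[type == "gene"] else gr[type == "exon"]
  if (!length(use)) stop("no usable gene records in ", path, call. = FALSE)
  df <- data.frame(
    gene_id = as.character(S4Vectors::mcols(use)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(use)),
    start = GenomicRanges::start(use) - 1L,
    end = GenomicRanges::end(use),
    strand = as.character(GenomicRanges::strand(use)),
    stringsAsFactors = FALSE
  )
  gname <- S4Vectors::mcols(use)$gene_name
  df$gene_name <- if (is.null(gname)) df$gene_id else {
    ifelse(is.na(gname), df$gene_id, as.character(gname))
  }
  unstranded <- df$strand %in% c("*", ".")
  if (any(unstranded)) {
    warning(length(unique(df$gene_id[unstranded])),
            " unstranded gene record(s) dropped (TSS undefined)")
    df <- df[!unstranded, ]
  }
  if (!nrow(df)) stop("no usable gene records in ", path, call. = FALSE)
  # merge multiple records per gene_id to their union span
  merged <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
    if (length(unique(g$chrom)) > 1 || length(unique(g$strand)) > 1) {
      stop("gene_id ", g$gene_id[1],
           " spans multiple chromosomes or strands", call. = FALSE)
    }
    data.frame(gene_id = g$gene_id[1], gene_name = g$gene_name[1],
               chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               strand = g$strand[1], stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start, merged$end,
                         merged$gene_id, method = "radix"), ]
  gene_annotation(merged)
}

#' Write a gene annotation as GTF
#'
#' One `gene` feature per gene, converting back to GTF's 1-based inclusive
#' coordinates; the inverse of [read_gtf()] on gene-level records.
#'
#' @param annotation A `GeneAnnotation`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  g <- g[order(g$chrom, g$start, g$end, g$gene_id, method = "radix"), ]
  lines <- sprintf(
    '%s\tchirpflow\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    g$chrom, as.integer(g$start) + 1L, as.integer(g$end), g$strand,
    g$gene_id, g$gene_name)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with a header; requires columns `gene_id`, `log2fc` and
#' `qvalue` (extra columns are ignored).
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `gene_id`, `log2fc`, `qvalue`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "qvalue")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("DE table ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  if (any(!is.finite(df$log2fc))) stop("non-finite log2fc in ", path, call. = FALSE)
  if (any(is.na(df$qvalue) | df$qvalue < 0 | df$qvalue > 1)) {
    stop("qvalue outside [0,1] in ", path, call. = FALSE)
  }
  df
}

#' Write a differential-expression table
#' @param de Data frame with columns `gene_id`, `log2fc`, `qvalue`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, c("gene_id", "log2fc", "qvalue")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
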