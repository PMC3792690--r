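# Readers/writers and the interval primitives they normalise to.

np_line <- function(chrom, start, end, name, score = 0, strand = ".",
                    signal = 30, p = -1, q = 2, summit = 10) {
  paste(chrom, start, end, name, score, strand, signal, p, q, summit,
        sep = "\t")
}

test_that("read_narrowpeak parses 10-column files and converts qValue to fdr", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("# comment", "track name=x",
               np_line("chr1", 100, 600, "pk1", q = 2.0),
               np_line("chr2", 0, 300, "pk2", q = 3.0, strand = "+")), f)
  ps <- read_narrowpeak(f, label = "s1")
  expect_s3_class(ps, "PeakSet")
  expect_equal(n_peaks(ps), 2)
  expect_equal(ps$peaks$fdr, c(10^-2, 10^-3))
  expect_equal(ps$peaks$fold_enrichment, c(30, 30))
  expect_equal(ps$peaks$summit_offset, c(10, 10))
  expect_equal(ps$peaks$strand, c("*", "+"))
})

test_that("narrowPeak -1 sentinels map to absent and BED6 has no stats", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(np_line("chr1", 100, 600, "pk1", signal = -1, q = -1,
                     summit = -1), f)
  ps <- read_narrowpeak(f)
  expect_true(is.na(ps$peaks$fold_enrichment))
  expect_true(is.na(ps$peaks$fdr))
  expect_true(is.na(ps$peaks$summit_offset))

  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t600\tpk1\t0\t.", b)
  ps <- read_narrowpeak(b)
  expect_equal(n_peaks(ps), 1)
  expect_true(all(is.na(ps$peaks[, c("fold_enrichment", "fdr",
                                     "summit_offset")])))
})

test_that("read_narrowpeak reports malformed lines by number", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c(np_line("chr1", 100, 600, "a"), "chr1\t1\t2\tbad"), f)
  expect_error(read_narrowpeak(f), "line 2.*6 or 10")
  writeLines(c(np_line("chr1", 100, 100, "a")), f)
  expect_error(read_narrowpeak(f), "line 1.*start < end")
  writeLines(np_line("chr1", "x", 600, "a"), f)
  expect_error(read_narrowpeak(f), "line 1.*non-numeric")
  writeLines(np_line("chr1", 100, 600, "a", strand = "?"), f)
  expect_error(read_narrowpeak(f), "strand")
  writeLines(character(0), f)
  expect_equal(n_peaks(read_narrowpeak(f)), 0)
})

test_that("write_bed sorts deterministically and round-trips", {
  ps <- mk_peaks(c("chr2", "chr1", "chr1"), c(50, 1000, 10),
                 c(100, 2000, 20), id = c("c", "a", "b"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, f)
  lines <- readLines(f)
  expect_equal(length(lines), 3)
  expect_equal(vapply(strsplit(lines, "\t"), `[`, "", 4), c("b", "a", "c"))
  back <- read_narrowpeak(f)
  expect_equal(back$peaks[, c("chrom", "start", "end")],
               data.frame(chrom = c("chr1", "chr1", "chr2"),
                          start = c(10, 1000, 50), end = c(20, 2000, 100)))
  write_bed(mk_peaks(character(0), numeric(0), numeric(0)), f)
  expect_equal(length(readLines(f)), 0)
})

test_that("narrowPeak round-trip preserves intervals, ids and stats", {
  ps <- mk_peaks("chr1", c(1000, 5000), c(2000, 5400),
                 fold = c(25, 30), fdr = c(0.01, 0.001))
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(ps, f)
  back <- read_narrowpeak(f)
  expect_equal(back$peaks$start, ps$peaks$start)
  expect_equal(back$peaks$end, ps$peaks$end)
  expect_equal(back$peaks$id, ps$peaks$id)
  expect_equal(back$peaks$fold_enrichment, ps$peaks$fold_enrichment,
               tolerance = 1e-6)
  expect_equal(back$peaks$fdr, ps$peaks$fdr, tolerance = 1e-6)
})

test_that("gap_distance: overlap, separation, cross-chromosome", {
  a <- genomic_interval("chr1", 0, 100)
  expect_equal(gap_distance(a, genomic_interval("chr1", 50, 150)), 0)
  expect_equal(gap_distance(a, genomic_interval("chr1", 100, 150)), 0) # abut
  expect_equal(gap_distance(a, genomic_interval("chr1", 150, 250)), 50)
  expect_equal(gap_distance(a, genomic_interval("chr2", 150, 250)), Inf)
  expect_error(genomic_interval("chr1", 100, 100), "start < end")
})

test_that("gap_distance is symmetric and obeys the triangle-like bound", {
  set.seed(11)
  for (rep in 1:50) {
    iv <- random_peak_df(3, chroms = "chr1", span = 5000, max_width = 800)
    g <- function(i, j) gap_distance(iv[i, ], iv[j, ])
    expect_equal(g(1, 2), g(2, 1))
    len_b <- iv$end[2] - iv$start[2]
    expect_lte(g(1, 3), g(1, 2) + g(2, 3) + len_b)
  }
})

test_that("read_gtf converts coordinates, derives TSS, infers from exons", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "gp"; gene_name "GP";',
    'chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tgene_id "gm";'), f)
  ann <- read_gtf(f)
  g <- ann$genes
  expect_equal(g$start[g$gene_id == "gp"], 1000)
  expect_equal(g$end[g$gene_id == "gp"], 2000)
  expect_equal(g$tss[g$gene_id == "gp"], 1000)
  expect_equal(g$tss[g$gene_id == "gm"], 1999)
  expect_equal(g$gene_name[g$gene_id == "gp"], "GP")

  # exon-only gene: span of its exons
  writeLines(c(
    'chr2\tsrc\texon\t1001\t1500\t.\t+\t.\tgene_id "ge";',
    'chr2\tsrc\texon\t1801\t2200\t.\t+\t.\tgene_id "ge";'), f)
  ann <- read_gtf(f)
  expect_equal(ann$genes$start, 1000)
  expect_equal(ann$genes$end, 2200)
})

test_that("read_gtf rejects unusable files and flags skipped records", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\tsrc\tgene\t1001\t2000\t.\t*\t.\tgene_id "gu";', f)
  expect_error(suppressWarnings(read_gtf(f)), "no usable gene records")
  writeLines(c(
    'chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\tgene\t3001\t4000\t.\t*\t.\tgene_id "gu";'), f)
  expect_warning(ann <- read_gtf(f), "unstranded")
  expect_equal(ann$genes$gene_id, "g1")
})

test_that("GTF write/read composes to the identity on gene records", {
  set.seed(7)
  genes <- random_gene_df(40)
  ann <- gene_annotation(genes)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  back <- read_gtf(f)
  ord <- order(ann$genes$gene_id)
  expect_equal(back$genes[order(back$genes$gene_id), ]$start,
               ann$genes[ord, ]$start)
  expect_equal(back$genes[order(back$genes$gene_id), ]$end,
               ann$genes[ord, ]$end)
  expect_equal(back$genes[order(back$genes$gene_id), ]$strand,
               ann$genes[ord, ]$strand)
  expect_equal(back$genes[order(back$genes$gene_id), ]$tss,
               ann$genes[ord, ]$tss)
})

test_that("peak_set and gene_annotation enforce their invariants", {
  expect_error(mk_peaks("chr1", c(0, 0), c(10, 10), id = c("a", "a")),
               "duplicate peak id")
  expect_error(peak_set(data.frame(id = "a", chrom = "chr1", start = 0,
                                   end = 10, summit_offset = 10)),
               "summit_offset")
  expect_error(gene_annotation(data.frame(gene_id = "g", chrom = "chr1",
                                          start = 0, end = 10,
                                          strand = "*")),
               "stranded")
  expect_error(gene_annotation(data.frame(gene_id = c("g", "g"),
                                          chrom = "chr1", start = 0,
                                          end = 10, strand = "+")),
               "duplicate gene_id")
})
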