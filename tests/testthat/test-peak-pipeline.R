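# Quality filtering, replicate consensus and control screening.

test_that("filter_peaks applies strict thresholds and drops absent stats", {
  ps <- mk_peaks("chr1", c(0, 100, 200, 300, 400, 500) * 10,
                 c(50, 150, 250, 350, 450, 550) * 10,
                 id = letters[1:6],
                 fold = c(25, 15, 25, 20, NA, 25),
                 fdr = c(0.01, 0.01, 0.06, 0.05, 0.01, NA))
  out <- filter_peaks(ps, chirp_thresholds())
  expect_equal(out$peaks$id, "a")
  # idempotent
  expect_identical(filter_peaks(out, chirp_thresholds())$peaks, out$peaks)
  # empty in, empty out
  empty <- mk_peaks(character(0), numeric(0), numeric(0))
  expect_equal(n_peaks(filter_peaks(empty)), 0)
})

test_that("replicate_consensus matches worked examples", {
  a <- mk_peaks("chr1", 5000, 5500, id = "a1", label = "A")
  b <- mk_peaks("chr1", 14000, 14400, id = "b1", label = "B")
  res <- replicate_consensus(a, b, window = 10000)
  expect_equal(res$n_replicated, 1)
  expect_equal(res$consensus$min_partner_gap, 8500)
  expect_equal(res$consensus$support_b, "b1")
  expect_equal(replicate_consensus(a, b, window = 8000)$n_replicated, 0)
  expect_error(replicate_consensus(a, b, window = -1), "non-negative")
})

test_that("identical peak sets self-match with zero gap at any window", {
  set.seed(21)
  df <- random_peak_df(30)
  a <- peak_set(df, label = "A")
  b <- peak_set(df, label = "B")
  for (w in c(0, 5000)) {
    res <- replicate_consensus(a, b, window = w)
    expect_equal(res$n_replicated, 30)
    expect_true(all(res$consensus$min_partner_gap == 0))
  }
})

test_that("consensus agrees with the all-pairs brute force (seeded trials)", {
  set.seed(31)
  for (trial in 1:25) {
    a <- peak_set(random_peak_df(sample(0:80, 1), "a"), label = "A")
    b <- peak_set(random_peak_df(sample(0:80, 1), "b"), label = "B")
    w <- sample(c(0, 100, 5000, 20000), 1)
    res <- replicate_consensus(a, b, window = w)
    oracle <- bf_replicate(a$peaks, b$peaks, w)
    hit <- vapply(oracle, function(o) length(o$partners) > 0, logical(1))
    expect_equal(res$consensus$id, a$peaks$id[hit])
    expect_equal(res$consensus$min_partner_gap,
                 vapply(oracle[hit], `[[`, numeric(1), "min_gap"))
    expect_equal(res$consensus$support_b,
                 vapply(oracle[hit], function(o)
                   paste(o$partners, collapse = ","), character(1)))
    # conservation: replicated + unmatched = all filtered A peaks
    expect_equal(res$n_replicated + sum(!hit), res$n_repA_in)
  }
})

test_that("replicated set grows monotonically with the window", {
  set.seed(41)
  for (trial in 1:10) {
    a <- peak_set(random_peak_df(40, "a"), label = "A")
    b <- peak_set(random_peak_df(40, "b"), label = "B")
    prev <- character(0)
    for (w in c(0, 1000, 5000, 20000, 1e6)) {
      ids <- replicate_consensus(a, b, window = w)$consensus$id
      expect_true(all(prev %in% ids))
      prev <- ids
    }
  }
})

test_that("summit mode measures summit-to-summit distance", {
  # summits 5 kb apart although the intervals nearly touch
  a <- peak_set(data.frame(id = "a1", chrom = "chr1", start = 0, end = 4900,
                           summit_offset = 0), label = "A")
  b <- peak_set(data.frame(id = "b1", chrom = "chr1", start = 5000,
                           end = 5200, summit_offset = 0), label = "B")
  expect_equal(replicate_consensus(a, b, 200)$n_replicated, 1)     # gap mode
  expect_equal(replicate_consensus(a, b, 200, mode = "summit")$n_replicated, 0)
  expect_equal(replicate_consensus(a, b, 5000, mode = "summit")$n_replicated, 1)
})

test_that("union representative spans anchor and partners", {
  a <- mk_peaks("chr1", 5000, 5500, id = "a1", label = "A")
  b <- mk_peaks("chr1", c(3000, 6000), c(3400, 6800),
                id = c("b1", "b2"), label = "B")
  anchor <- replicate_consensus(a, b, 10000)
  expect_equal(c(anchor$consensus$start, anchor$consensus$end), c(5000, 5500))
  un <- replicate_consensus(a, b, 10000, representative = "union")
  expect_equal(c(un$consensus$start, un$consensus$end), c(3000, 6800))
})

test_that("flag_control_proximity flags by pooled nearest gap", {
  a <- mk_peaks("chr1", 5000, 5500, id = "a1", label = "A")
  b <- mk_peaks("chr1", 5100, 5600, id = "b1", label = "B")
  res <- replicate_consensus(a, b, 10000)
  far <- mk_peaks("chr1", 20000, 20100, label = "c1", role = "control")
  res1 <- flag_control_proximity(res, far, 10000)
  expect_false(res1$consensus$control_proximal)
  expect_equal(res1$consensus$nearest_control_gap, 14500)
  expect_equal(res1$n_controls_within_window, 0)

  over <- mk_peaks("chr1", 5200, 5300, label = "c2", role = "control")
  res2 <- flag_control_proximity(res, list(far, over), 10000)
  expect_true(res2$consensus$control_proximal)
  expect_equal(res2$consensus$nearest_control_gap, 0)
  expect_equal(res2$n_controls_within_window, 1)
  expect_equal(nrow(specific_peaks(res2)), 0)

  other_chrom <- mk_peaks("chr9", 5000, 5600, label = "c3", role = "control")
  res3 <- flag_control_proximity(res, other_chrom, 10000)
  expect_equal(res3$consensus$nearest_control_gap, Inf)
  expect_false(res3$consensus$control_proximal)
  expect_error(flag_control_proximity(res, far, -5), "non-negative")
  expect_error(specific_peaks(res), "flag_control_proximity")
})

test_that("control gaps agree with the brute force on seeded trials", {
  set.seed(51)
  for (trial in 1:15) {
    a <- peak_set(random_peak_df(30, "a"), label = "A")
    ctrl <- peak_set(random_peak_df(sample(0:40, 1), "c"), label = "C",
                     role = "control")
    res <- replicate_consensus(a, a, 0)  # consensus = all of a
    res <- flag_control_proximity(res, ctrl, 5000)
    expect_equal(res$consensus$nearest_control_gap,
                 bf_nearest_gap(a$peaks, ctrl$peaks))
    expect_equal(res$consensus$control_proximal,
                 bf_nearest_gap(a$peaks, ctrl$peaks) <= 5000)
  }
})

test_that("pairwise_window_overlap computes asymmetric fractions", {
  s1 <- mk_peaks("chr1", c(0, 100000, 200000, 300000) + 0,
                 c(0, 100000, 200000, 300000) + 500, label = "s1")
  # exactly one of s1's 4 peaks has a partner in s2 within 1 kb
  s2 <- mk_peaks("chr1", 1000, 1500, label = "s2")
  m <- pairwise_window_overlap(list(s1, s2), window = 1000)
  expect_equal(m["s1", "s2"], 0.25)
  expect_equal(m["s2", "s1"], 1)
  expect_equal(diag(m), c(s1 = 1, s2 = 1))

  far <- mk_peaks("chr1", 900000, 900500, label = "far")
  m2 <- pairwise_window_overlap(list(s1, far), window = 1000)
  expect_equal(m2["s1", "far"], 0)
  expect_equal(m2["far", "s1"], 0)

  m3 <- pairwise_window_overlap(list(s1, s1), window = 0)
  expect_true(all(m3 == 1))

  empty <- mk_peaks(character(0), numeric(0), numeric(0), label = "e")
  m4 <- pairwise_window_overlap(list(s1, empty), window = 1000)
  expect_true(all(is.na(m4["e", ])))
  expect_equal(attr(m4, "undefined_rows"), "e")
  expect_error(pairwise_window_overlap(list(s1), 1000), "at least 2")
})
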