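test_that("median normalization matches the worked examples", {
  w <- tibble::tibble(chrom = "c", window_start = 0:4 * 100,
                      raw_depth = c(10, 20, 30, 20, 20))
  expect_equal(normalize_depth(w)$normalized, c(0.5, 1.0, 1.5, 1.0, 1.0))
  const <- tibble::tibble(chrom = "c", window_start = 0:9 * 100,
                          raw_depth = 40)
  expect_true(all(normalize_depth(const)$normalized == 1))
  zero <- tibble::tibble(chrom = "c", window_start = 0:4 * 100, raw_depth = 0)
  expect_error(normalize_depth(zero), "median")
})

test_that("a planted region normalizes near its copy number against a CN=1 median", {
  # a 20% amplified fraction inflates the genome-wide median a little, so
  # the copy-number readout is the segment mean relative to the background
  p <- simulate_depth_profile(1000, 80,
                              planted_segments = list(c(1, 200, 2)), seed = 3)
  nd <- normalize_depth(p$evolved)
  expect_equal(mean(nd$normalized[1:200]) / median(nd$normalized[201:1000]),
               2, tolerance = 0.05)
  expect_equal(median(nd$normalized[201:1000]), 1, tolerance = 0.10)
})

test_that("ancestor subtraction zeroes identical profiles and checks grids", {
  p <- simulate_depth_profile(300, 50, seed = 1)
  n <- normalize_depth(p$ancestor)
  expect_true(all(subtract_ancestor(n, n)$delta == 0))
  shifted <- dplyr::mutate(n, window_start = window_start + 100L)
  expect_error(subtract_ancestor(n, shifted), "grids differ")
  expect_error(subtract_ancestor(n, n[-1, ]), "grids differ")
})

test_that("smoothing averages over the span with symmetric edge shrink", {
  imp <- tibble::tibble(chrom = "c", window_start = 0:4 * 100,
                        delta = c(0, 0, 1, 0, 0))
  expect_equal(smooth_delta(imp, span = 5)$smoothed, c(0, 1 / 3, 0.2, 1 / 3, 0))
  const <- tibble::tibble(chrom = "c", window_start = 0:9 * 100, delta = 0.7)
  expect_true(all(smooth_delta(const)$smoothed == 0.7))
  expect_equal(smooth_delta(imp, span = 1)$smoothed, imp$delta)
  expect_error(smooth_delta(imp, span = 4), "odd")
  # interior-dominated mean preservation (zero-delta edges)
  set.seed(9)
  v <- c(rep(0, 10), rnorm(80), rep(0, 10))
  w <- tibble::tibble(chrom = "c", window_start = (0:99) * 100, delta = v)
  expect_equal(mean(smooth_delta(w)$smoothed), mean(v), tolerance = 1e-12)
})

test_that("segment calling respects threshold and minimum run length", {
  flat <- tibble::tibble(chrom = "c", window_start = 0:49 * 100, smoothed = 0)
  expect_identical(nrow(call_segments(flat)), 0L)
  short_run <- dplyr::mutate(flat,
                             smoothed = ifelse(window_start < 500, 1, 0))
  expect_identical(nrow(call_segments(short_run, min_windows = 10)), 0L)
  expect_identical(nrow(call_segments(short_run, min_windows = 5)), 1L)
  del <- dplyr::mutate(flat,
                       smoothed = ifelse(window_start >= 1000 &
                                           window_start < 3000, -0.8, 0))
  seg <- call_segments(del)
  expect_identical(seg$direction, "deletion")
  expect_equal(seg$start, 1000)
  expect_equal(seg$end, 3000)
  expect_equal(seg$mean_delta, -0.8)
  # a one-window dip inside a long run is bridged, not split
  dipped <- dplyr::mutate(flat,
                          smoothed = ifelse(window_start >= 500 &
                                              window_start < 3000, 1, 0))
  dipped$smoothed[dipped$window_start == 1500] <- 0.2
  bridged <- call_segments(dipped)
  expect_identical(nrow(bridged), 1L)
  expect_equal(bridged$start, 500)
  expect_equal(bridged$end, 3000)
  strict <- call_segments(dipped, merge_gap = 0)
  expect_identical(nrow(strict), 2L)
})

test_that("noiseless pipeline composition returns the planted copy-number delta", {
  p <- simulate_depth_profile(600, 50, planted_segments = list(c(201, 400, 3)),
                              noiseless = TRUE)
  res <- cnv_pipeline(p$evolved, p$ancestor)
  expect_identical(nrow(res$segments), 1L)
  # interior windows carry exactly cn - 1 = 2 after smoothing
  interior <- dplyr::filter(res$windows, window_start >= 20200,
                            window_start < 39800)
  expect_true(all(abs(interior$smoothed - 2) < 1e-9))
})

test_that("binomial recurrence test matches exact summation", {
  segs2 <- tibble::tibble(chrom = "c", start = c(0, 100), end = c(50, 150),
                          direction = "amplification")
  r <- test_recurrence(segs2, list(chrom = "c", start = 0, end = 500), 1000)
  expect_equal(r$p_value, 0.25) # k = n = 2, p0 = 0.5
  miss <- test_recurrence(segs2, list(chrom = "c", start = 600, end = 900),
                          1000)
  expect_identical(miss$k_hits, 0L)
  expect_equal(miss$p_value, 1.0)
  # k = 11 of n = 30 at p0 = 0.01, against the choose() oracle
  segs30 <- tibble::tibble(
    chrom = "c",
    start = c(rep(0L, 11), seq(2000L, by = 100L, length.out = 19)),
    end = c(rep(10L, 11), seq(2010L, by = 100L, length.out = 19)),
    direction = "amplification")
  r30 <- test_recurrence(segs30, list(chrom = "c", start = 0, end = 10), 1000)
  expect_identical(r30$k_hits, 11L)
  expect_equal(r30$p_value, oracle_binom_tail(11, 30, 0.01), tolerance = 1e-12)
  expect_error(test_recurrence(segs2, list(chrom = "c", start = -1, end = 10),
                               1000), "bounds")
})

test_that("recurrence p-value decreases as more events hit the locus", {
  make_segs <- function(k, n) tibble::tibble(
    chrom = "c",
    start = c(rep(0L, k), seq(5000L, by = 100L, length.out = n - k)),
    end = c(rep(10L, k), seq(5010L, by = 100L, length.out = n - k)),
    direction = "amplification")
  locus <- list(chrom = "c", start = 0, end = 100)
  p <- vapply(1:10, function(k)
    test_recurrence(make_segs(k, 12), locus, 1e4)$p_value, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("planted CN=2 segments are recovered with tight boundaries", {
  hits <- vapply(1:10, function(seed) {
    p <- simulate_depth_profile(2000, 50,
                                planted_segments = list(c(501, 800, 2)),
                                seed = seed)
    segs <- cnv_pipeline(p$evolved, p$ancestor)$segments
    amp <- dplyr::filter(segs, direction == "amplification")
    nrow(amp) == 1 &&
      abs(amp$start - 500 * 100) <= 500 &&
      abs(amp$end - 800 * 100) <= 500
  }, logical(1))
  expect_true(all(hits))
})
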