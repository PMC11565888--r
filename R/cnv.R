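#' Normalize windowed read depths to the genome-wide median
#'
#' Divides every 100-bp window's raw depth by the genome-wide median raw
#' depth, controlling for sequencing-depth differences between samples.
#'
#' @param windows Tibble with `chrom`, `window_start` (0-based, 100-bp
#'   half-open grid) and `raw_depth`.
#' @return The tibble with a `normalized` column added.
#' @examples
#' w <- tibble::tibble(chrom = "c", window_start = 0:4 * 100,
#'                     raw_depth = c(10, 20, 30, 20, 20))
#' normalize_depth(w)$normalized
#' @export
normalize_depth <- function(windows) {
  stopifnot(all(c("chrom", "window_start", "raw_depth") %in% names(windows)))
  if (any(windows$raw_depth < 0)) abort("Raw depths must be >= 0.")
  med <- median(windows$raw_depth)
  if (med <= 0) abort("Genome-wide median depth is 0; cannot normalize.")
  mutate(windows, normalized = .data$raw_depth / med)
}

#' Subtract the ancestor depth profile from an evolved one
#'
#' Per-window difference of normalized depths (evolved minus ancestor),
#' removing shared artefacts such as repetitive-region mapping noise. The
#' two profiles must be on the identical window grid.
#'
#' @param evolved,ancestor Normalized window tibbles ([normalize_depth()]).
#' @return The evolved tibble with a `delta` column added.
#' @export
subtract_ancestor <- function(evolved, ancestor) {
  stopifnot("normalized" %in% names(evolved),
            "normalized" %in% names(ancestor))
  if (nrow(evolved) != nrow(ancestor)) {
    abort("Window grids differ in size; profiles must share the same 100-bp grid.")
  }
  if (!all(evolved$chrom == ancestor$chrom) ||
      !all(evolved$window_start == ancestor$window_start)) {
    bad <- which(evolved$chrom != ancestor$chrom |
                   evolved$window_start != ancestor$window_start)[1]
    abort(paste0("Window grids differ (first mismatch at row ", bad,
                 "); profiles must share the same 100-bp grid."))
  }
  mutate(evolved, delta = .data$normalized - ancestor$normalized)
}

#' Smooth per-window deltas with a centred moving average
#'
#' Moving average over `span` windows (default 5, i.e. 500 bp) within each
#' contig; at contig edges the window shrinks symmetrically to the
#' available points, keeping the output aligned to the input grid so
#' profiles remain comparable across populations. Smoothed values refer to
#' the genomic coordinate at the centre of the smoothing window.
#'
#' @param windows Tibble with `chrom`, `window_start`, `delta`.
#' @param span Odd number of windows to average (>= 1).
#' @return The tibble with a `smoothed` column added.
#' @examples
#' w <- tibble::tibble(chrom = "c", window_start = 0:4 * 100,
#'                     delta = c(0, 0, 1, 0, 0))
#' smooth_delta(w)$smoothed[3] # 0.2
#' @export
smooth_delta <- function(windows, span = 5) {
  if (span %% 2 == 0 || span < 1) abort("`span` must be odd and >= 1.")
  half <- (span - 1) / 2
  windows %>%
    group_by(.data$chrom) %>%
    mutate(smoothed = {
      v <- .data$delta
      n <- length(v)
      vapply(seq_len(n), function(i) {
        k <- min(half, i - 1, n - i) # symmetric shrink at edges
        mean(v[(i - k):(i + k)])
      }, numeric(1))
    }) %>%
    ungroup()
}

#' Call amplified and deleted segments from a smoothed delta profile
#'
#' Maximal runs of at least `min_windows` consecutive windows whose
#' smoothed delta is `>= threshold` (amplification) or `<= -threshold`
#' (deletion) become segments; `mean_delta` is the mean smoothed delta of
#' the run (in copies relative to the ancestor).
#'
#' Runs separated by at most `merge_gap` sub-threshold windows are bridged
#' before the length filter, so a long event is not split by single-window
#' noise dips (set `merge_gap = 0` for strict runs).
#'
#' @param windows Tibble with `chrom`, `window_start`, `smoothed`.
#' @param threshold Calling threshold in copies (default 0.5).
#' @param min_windows Minimum run length in windows (default 10, i.e. 1 kb).
#' @param merge_gap Maximum gap (windows) bridged between same-direction
#'   runs (default 5, one smoothing span).
#' @return Tibble of segments: `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `direction`, `mean_delta`, `n_windows`.
#' @export
call_segments <- function(windows, threshold = 0.5, min_windows = 10,
                          merge_gap = 5) {
  stopifnot("smoothed" %in% names(windows))
  if (!all(is.finite(windows$smoothed))) abort("Smoothed values must be finite.")
  empty <- tibble(start = numeric(0), end = numeric(0),
                  direction = character(0), mean_delta = numeric(0),
                  n_windows = integer(0))
  windows %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      state <- ifelse(d$smoothed >= threshold, 1L,
                      ifelse(d$smoothed <= -threshold, -1L, 0L))
      r <- rle(state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- tibble(value = r$values, start = starts, end = ends) %>%
        filter(.data$value != 0L)
      if (nrow(runs) == 0) return(empty)
      # bridge short neutral gaps between same-direction runs
      merged <- runs[1, ]
      for (k in seq_len(nrow(runs))[-1]) {
        last <- nrow(merged)
        if (runs$value[k] == merged$value[last] &&
            runs$start[k] - merged$end[last] - 1 <= merge_gap) {
          merged$end[last] <- runs$end[k]
        } else merged <- bind_rows(merged, runs[k, ])
      }
      merged <- filter(merged, .data$end - .data$start + 1 >= min_windows)
      if (nrow(merged) == 0) return(empty)
      purrr::map(seq_len(nrow(merged)), function(k) {
        i <- merged$start[k]:merged$end[k]
        tibble(start = d$window_start[merged$start[k]],
               end = d$window_start[merged$end[k]] + 100,
               direction = if (merged$value[k] > 0) "amplification"
                           else "deletion",
               mean_delta = mean(d$smoothed[i]),
               n_windows = length(i))
      }) %>% bind_rows()
    }) %>% ungroup()
}

#' Binomial recurrence test for amplifications at a locus
#'
#' Tests whether `k` of the `n` segmental amplifications observed across
#' populations overlapping one locus is more than expected if amplification
#' locations were uniform on the genome: under that null each event hits
#' the locus with probability `p0 = locus length / genome size`, and the
#' p-value is the exact binomial upper tail `P(Binom(n, p0) >= k)`.
#'
#' @param segments Tibble of called segments across populations (needs
#'   `chrom`, `start`, `end`, `direction`; e.g. row-bound
#'   [call_segments()] outputs with a `population` column).
#' @param locus List or tibble-row with `chrom`, `start`, `end`
#'   (bp, 0-based half-open).
#' @param genome_size Genome length in bp.
#' @return Tibble: `k_hits`, `n_events`, `p0`, `p_value`.
#' @examples
#' segs <- tibble::tibble(chrom = "c", start = c(0, 500), end = c(400, 900),
#'                        direction = "amplification")
#' test_recurrence(segs, list(chrom = "c", start = 0, end = 450), 900)
#' @export
test_recurrence <- function(segments, locus, genome_size) {
  if (locus$start < 0 || locus$end > genome_size || locus$end <= locus$start)
    abort("Locus outside genome bounds.")
  amp <- filter(segments, .data$direction == "amplification")
  n <- nrow(amp)
  if (n == 0) abort("No amplification events to test.")
  k <- sum(amp$chrom == locus$chrom &
             amp$start < locus$end & amp$end > locus$start)
  p0 <- (locus$end - locus$start) / genome_size
  p <- if (k == 0) 1 else sum(dbinom(k:n, n, p0)) # exact upper-tail sum
  tibble(k_hits = k, n_events = n, p0 = p0, p_value = min(p, 1))
}

#' Run the depth-to-segments CNV pipeline on one evolved/ancestor pair
#'
#' Convenience composition: [normalize_depth()] both profiles,
#' [subtract_ancestor()], [smooth_delta()], [call_segments()].
#'
#' @param evolved,ancestor Raw window tibbles (`chrom`, `window_start`,
#'   `raw_depth`).
#' @inheritParams smooth_delta
#' @inheritParams call_segments
#' @return List with `windows` (per-window tibble carrying `normalized`,
#'   `delta`, `smoothed`) and `segments`.
#' @export
cnv_pipeline <- function(evolved, ancestor, span = 5, threshold = 0.5,
                         min_windows = 10, merge_gap = 5) {
  w <- normalize_depth(evolved) %>%
    subtract_ancestor(normalize_depth(ancestor)) %>%
    smooth_delta(span = span)
  list(windows = w,
       segments = call_segments(w, threshold, min_windows, merge_gap))
}
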