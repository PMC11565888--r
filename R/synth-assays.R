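#' Simulate a two-colour competition count series
#'
#' Emulates the flow-cytometry competition assay: a non-fluorescent test
#' strain is co-cultured with a fluorescent reference, sampled at the start
#' (`t0`, just after dilution) and end (`t24`, at saturation) of each 24 h
#' growth cycle. The true ratio of non-fluorescent to fluorescent cells
#' follows `ln r(g) = ln r0 + s * g` over cumulative generations `g`;
#' channel counts are binomial draws of `events_per_sample` events from the
#' true ratio (exact expectations when `noiseless`), while `total_events`
#' grows by `dilution_factor` within each cycle so that the per-day
#' generation count recovered from totals is `log2(dilution_factor)`.
#' The day-0 initial sample is cycle 1's `t0` with cumulative g = 0.
#'
#' @param s Per-generation log-fitness difference (selection coefficient) of
#'   the test strain relative to the reference.
#' @param days Number of 24 h growth cycles.
#' @param dilution_factor Fold-regrowth within each cycle (1:1000 standard).
#' @param events_per_sample Flow events acquired per ratio measurement.
#' @param seed Integer seed (`NULL` = current stream).
#' @param noiseless If `TRUE`, channel counts are exact expectations.
#' @param r0 Initial non-fluorescent : fluorescent ratio.
#' @return A tibble (flow count series) with columns `sample`, `day`,
#'   `hours`, `fluorescent_events`, `nonfluorescent_events`, `total_events`.
#' @examples
#' simulate_competition_counts(s = 0.05, days = 3, noiseless = TRUE)
#' @export
simulate_competition_counts <- function(s, days = 3, dilution_factor = 1000,
                                        events_per_sample = 1e5, seed = NULL,
                                        noiseless = FALSE, r0 = 1) {
  stopifnot(events_per_sample > 0, days >= 1, dilution_factor > 1)
  local_seed(seed)
  n_gen <- log2(dilution_factor)
  rows <- purrr::map(seq_len(days), function(d) {
    g0 <- (d - 1) * n_gen
    tibble(
      sample = c("t0", "t24"), day = d,
      hours = c(24 * (d - 1) + 5, 24 * d + 5),
      g_true = c(g0, g0 + n_gen),
      total_events = c(events_per_sample,
                       events_per_sample * dilution_factor)
    )
  }) %>% bind_rows()
  p_nonfluor <- 1 / (1 + 1 / (r0 * exp(s * rows$g_true))) # r/(1+r)
  nf <- if (noiseless) events_per_sample * p_nonfluor
        else rbinom(nrow(rows), events_per_sample, p_nonfluor)
  rows %>%
    mutate(nonfluorescent_events = nf,
           fluorescent_events = events_per_sample - nf) %>%
    select("sample", "day", "hours", "fluorescent_events",
           "nonfluorescent_events", "total_events")
}

#' Simulate paired ancestor/evolved read-depth profiles
#'
#' Draws per-window (100 bp, 0-based half-open) read depths from a
#' negative binomial around `mean_depth` (ancestor) and
#' `mean_depth * copy_number` (evolved, inside planted segments). The
#' `dispersion` parameter is the negative-binomial size; larger values
#' approach Poisson counts. Planted segments are given in window units.
#'
#' @param genome_windows Number of 100-bp windows.
#' @param mean_depth Mean read depth per window at copy number 1.
#' @param planted_segments List of `c(start, end, copy_number)` triples in
#'   window indices (1-based, inclusive); segments must not overlap and
#'   `copy_number >= 0`.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed (`NULL` = current stream).
#' @param noiseless If `TRUE`, counts equal their expectations exactly.
#' @param chrom Contig name for the emitted windows.
#' @return A list with tibbles `ancestor` and `evolved`, each with `chrom`,
#'   `window_start` (0-based), `raw_depth`, plus `truth` (the planted
#'   per-window copy number).
#' @examples
#' prof <- simulate_depth_profile(500, 50,
#'   planted_segments = list(c(101, 200, 2)), seed = 1)
#' @export
simulate_depth_profile <- function(genome_windows, mean_depth,
                                   planted_segments = list(),
                                   dispersion = 100, seed = NULL,
                                   noiseless = FALSE, chrom = "chr01") {
  stopifnot(genome_windows >= 1, mean_depth > 0, dispersion > 0)
  cn <- rep(1, genome_windows)
  covered <- rep(FALSE, genome_windows)
  for (seg in planted_segments) {
    stopifnot(length(seg) == 3)
    if (seg[1] < 1 || seg[2] > genome_windows || seg[2] < seg[1])
      abort("Planted segment outside genome bounds.")
    if (seg[3] < 0) abort("Planted copy_number must be >= 0.")
    idx <- seg[1]:seg[2]
    if (any(covered[idx])) abort("Planted segments overlap.")
    covered[idx] <- TRUE
    cn[idx] <- seg[3]
  }
  local_seed(seed)
  draw <- function(mu) {
    if (noiseless) mu else rnbinom(length(mu), size = dispersion, mu = mu)
  }
  ws <- as.integer((seq_len(genome_windows) - 1) * 100)
  list(
    ancestor = tibble(chrom = chrom, window_start = ws,
                      raw_depth = draw(rep(mean_depth, genome_windows))),
    evolved = tibble(chrom = chrom, window_start = ws,
                     raw_depth = draw(mean_depth * cn)),
    truth = tibble(chrom = chrom, window_start = ws, copy_number = cn)
  )
}

#' Simulate a plate-reader OD600 growth curve
#'
#' Logistic growth `OD(t) = K od0 e^{r t'} / (K + od0 (e^{r t'} - 1))` with
#' `t' = max(0, t - lag)`, sampled every `interval` minutes, plus Gaussian
#' measurement noise.
#'
#' @param r Exponential growth rate (per minute).
#' @param K Carrying capacity (maximum OD600).
#' @param od0 Initial OD600.
#' @param lag Lag phase duration (minutes).
#' @param noise_sd Standard deviation of Gaussian OD noise (0 = noiseless).
#' @param interval Sampling interval (minutes; plate reader default 10).
#' @param duration Total run time (minutes).
#' @param seed Integer seed (`NULL` = current stream).
#' @param well Well label attached to the series.
#' @return Tibble with `time_min`, `well`, `od600`.
#' @examples
#' simulate_od_curve(r = 0.005, K = 1.2, od0 = 0.05, duration = 60)
#' @export
simulate_od_curve <- function(r, K, od0, lag = 0, noise_sd = 0,
                              interval = 10, duration = 2880, seed = NULL,
                              well = "A1") {
  stopifnot(r > 0, K > od0, od0 > 0, interval > 0, duration >= 0)
  local_seed(seed)
  t <- seq(0, duration, by = interval)
  te <- pmax(0, t - lag)
  od <- K * od0 * exp(r * te) / (K + od0 * (exp(r * te) - 1))
  if (noise_sd > 0) od <- od + rnorm(length(od), 0, noise_sd)
  tibble(time_min = t, well = well, od600 = od)
}

#' Simulate a DNA-content (cell-cycle) event sample
#'
#' Mixture emulating a SYTOX/FACS DNA histogram of an asynchronous
#' population: a Gaussian 1C (G1) peak, a Gaussian 2C (G2/M) peak with mean
#' exactly twice the 1C mean, and a uniform S-phase bridge between the two
#' peak positions, in proportions `f_g1`, `f_g2`, `f_s`. Peak widths scale
#' with their means through a common coefficient of variation.
#'
#' @param f_g1,f_s,f_g2 Phase fractions; must sum to 1.
#' @param cv Coefficient of variation of the fluorescence peaks (> 0).
#' @param n_events Number of cells (events) to draw.
#' @param seed Integer seed (`NULL` = current stream).
#' @param mean_1c Fluorescence position of the 1C peak (arbitrary units).
#' @param n_bins Number of histogram bins.
#' @return A list of class `dna_histogram`: `events` (fluorescence values),
#'   `histogram` (tibble `bin_center`, `count`; counts sum to `n_events`),
#'   and the generating parameters.
#' @examples
#' h <- simulate_dna_histogram(0.25, 0.25, 0.5, cv = 0.08, n_events = 1e4,
#'                             seed = 1)
#' sum(h$histogram$count)
#' @export
simulate_dna_histogram <- function(f_g1, f_s, f_g2, cv = 0.08,
                                   n_events = 10000, seed = NULL,
                                   mean_1c = 100, n_bins = 256) {
  if (abs(f_g1 + f_s + f_g2 - 1) > 1e-9) abort("Phase fractions must sum to 1.")
  if (any(c(f_g1, f_s, f_g2) < 0)) abort("Phase fractions must be >= 0.")
  if (cv <= 0) abort("`cv` must be > 0.")
  stopifnot(n_events >= 1)
  local_seed(seed)
  comp <- sample.int(3, n_events, replace = TRUE, prob = c(f_g1, f_s, f_g2))
  x <- numeric(n_events)
  x[comp == 1] <- rnorm(sum(comp == 1), mean_1c, cv * mean_1c)
  x[comp == 2] <- runif(sum(comp == 2), mean_1c, 2 * mean_1c)
  x[comp == 3] <- rnorm(sum(comp == 3), 2 * mean_1c, cv * 2 * mean_1c)
  breaks <- seq(0, 3 * mean_1c, length.out = n_bins + 1)
  xc <- pmin(pmax(x, breaks[1]), breaks[length(breaks)] - 1e-9) # clip tails
  counts <- tabulate(findInterval(xc, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  structure(
    list(events = x,
         histogram = tibble(bin_center = (head(breaks, -1) + tail(breaks, -1)) / 2,
                            count = counts),
         params = list(f_g1 = f_g1, f_s = f_s, f_g2 = f_g2, cv = cv,
                       n_events = n_events, mean_1c = mean_1c)),
    class = "dna_histogram"
  )
}
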