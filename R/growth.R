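#' Fit a growth curve by sliding-window log-linear regression
#'
#' The maximum specific growth rate is the largest slope of `ln(OD)` versus
#' time over all windows of `window_points` consecutive timepoints — the
#' standard plate-reader analysis, robust to lag and saturation phases.
#' Doubling time is `ln(2) / rate`; the maximum OD is taken from a 3-point
#' running-median smoothed curve to resist single-read spikes.
#'
#' @param series Tibble with `time_min` (strictly increasing) and `od600`;
#'   at least 5 timepoints.
#' @param window_points Points per regression window (default 8, i.e.
#'   ~80 min at 10-min sampling); >= 3 and <= the number of timepoints.
#' @param blank Optional blank OD600 subtracted before fitting; negative
#'   blanked values are clipped to 0 with a warning.
#' @return Object of class `growth_fit`: `growth_rate` (per minute),
#'   `doubling_time` (minutes), `max_od`, `fit_window` (start/end minutes),
#'   `r_squared`, `no_growth` flag, and the (blanked) data.
#' @examples
#' od <- simulate_od_curve(r = 0.005, K = 1.2, od0 = 0.05, duration = 600)
#' fit_growth_curve(od)$doubling_time # ~ log(2)/0.005 = 138.6 min
#' @export
fit_growth_curve <- function(series, window_points = 8, blank = 0) {
  stopifnot(all(c("time_min", "od600") %in% names(series)))
  t <- series$time_min
  od <- series$od600 - blank
  if (is.unsorted(t, strictly = TRUE)) abort("Time must be strictly increasing.")
  if (length(t) < 5) abort("Need at least 5 timepoints.")
  if (window_points < 3 || window_points > length(t))
    abort("`window_points` must be >= 3 and <= the number of timepoints.")
  if (any(od < 0)) {
    warn("Negative OD after blank subtraction; clipped to 0.")
    od <- pmax(od, 0)
  }
  if (all(od == 0)) abort("No growth signal: all OD values are zero.")

  max_od <- max(stats::runmed(od, 3))
  logod <- suppressWarnings(log(od))
  n <- length(t)
  best <- list(rate = 0, r2 = NA_real_, win = c(NA_real_, NA_real_))
  for (i in seq_len(n - window_points + 1)) {
    j <- i + window_points - 1
    y <- logod[i:j]
    if (!all(is.finite(y))) next
    x <- t[i:j]
    sl <- stats::cov(x, y) / stats::var(x)
    if (sl > best$rate) {
      ssr <- sum((y - mean(y) - sl * (x - mean(x)))^2)
      sst <- sum((y - mean(y))^2)
      best <- list(rate = sl, r2 = if (sst > 0) 1 - ssr / sst else NA_real_,
                   win = c(x[1], x[length(x)]))
    }
  }
  no_growth <- best$rate <= 0
  if (no_growth) inform("No growth detected (rate <= 0 in every window).")
  structure(
    list(growth_rate = max(best$rate, 0),
         doubling_time = if (no_growth) Inf else log(2) / best$rate,
         max_od = max_od, fit_window = best$win, r_squared = best$r2,
         no_growth = no_growth, window_points = window_points,
         data = tibble(time_min = t, od600 = od)),
    class = "growth_fit")
}

#' Gate a DNA-content histogram into G1/S/G2 fractions
#'
#' Fits a constrained mixture to the binned fluorescence histogram: a
#' Gaussian 1C (G1) peak, a Gaussian 2C (G2/M) peak whose mean is fixed at
#' twice the 1C mean, and a uniform S-phase bridge spanning the two peak
#' positions; both peaks share one coefficient of variation. The phase
#' fractions are the fitted mixture weights. A simple threshold mode
#' (`method = "threshold"`) cuts the histogram at 1.25x and 1.75x the 1C
#' mode instead.
#'
#' @param hist A `dna_histogram` object ([simulate_dna_histogram()] /
#'   [read_dna_histogram()]) or a tibble with `bin_center` and `count`.
#' @param method `"mixture"` (default) or `"threshold"`.
#' @return Object of class `phase_estimate` with `f_g1`, `f_s`, `f_g2`,
#'   fitted `mean_1c` and `cv`, the `method`, and a `warning` field when
#'   the 2C mode is effectively absent.
#' @examples
#' h <- simulate_dna_histogram(0.25, 0.25, 0.5, n_events = 2e4, seed = 1)
#' gate_dna_content(h)
#' @export
gate_dna_content <- function(hist, method = c("mixture", "threshold")) {
  method <- match.arg(method)
  h <- if (inherits(hist, "dna_histogram")) hist$histogram else as_tibble(hist)
  stopifnot(all(c("bin_center", "count") %in% names(h)))
  if (sum(h$count) <= 0) abort("Histogram has no events.")
  x <- h$bin_center
  cnt <- h$count
  total <- sum(cnt)

  # 1C mode: strongest bin in the lower half of the occupied range
  occ <- range(x[cnt > 0])
  lower <- x <= mean(occ)
  if (!any(cnt[lower] > 0)) abort("No detectable 1C mode.")
  mu1_0 <- x[lower][which.max(cnt[lower])]

  if (method == "threshold") {
    f1 <- sum(cnt[x < 1.25 * mu1_0]) / total
    f2 <- sum(cnt[x > 1.75 * mu1_0]) / total
    return(new_phase_estimate(f1, 1 - f1 - f2, f2, mu1_0, NA_real_, method))
  }

  nll <- function(par) {
    mu1 <- exp(par[1]); cv <- exp(par[2])
    wraw <- c(0, par[3], par[4])
    w <- exp(wraw) / sum(exp(wraw)) # softmax: (g1, s, g2)
    dens <- w[1] * dnorm(x, mu1, cv * mu1) +
      w[2] * dunif(x, mu1, 2 * mu1) +
      w[3] * dnorm(x, 2 * mu1, 2 * cv * mu1)
    -sum(cnt * log(pmax(dens, 1e-300)))
  }
  fit <- tryCatch(
    optim(c(log(mu1_0), log(0.08), 0, 0), nll, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error") || fit$convergence != 0)
    abort(paste0("Mixture fit did not converge",
                 if (inherits(fit, "error")) paste0(": ", conditionMessage(fit))
                 else paste0(" (optim code ", fit$convergence, ")")))
  w <- exp(c(0, fit$par[3], fit$par[4]))
  w <- w / sum(w)
  warn_msg <- NULL
  if (w[3] < 1e-4) {
    warn_msg <- "2C mode effectively absent; f_g2 ~ 0."
    warn(warn_msg)
  }
  new_phase_estimate(w[1], w[2], w[3], exp(fit$par[1]), exp(fit$par[2]),
                     method, warn_msg)
}

new_phase_estimate <- function(f_g1, f_s, f_g2, mean_1c, cv, method,
                               warning = NULL, t_g1 = NA_real_,
                               t_s = NA_real_, t_g2 = NA_real_,
                               doubling_time_used = NA_real_) {
  structure(list(f_g1 = f_g1, f_s = f_s, f_g2 = f_g2,
                 t_g1 = t_g1, t_s = t_s, t_g2 = t_g2,
                 doubling_time_used = doubling_time_used,
                 mean_1c = mean_1c, cv = cv, method = method,
                 warning = warning),
            class = "phase_estimate")
}

#' Convert phase fractions into phase durations
#'
#' Multiplies each cell-cycle phase fraction by the population doubling
#' time: `t_phase = f_phase * doubling_time`. (This linear mapping ignores
#' the age structure of exponentially growing populations; it is the
#' conventional first-order estimate.)
#'
#' @param phases A `phase_estimate` (from [gate_dna_content()]) or a
#'   numeric vector `c(f_g1, f_s, f_g2)`.
#' @param doubling_time Doubling time in minutes (> 0).
#' @return A `phase_estimate` with `t_g1`, `t_s`, `t_g2` (minutes) filled
#'   in; durations sum to `doubling_time`.
#' @examples
#' phase_durations(c(0.25, 0.25, 0.50), 100)
#' @export
phase_durations <- function(phases, doubling_time) {
  if (doubling_time <= 0 || !is.finite(doubling_time))
    abort("`doubling_time` must be finite and > 0.")
  if (is.numeric(phases)) {
    stopifnot(length(phases) == 3)
    phases <- new_phase_estimate(phases[1], phases[2], phases[3],
                                 NA_real_, NA_real_, "supplied")
  }
  f <- c(phases$f_g1, phases$f_s, phases$f_g2)
  if (abs(sum(f) - 1) > 1e-6) abort("Phase fractions must sum to 1.")
  phases$t_g1 <- f[1] * doubling_time
  phases$t_s <- f[2] * doubling_time
  phases$t_g2 <- f[3] * doubling_time
  phases$doubling_time_used <- doubling_time
  phases
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth curve fit (sliding log-linear window)\n")
  if (x$no_growth) cat("  no growth detected\n")
  cat(sprintf("  rate: %.5g /min, doubling time: %.2f min, max OD: %.3f\n",
              x$growth_rate, x$doubling_time, x$max_od))
  if (!x$no_growth)
    cat(sprintf("  window: %g-%g min (%d points), R^2 %.4f\n",
                x$fit_window[1], x$fit_window[2], x$window_points,
                x$r_squared))
  invisible(x)
}

#' @export
print.phase_estimate <- function(x, ...) {
  cat("Cell-cycle phase estimate (", x$method, " gating)\n", sep = "")
  cat(sprintf("  fractions: G1 %.3f, S %.3f, G2/M %.3f\n",
              x$f_g1, x$f_s, x$f_g2))
  if (is.finite(x$doubling_time_used))
    cat(sprintf("  durations: G1 %.1f, S %.1f, G2/M %.1f min (Td %.1f)\n",
                x$t_g1, x$t_s, x$t_g2, x$doubling_time_used))
  invisible(x)
}
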