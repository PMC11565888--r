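#' Plot methods for evorepair results
#'
#' `ggplot2::autoplot()` methods: the `(g, ln r)` regression behind a
#' fitness estimate, a fitness trajectory with its power-law fit, a growth
#' curve with the fitted exponential window, and a gated DNA-content
#' histogram. [plot_cnv_profile()] draws a smoothed per-window delta
#' profile with called segments.
#'
#' @param object A fitted evorepair object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name evorepair-plots
NULL

#' @rdname evorepair-plots
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_abline geom_rect geom_hline labs theme_minimal annotate
#' @export
autoplot.fitness_fit <- function(object, ...) {
  ggplot(object$points, aes(x = .data$g, y = .data$log_ratio)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "steelblue") +
    labs(x = "Cumulative generations", y = "ln(test / reference)",
         title = sprintf("Relative fitness %+.4f per generation",
                         object$slope)) +
    theme_minimal()
}

#' @rdname evorepair-plots
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$generation, y = .data$fitness)) +
    geom_point() +
    labs(x = "Generations", y = "Mean relative fitness",
         title = if (object$converged)
           sprintf("w(t) = (%.3g t)^%.2f + %.2f", object$b, object$a,
                   object$w0)
         else "Power-law fit did not converge") +
    theme_minimal()
  if (object$converged) {
    tt <- seq(0, max(object$data$generation), length.out = 200)
    p <- p + geom_line(
      data = tibble(generation = tt,
                    fitness = (object$b * tt)^object$a + object$w0),
      colour = "steelblue")
  }
  p
}

#' @rdname evorepair-plots
#' @export
autoplot.growth_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$time_min, y = .data$od600)) +
    geom_point(size = 0.6) +
    labs(x = "Time (min)", y = "OD600",
         title = sprintf("rate %.4g /min, doubling %.1f min, max OD %.2f",
                         object$growth_rate, object$doubling_time,
                         object$max_od)) +
    theme_minimal()
  if (!object$no_growth)
    p <- p + annotate("rect", xmin = object$fit_window[1],
                      xmax = object$fit_window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "steelblue")
  p
}

#' @rdname evorepair-plots
#' @param hist The `dna_histogram` (or histogram tibble) that was gated.
#' @export
autoplot.phase_estimate <- function(object, hist, ...) {
  h <- if (inherits(hist, "dna_histogram")) hist$histogram else hist
  ggplot(h, aes(x = .data$bin_center, y = .data$count)) +
    geom_col(width = diff(h$bin_center[1:2]), fill = "grey70") +
    annotate("text", x = object$mean_1c, y = max(h$count),
             label = sprintf("G1 %.2f", object$f_g1)) +
    annotate("text", x = 2 * object$mean_1c, y = max(h$count),
             label = sprintf("G2 %.2f", object$f_g2)) +
    labs(x = "DNA content (a.u.)", y = "Events",
         title = sprintf("G1/S/G2 = %.2f / %.2f / %.2f",
                         object$f_g1, object$f_s, object$f_g2)) +
    theme_minimal()
}

#' @rdname evorepair-plots
#' @param windows Per-window tibble with `window_start` and `smoothed`
#'   (e.g. `cnv_pipeline()$windows`).
#' @param segments Optional segment tibble from [call_segments()].
#' @export
plot_cnv_profile <- function(windows, segments = NULL, ...) {
  p <- ggplot(windows, aes(x = .data$window_start / 1000,
                           y = .data$smoothed)) +
    geom_line(linewidth = 0.3) +
    geom_hline(yintercept = 0, colour = "grey50") +
    labs(x = "Position (kb)", y = "Copy-number delta vs ancestor") +
    theme_minimal()
  if (!is.null(segments) && nrow(segments) > 0)
    p <- p + geom_rect(data = segments,
                       aes(xmin = .data$start / 1000, xmax = .data$end / 1000,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15, fill = "tomato")
  p
}
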