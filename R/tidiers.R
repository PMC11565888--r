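#' Tidy and glance methods for evorepair fits
#'
#' Broom-style one-row-per-term (`tidy()`) and one-row-per-model
#' (`glance()`) summaries for the fitted objects returned by
#' [estimate_fitness()], [fit_power_law()], [fit_growth_curve()] and
#' [gate_dna_content()].
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name evorepair-tidiers
NULL

#' @rdname evorepair-tidiers
#' @export
tidy.fitness_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std_error = c(NA_real_, x$standard_error))
}

#' @rdname evorepair-tidiers
#' @export
glance.fitness_fit <- function(x, ...) {
  tibble(slope = x$slope, standard_error = x$standard_error,
         r_squared = x$r_squared, n_points = x$n_points)
}

#' @rdname evorepair-tidiers
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("a", "b", "w0"),
         estimate = c(x$a, x$b, x$w0),
         fixed = c(FALSE, FALSE, TRUE))
}

#' @rdname evorepair-tidiers
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, w0 = x$w0, r_squared = x$r_squared,
         r_squared_linear = x$r_squared_linear, converged = x$converged,
         n_points = x$n_points)
}

#' @rdname evorepair-tidiers
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("growth_rate", "doubling_time", "max_od"),
         estimate = c(x$growth_rate, x$doubling_time, x$max_od))
}

#' @rdname evorepair-tidiers
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(growth_rate = x$growth_rate, doubling_time = x$doubling_time,
         max_od = x$max_od, r_squared = x$r_squared,
         no_growth = x$no_growth)
}

#' @rdname evorepair-tidiers
#' @export
tidy.phase_estimate <- function(x, ...) {
  tibble(phase = c("G1", "S", "G2"),
         fraction = c(x$f_g1, x$f_s, x$f_g2),
         duration_min = c(x$t_g1, x$t_s, x$t_g2))
}

#' @rdname evorepair-tidiers
#' @export
glance.phase_estimate <- function(x, ...) {
  tibble(f_g1 = x$f_g1, f_s = x$f_s, f_g2 = x$f_g2,
         doubling_time_used = x$doubling_time_used, method = x$method)
}
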