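#' Fit the power-law adaptation model to a fitness trajectory
#'
#' Fits `w(t) = (b t)^a + w0` to mean-fitness-vs-generation points by
#' bounded nonlinear least squares, with the ancestral fitness `w0` fixed at
#' the measured t = 0 value (not estimated). `b` is the adaptation rate
#' (per generation) and `a` the diminishing-returns exponent. A straight
#' line is fitted alongside and both R-squared values are reported so the
#' two models can be compared. Optimisation failure is a reportable state
#' (`converged = FALSE`), not an exception, because real trajectories do
#' occasionally defeat the fit.
#'
#' Bounds are `b` in [0, 1], `a` in (0, 1.5]; the optimiser is restarted
#' from `a` in {0.3, 0.5, 0.8} and the best of the converged starts is kept.
#'
#' @param traj Tibble with columns `generation` and `fitness`, including a
#'   t = 0 point (used as `w0`); at least 4 points.
#' @param w0 Ancestral fitness; default taken from the `generation == 0` row.
#' @param fix_a Optional fixed value for the exponent `a`; with `fix_a = 1`
#'   the model degenerates to the straight line `b t + w0` and only `b` is
#'   estimated.
#' @return Object of class `powerlaw_fit`: `a`, `b`, `w0`, `r_squared`,
#'   `r_squared_linear`, `converged`, `n_points`, plus the data.
#' @examples
#' t <- seq(0, 1000, by = 100)
#' traj <- tibble::tibble(generation = t, fitness = (0.002 * t)^0.5 + 0.7)
#' fit_power_law(traj)
#' @export
fit_power_law <- function(traj, w0 = NULL, fix_a = NULL) {
  if (!all(c("generation", "fitness") %in% names(traj)))
    abort("`traj` needs columns `generation` and `fitness`.")
  traj <- arrange(traj, .data$generation)
  if (any(traj$generation < 0)) abort("Generations must be non-negative.")
  if (nrow(traj) < 4) abort("Need at least 4 trajectory points to fit.")
  if (is.null(w0)) {
    z <- traj$fitness[traj$generation == 0]
    if (length(z) == 0)
      abort("No generation-0 point; supply `w0` explicitly.")
    w0 <- mean(z)
  }
  t <- traj$generation
  w <- traj$fitness
  ss_tot <- sum((w - mean(w))^2)

  lin <- lm(w ~ t)
  r2_lin <- if (ss_tot > 0) 1 - sum(residuals(lin)^2) / ss_tot else NA_real_

  flat <- ss_tot < 1e-24
  best <- NULL
  if (!flat) {
    dat <- data.frame(t = t, w = w)
    starts <- if (is.null(fix_a)) c(0.3, 0.5, 0.8) else fix_a
    for (a0 in starts) {
      # crude b start: invert the model at the last point
      dw <- max(w[length(w)] - w0, 1e-6)
      b0 <- min(max(dw^(1 / a0) / max(t), 1e-9), 1)
      fit <- tryCatch(
        if (is.null(fix_a)) {
          minpack.lm::nlsLM(
            w ~ (b * t)^a + w0, data = dat,
            start = list(b = b0, a = a0),
            lower = c(b = 0, a = 1e-6), upper = c(b = 1, a = 1.5),
            control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
          a <- fix_a
          minpack.lm::nlsLM(
            w ~ (b * t)^a + w0, data = dat, start = list(b = b0),
            lower = c(b = 0), upper = c(b = 1),
            control = minpack.lm::nls.lm.control(maxiter = 200))
        },
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(residuals(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }

  if (flat || is.null(best)) {
    return(structure(
      list(a = NA_real_, b = if (flat) 0 else NA_real_, w0 = w0,
           r_squared = NA_real_, r_squared_linear = r2_lin,
           converged = FALSE, n_points = nrow(traj), data = traj),
      class = "powerlaw_fit"))
  }
  cf <- coef(best$fit)
  structure(
    list(a = if (is.null(fix_a)) unname(cf["a"]) else fix_a,
         b = unname(cf["b"]), w0 = w0,
         r_squared = 1 - best$rss / ss_tot, r_squared_linear = r2_lin,
         converged = TRUE, n_points = nrow(traj), data = traj),
    class = "powerlaw_fit")
}

#' Fit power-law models to many populations at once
#'
#' @param trajectories Tibble with columns `population`, `condition`
#'   (optional), `generation`, `fitness`.
#' @return Tibble with one row per population: `population`, `condition`,
#'   `a`, `b`, `w0`, `r_squared`, `r_squared_linear`, `converged`.
#' @export
fit_power_law_all <- function(trajectories) {
  grp <- intersect(c("population", "condition"), names(trajectories))
  trajectories %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::group_modify(function(d, key) {
      f <- fit_power_law(d)
      tibble(a = f$a, b = f$b, w0 = f$w0, r_squared = f$r_squared,
             r_squared_linear = f$r_squared_linear, converged = f$converged)
    }) %>%
    ungroup()
}

#' Pairwise comparison of adaptation rates between conditions
#'
#' Mann-Whitney (Wilcoxon rank-sum) tests on the fitted `b` values of every
#' pair of conditions, with Bonferroni correction over the number of pairs.
#' Non-converged fits are dropped; a condition left with no converged fits
#' is excluded with a warning.
#'
#' @param fits Tibble from [fit_power_law_all()] (needs `condition`, `b`,
#'   `converged`), or a named list of numeric `b` vectors.
#' @return Tibble: `group1`, `group2`, `n1`, `n2`, `statistic`, `p_value`,
#'   `adj_p_value` (Bonferroni, capped at 1).
#' @examples
#' compare_adaptation_rates(list(low = c(1, 2, 3), high = c(101, 102, 103)))
#' @export
compare_adaptation_rates <- function(fits) {
  if (is.data.frame(fits)) {
    lev <- unique(fits$condition) # keep groups whose fits all failed visible
    fits <- filter(fits, .data$converged)
    groups <- split(fits$b, factor(fits$condition, levels = lev))
  } else groups <- fits
  empty <- vapply(groups, function(g) length(g) == 0, logical(1))
  if (any(empty)) {
    warn(paste0("Excluding groups with no converged fits: ",
                paste(names(groups)[empty], collapse = ", ")))
    groups <- groups[!empty]
  }
  if (length(groups) < 2) abort("Need at least two groups with converged fits.")
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  res <- purrr::map(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    wt <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    tibble(group1 = pr[1], group2 = pr[2], n1 = length(a), n2 = length(b),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  }) %>% bind_rows()
  mutate(res, adj_p_value = pmin(1, .data$p_value * length(pairs)))
}

#' Serial-passage design: generations per passage and effective size
#'
#' In a serial-dilution regime the culture doubles back up by the dilution
#' factor each cycle, so generations per passage `n = log2(dilution_factor)`
#' and the effective population size is `Ne ~ N0 * n` with `N0` the
#' bottleneck census size.
#'
#' @param dilution_factor Fold-dilution per passage (> 1).
#' @param bottleneck_size Cells transferred at each passage (N0 >= 1).
#' @return Tibble with `dilution_factor`, `generations_per_passage`,
#'   `bottleneck_size`, `effective_size`.
#' @examples
#' design_passage(1000, 1e5) # ~10 generations/passage, Ne ~ 1e6
#' @export
design_passage <- function(dilution_factor, bottleneck_size) {
  if (any(dilution_factor <= 1)) abort("`dilution_factor` must be > 1.")
  if (any(bottleneck_size < 1)) abort("`bottleneck_size` must be >= 1.")
  n <- log2(dilution_factor)
  tibble(dilution_factor = dilution_factor,
         generations_per_passage = n,
         bottleneck_size = bottleneck_size,
         effective_size = bottleneck_size * n)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law adaptation fit: w(t) = (b t)^a + w0\n")
  if (x$converged) {
    cat(sprintf("  b = %.5g, a = %.4f, w0 = %.4f (fixed)\n", x$b, x$a, x$w0))
    cat(sprintf("  R^2 = %.4f (linear fit R^2 = %.4f), n = %d\n",
                x$r_squared, x$r_squared_linear, x$n_points))
  } else {
    cat(sprintf("  fit did not converge (n = %d, w0 = %.4f, b = %s)\n",
                x$n_points, x$w0, format(x$b)))
  }
  invisible(x)
}
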