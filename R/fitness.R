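#' Ratio of non-fluorescent to fluorescent events
#'
#' @param fluorescent,nonfluorescent Event counts from one flow sample.
#' @return `nonfluorescent / fluorescent` (vectorised).
#' @examples
#' compute_ratio(500, 1500)
#' @export
compute_ratio <- function(fluorescent, nonfluorescent) {
  if (any(fluorescent <= 0))
    abort("Reference strain extinct/undetected: fluorescent events must be > 0.")
  if (any(nonfluorescent < 0)) abort("Counts must be >= 0.")
  nonfluorescent / fluorescent
}

#' Generations elapsed between two total-event measurements
#'
#' `g = log2(events_t24 / events_t0)`: population doublings inferred from
#' the growth of total flow events over one culture cycle.
#'
#' @param events_t0,events_t24 Total events at the start and end of a cycle.
#' @return Number of generations (vectorised); negative values (culture
#'   shrank) are returned with a warning.
#' @examples
#' compute_generations(2000, 2048000) # 10 doublings
#' @export
compute_generations <- function(events_t0, events_t24) {
  if (any(events_t0 <= 0) || any(events_t24 <= 0))
    abort("Total event counts must be > 0.")
  g <- log2(events_t24 / events_t0)
  if (any(g < 0)) warn("Negative generation count: culture shrank between samples.")
  g
}

#' Estimate relative fitness from a competition count series
#'
#' Converts a flow count series (see [simulate_competition_counts()] /
#' [read_flow_counts()]) into `(g, ln r)` points — cumulative generations
#' from per-day total-event growth, natural-log ratio from the two channel
#' counts — and regresses `ln r` on `g` by ordinary least squares. The slope
#' is the per-generation relative fitness of the non-fluorescent test
#' strain versus the fluorescent reference.
#'
#' Cumulative generations start at 0 at the day-0 sample (the assay's
#' initial 5 h sample); each day contributes `log2(total_t24 / total_t0)`.
#' Optionally the regression is weighted by total channel events.
#'
#' @param series Flow-count tibble with columns `sample` (`"t0"`/`"t24"`),
#'   `day`, `fluorescent_events`, `nonfluorescent_events`, `total_events`.
#' @param weighted If `TRUE`, weight each point by its channel-event total.
#' @return Object of class `fitness_fit`: list with `slope` (relative
#'   fitness per generation), `intercept`, `standard_error`, `n_points`,
#'   `r_squared`, `points` (tibble of `g`, `log_ratio`) and the `lm` fit.
#' @examples
#' sim <- simulate_competition_counts(s = 0.05, days = 3, noiseless = TRUE)
#' estimate_fitness(sim)$slope
#' @export
estimate_fitness <- function(series, weighted = FALSE) {
  req <- c("sample", "day", "fluorescent_events", "nonfluorescent_events",
           "total_events")
  if (!all(req %in% names(series)))
    abort(paste0("`series` must have columns: ", paste(req, collapse = ", ")))
  if (nrow(series) < 2) abort("Need at least 2 valid (g, ln r) points.")

  per_day <- series %>%
    select("sample", "day", "total_events") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "total_events") %>%
    arrange(.data$day) %>%
    mutate(g_day = compute_generations(.data$t0, .data$t24),
           g_end = cumsum(.data$g_day),
           g_start = .data$g_end - .data$g_day)

  pts <- series %>%
    left_join(select(per_day, "day", "g_start", "g_end"), by = "day") %>%
    mutate(
      g = ifelse(.data$sample == "t0", .data$g_start, .data$g_end),
      ratio = compute_ratio(.data$fluorescent_events,
                            .data$nonfluorescent_events),
      log_ratio = log(.data$ratio),
      w = .data$fluorescent_events + .data$nonfluorescent_events
    ) %>%
    filter(is.finite(.data$log_ratio))

  if (nrow(pts) < 2) abort("Need at least 2 valid (g, ln r) points.")
  if (diff(range(pts$g)) < 1e-12) abort("No generation spread: identical g values.")

  fit <- if (weighted) lm(log_ratio ~ g, data = pts, weights = pts$w)
         else lm(log_ratio ~ g, data = pts)
  sm <- suppressWarnings(summary(fit)) # noiseless input fits exactly
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         standard_error = unname(sm$coefficients[2, 2]),
         n_points = nrow(pts), r_squared = sm$r.squared,
         points = select(pts, "day", "sample", "g", "log_ratio"),
         fit = fit),
    class = "fitness_fit"
  )
}

#' Normalize a fitness estimate against a baseline strain
#'
#' Per-generation log-fitness is additive, so normalization across
#' conditions (or against the deletion ancestor for delta-fitness) is the
#' difference of slopes.
#'
#' @param test,baseline `fitness_fit` objects, or bare slopes.
#' @return Delta fitness (test minus baseline), a number.
#' @examples
#' normalize_fitness(-0.10, -0.14)
#' @export
normalize_fitness <- function(test, baseline) {
  s <- function(x) if (inherits(x, "fitness_fit")) x$slope else as.numeric(x)
  s(test) - s(baseline)
}

#' Expected fitness of a genotype assuming additive mutation effects
#'
#' Adds each mutation's fitness effect (measured in the matching condition)
#' to the ancestor's fitness, the additivity assumption used to compare
#' computed with observed fitness of evolved clones.
#'
#' @param ancestor_fitness Per-generation relative fitness of the ancestor.
#' @param effects Tibble with columns `gene` and `effect`, or a bare numeric
#'   vector of effects (then duplicates are not checked).
#' @return Expected per-generation relative fitness.
#' @examples
#' computed_fitness(-0.15, tibble::tibble(gene = c("A", "B", "C"),
#'                                        effect = c(0.04, 0.03, 0.02)))
#' @export
computed_fitness <- function(ancestor_fitness, effects) {
  if (is.data.frame(effects)) {
    if (anyDuplicated(effects$gene))
      abort("Duplicate gene ids in `effects`; each mutation counts once.")
    effects <- effects$effect
  }
  ancestor_fitness + sum(effects)
}

#' Aggregate replicate fitness estimates per strain
#'
#' Mean and SD of replicate slopes (at least three independent biological
#' replicates in the assay design), optionally normalized against a
#' baseline strain measured in the same condition.
#'
#' @param estimates Tibble with columns `strain`, `replicate`, `slope`
#'   (e.g. built from repeated [estimate_fitness()] calls).
#' @param baseline Optional strain name to subtract (mean slope).
#' @return Tibble with `strain`, `n`, `mean_fitness`, `sd_fitness` and, if
#'   `baseline` is given, `delta_fitness`.
#' @export
aggregate_fitness <- function(estimates, baseline = NULL) {
  out <- estimates %>%
    group_by(.data$strain) %>%
    summarise(n = dplyr::n(), mean_fitness = mean(.data$slope),
              sd_fitness = sd(.data$slope), .groups = "drop")
  if (!is.null(baseline)) {
    if (!baseline %in% out$strain) abort("`baseline` strain not found.")
    b <- out$mean_fitness[out$strain == baseline]
    out <- mutate(out, delta_fitness = .data$mean_fitness - b)
  }
  out
}

#' Compare strain fitness by ANOVA with Tukey HSD
#'
#' One-way ANOVA of replicate slopes across strains followed by Tukey's
#' honestly-significant-difference pairwise comparisons, returned as a tidy
#' table of adjusted p-values.
#'
#' @param estimates Tibble with columns `strain` and `slope`.
#' @return List with `anova` (tibble: term, df, F, p) and `pairwise`
#'   (tibble: comparison, estimate, conf.low, conf.high, adj_p_value).
#' @export
compare_fitness <- function(estimates) {
  if (length(unique(estimates$strain)) < 2)
    abort("Need at least two strains to compare.")
  d <- data.frame(strain = factor(estimates$strain), slope = estimates$slope)
  fit <- aov(slope ~ strain, data = d)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$strain
  list(
    anova = tibble(term = trimws(rownames(an)), df = an$Df,
                   statistic = an$`F value`, p_value = an$`Pr(>F)`),
    pairwise = tibble(comparison = rownames(tk), estimate = tk[, "diff"],
                      conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
                      adj_p_value = tk[, "p adj"])
  )
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat("Competition fitness estimate\n")
  cat(sprintf("  slope (relative fitness / generation): %+.4f (SE %.4f)\n",
              x$slope, x$standard_error))
  cat(sprintf("  n points: %d, R^2: %.4f\n", x$n_points, x$r_squared))
  invisible(x)
}
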