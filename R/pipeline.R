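pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = "evorepair-run",
    stages = c("synthetic", "growth", "cellcycle", "fitness", "dynamics",
               "converge", "cnv"),
    # statistical / windowing parameters (field-standard defaults)
    alpha = 0.05,
    regulatory_bp = 500,
    orf_extension_bp = 1000,
    window_bp = 100,
    smoothing_span = 5,
    cnv_threshold = 0.5,
    cnv_min_windows = 10,
    window_points = 8,
    dilution_factor = 1000,
    # synthetic-stage scale
    n_genes = 6000,
    n_populations = 12,
    n_passages = 100,
    mutation_populations = 48,
    lambda = 2e-6,
    convergent_targets = list(GENE0100 = 50, GENE2000 = 50, GENE4000 = 50),
    competition_s = 0.03,
    competition_days = 3,
    events_per_sample = 1e5,
    depth_windows = 2000,
    mean_depth = 50,
    planted_segment = c(start = 501, end = 800, copy_number = 2),
    od_rate = 0.004, od_k = 1.2, od0 = 0.05,
    dna_fractions = c(g1 = 0.25, s = 0.25, g2 = 0.50),
    dna_events = 1e5
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config file (or takes a named list), fills in defaults for
#' unset keys, rejects unknown keys outright, and range-checks every
#' parameter. An empty file yields the all-defaults configuration.
#'
#' @param config Path to a YAML file, a named list, or `NULL` for defaults.
#' @return A validated list of class `run_config`.
#' @examples
#' cfg <- validate_config(list(alpha = 0.01, stages = "synthetic"))
#' cfg$alpha
#' @export
validate_config <- function(config = NULL) {
  defaults <- pipeline_defaults()
  user <- if (is.null(config)) list()
          else if (is.character(config)) yaml::read_yaml(config) %||% list()
          else config
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort(paste0("Unknown config keys: ", paste(unknown, collapse = ", ")))
  cfg <- defaults
  cfg[names(user)] <- user # wholesale replacement (no nested-list merging)

  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$regulatory_bp >= 0, "regulatory_bp must be >= 0")
  chk(cfg$orf_extension_bp >= 0, "orf_extension_bp must be >= 0")
  chk(cfg$window_bp > 0, "window_bp must be > 0")
  chk(cfg$smoothing_span >= 1 && cfg$smoothing_span %% 2 == 1,
      "smoothing_span must be odd and >= 1")
  chk(cfg$cnv_min_windows >= 1, "cnv_min_windows must be >= 1")
  chk(cfg$dilution_factor > 1, "dilution_factor must be > 1")
  chk(cfg$window_points >= 3, "window_points must be >= 3")
  chk(cfg$lambda >= 0, "lambda must be >= 0")
  chk(all(unlist(cfg$convergent_targets) >= 1),
      "convergent_targets enrichment factors must be >= 1")
  chk(abs(sum(cfg$dna_fractions) - 1) < 1e-9, "dna_fractions must sum to 1")
  chk(length(cfg$stages) > 0 &&
        all(cfg$stages %in% pipeline_defaults()$stages),
      "stages must be a subset of the known stage names")
  if (length(errs))
    abort(paste0("Invalid configuration:\n  - ",
                 paste(errs, collapse = "\n  - ")))
  structure(cfg, class = "run_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order: `synthetic` generates
#' every input (and truth files) under `output_dir`; `growth`, `cellcycle`,
#' `fitness`, `dynamics`, `converge` and `cnv` each read the synthetic
#' inputs, run the corresponding analysis and write TSV results. Identical
#' config and seed reproduce all outputs. A failing stage is recorded as
#' `failed` and its dependents are skipped.
#'
#' @param config A `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return Object of class `run_report`: tibble `stages` (stage, status,
#'   detail), list `results` with each stage's main table, and a
#'   `provenance` block (config hash, seed, package version).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  status <- tibble(stage = character(0), status = character(0),
                   detail = character(0))
  results <- list()
  synthetic_ok <- FALSE

  run_stage <- function(name, needs_synthetic, fun) {
    if (!name %in% cfg$stages) return(invisible())
    if (needs_synthetic && !synthetic_ok) {
      status <<- bind_rows(status, tibble(
        stage = name, status = "skipped",
        detail = "synthetic inputs unavailable"))
      return(invisible())
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status <<- bind_rows(status, tibble(stage = name, status = "failed",
                                          detail = conditionMessage(res)))
    } else {
      results[[name]] <<- res$result
      status <<- bind_rows(status, tibble(stage = name, status = "ok",
                                          detail = res$detail))
    }
    invisible()
  }

  run_stage("synthetic", FALSE, function() {
    genes <- make_gene_models(cfg$n_genes, seed = derive_seed(cfg$seed, "genes"))
    write_gene_models(genes, out("gene_models.tsv"))
    write_gene_models_gff3(genes, out("gene_models.gff3"))
    variants <- simulate_mutation_dataset(
      genes, cfg$lambda, cfg$mutation_populations,
      convergent_targets = unlist(cfg$convergent_targets),
      seed = derive_seed(cfg$seed, "mutations"))
    write_variants(variants, out("variants.tsv"))
    counts <- simulate_competition_counts(
      s = cfg$competition_s, days = cfg$competition_days,
      dilution_factor = cfg$dilution_factor,
      events_per_sample = cfg$events_per_sample,
      seed = derive_seed(cfg$seed, "competition"))
    write_flow_counts(counts, out("flow_counts.csv"))
    seg <- cfg$planted_segment
    prof <- simulate_depth_profile(
      cfg$depth_windows, cfg$mean_depth,
      planted_segments = list(unname(seg)),
      seed = derive_seed(cfg$seed, "depth"))
    write_depth(prof$ancestor, out("depth_ancestor.tsv"))
    write_depth(prof$evolved, out("depth_evolved.tsv"))
    od <- simulate_od_curve(cfg$od_rate, cfg$od_k, cfg$od0, noise_sd = 0.003,
                            seed = derive_seed(cfg$seed, "od"))
    write_od_curve(od, out("od600.csv"))
    f <- cfg$dna_fractions
    hist <- simulate_dna_histogram(f[["g1"]], f[["s"]], f[["g2"]],
                                   n_events = cfg$dna_events,
                                   seed = derive_seed(cfg$seed, "dna"))
    write_dna_histogram(hist, out("dna_content.csv"))
    sim <- simulate_serial_transfer(sim_config(
      seed = derive_seed(cfg$seed, "transfer"),
      n_populations = cfg$n_populations, n_passages = cfg$n_passages,
      dilution_factor = cfg$dilution_factor, gene_models = genes,
      target_genes = names(cfg$convergent_targets)))
    readr::write_tsv(mutate(sim$fitness, condition = "demo"),
                     out("fitness_trajectories.tsv"))
    write_truth_json(list(
      seed = cfg$seed, lambda = cfg$lambda,
      convergent_targets = cfg$convergent_targets,
      competition_s = cfg$competition_s,
      planted_segment = as.list(seg),
      od = list(rate = cfg$od_rate, K = cfg$od_k, od0 = cfg$od0),
      dna_fractions = as.list(f)), out("truth.json"))
    synthetic_ok <<- TRUE
    list(result = list(genes = genes), detail = "inputs + truth.json written")
  })

  run_stage("growth", TRUE, function() {
    od <- read_od_curve(out("od600.csv"))
    fit <- fit_growth_curve(od, window_points = cfg$window_points)
    res <- tibble(growth_rate = fit$growth_rate,
                  doubling_time = fit$doubling_time, max_od = fit$max_od,
                  r_squared = fit$r_squared)
    readr::write_tsv(res, out("growth_summary.tsv"))
    list(result = res, detail = sprintf("rate %.4g /min", fit$growth_rate))
  })

  run_stage("cellcycle", TRUE, function() {
    h <- read_dna_histogram(out("dna_content.csv"))
    gs <- results$growth
    td <- if (!is.null(gs)) gs$doubling_time else log(2) / cfg$od_rate
    ph <- phase_durations(gate_dna_content(h), td)
    res <- tibble(f_g1 = ph$f_g1, f_s = ph$f_s, f_g2 = ph$f_g2,
                  t_g1 = ph$t_g1, t_s = ph$t_s, t_g2 = ph$t_g2,
                  doubling_time_used = ph$doubling_time_used)
    readr::write_tsv(res, out("cellcycle_summary.tsv"))
    list(result = res,
         detail = sprintf("G1/S/G2 = %.2f/%.2f/%.2f", ph$f_g1, ph$f_s, ph$f_g2))
  })

  run_stage("fitness", TRUE, function() {
    counts <- read_flow_counts(out("flow_counts.csv"))
    fit <- estimate_fitness(counts)
    res <- tibble(slope = fit$slope, standard_error = fit$standard_error,
                  n_points = fit$n_points, r_squared = fit$r_squared)
    readr::write_tsv(res, out("fitness_estimate.tsv"))
    list(result = res, detail = sprintf("slope %+.4f", fit$slope))
  })

  run_stage("dynamics", TRUE, function() {
    traj <- readr::read_tsv(out("fitness_trajectories.tsv"),
                            show_col_types = FALSE) %>%
      rename(fitness = "mean_fitness")
    fits <- fit_power_law_all(traj)
    readr::write_tsv(fits, out("powerlaw_fits.tsv"))
    nc <- sum(!fits$converged)
    if (nc > 0)
      warn(paste0("Power-law fit not possible for population(s): ",
                  paste(fits$population[!fits$converged], collapse = ", ")))
    list(result = fits,
         detail = sprintf("%d/%d fits converged", sum(fits$converged),
                          nrow(fits)))
  })

  run_stage("converge", TRUE, function() {
    genes <- read_gene_models(out("gene_models.tsv"))
    variants <- read_variants(out("variants.tsv"))
    res <- detect_convergence(variants, genes, alpha = cfg$alpha)
    readr::write_tsv(as_tibble(res), out("convergence.tsv"))
    sig <- res$unit[res$significant]
    list(result = res,
         detail = sprintf("%d significant unit(s): %s", length(sig),
                          paste(sig, collapse = ", ")))
  })

  run_stage("cnv", TRUE, function() {
    evo <- read_depth(out("depth_evolved.tsv"))
    anc <- read_depth(out("depth_ancestor.tsv"))
    res <- cnv_pipeline(evo, anc, span = cfg$smoothing_span,
                        threshold = cfg$cnv_threshold,
                        min_windows = cfg$cnv_min_windows)
    readr::write_tsv(res$segments, out("cnv_segments.tsv"))
    list(result = res$segments,
         detail = sprintf("%d segment(s) called", nrow(res$segments)))
  })

  structure(
    list(stages = status, results = results,
         provenance = list(
           config = unclass(cfg), config_hash = rlang::hash(unclass(cfg)),
           seed = cfg$seed,
           package_version = as.character(utils::packageVersion("evorepair")),
           r_version = R.version.string,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("evorepair pipeline report (seed ", x$provenance$seed, ", config ",
      substr(x$provenance$config_hash, 1, 8), ")\n", sep = "")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-10s %-8s %s\n", x$stages$stage[i], x$stages$status[i],
                x$stages$detail[i]))
  invisible(x)
}
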