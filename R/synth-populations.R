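#' Configuration for the serial-transfer evolution simulator
#'
#' Bundles and validates the parameters of the forward simulation. Defaults
#' mirror the regime of the evolution experiment the package analyses:
#' twelve parallel populations per condition, daily 1:1000 dilutions
#' (log2(1000) ~ 10 generations per passage), 100 passages (~1000
#' generations), saturation around 1e8 cells so the bottleneck N0 is ~1e5
#' and Ne = N0 x n ~ 1e6.
#'
#' @param seed Integer seed for the whole simulation; per-population child
#'   seeds are derived with [derive_seed()].
#' @param n_populations Number of independent replicate populations.
#' @param n_passages Number of serial passages (growth/dilution cycles).
#' @param dilution_factor Fold-dilution at each passage (> 1).
#' @param saturation_size Census size at saturation (cells); the bottleneck
#'   is `saturation_size / dilution_factor`.
#' @param beneficial_rate,neutral_rate Mutations per cell per generation.
#' @param effect_size_distribution Distribution of per-generation log-fitness
#'   effects of beneficial mutations: `list(dist = "exponential", mean = s)`
#'   or `list(dist = "constant", value = s)`. The exponential is the
#'   canonical beneficial distribution-of-fitness-effects choice.
#' @param target_genes Character vector of gene ids that receive all
#'   beneficial mutations (convergence targets); `NULL` spreads beneficial
#'   hits uniformly over the gene universe.
#' @param gene_models Optional gene-model tibble ([make_gene_models()]) used
#'   to assign genes and positions to mutations; if `NULL`, neutral hits are
#'   drawn from a default universe of 1000 gene ids and positions are `NA`.
#' @param w0 Ancestral relative fitness (vs the assay reference strain).
#' @param init_effects,init_freqs Per-generation log-fitness effects and
#'   starting frequencies of the founding lineages (defaults: one neutral
#'   ancestor lineage at frequency 1).
#' @param deterministic If `TRUE`, the bottleneck keeps exact lineage
#'   proportions instead of multinomial sampling (drift switched off).
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_populations = 2, n_passages = 10)
#' cfg$bottleneck_size
#' @export
sim_config <- function(seed = 1L,
                       n_populations = 12,
                       n_passages = 100,
                       dilution_factor = 1000,
                       saturation_size = 1e8,
                       beneficial_rate = 1e-6,
                       neutral_rate = 1e-7,
                       effect_size_distribution = list(dist = "exponential",
                                                       mean = 0.05),
                       target_genes = NULL,
                       gene_models = NULL,
                       w0 = 0.85,
                       init_effects = 0,
                       init_freqs = 1,
                       deterministic = FALSE) {
  if (dilution_factor <= 1) abort("`dilution_factor` must be > 1.")
  if (beneficial_rate < 0 || neutral_rate < 0) abort("Mutation rates must be >= 0.")
  n0 <- saturation_size / dilution_factor
  if (n0 < 1) abort("Bottleneck size (saturation_size / dilution_factor) is < 1 cell.")
  if (!all(is.finite(init_effects))) abort("Non-finite fitness effect in `init_effects`.")
  if (length(init_effects) != length(init_freqs))
    abort("`init_effects` and `init_freqs` must have the same length.")
  if (abs(sum(init_freqs) - 1) > 1e-9) abort("`init_freqs` must sum to 1.")
  if (!is.null(target_genes) && !is.null(gene_models) &&
      !all(target_genes %in% gene_models$gene))
    abort("Some `target_genes` are absent from `gene_models`.")
  structure(
    list(seed = as.integer(seed), n_populations = n_populations,
         n_passages = n_passages, dilution_factor = dilution_factor,
         saturation_size = saturation_size,
         bottleneck_size = round(n0),
         generations_per_passage = log2(dilution_factor),
         beneficial_rate = beneficial_rate, neutral_rate = neutral_rate,
         effect_size_distribution = effect_size_distribution,
         target_genes = target_genes, gene_models = gene_models,
         w0 = w0, init_effects = init_effects, init_freqs = init_freqs,
         deterministic = deterministic),
    class = "sim_config"
  )
}

draw_effects <- function(k, dfe) {
  if (k == 0) return(numeric(0))
  eff <- switch(dfe$dist,
    exponential = rexp(k, rate = 1 / dfe$mean),
    constant = rep(dfe$value, k),
    abort(paste0("Unknown effect-size distribution '", dfe$dist, "'."))
  )
  if (!all(is.finite(eff))) abort("Non-finite fitness effect drawn.")
  eff
}

#' Simulate serial-transfer evolution with selection
#'
#' Forward Wright-Fisher simulation of the serial-dilution regime: at each
#' passage the population is bottlenecked by multinomial sampling of
#' `N0 = saturation_size / dilution_factor` cells, new mutant lineages are
#' injected (Poisson, rate per cell per generation, counted at the
#' bottleneck census), and the culture regrows deterministically to
#' saturation with lineage weights `exp(effect_sum * n)` over the
#' `n = log2(dilution_factor)` generations of the cycle.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `serial_transfer_sim`: a list with tibbles
#'   `lineages` (population, lineage, parent, effect_sum),
#'   `mutations` (population, mutation, lineage, gene, position, effect,
#'   read_fraction in percent at the final passage),
#'   `fitness` (population, passage, generation, mean_fitness), and
#'   `frequencies` (population, passage, lineage, freq; zero-frequency
#'   lineages omitted), plus the `config`.
#' @examples
#' sim <- simulate_serial_transfer(sim_config(seed = 1, n_populations = 1,
#'                                            n_passages = 5))
#' sim$fitness
#' @export
simulate_serial_transfer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pops <- purrr::map(seq_len(config$n_populations), function(p) {
    simulate_one_population(config, derive_seed(config$seed, paste0("pop", p))) %>%
      purrr::map(~ mutate(.x, population = paste0("pop", p), .before = 1))
  })
  out <- list(
    lineages = bind_rows(purrr::map(pops, "lineages")),
    mutations = bind_rows(purrr::map(pops, "mutations")),
    fitness = bind_rows(purrr::map(pops, "fitness")),
    frequencies = bind_rows(purrr::map(pops, "frequencies")),
    config = config
  )
  structure(out, class = "serial_transfer_sim")
}

simulate_one_population <- function(config, seed) {
  local_seed(seed)
  n_gen <- config$generations_per_passage
  n0 <- config$bottleneck_size
  dfe <- config$effect_size_distribution

  gene_pool <- if (!is.null(config$gene_models)) config$gene_models$gene
               else sprintf("GENE%04d", seq_len(1000))
  targets <- config$target_genes %||% gene_pool

  parent <- rep(0L, length(config$init_effects))
  effect <- config$init_effects
  freq <- config$init_freqs
  mut_lineage <- integer(0); mut_gene <- character(0)
  mut_pos <- numeric(0); mut_effect <- numeric(0)

  mean_fit <- numeric(config$n_passages + 1)
  mean_fit[1] <- config$w0 + sum(freq * effect)
  freq_log <- vector("list", config$n_passages + 1)
  freq_log[[1]] <- tibble(passage = 0L, lineage = seq_along(freq), freq = freq)

  assign_gene <- function(beneficial) {
    pool <- if (beneficial) targets else gene_pool
    g <- pool[sample.int(length(pool), 1L)]
    pos <- NA_real_
    if (!is.null(config$gene_models)) {
      row <- config$gene_models[config$gene_models$gene == g, ]
      pos <- floor(runif(1, row$start, row$end + 1))
    }
    list(gene = g, pos = pos)
  }

  for (pas in seq_len(config$n_passages)) {
    # 1. bottleneck (multinomial drift unless deterministic)
    if (!config$deterministic) {
      counts <- as.vector(rmultinom(1, size = n0, prob = freq))
      freq <- counts / n0
    }
    # 2. mutation supply at the bottleneck census
    k_b <- rpois(1, n0 * config$beneficial_rate * n_gen)
    k_n <- rpois(1, n0 * config$neutral_rate * n_gen)
    if (k_b + k_n > 0) {
      new_eff <- c(draw_effects(k_b, dfe), rep(0, k_n))
      is_ben <- c(rep(TRUE, k_b), rep(FALSE, k_n))
      for (j in seq_along(new_eff)) {
        par <- sample.int(length(freq), 1L, prob = freq)
        lid <- length(freq) + 1L
        parent <- c(parent, par)
        effect <- c(effect, effect[par] + new_eff[j])
        take <- min(1 / n0, freq[par])
        freq[par] <- freq[par] - take
        freq <- c(freq, take)
        ga <- assign_gene(is_ben[j])
        mut_lineage <- c(mut_lineage, lid)
        mut_gene <- c(mut_gene, ga$gene)
        mut_pos <- c(mut_pos, ga$pos)
        mut_effect <- c(mut_effect, new_eff[j])
      }
      freq <- freq / sum(freq)
    }
    # 3. deterministic regrowth with selection over n_gen generations
    w <- exp(effect * n_gen)
    freq <- freq * w
    freq <- freq / sum(freq)

    mean_fit[pas + 1] <- config$w0 + sum(freq * effect)
    keep <- freq > 0
    freq_log[[pas + 1]] <- tibble(passage = pas,
                                  lineage = which(keep), freq = freq[keep])
  }

  # final read fraction of each mutation: summed frequency of the subtree
  # rooted at the lineage that introduced it
  carries <- function(lin, anc) {
    while (lin > 0) {
      if (lin == anc) return(TRUE)
      lin <- parent[lin]
    }
    FALSE
  }
  final <- freq
  read_frac <- vapply(mut_lineage, function(anc) {
    100 * sum(final[vapply(seq_along(final), carries, logical(1), anc = anc)])
  }, numeric(1))

  list(
    lineages = tibble(lineage = seq_along(parent), parent = parent,
                      effect_sum = effect),
    mutations = tibble(mutation = seq_along(mut_lineage),
                       lineage = mut_lineage, gene = mut_gene,
                       position = mut_pos, effect = mut_effect,
                       read_fraction = read_frac),
    fitness = tibble(passage = 0:config$n_passages,
                     generation = (0:config$n_passages) * n_gen,
                     mean_fitness = mean_fit),
    frequencies = bind_rows(freq_log)
  )
}

#' Simulate per-population mutation tables under a Poisson null (or with
#' planted convergence targets)
#'
#' For every gene `g` with effective length `N_g = cds_length + 1000` and
#' every population, the number of mutations is drawn
#' `Poisson(lambda_true * N_g * enrichment_g)`; positions are uniform over
#' the gene's extended span (CDS +/- 500 bp) and read fractions uniform on
#' (0, 100] percent. With all enrichment factors at 1 this is the null model
#' of the convergence test; planted targets with enrichment > 1 provide the
#' alternative for power analyses.
#'
#' @param gene_models Gene-model tibble (see [make_gene_models()]).
#' @param lambda_true Per-base mutation rate (mutations / bp / population).
#' @param n_populations Number of independent populations.
#' @param convergent_targets Named numeric vector of enrichment factors
#'   (`c(GENE0005 = 50)`) or `NULL` for the pure null. Factors must be >= 1.
#' @param seed Integer seed (`NULL` = current stream).
#' @param synonymous_fraction Fraction of coding hits emitted as synonymous.
#' @return Tibble of variant records: `population`, `chrom`, `pos`, `ref`,
#'   `alt`, `read_fraction` (percent), `gene`, `annotation_class`.
#' @examples
#' genes <- make_gene_models(50, seed = 1)
#' v <- simulate_mutation_dataset(genes, 2e-6, 48, seed = 1)
#' @export
simulate_mutation_dataset <- function(gene_models, lambda_true, n_populations,
                                      convergent_targets = NULL, seed = NULL,
                                      synonymous_fraction = 0) {
  stopifnot(lambda_true >= 0, n_populations >= 1)
  if (!is.null(convergent_targets)) {
    if (is.null(names(convergent_targets)) || any(convergent_targets < 1))
      abort("`convergent_targets` must be a named vector of factors >= 1.")
    missing <- setdiff(names(convergent_targets), gene_models$gene)
    if (length(missing))
      abort(paste0("Unknown gene id in `convergent_targets`: ",
                   paste(missing, collapse = ", ")))
  }
  local_seed(seed)
  ng <- nrow(gene_models)
  enrich <- rep(1, ng)
  if (!is.null(convergent_targets))
    enrich[match(names(convergent_targets), gene_models$gene)] <- convergent_targets
  mu <- lambda_true * gene_models$N * enrich
  # hits per gene x population
  hits <- matrix(rpois(ng * n_populations, mu), nrow = ng)
  idx <- which(hits > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(population = character(0), chrom = character(0),
                  pos = integer(0), ref = character(0), alt = character(0),
                  read_fraction = numeric(0), gene = character(0),
                  annotation_class = character(0)))
  }
  reps <- hits[idx]
  gi <- rep(idx[, 1], reps)
  pop <- rep(idx[, 2], reps)
  gm <- gene_models[gi, ]
  pos <- floor(runif(length(gi), gm$start - 500, gm$end + 500 + 1))
  in_cds <- pos >= gm$start & pos <= gm$end
  cls <- ifelse(in_cds,
                ifelse(runif(length(gi)) < synonymous_fraction,
                       "synonymous", "nonsynonymous"),
                "regulatory")
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(gi), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  tibble(
    population = sprintf("pop%02d", pop),
    chrom = gm$chrom, pos = as.integer(pos), ref = ref, alt = unname(alt),
    read_fraction = 100 * (1 - runif(length(gi))), # uniform on (0, 100]
    gene = gm$gene, annotation_class = cls
  ) %>% arrange(.data$population, .data$chrom, .data$pos)
}
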