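test_that("serial transfer with all rates zero keeps mean fitness at w0", {
  cfg <- sim_config(seed = 7, n_populations = 2, n_passages = 15,
                    beneficial_rate = 0, neutral_rate = 0, w0 = 0.85)
  sim <- simulate_serial_transfer(cfg)
  expect_true(all(abs(sim$fitness$mean_fitness - 0.85) < 1e-12))
})

test_that("lineage frequencies sum to one at every passage", {
  cfg <- sim_config(seed = 11, n_populations = 3, n_passages = 25,
                    saturation_size = 1e7, beneficial_rate = 1e-5,
                    neutral_rate = 1e-6)
  sim <- simulate_serial_transfer(cfg)
  sums <- sim$frequencies |>
    dplyr::group_by(population, passage) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("a beneficial lineage rises monotonically under deterministic selection", {
  cfg <- sim_config(seed = 1, n_populations = 1, n_passages = 20,
                    beneficial_rate = 0, neutral_rate = 0,
                    init_effects = c(0.05, 0), init_freqs = c(0.5, 0.5),
                    deterministic = TRUE)
  sim <- simulate_serial_transfer(cfg)
  f1 <- sim$frequencies |>
    dplyr::filter(lineage == 1) |>
    dplyr::arrange(passage) |>
    dplyr::pull(freq)
  expect_length(f1, 21)
  expect_true(all(diff(f1) > 0))
})

test_that("final mutation read fractions equal summed carrier-lineage frequencies", {
  cfg <- sim_config(seed = 3, n_populations = 1, n_passages = 30,
                    saturation_size = 1e7, beneficial_rate = 2e-5)
  sim <- simulate_serial_transfer(cfg)
  final <- sim$frequencies |> dplyr::filter(passage == max(passage))
  lin <- sim$lineages
  # oracle: walk parent pointers independently of the implementation
  descends <- function(l, anc) {
    while (l > 0) { if (l == anc) return(TRUE); l <- lin$parent[lin$lineage == l] }
    FALSE
  }
  for (i in seq_len(min(5, nrow(sim$mutations)))) {
    m <- sim$mutations[i, ]
    carriers <- final$lineage[vapply(final$lineage, descends, logical(1),
                                     anc = m$lineage)]
    expect_equal(m$read_fraction,
                 100 * sum(final$freq[final$lineage %in% carriers]),
                 tolerance = 1e-9)
  }
})

test_that("target genes dominate hit counts across many simulation seeds", {
  genes <- make_gene_models(50, seed = 5)
  targets <- c("GENE0010", "GENE0020", "GENE0030")
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_populations = 6, n_passages = 20,
                      saturation_size = 1e7, beneficial_rate = 1e-5,
                      neutral_rate = 2e-6, target_genes = targets,
                      gene_models = genes)
    sim <- simulate_serial_transfer(cfg)
    hits <- sim$mutations |> dplyr::count(gene)
    target_hits <- hits$n[match(targets, hits$gene)]
    target_hits[is.na(target_hits)] <- 0
    neutral_max <- max(c(0, hits$n[!hits$gene %in% targets]))
    expect_gt(min(target_hits), neutral_max)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 42, n_populations = 2, n_passages = 10,
                    beneficial_rate = 1e-5, saturation_size = 1e7)
  expect_identical(simulate_serial_transfer(cfg)$mutations,
                   simulate_serial_transfer(cfg)$mutations)
  expect_identical(
    simulate_competition_counts(0.03, seed = 9),
    simulate_competition_counts(0.03, seed = 9))
  expect_identical(
    simulate_depth_profile(200, 50, seed = 9)$evolved,
    simulate_depth_profile(200, 50, seed = 9)$evolved)
  g <- make_gene_models(30, seed = 2)
  expect_identical(simulate_mutation_dataset(g, 1e-5, 4, seed = 9),
                   simulate_mutation_dataset(g, 1e-5, 4, seed = 9))
})

test_that("noiseless competition counts lie exactly on the expected log-ratio line", {
  s <- 0.05
  counts <- simulate_competition_counts(s = s, days = 3, dilution_factor = 1024,
                                        noiseless = TRUE, r0 = 1)
  lr <- log(counts$nonfluorescent_events / counts$fluorescent_events)
  g <- rep(c(0, 10), 3) + rep(c(0, 10, 20), each = 2)
  expect_true(all(abs(lr - s * g) < 1e-12))
  # s = 0, r0 = 1: channels identical everywhere
  eq <- simulate_competition_counts(s = 0, days = 2, noiseless = TRUE)
  expect_equal(eq$fluorescent_events, eq$nonfluorescent_events)
  # total events grow by the dilution factor within each day
  wide <- tidyr::pivot_wider(eq[, c("sample", "day", "total_events")],
                             names_from = sample, values_from = total_events)
  expect_true(all(wide$t24 / wide$t0 == 1000))
})

test_that("depth generator plants copy number where asked and nowhere else", {
  # noiseless: delta is exactly cn - 1
  prof <- simulate_depth_profile(300, 50, planted_segments = list(c(101, 200, 2)),
                                 noiseless = TRUE)
  expect_equal(prof$evolved$raw_depth[101:200], rep(100, 100))
  expect_equal(prof$evolved$raw_depth[-(101:200)], rep(50, 200))
  zero <- simulate_depth_profile(100, 50, planted_segments = list(c(11, 20, 0)),
                                 noiseless = TRUE)
  expect_true(all(zero$evolved$raw_depth[11:20] == 0))
  expect_error(
    simulate_depth_profile(100, 50,
                           planted_segments = list(c(1, 20, 2), c(15, 30, 3))),
    "overlap")
  # stochastic: depth in a long CN=2 segment averages ~2x the background
  means <- vapply(1:10, function(seed) {
    p <- simulate_depth_profile(1000, 50,
                                planted_segments = list(c(401, 600, 2)),
                                seed = seed)
    nd <- normalize_depth(p$evolved)
    mean(nd$normalized[401:600]) / median(nd$normalized[-(401:600)])
  }, numeric(1))
  expect_true(all(abs(means - 2) / 2 < 0.05))
})

test_that("OD generator matches the logistic closed form and handles edge cases", {
  od <- simulate_od_curve(r = 0.005, K = 1.2, od0 = 0.05, lag = 0,
                          noise_sd = 0, interval = 10, duration = 300)
  t <- od$time_min
  expect_equal(od$od600,
               1.2 * 0.05 * exp(0.005 * t) / (1.2 + 0.05 * (exp(0.005 * t) - 1)),
               tolerance = 1e-12)
  single <- simulate_od_curve(r = 0.01, K = 1, od0 = 0.1, duration = 0)
  expect_equal(nrow(single), 1)
  expect_equal(single$od600, 0.1)
})

test_that("DNA-content generator conserves events and degenerates correctly", {
  h <- simulate_dna_histogram(0.25, 0.25, 0.5, cv = 0.08, n_events = 5000,
                              seed = 1)
  expect_identical(sum(h$histogram$count), 5000L)
  pure_g1 <- simulate_dna_histogram(1, 0, 0, cv = 0.01, n_events = 2000,
                                    seed = 2)
  expect_true(all(abs(pure_g1$events - 100) < 10)) # all at the 1C position
  two_peaks <- simulate_dna_histogram(0.5, 0, 0.5, cv = 0.001,
                                      n_events = 10000, seed = 3)
  lower <- sum(two_peaks$events < 150) / 10000
  expect_equal(lower, 0.5, tolerance = 0.03)
  expect_error(simulate_dna_histogram(0.5, 0.2, 0.3, cv = 0), "cv")
  expect_error(simulate_dna_histogram(0.5, 0.2, 0.2, cv = 0.1), "sum to 1")
})

test_that("mutation-dataset generator honours rate, targets and errors", {
  genes <- make_gene_models(400, seed = 1)
  expect_identical(
    nrow(simulate_mutation_dataset(genes, 0, 10, seed = 1)), 0L)
  expect_error(
    simulate_mutation_dataset(genes, 1e-6, 10, c(NOPE = 5), seed = 1),
    "Unknown gene")
  # lambda recovery on a large null draw
  v <- simulate_mutation_dataset(genes, 2e-6, 48, seed = 4)
  lam <- compute_lambda(v, genes)
  expect_equal(lam$lambda, 2e-6 * 48, tolerance = 0.1)
  expect_true(all(v$read_fraction > 0 & v$read_fraction <= 100))
  expect_true(all(v$pos >= genes$start[match(v$gene, genes$gene)] - 500))
  expect_true(all(v$pos <= genes$end[match(v$gene, genes$gene)] + 500))
})
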