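test_that("variants are classified by position and codon effect", {
  genes <- fixture_genes()
  cds <- fixture_cds()
  v <- tibble::tibble(
    chrom = "chrA",
    pos = c(2003, 2006, 1701, 1400, 2006),
    ref = c("G", "T", "A", "A", "T"),
    alt = c("A", "C", "G", "G", "A"),
    population = "p1")
  cl <- classify_variants(v[1:4, ], genes, cds = cds)
  expect_identical(cl$annotation_class[1], "nonsynonymous") # ATG -> ATA, M -> I
  expect_identical(cl$annotation_class[3], "regulatory")    # 300 bp upstream
  expect_identical(cl$gene[3], "G1")
  expect_identical(cl$annotation_class[4], "intergenic")    # 601 bp upstream
  expect_true(is.na(cl$gene[4]))
  expect_error(classify_variants(
    tibble::tibble(chrom = "chrZ", pos = 1, ref = "A", alt = "C"), genes),
    "unknown contig")
})

test_that("codon check distinguishes synonymous from nonsynonymous SNVs", {
  genes <- fixture_genes()
  cds <- fixture_cds()
  # G1 CDS ATG GCT TAA at 2001-2009 (+): pos 2006 is codon 2 pos 3 (T)
  syn <- tibble::tibble(chrom = "chrA", pos = 2006, ref = "T", alt = "A")
  expect_identical(classify_variants(syn, genes, cds)$annotation_class,
                   "synonymous") # GCT -> GCA, both Ala
  nonsyn <- tibble::tibble(chrom = "chrA", pos = 2005, ref = "C", alt = "A")
  expect_identical(classify_variants(nonsyn, genes, cds)$annotation_class,
                   "nonsynonymous") # GCT -> GAT, Ala -> Asp
  # start codon ATG -> ATA (M -> I)
  m2i <- tibble::tibble(chrom = "chrA", pos = 2003, ref = "G", alt = "A")
  expect_identical(classify_variants(m2i, genes, cds)$annotation_class,
                   "nonsynonymous")
  # minus-strand gene G2 at 6001-6012, coding ATG AAA CCC TAA:
  # genomic pos 6012 is coding offset 0 (A of ATG); genomic base is T
  minus_syn <- tibble::tibble(chrom = "chrA", pos = 6004, ref = "G", alt = "C")
  # offset = 6012 - 6004 = 8 -> codon 3 (CCC) pos 3; C>G genomic = G>C coding
  expect_identical(classify_variants(minus_syn, genes, cds)$annotation_class,
                   "synonymous") # CCC -> CCG, both Pro
  # indel in CDS counts as a coding (nonsynonymous-equivalent) hit
  indel <- tibble::tibble(chrom = "chrA", pos = 2004, ref = "CT", alt = "C")
  expect_identical(classify_variants(indel, genes, cds)$annotation_class,
                   "nonsynonymous")
  # missing CDS with codon check requested falls back with a warning
  expect_warning(
    cl <- classify_variants(syn, genes, cds = cds["G2"]),
    "No CDS sequence")
  expect_identical(cl$annotation_class, "coding_unclassified")
})

test_that("lambda is the counted-mutation total over summed effective lengths", {
  genes <- tibble::tibble(gene = sprintf("g%d", 1:3), chrom = "c",
                          start = c(1, 5000, 9000), end = c(3000, 7999, 11999),
                          strand = "+", cds_length = c(2000, 2000, 2000),
                          N = c(3000, 3000, 3000))
  v <- tibble::tibble(annotation_class = c(rep("nonsynonymous", 5),
                                           rep("regulatory", 3),
                                           rep("synonymous", 4)))
  lam <- compute_lambda(v, genes)
  expect_equal(lam$lambda, 8 / 9000)
  expect_identical(lam$n_mutations, 8L)
  expect_message(
    lam0 <- compute_lambda(v[v$annotation_class == "synonymous", ], genes),
    "lambda = 0")
  expect_equal(lam0$lambda, 0)
  expect_error(compute_lambda(v, genes[0, ]), "denominator")
})

test_that("Poisson upper tail matches brute-force summation and known values", {
  expect_equal(poisson_tail(0, 5), 1.0)
  expect_equal(poisson_tail(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_tail(2, 1), 1 - 2 * exp(-1), tolerance = 1e-12)
  for (mu in c(0.01, 0.5, 2, 7.3)) {
    for (n in c(0, 1, 2, 5, 17)) {
      expect_equal(poisson_tail(n, mu), oracle_poisson_tail(n, mu),
                   tolerance = 1e-10)
    }
  }
  expect_error(poisson_tail(1, 0), "mu")
  expect_error(poisson_tail(-1, 1), "n_hits")
})

test_that("Poisson tail is monotone in hits and in expectation", {
  mu <- 3
  p_by_n <- poisson_tail(0:20, mu)
  expect_true(all(diff(p_by_n) < 0))
  mus <- seq(0.5, 10, by = 0.5)
  p_by_mu <- poisson_tail(rep(4, length(mus)), mus)
  expect_true(all(diff(p_by_mu) > 0))
})

test_that("BH correction reproduces the step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  bh <- bh_correct(p)
  expect_equal(bh$q_value, rep(0.04, 4))
  expect_equal(bh$q_value, oracle_bh(p))
  expect_equal(bh_correct(0.03)$q_value, 0.03)
  expect_false(any(bh_correct(c(0.5, 0.6))$significant))
  set.seed(2)
  pr <- runif(50)
  expect_equal(bh_correct(pr)$q_value, oracle_bh(pr))
  expect_true(all(bh_correct(pr)$q_value >= pr))
  expect_identical(nrow(bh_correct(numeric(0))), 0L)
  expect_error(bh_correct(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("convergence detection flags a strongly enriched gene", {
  genes <- make_gene_models(500, seed = 2)
  v <- simulate_mutation_dataset(genes, 2e-6, 48, c(GENE0123 = 50), seed = 7)
  res <- detect_convergence(v, genes)
  expect_s3_class(res, "convergence_result")
  expect_true("GENE0123" %in% res$unit[res$significant])
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  expect_true(all(res$significant == (res$q_value <= 0.05)))
  expect_identical(nrow(res), 500L)
  # sorted by q
  expect_true(!is.unsorted(res$q_value))
})

test_that("GO-term units sum member-gene lengths and hits", {
  genes <- make_gene_models(30, seed = 3)
  go_map <- tibble::tibble(
    gene = genes$gene[1:9],
    go_term = rep(c("GO:1", "GO:2", "GO:3"), each = 3))
  v <- simulate_mutation_dataset(genes, 5e-5, 10, seed = 5)
  expect_error(detect_convergence(v, genes, unit = "go_term"), "go_map")
  res <- detect_convergence(v, genes, unit = "go_term", go_map = go_map)
  expect_identical(nrow(res), 3L)
  for (term in res$unit) {
    members <- go_map$gene[go_map$go_term == term]
    expect_identical(res$N[res$unit == term],
                     sum(genes$N[genes$gene %in% members]))
  }
  # a term whose members have zero hits gets p = 1
  empty_map <- tibble::tibble(gene = genes$gene[10:12], go_term = "GO:EMPTY")
  v_none <- dplyr::filter(v, !gene %in% empty_map$gene)
  res2 <- detect_convergence(v_none, genes, unit = "go_term",
                             go_map = dplyr::bind_rows(go_map, empty_map))
  expect_equal(res2$p_value[res2$unit == "GO:EMPTY"], 1.0)
})

test_that("background filtering removes only shared significant units", {
  genes <- make_gene_models(200, seed = 4)
  focal <- detect_convergence(
    simulate_mutation_dataset(genes, 2e-6, 48, c(GENE0010 = 60,
                                                 GENE0020 = 60), seed = 1),
    genes)
  bg_empty <- detect_convergence(
    simulate_mutation_dataset(genes, 2e-6, 48, seed = 2), genes)
  # null background: very likely nothing significant; construct determinism
  bg_none <- dplyr::mutate(bg_empty, significant = FALSE)
  expect_identical(nrow(filter_background(focal, bg_none)), nrow(focal))
  bg_hit <- dplyr::mutate(bg_empty,
                          significant = bg_empty$unit == "GENE0010")
  filtered <- filter_background(focal, bg_hit)
  expect_false("GENE0010" %in% filtered$unit)
  expect_true("GENE0020" %in% filtered$unit)
})

test_that("clonality statistics summarise and test read-fraction profiles", {
  v <- tibble::tibble(
    population = rep(c("p1", "p2", "p3", "p4"), each = 3),
    read_fraction = c(10, 20, 30, 15, 25, 35, 60, 70, 80, 65, 75, 85),
    annotation_class = "nonsynonymous")
  groups <- tibble::tibble(population = c("p1", "p2", "p3", "p4"),
                           genotype = c("wt", "wt", "mut", "mut"),
                           condition = c("glc2", "glc2", "glc2", "glc2"))
  cs <- clonality_stats(v, groups)
  expect_equal(cs$per_population$median_read_fraction,
               c(20, 25, 70, 75))
  ks <- dplyr::filter(cs$tests, test == "kolmogorov_smirnov")
  expect_equal(ks$statistic, 1.0) # disjoint supports
  identical_groups <- clonality_stats(
    dplyr::mutate(v, read_fraction = rep(c(10, 20, 30), 4)), groups)
  ks2 <- dplyr::filter(identical_groups$tests, test == "kolmogorov_smirnov")
  expect_equal(ks2$statistic, 0)
  expect_equal(ks2$p_value, 1)
})

test_that("Fisher comparisons between conditions match hypergeometric enumeration", {
  tab <- tibble::tibble(
    unit = rep(c("u1", "u2"), each = 2),
    condition = rep(c("low", "high"), 2),
    n_hits = c(5, 0, 0, 5))
  res <- compare_units_between_conditions(tab)
  r1 <- dplyr::filter(res, unit == "u1")
  expect_equal(r1$p_value,
               oracle_fisher2x2(matrix(c(5, 0, 0, 5), 2)), tolerance = 1e-9)
  expect_equal(r1$p_value, 0.00794, tolerance = 1e-3)
  even <- tibble::tibble(unit = rep(c("u1", "u2"), each = 2),
                         condition = rep(c("a", "b"), 2),
                         n_hits = c(2, 2, 2, 2))
  expect_equal(compare_units_between_conditions(even)$p_value, c(1, 1))
  onecond <- tibble::tibble(unit = "u1", condition = c("a", "b"),
                            n_hits = c(3, 0))
  expect_error(compare_units_between_conditions(onecond), "non-empty")
})
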