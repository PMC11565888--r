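#' Classify variants against gene models
#'
#' Assigns each variant an annotation class following the mutation-calling
#' rule of the pipeline: a variant is a candidate mutation if it (1) causes
#' a non-synonymous substitution in a coding sequence or (2) falls in a
#' regulatory region, the 500 bp up- and downstream of the coding sequence.
#' Positions inside a gene span are coding; with per-gene CDS sequence
#' supplied, SNVs are translated codon-wise into `synonymous` /
#' `nonsynonymous`; indels in CDS count as coding (nonsynonymous-equivalent)
#' hits regardless of frame. Without CDS sequence coding SNVs are labelled
#' `coding_unclassified` with a warning when a codon check was requested.
#' Positions within 500 bp of a span are `regulatory` (assigned to that
#' gene); everything else is `intergenic`. If a position falls in the
#' extended span of several genes it is assigned to the gene with the
#' nearest CDS boundary; exact ties produce one row per gene, flagged.
#'
#' @param variants Tibble with `chrom`, `pos` (1-based), `ref`, `alt` and
#'   any carry-through columns (e.g. `population`, `read_fraction`).
#' @param genes Gene-model tibble (`gene`, `chrom`, `start`, `end`,
#'   `strand`, `cds_length`).
#' @param cds Optional named character vector of CDS nucleotide sequences
#'   (5'->3' on the coding strand), one per gene, enabling the codon check.
#' @param regulatory_bp Regulatory window half-width (default 500 bp).
#' @return The input tibble with `gene`, `annotation_class` and `tie` added;
#'   intergenic variants keep `gene = NA`.
#' @examples
#' genes <- tibble::tibble(gene = "G1", chrom = "chr01", start = 1001,
#'                         end = 1009, strand = "+", cds_length = 9)
#' v <- tibble::tibble(chrom = "chr01", pos = 700, ref = "A", alt = "G")
#' classify_variants(v, genes)$annotation_class # regulatory (301 bp upstream)
#' @export
classify_variants <- function(variants, genes, cds = NULL,
                              regulatory_bp = 500) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            all(c("gene", "chrom", "start", "end") %in% names(genes)))
  if (nrow(variants) == 0)
    return(mutate(variants, gene = character(0), annotation_class = character(0),
                  tie = logical(0)))
  bad <- !variants$chrom %in% genes$chrom
  if (any(bad))
    abort(paste0("Variant on unknown contig: ",
                 paste(unique(variants$chrom[bad]), collapse = ", ")))

  rows <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    g <- genes %>%
      filter(.data$chrom == v$chrom,
             v$pos >= .data$start - regulatory_bp,
             v$pos <= .data$end + regulatory_bp)
    if (nrow(g) == 0)
      return(mutate(v, gene = NA_character_,
                    annotation_class = "intergenic", tie = FALSE))
    # distance to the nearest CDS boundary; 0 inside the CDS span
    d <- pmax(0, pmax(g$start - v$pos, v$pos - g$end))
    g <- g[d == min(d), , drop = FALSE]
    tie <- nrow(g) > 1
    purrr::map(seq_len(nrow(g)), function(j) {
      gm <- g[j, ]
      inside <- v$pos >= gm$start && v$pos <= gm$end
      cls <- if (!inside) "regulatory"
             else classify_coding(v, gm, cds)
      mutate(v, gene = gm$gene, annotation_class = cls, tie = tie)
    }) %>% bind_rows()
  }) %>% bind_rows()
  rows
}

# Codon-level synonymous/nonsynonymous decision for a coding variant.
classify_coding <- function(v, gm, cds) {
  is_snv <- nchar(v$ref) == 1 && nchar(v$alt) == 1
  if (!is_snv) return("nonsynonymous") # indels in CDS count as coding hits
  if (is.null(cds) || !gm$gene %in% names(cds)) {
    if (!is.null(cds))
      warn(paste0("No CDS sequence for ", gm$gene,
                  "; coding variant left unclassified."))
    return(if (is.null(cds)) "nonsynonymous" else "coding_unclassified")
  }
  seq <- toupper(cds[[gm$gene]])
  # offset within the CDS on the coding strand
  off <- if (identical(gm$strand, "-")) gm$end - v$pos else v$pos - gm$start
  if (off < 0 || off >= nchar(seq)) return("nonsynonymous")
  ref <- toupper(v$ref); alt <- toupper(v$alt)
  if (identical(gm$strand, "-")) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- comp[[ref]]; alt <- comp[[alt]]
  }
  if (substr(seq, off + 1, off + 1) != ref)
    warn(paste0("Reference allele mismatch at ", gm$gene, " position ", v$pos))
  ci <- off %/% 3            # codon index (0-based)
  cp <- off %% 3             # position within codon
  codon <- substr(seq, ci * 3 + 1, ci * 3 + 3)
  mutated <- codon
  substr(mutated, cp + 1, cp + 1) <- alt
  aa0 <- seqinr::translate(strsplit(codon, "")[[1]])
  aa1 <- seqinr::translate(strsplit(mutated, "")[[1]])
  if (identical(aa0, aa1)) "synonymous" else "nonsynonymous"
}

#' Genome-wide per-base mutation rate
#'
#' `lambda = (SNPs + indels) / coding base pairs`, where the denominator is
#' the summed effective gene length `N = cds_length + 1000` (1000 bp per ORF
#' for regulatory sequence) and the numerator counts classified mutations in
#' the configured classes.
#'
#' @param variants Classified variant tibble ([classify_variants()] output
#'   or generator output with `annotation_class`).
#' @param genes Gene-model tibble with `cds_length` (or `N`).
#' @param count_classes Annotation classes entering the numerator.
#' @return List with `lambda`, `n_mutations`, `coding_bp`.
#' @examples
#' # 120 mutations over 9 Mb of effective coding sequence
#' @export
compute_lambda <- function(variants, genes,
                           count_classes = c("nonsynonymous", "regulatory",
                                             "coding_unclassified")) {
  N <- if ("N" %in% names(genes)) genes$N else genes$cds_length + 1000
  denom <- sum(N)
  if (denom <= 0) abort("Empty denominator: no coding base pairs.")
  n <- sum(variants$annotation_class %in% count_classes)
  if (n == 0)
    inform("No counted mutations: lambda = 0, convergence testing disabled.")
  list(lambda = n / denom, n_mutations = n, coding_bp = denom)
}

#' Poisson upper-tail probability via the incomplete gamma function
#'
#' `P(X >= n)` for `X ~ Poisson(mu)`, the probability of observing at least
#' `n` mutations in a gene with expectation `mu = lambda * N` under the
#' random-mutation null. Computed through the regularized incomplete gamma
#' identity `P(X >= n) = P(Gamma(n, 1) <= mu)`, i.e. `pgamma(mu, n)`.
#'
#' @param n_hits Observed mutation count(s), >= 0.
#' @param mu Expected count(s) `lambda * N`, > 0.
#' @return Tail probability in (0, 1] (vectorised).
#' @examples
#' poisson_tail(1, 1) # 1 - exp(-1)
#' @export
poisson_tail <- function(n_hits, mu) {
  if (any(mu <= 0)) abort("`mu` must be > 0.")
  if (any(n_hits < 0)) abort("`n_hits` must be >= 0.")
  ifelse(n_hits == 0, 1, pgamma(mu, pmax(n_hits, 1)))
}

#' Benjamini-Hochberg correction with significance flags
#'
#' Step-up false-discovery-rate adjustment (delegated to
#' `stats::p.adjust(method = "BH")`), flagging q-values at or below `alpha`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return Tibble with `p_value`, `q_value`, `significant`.
#' @examples
#' bh_correct(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0)
    return(tibble(p_value = numeric(0), q_value = numeric(0),
                  significant = logical(0)))
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must be in (0, 1].")
  q <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, q_value = q, significant = q <= alpha)
}

#' Detect convergent evolution across populations
#'
#' Pools mutation counts per unit (gene, or GO term with effective length
#' and hits summed over member genes) across all populations, computes the
#' Poisson upper-tail p-value at `mu = lambda * N_unit` with `lambda`
#' estimated from the same variant set, and applies Benjamini-Hochberg
#' correction across all tested units. Units mutated significantly more
#' often than the random null are the putatively adaptive (convergent)
#' targets.
#'
#' @param variants Classified variant tibble with `gene` and
#'   `annotation_class` (and `population`, carried but pooled).
#' @param genes Gene-model tibble.
#' @param unit `"gene"` or `"go_term"`.
#' @param go_map Tibble `gene`, `go_term` (required for the GO unit).
#' @param alpha FDR level.
#' @param count_classes Annotation classes counted as hits (also used for
#'   `lambda`; keep numerator and denominator consistent).
#' @param collapse_populations If `TRUE`, several hits to one gene within
#'   one population count once (sensitivity mode); default counts every
#'   mutation, as the Poisson model counts mutations.
#' @return Object of class `convergence_result`: tibble with `unit`,
#'   `n_hits`, `N`, `p_value`, `q_value`, `significant`, sorted by
#'   `q_value`, with `lambda` and settings as attributes.
#' @examples
#' genes <- make_gene_models(200, seed = 1)
#' v <- simulate_mutation_dataset(genes, 2e-6, 48, c(GENE0005 = 50), seed = 1)
#' head(detect_convergence(v, genes), 3)
#' @export
detect_convergence <- function(variants, genes, unit = c("gene", "go_term"),
                               go_map = NULL, alpha = 0.05,
                               count_classes = c("nonsynonymous", "regulatory",
                                                 "coding_unclassified"),
                               collapse_populations = FALSE) {
  unit <- match.arg(unit)
  if (unit == "go_term" && is.null(go_map))
    abort("GO-term unit requested without a `go_map`.")
  lam <- compute_lambda(variants, genes, count_classes)
  if (lam$lambda <= 0)
    abort("lambda is 0 (no counted mutations); convergence testing disabled.")
  counted <- filter(variants, .data$annotation_class %in% count_classes,
                    !is.na(.data$gene))
  if (collapse_populations)
    counted <- distinct(counted, .data$population, .data$gene)
  gene_hits <- counted %>% count(.data$gene, name = "n_hits")

  N <- if ("N" %in% names(genes)) genes$N else genes$cds_length + 1000
  per_gene <- tibble(gene = genes$gene, N = N) %>%
    left_join(gene_hits, by = "gene") %>%
    mutate(n_hits = tidyr::replace_na(.data$n_hits, 0L))

  units <- if (unit == "gene") {
    per_gene %>% rename(unit = "gene")
  } else {
    go_map %>%
      left_join(per_gene, by = "gene") %>%
      filter(!is.na(.data$N)) %>%
      group_by(unit = .data$go_term) %>%
      summarise(N = sum(.data$N), n_hits = sum(.data$n_hits),
                .groups = "drop")
  }
  bh <- bh_correct(poisson_tail(units$n_hits, lam$lambda * units$N), alpha)
  out <- units %>%
    mutate(p_value = bh$p_value, q_value = bh$q_value,
           significant = bh$significant) %>%
    arrange(.data$q_value, desc(.data$n_hits))
  structure(out, class = c("convergence_result", class(out)),
            lambda = lam$lambda, n_mutations = lam$n_mutations,
            coding_bp = lam$coding_bp, unit = unit, alpha = alpha)
}

#' Filter a convergence result against a background set
#'
#' Removes from the focal result any unit that is significant in the
#' background (e.g. genes significantly mutated in the wild-type
#' populations, which are generic media-adaptation targets rather than
#' responses to the perturbation under study).
#'
#' @param focal,background `convergence_result` tables on the same universe.
#' @return The focal table without units significant in the background.
#' @export
filter_background <- function(focal, background) {
  bg <- background$unit[background$significant]
  filter(focal, !.data$unit %in% bg)
}

#' Clonality and mutation-load statistics per population
#'
#' Per-population medians of variant read fractions and mutation counts,
#' compared between genotypes (Mann-Whitney on total and synonymous counts
#' and on median fractions), across conditions (Kruskal-Wallis on counts),
#' and between genotypes on the pooled read-fraction distributions
#' (two-sample Kolmogorov-Smirnov).
#'
#' @param variants Variant tibble with `population`, `read_fraction`,
#'   `annotation_class`.
#' @param groups Tibble mapping `population` to `genotype` and `condition`.
#' @return List: `per_population` summary tibble and `tests` tibble
#'   (test, grouping, response, statistic, p_value).
#' @export
clonality_stats <- function(variants, groups) {
  stopifnot(all(c("population", "genotype", "condition") %in% names(groups)))
  d <- variants %>% left_join(groups, by = "population")
  per_pop <- d %>%
    group_by(.data$population, .data$genotype, .data$condition) %>%
    summarise(n_mutations = dplyr::n(),
              n_synonymous = sum(.data$annotation_class == "synonymous"),
              median_read_fraction = median(.data$read_fraction),
              .groups = "drop")

  tests <- list()
  gts <- unique(per_pop$genotype)
  small <- any(table(per_pop$genotype) < 2)
  if (length(gts) == 2 && !small) {
    split2 <- function(col) split(per_pop[[col]], per_pop$genotype)
    for (resp in c("n_mutations", "n_synonymous", "median_read_fraction")) {
      s <- split2(resp)
      wt <- suppressWarnings(wilcox.test(s[[1]], s[[2]]))
      tests[[length(tests) + 1]] <-
        tibble(test = "mann_whitney", grouping = "genotype", response = resp,
               statistic = unname(wt$statistic), p_value = wt$p.value)
    }
    ks_s <- split(d$read_fraction, d$genotype)
    ks <- suppressWarnings(ks.test(ks_s[[1]], ks_s[[2]]))
    tests[[length(tests) + 1]] <-
      tibble(test = "kolmogorov_smirnov", grouping = "genotype",
             response = "read_fraction", statistic = unname(ks$statistic),
             p_value = ks$p.value)
  } else if (length(gts) >= 2) {
    warn("A genotype has < 2 populations; genotype tests skipped.")
  }
  if (length(unique(per_pop$condition)) >= 2) {
    kw <- kruskal.test(per_pop$n_mutations, factor(per_pop$condition))
    tests[[length(tests) + 1]] <-
      tibble(test = "kruskal_wallis", grouping = "condition",
             response = "n_mutations", statistic = unname(kw$statistic),
             p_value = kw$p.value)
  }
  list(per_population = per_pop,
       tests = if (length(tests)) bind_rows(tests)
               else tibble(test = character(0), grouping = character(0),
                           response = character(0), statistic = numeric(0),
                           p_value = numeric(0)))
}

#' Fisher's exact comparison of unit hits between conditions
#'
#' For every unit and every pair of conditions, builds the 2x2 table of
#' (hits in unit vs hits elsewhere) x (condition A vs condition B) and
#' applies a two-sided Fisher's exact test.
#'
#' @param hit_table Tibble `unit`, `condition`, `n_hits`.
#' @return Tibble `unit`, `condition1`, `condition2`, `odds_ratio`,
#'   `p_value`, `degenerate` (TRUE when a margin is zero, p fixed at 1).
#' @export
compare_units_between_conditions <- function(hit_table) {
  conds <- unique(hit_table$condition)
  conds <- conds[vapply(conds, function(cc)
    sum(hit_table$n_hits[hit_table$condition == cc]) > 0, logical(1))]
  if (length(conds) < 2) abort("Need two non-empty conditions to compare.")
  totals <- hit_table %>% group_by(.data$condition) %>%
    summarise(total = sum(.data$n_hits), .groups = "drop")
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    purrr::map(unique(hit_table$unit), function(u) {
      k <- function(cc) {
        v <- hit_table$n_hits[hit_table$unit == u & hit_table$condition == cc]
        if (length(v)) sum(v) else 0L
      }
      tot <- function(cc) totals$total[totals$condition == cc]
      m <- matrix(c(k(pr[1]), tot(pr[1]) - k(pr[1]),
                    k(pr[2]), tot(pr[2]) - k(pr[2])), nrow = 2)
      degen <- any(rowSums(m) == 0) || any(colSums(m) == 0)
      ft <- if (degen) NULL else fisher.test(m)
      tibble(unit = u, condition1 = pr[1], condition2 = pr[2],
             odds_ratio = if (degen) NA_real_ else unname(ft$estimate),
             p_value = if (degen) 1 else ft$p.value,
             degenerate = degen)
    }) %>% bind_rows()
  }) %>% bind_rows()
}
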