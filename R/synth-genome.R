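#' Build a synthetic yeast-like gene annotation
#'
#' Lays out `n_genes` non-overlapping gene models across 16 chromosomes with
#' log-normally distributed CDS lengths (median ~1.35 kb, the budding-yeast
#' scale) and intergenic gaps wide enough that the +/-500 bp regulatory
#' extensions of neighbouring genes never overlap. Used as the annotation
#' universe for the mutation-dataset generator and the convergence test.
#'
#' @param n_genes Number of genes to lay out.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param intergenic_gap Gap between consecutive gene spans in bp. Must be
#'   > 1000 so extended (+/-500 bp) spans stay disjoint.
#' @param cds_meanlog,cds_sdlog Log-normal parameters for CDS length.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`, `strand`,
#'   `cds_length` and the Poisson effective length `N = cds_length + 1000`
#'   (1-based inclusive coordinates).
#' @examples
#' genes <- make_gene_models(100, seed = 1)
#' all(genes$N == genes$cds_length + 1000)
#' @export
make_gene_models <- function(n_genes, seed = NULL, intergenic_gap = 1200,
                             cds_meanlog = log(1350), cds_sdlog = 0.45) {
  stopifnot(n_genes >= 1, intergenic_gap > 1000)
  local_seed(seed)
  cds <- round(exp(rnorm(n_genes, cds_meanlog, cds_sdlog)))
  cds <- pmin(pmax(cds, 300), 15000)
  cds <- cds - (cds %% 3) # whole codons
  chrom_of <- sort(rep_len(seq_len(16), n_genes))
  genes <- tibble(
    gene = sprintf("GENE%04d", seq_len(n_genes)),
    chrom = sprintf("chr%02d", chrom_of),
    cds_length = cds,
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  ) %>%
    group_by(.data$chrom) %>%
    mutate(
      start = intergenic_gap +
        cumsum(dplyr::lag(.data$cds_length + intergenic_gap, default = 0)),
      end = .data$start + .data$cds_length - 1
    ) %>%
    ungroup() %>%
    mutate(N = .data$cds_length + 1000) %>%
    select("gene", "chrom", "start", "end", "strand", "cds_length", "N")
  genes
}

#' Chromosome sizes implied by a gene-model table
#'
#' @param genes Gene-model tibble from [make_gene_models()] or
#'   [read_gene_models()].
#' @param margin Extra bp appended after the last gene of each chromosome.
#' @return Tibble with `chrom` and `length` (bp).
#' @export
contig_sizes <- function(genes, margin = 1200) {
  genes %>%
    group_by(.data$chrom) %>%
    summarise(length = max(.data$end) + margin, .groups = "drop")
}
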