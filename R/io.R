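#' Read and write the package's plain-text data dialects
#'
#' Small readers and writers for the tabular formats the pipeline consumes
#' and the generators emit: flow-cytometry competition counts (CSV),
#' variant tables (TSV or minimal VCF), gene annotations (TSV mirror or
#' GFF3), windowed read depths (TSV), OD600 curves (CSV), DNA-content
#' histograms (CSV) and gene-to-GO maps (TSV). All readers return tibbles.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @name evorepair-io
NULL

#' @rdname evorepair-io
#' @export
write_flow_counts <- function(x, path) {
  readr::write_csv(select(x, "sample", "day", "hours", "fluorescent_events",
                          "nonfluorescent_events", "total_events"), path)
  invisible(path)
}

#' @rdname evorepair-io
#' @export
read_flow_counts <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample = "c", day = "i"))
}

#' @rdname evorepair-io
#' @export
write_variants <- function(x, path) {
  cols <- intersect(c("population", "chrom", "pos", "ref", "alt",
                      "read_fraction", "gene", "annotation_class"), names(x))
  readr::write_tsv(select(x, dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname evorepair-io
#' @export
read_variants <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", pos = "i"))
}

#' Write variants as a minimal VCF (one file per population set)
#'
#' Emits a VCFv4.2 file with `CHROM POS ID REF ALT QUAL FILTER INFO`, the
#' read fraction as `AF` (fraction of reads, 0-1) and the population id as
#' `POP` in INFO.
#'
#' @rdname evorepair-io
#' @export
write_variants_vcf <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant read fraction\">",
           "##INFO=<ID=POP,Number=1,Type=String,Description=\"Population id\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6f;POP=%s",
                  x$chrom, x$pos, x$ref, x$alt, x$read_fraction / 100,
                  x$population %||% ".")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF into the variant-table dialect (requires vcfR)
#'
#' @rdname evorepair-io
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("Reading VCF requires the vcfR package.")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  pop <- vcfR::extract.info(v, "POP")
  tibble(population = pop, chrom = fix$CHROM, pos = as.integer(fix$POS),
         ref = fix$REF, alt = fix$ALT, read_fraction = 100 * af)
}

#' @rdname evorepair-io
#' @export
write_gene_models <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname evorepair-io
#' @export
read_gene_models <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"N" %in% names(g)) g <- mutate(g, N = .data$cds_length + 1000)
  g
}

#' Write gene models as GFF3 (1-based inclusive gene features)
#'
#' @rdname evorepair-io
#' @export
write_gene_models_gff3 <- function(x, path) {
  lines <- sprintf(
    "%s\tevorepair\tgene\t%d\t%d\t.\t%s\t.\tID=%s;cds_length=%d",
    x$chrom, x$start, x$end, x$strand, x$gene, x$cds_length)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname evorepair-io
#' @export
read_gene_models_gff3 <- function(path) {
  g <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_names = c("chrom", "source", "type", "start",
                                     "end", "score", "strand", "phase",
                                     "attributes"))
  g <- filter(g, .data$type == "gene")
  get_attr <- function(a, key)
    sub(paste0(".*", key, "=([^;]+).*"), "\\1", a)
  g %>%
    mutate(gene = get_attr(.data$attributes, "ID"),
           cds_length = as.integer(get_attr(.data$attributes, "cds_length")),
           N = .data$cds_length + 1000) %>%
    select("gene", "chrom", "start", "end", "strand", "cds_length", "N")
}

#' @rdname evorepair-io
#' @export
write_depth <- function(x, path) {
  readr::write_tsv(select(x, "chrom", "window_start", "raw_depth"), path)
  invisible(path)
}

#' @rdname evorepair-io
#' @export
read_depth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chrom = "c", window_start = "i"))
}

#' @rdname evorepair-io
#' @export
write_od_curve <- function(x, path) {
  readr::write_csv(select(x, "time_min", "well", "od600"), path)
  invisible(path)
}

#' @rdname evorepair-io
#' @export
read_od_curve <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname evorepair-io
#' @export
write_dna_histogram <- function(x, path) {
  h <- if (inherits(x, "dna_histogram")) x$histogram else x
  readr::write_csv(select(h, "bin_center", "count"), path)
  invisible(path)
}

#' @rdname evorepair-io
#' @export
read_dna_histogram <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname evorepair-io
#' @export
read_go_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_names = c("gene", "go_term"), comment = "#")
}

#' Write planted-truth parameters as JSON (for recovery tests)
#'
#' @param truth A named list of planted parameters.
#' @rdname evorepair-io
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
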