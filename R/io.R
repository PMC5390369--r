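#' Read / write Bismark-style cytosine report tables
#'
#' Headerless TSV with columns chrom, pos (1-based), strand, methylated
#' count, unmethylated count, context, trinucleotide — the per-cytosine
#' layout emitted by bisulfite callers.
#'
#' @param path File path.
#' @return A tibble of cytosine records.
#' @export
read_cytosine_report <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "strand", "count_m", "count_u",
                  "context", "trinucleotide"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      strand = readr::col_character(),
      count_m = readr::col_integer(),
      count_u = readr::col_integer(),
      context = readr::col_character(),
      trinucleotide = readr::col_character()
    ),
    progress = FALSE
  )
}

#' @rdname read_cytosine_report
#' @param records Cytosine record tibble.
#' @export
write_cytosine_report <- function(records, path) {
  records |>
    select("chrom", "pos", "strand", "count_m", "count_u",
           "context", "trinucleotide") |>
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write a gene-element annotation as GFF3
#'
#' Serialises the flat feature tibble used throughout the package (one row
#' per gene/promoter/exon/intron instance) through `rtracklayer`, storing
#' the element kind in the GFF3 `type` column and the gene id in the
#' `gene_id` attribute. `read_gene_annotation()` inverts it exactly.
#'
#' @param annotation Feature tibble from [simulate_annotation()] (columns
#'   `gene_id`, `chrom`, `strand`, `element`, `start`, `end`).
#' @param path GFF3 path.
#' @export
write_gene_annotation <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand
  )
  gr$type <- annotation$element
  gr$gene_id <- annotation$gene_id
  gr$ID <- sprintf("%s.%s.%d", annotation$gene_id, annotation$element,
                   seq_len(nrow(annotation)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    element = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) |>
    arrange(.data$chrom, .data$start, .data$gene_id, .data$element)
}

#' Write planted DMR truth intervals as BED
#'
#' 0-based half-open BED4+1: chrom, start, end, context, delta.
#'
#' @param dmrs Planted interval tibble (`chrom`, `start`, `end`,
#'   `context`, `delta`).
#' @param path Output path.
#' @export
write_truth_bed <- function(dmrs, path) {
  dmrs |>
    select("chrom", "start", "end", "context", "delta") |>
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "context", "delta"),
    col_types = "ciicd", progress = FALSE
  )
}

#' Write window methylation levels as per-context bedGraph tracks
#'
#' One bedGraph file per context (`<prefix>_<context>.bedGraph`), holding
#' chrom, start, end (0-based half-open) and pooled methylation level;
#' windows with no coverage in the context are omitted.
#'
#' @param windows Window table from [window_ml()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_window_bedgraph <- function(windows, dir, prefix = "window_ml") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ctx in unique(windows$context)) {
    f <- file.path(dir, paste0(prefix, "_", ctx, ".bedGraph"))
    windows |>
      filter(.data$context == ctx, !is.na(.data$ml)) |>
      select("chrom", "start", "end", "ml") |>
      readr::write_tsv(f, col_names = FALSE, progress = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Write detected DMRs as BED6+
#'
#' Columns: chrom, start, end, name, score (`-10 log10 q`, capped at
#' 10000), strand `"."`, then context scope, p, q, per-condition
#' methylation levels, delta and direction.
#'
#' @param dmrs DMR tibble from [detect_dmrs()]/[tidy()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(10000, round(-10 * log10(pmax(dmrs$qvalue, 1e-1000))))
  dmrs |>
    mutate(name = sprintf("dmr_%s_%d", .data$scope, row_number()),
           score = score, bed_strand = ".") |>
    select("chrom", "start", "end", "name", "score", "bed_strand",
           "scope", "pvalue", "qvalue", "ml_a", "ml_b", "delta_ml",
           "direction") |>
    readr::write_tsv(path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
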