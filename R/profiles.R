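#' Bin a gene element class into a 20-bin methylation metaprofile
#'
#' Each instance of the element (promoter, exon or intron) is scaled to
#' `n_bins` equal bins in the gene's 5'->3' orientation (minus-strand
#' instances are reversed so bin 1 is always nearest the TSS side). Every
#' covered site of the requested context contributes its corrected
#' methylation level to the bin(s) its single-base position overlaps, with
#' fractional weights where a base straddles a bin boundary; the profile
#' is the mean over instances of each defined bin.
#'
#' @param calls Site calls from [call_methylated_sites()] (needs `chrom`,
#'   `pos`, `context` and the `ml` column).
#' @param annotation Feature tibble (see [simulate_annotation()]).
#' @param element Element class: `"promoter"`, `"exon"` or `"intron"`
#'   (or `"gene"` for whole bodies).
#' @param context Cytosine context to profile.
#' @param n_bins Number of bins (20 by convention).
#' @param ml_col Which methylation-level column to average
#'   (`"ml_corrected"` by default).
#' @return A `meth_profile` tibble: `element`, `context`, `bin`,
#'   `mean_ml`, `n_elements` (instances contributing anywhere).
#' @export
bin_element_profile <- function(calls, annotation, element, context,
                                n_bins = 20, ml_col = "ml_corrected") {
  feats <- filter(annotation, .data$element == !!element)
  empty <- structure(
    tibble(element = character(), context = character(), bin = integer(),
           mean_ml = double(), n_elements = integer()),
    class = c("meth_profile", class(tibble())))
  if (!nrow(feats)) return(empty)
  sites <- filter(calls, .data$context == !!context,
                  !is.na(.data[[ml_col]]))
  per_inst <- purrr::pmap(
    feats[c("chrom", "strand", "start", "end")],
    function(chrom, strand, start, end) {
      hit <- which(sites$chrom == chrom & sites$pos >= start &
                     sites$pos <= end)
      if (!length(hit)) return(NULL)
      len <- end - start + 1
      # 0-based offset of the site's base within the element, 5'->3'
      off <- if (strand == "-") end - sites$pos[hit] else sites$pos[hit] - start
      bw <- bin_weights(off, len, n_bins)
      tibble(bin = bw$bin,
             w = bw$w,
             ml = sites[[ml_col]][hit][bw$site])
    })
  contributing <- !vapply(per_inst, is.null, logical(1))
  if (!any(contributing)) return(empty)
  inst_bins <- purrr::imap(per_inst[contributing], function(d, i) {
    d |>
      group_by(.data$bin) |>
      summarise(ml = sum(.data$w * .data$ml) / sum(.data$w),
                .groups = "drop") |>
      mutate(instance = i)
  }) |> bind_rows()
  prof <- inst_bins |>
    group_by(.data$bin) |>
    summarise(mean_ml = mean(.data$ml), .groups = "drop") |>
    tidyr::complete(bin = seq_len(n_bins)) |>
    mutate(element = element, context = context,
           n_elements = sum(contributing)) |>
    select("element", "context", "bin", "mean_ml", "n_elements")
  structure(prof, class = c("meth_profile", class(prof)))
}

# fractional overlap of 1-base sites with equal bins of an element of
# `len` bases; per element instance the weights of all positions sum to len
bin_weights <- function(off, len, n_bins) {
  binw <- len / n_bins
  lo <- off / binw           # base interval [lo, hi) in bin units
  hi <- (off + 1) / binw     # may span several bins when binw < 1
  b1 <- pmax(0, pmin(floor(lo), n_bins - 1))
  b2 <- pmax(b1, pmin(ceiling(hi) - 1, n_bins - 1))
  nb <- b2 - b1 + 1
  site <- rep(seq_along(off), nb)
  j <- sequence(nb, from = b1)
  w <- (pmin(hi[site], j + 1) - pmax(lo[site], j)) * binw
  keep <- w > 1e-12
  list(bin = as.integer(j[keep]) + 1L, w = w[keep], site = site[keep])
}

#' Metaprofiles for every element class and context
#'
#' Convenience wrapper over [bin_element_profile()] for the cross of
#' elements and contexts.
#'
#' @inheritParams bin_element_profile
#' @param elements Element classes to profile.
#' @param contexts Contexts to profile.
#' @return A `meth_profile` tibble stacking all element/context profiles.
#' @export
element_metaprofile <- function(calls, annotation,
                                elements = c("promoter", "exon", "intron"),
                                contexts = c("CG", "CHG", "CHH"),
                                n_bins = 20, ml_col = "ml_corrected") {
  out <- tidyr::expand_grid(element = elements, context = contexts) |>
    purrr::pmap(function(element, context) {
      bin_element_profile(calls, annotation, element, context,
                          n_bins = n_bins, ml_col = ml_col)
    }) |>
    bind_rows()
  structure(out, class = c("meth_profile", class(tibble())))
}

#' Normalise expression to the log-ratio scale
#'
#' Per gene, `fpkm_log_ratio = log10(FPKM) / log10(max(FPKM))`, so the
#' most expressed gene maps to 1 and an FPKM of 1 maps to 0. Requires
#' `max(FPKM) > 1` (otherwise the denominator is not positive); genes with
#' `FPKM <= 0` get `NA`.
#'
#' @param expression Tibble with `gene_id` and `fpkm`.
#' @return Input with an `fpkm_log_ratio` column.
#' @export
fpkm_log_ratio <- function(expression) {
  mx <- max(expression$fpkm, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 1) {
    stop("max(FPKM) must exceed 1 for the log-ratio to be defined",
         call. = FALSE)
  }
  mutate(expression, fpkm_log_ratio = ifelse(
    .data$fpkm > 0, log10(.data$fpkm) / log10(mx), NA_real_
  ))
}

#' Split sites into high- and low-methylation classes
#'
#' CG sites are "high" when their methylation level exceeds 0.75; CHG and
#' CHH sites when it exceeds 0.25 (strict inequalities); everything else
#' is "low". Thresholds are configurable per context.
#'
#' @inheritParams bin_element_profile
#' @param thresholds Named per-context thresholds.
#' @return `calls` with an added `meth_class` column (`"high"`/`"low"`).
#' @export
split_high_low <- function(calls,
                           thresholds = c(CG = 0.75, CHG = 0.25, CHH = 0.25),
                           ml_col = "ml_corrected") {
  thr <- unname(thresholds[calls$context])
  mutate(calls,
         meth_class = ifelse(.data[[ml_col]] > thr, "high", "low"))
}

#' Position frequency matrix around aligned methylcytosines
#'
#' Column base frequencies (optionally pseudocounted) of a set of
#' equal-length flanks with the cytosine at offset 0, plus per-offset
#' information content `2 - H` in bits, where `H` is the Shannon entropy
#' of the column over A/C/G/T.
#'
#' @param flanks Character vector of `2k + 1`-mers with C at the centre
#'   (e.g. the `flank` column of [extract_flanks()]).
#' @param pseudocount Count added to every cell before normalising.
#' @return A `meth_pfm` object: list with `freq` (4 x offsets matrix),
#'   `ic` (bits per offset), `n`. `tidy()` gives a long tibble.
#' @export
build_pfm <- function(flanks, pseudocount = 0) {
  if (!length(flanks)) stop("no flank sequences given", call. = FALSE)
  w <- unique(nchar(flanks))
  if (length(w) != 1L) stop("flanks must all have the same length", call. = FALSE)
  if (w %% 2L == 0L) stop("flank length must be odd (C at offset 0)", call. = FALSE)
  k <- (w - 1L) %/% 2L
  bases <- c("A", "C", "G", "T")
  mat <- matrix(unlist(strsplit(flanks, "", fixed = TRUE)), nrow = w)
  counts <- vapply(seq_len(w), function(i) {
    tabulate(factor(mat[i, ], levels = bases), nbins = 4L)
  }, numeric(4))
  counts <- counts + pseudocount
  freq <- sweep(counts, 2, colSums(counts), "/")
  dimnames(freq) <- list(base = bases, offset = as.character(-k:k))
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  ic <- 2 + colSums(plogp)
  structure(list(freq = freq, ic = ic, n = length(flanks), k = k),
            class = "meth_pfm")
}

#' @export
print.meth_pfm <- function(x, ...) {
  cat(sprintf("<meth_pfm> %d sequences, offsets -%d..%d\n", x$n, x$k, x$k))
  cat("information content (bits):\n")
  print(round(x$ic, 3))
  invisible(x)
}

#' @rdname build_pfm
#' @param x A `meth_pfm`.
#' @param ... Unused.
#' @method tidy meth_pfm
#' @export
tidy.meth_pfm <- function(x, ...) {
  as_tibble(as.data.frame.table(x$freq, responseName = "freq")) |>
    mutate(offset = as.integer(as.character(.data$offset)),
           base = as.character(.data$base)) |>
    left_join(tibble(offset = as.integer(names(x$ic)), ic = unname(x$ic)),
              by = "offset") |>
    arrange(.data$offset, .data$base)
}

#' Associate DMRs with overlapping gene elements
#'
#' Labels each DMR with the gene elements (promoter/exon/intron) it
#' overlaps, one row per (DMR, gene, element); DMRs overlapping no
#' annotated element are labelled `"intergenic"`. Promoters in the
#' annotation are already strand-aware.
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end` 0-based half-open).
#' @param annotation Feature tibble (1-based inclusive coordinates).
#' @return `dmrs` with `gene_id` and `element` columns added.
#' @export
associate_dmr_genes <- function(dmrs, annotation) {
  feats <- annotation |>
    filter(.data$element %in% c("promoter", "exon", "intron")) |>
    mutate(f_start0 = .data$start - 1L, f_end0 = .data$end)
  dmrs <- mutate(dmrs, .dmr_id = row_number())
  hits <- inner_join(
    dmrs, feats,
    by = join_by("chrom", overlaps("start", "end", "f_start0", "f_end0",
                                   bounds = "[)"))
  ) |>
    dplyr::distinct(.data$.dmr_id, .data$gene_id, .data$element)
  out <- left_join(dmrs, hits, by = ".dmr_id") |>
    mutate(element = ifelse(is.na(.data$element), "intergenic",
                            .data$element)) |>
    select(-".dmr_id")
  out
}

#' Predict CpG-island-like intervals
#'
#' Gardiner-Garden-style scan: every `window`-base window is evaluated for
#' GC fraction and observed/expected CpG ratio
#' `OE = (#CG dinucleotides * window) / (#C * #G)`; windows strictly
#' exceeding both `min_gc` and `min_oe` are merged into maximal runs, and
#' runs longer than `min_size` are reported.
#'
#' @param sequence A single DNA sequence (character).
#' @param min_size Minimum island size (strict, bases).
#' @param min_gc Minimum GC fraction (strict).
#' @param min_oe Minimum observed/expected CpG ratio (strict).
#' @param window Scanning window size.
#' @return Tibble of islands: `start`, `end` (0-based half-open), `gc`,
#'   `obs_exp` (recomputed over the merged interval).
#' @export
predict_cpg_islands <- function(sequence, min_size = 100, min_gc = 0.5,
                                min_oe = 0.6, window = 200) {
  sequence <- toupper(sequence[[1]])
  L <- nchar(sequence)
  if (L < min_size) stop("sequence shorter than `min_size`", call. = FALSE)
  empty <- tibble(start = integer(), end = integer(), gc = double(),
                  obs_exp = double())
  if (L < window) return(empty)
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  isC <- cumsum(c(0L, b == "C"))
  isG <- cumsum(c(0L, b == "G"))
  isCG <- cumsum(c(0L, 0L, b[-L] == "C" & b[-1] == "G"))
  starts <- seq_len(L - window + 1L)            # 1-based window starts
  stat <- function(s, e) {                      # 1-based inclusive
    nc <- isC[e + 1L] - isC[s]
    ng <- isG[e + 1L] - isG[s]
    ncg <- isCG[e + 1L] - isCG[s + 1L]          # CG dinucs starting in [s, e-1]
    len <- e - s + 1L
    list(gc = (nc + ng) / len,
         oe = ifelse(nc * ng > 0, ncg * len / (nc * ng), 0))
  }
  st <- stat(starts, starts + window - 1L)
  pass <- st$gc > min_gc & st$oe > min_oe
  if (!any(pass)) return(empty)
  # merge overlapping passing windows into maximal runs
  ps <- starts[pass]
  run_id <- cumsum(c(TRUE, diff(ps) > window))
  islands <- tibble(s = ps, id = run_id) |>
    group_by(.data$id) |>
    summarise(start1 = min(.data$s), end1 = max(.data$s) + window - 1L,
              .groups = "drop") |>
    filter(.data$end1 - .data$start1 + 1L > min_size)
  if (!nrow(islands)) return(empty)
  fin <- stat(islands$start1, islands$end1)
  tibble(start = islands$start1 - 1L, end = islands$end1,
         gc = fin$gc, obs_exp = fin$oe)
}
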