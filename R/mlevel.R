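#' Estimate the bisulfite non-conversion rate from a lambda spike-in
#'
#' The spike-in is fully unmethylated, so any read reporting a methylated
#' state at a lambda cytosine escaped conversion. The rate is the pooled
#' methylated fraction over all lambda cytosines,
#' `sum(count_m) / sum(count_m + count_u)`.
#'
#' @param lambda_records Cytosine record tibble for the lambda contig
#'   (columns `count_m`, `count_u`).
#' @return Non-conversion rate `r` in `[0, 1]`.
#' @export
estimate_nonconversion <- function(lambda_records) {
  total <- sum(lambda_records$count_m) + sum(lambda_records$count_u)
  if (total == 0) {
    stop("lambda records have zero total coverage", call. = FALSE)
  }
  sum(lambda_records$count_m) / total
}

#' Per-site methylation level
#'
#' `ML = count_m / (count_m + count_u)`, the fraction of reads reporting
#' the cytosine as methylated. Sites with zero coverage return `NA` (they
#' are undefined, not zero) and are excluded from summaries.
#'
#' @param count_m Methylated read counts.
#' @param count_u Unmethylated read counts.
#' @return Numeric vector of methylation levels in `[0, 1]` (`NA` where
#'   coverage is zero).
#' @examples
#' compute_ml(5, 15)   # 0.25
#' @export
compute_ml <- function(count_m, count_u) {
  total <- count_m + count_u
  ifelse(total > 0, count_m / total, NA_real_)
}

#' Correct methylation levels for bisulfite non-conversion
#'
#' Given non-conversion rate `r`, the corrected level is
#' `(ML - r) / (1 - r)`, clamped to `[0, 1]`. This inverts the
#' contamination `ML_obs = p + (1 - p) r` exactly in expectation.
#'
#' @param ml Raw methylation levels.
#' @param r Non-conversion rate, `0 <= r < 1`.
#' @return Corrected methylation levels.
#' @export
correct_ml <- function(ml, r) {
  if (length(r) != 1L || is.na(r) || r < 0 || r >= 1) {
    stop("`r` must be a single value in [0, 1)", call. = FALSE)
  }
  pmin(1, pmax(0, (ml - r) / (1 - r)))
}

#' Call methylated sites with a binomial non-conversion null
#'
#' Models the methylated count at a covered site as
#' `Binomial(count_m + count_u, r)` under the null that the site is
#' unmethylated and every methylated-looking read is a conversion failure.
#' The one-sided tail `P[X >= count_m]` is corrected across sites by
#' Benjamini-Hochberg; a site is called methylated when `q <= alpha`.
#' Raw and corrected methylation levels are attached.
#'
#' @param records Cytosine record tibble (`count_m`, `count_u`, ...).
#' @param r Non-conversion rate from [estimate_nonconversion()].
#' @param alpha FDR threshold for the methylated call.
#' @param min_coverage Minimum reads for a site to be tested (>= 1).
#' @return Input records (covered sites only) with `ml_raw`,
#'   `ml_corrected`, `pvalue`, `qvalue`, `is_methylated`.
#' @export
call_methylated_sites <- function(records, r, alpha = 0.05,
                                  min_coverage = 1) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  min_coverage <- max(1L, min_coverage)
  out <- records |>
    mutate(.coverage = .data$count_m + .data$count_u) |>
    filter(.data$.coverage >= min_coverage)
  out$ml_raw <- compute_ml(out$count_m, out$count_u)
  out$ml_corrected <- correct_ml(out$ml_raw, r)
  out$pvalue <- pbinom(out$count_m - 1L, out$.coverage, r,
                       lower.tail = FALSE)
  out$qvalue <- p.adjust(out$pvalue, method = "BH")
  out$is_methylated <- out$qvalue <= alpha
  select(out, -".coverage")
}

# all sliding windows of a chromosome: 0-based half-open starts every
# `step`, truncated at the chromosome end
tile_windows <- function(lengths, window, step) {
  purrr::map2(names(lengths), lengths, function(chrom, L) {
    if (L <= 0) return(NULL)
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    tibble(chrom = chrom, start = starts,
           end = pmin(starts + window, as.integer(L)))
  }) |> bind_rows()
}

# expand records to (record, window-start) pairs for overlapping windows
assign_windows <- function(records, window, step) {
  p0 <- records$pos - 1L
  kmax <- p0 %/% step
  kmin <- pmax(0L, (p0 - window) %/% step + 1L)
  nwin <- kmax - kmin + 1L
  tibble(
    row = rep(seq_len(nrow(records)), nwin),
    win_start = as.integer(sequence(nwin, from = kmin) * step)
  )
}

#' Pool methylation counts in sliding genomic windows
#'
#' Sums methylated and unmethylated read counts per window and context and
#' reports the pooled methylation level (sum m / sum total). Defaults to
#' 3,000 bp windows stepped by 600 bp. Windows with zero coverage in a
#' context are emitted with `NA` pooled ML. Chromosome extents come from
#' `genome` when supplied, otherwise from the largest covered position per
#' chromosome; chromosomes with no records emit no windows.
#'
#' @param records Cytosine record tibble.
#' @inheritParams as_genome
#' @param window Window width in bases.
#' @param step Step between window starts in bases.
#' @param contexts Contexts to tabulate.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `context`,
#'   `count_m`, `count_u`, `ml`.
#' @export
window_ml <- function(records, genome = NULL, window = 3000, step = 600,
                      contexts = c("CG", "CHG", "CHH")) {
  if (step > window) {
    warning("`step` exceeds `window`; positions between windows are skipped")
  }
  records <- filter(records, .data$context %in% contexts)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), count_m = integer(),
                  count_u = integer(), ml = double())
  if (!nrow(records) && is.null(genome)) return(empty)
  if (is.null(genome)) {
    lens <- records |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$pos), .groups = "drop")
    lengths <- setNames(lens$len, lens$chrom)
  } else {
    cl <- chrom_lengths(genome)
    lengths <- setNames(cl$length, cl$chrom)
  }
  tiles <- tile_windows(lengths, window, step)
  if (is.null(tiles) || !nrow(tiles)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), count_m = integer(),
                  count_u = integer(), ml = double()))
  }
  asg <- assign_windows(records, window, step)
  pooled <- tibble(
    chrom = records$chrom[asg$row],
    start = asg$win_start,
    context = records$context[asg$row],
    count_m = records$count_m[asg$row],
    count_u = records$count_u[asg$row]
  ) |>
    group_by(.data$chrom, .data$start, .data$context) |>
    summarise(count_m = sum(.data$count_m), count_u = sum(.data$count_u),
              .groups = "drop")
  tidyr::expand_grid(tiles, context = contexts) |>
    left_join(pooled, by = c("chrom", "start", "context")) |>
    mutate(
      count_m = tidyr::replace_na(.data$count_m, 0L),
      count_u = tidyr::replace_na(.data$count_u, 0L),
      ml = compute_ml(.data$count_m, .data$count_u)
    ) |>
    arrange(.data$chrom, .data$start, .data$context)
}

#' Context composition summaries of methylated cytosines
#'
#' Computes, per condition, the two percentage families of a
#' bisulfite-study summary table: the share of methylated cytosines in
#' each context among all methylated cytosines (composition), and the
#' percentage of methylated cytosines among all covered cytosines of each
#' context (penetrance). Percentages are kept unrounded and additionally
#' reported rounded half-up to 2 decimals.
#'
#' @param calls Output of [call_methylated_sites()]; if a `condition`
#'   column is present the summary is stratified by it.
#' @return Tibble with rows per (condition,) context (`CG`, `CHG`, `CHH`,
#'   `all`) and columns `n_sites`, `n_methylated`, `pct_of_mc`,
#'   `pct_methylated` plus their `_2dp` rounded versions.
#' @export
context_summary <- function(calls) {
  calls <- filter(calls, .data$context %in% c("CG", "CHG", "CHH"))
  if (!"condition" %in% names(calls)) calls$condition <- NA_character_
  per_ctx <- calls |>
    group_by(.data$condition, .data$context) |>
    summarise(n_sites = n(), n_methylated = sum(.data$is_methylated),
              .groups = "drop_last") |>
    mutate(pct_of_mc = 100 * .data$n_methylated / sum(.data$n_methylated)) |>
    ungroup()
  overall <- per_ctx |>
    group_by(.data$condition) |>
    summarise(context = "all", n_sites = sum(.data$n_sites),
              n_methylated = sum(.data$n_methylated),
              pct_of_mc = 100, .groups = "drop")
  bind_rows(per_ctx, overall) |>
    mutate(
      pct_methylated = 100 * .data$n_methylated / .data$n_sites,
      pct_of_mc_2dp = round_half_up(.data$pct_of_mc),
      pct_methylated_2dp = round_half_up(.data$pct_methylated)
    ) |>
    arrange(.data$condition,
            match(.data$context, c("all", "CG", "CHG", "CHH")))
}

#' Summarise a bisulfite sequencing run table
#'
#' Given per-sample clean/mapped read counts and per-context methylated
#' cytosine tallies, computes the derived summary cells: mapping rate (%)
#' and each context's share of all methylated cytosines (%), rounded
#' half-up to 2 decimals alongside the exact values.
#'
#' @param runs Tibble with columns `sample`, `total_reads`,
#'   `mapped_reads`, `mc_cg`, `mc_chg`, `mc_chh`.
#' @return Tibble with `mc_total`, `mapping_rate_pct`, `pct_mcg`,
#'   `pct_mchg`, `pct_mchh` and `_2dp` rounded versions.
#' @export
bisulfite_run_summary <- function(runs) {
  runs |>
    mutate(
      mc_total = .data$mc_cg + .data$mc_chg + .data$mc_chh,
      mapping_rate_pct = 100 * .data$mapped_reads / .data$total_reads,
      pct_mcg = 100 * .data$mc_cg / .data$mc_total,
      pct_mchg = 100 * .data$mc_chg / .data$mc_total,
      pct_mchh = 100 * .data$mc_chh / .data$mc_total,
      across(c("mapping_rate_pct", "pct_mcg", "pct_mchg", "pct_mchh"),
             round_half_up, .names = "{.col}_2dp")
    )
}
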