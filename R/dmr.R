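#' Two-sided Fisher exact test for 2x2 methylation count tables
#'
#' Computes the two-sided Fisher exact p-value by hypergeometric
#' enumeration: the sum of probabilities of all tables with the observed
#' margins whose probability does not exceed the observed table's (with
#' the conventional `1 + 1e-7` tie guard). Vectorised over windows; a
#' single 2x2 matrix `rbind(c(m_a, u_a), c(m_b, u_b))` may be given
#' instead.
#'
#' @param m_a,u_a Methylated/unmethylated pooled counts, condition A (or a
#'   2x2 matrix as the only argument).
#' @param m_b,u_b Counts for condition B.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher_window_test(rbind(c(10, 10), c(10, 10)))  # 1
#' @export
fisher_window_test <- function(m_a, u_a = NULL, m_b = NULL, u_b = NULL) {
  if (is.matrix(m_a)) {
    stopifnot(all(dim(m_a) == c(2L, 2L)))
    tab <- m_a
    m_a <- tab[1, 1]; u_a <- tab[1, 2]; m_b <- tab[2, 1]; u_b <- tab[2, 2]
  }
  if (any(c(m_a, u_a, m_b, u_b) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  vapply(seq_along(m_a), function(i) {
    r1 <- m_a[i] + u_a[i]
    r2 <- m_b[i] + u_b[i]
    c1 <- m_a[i] + m_b[i]
    if (r1 + r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
    lo <- max(0, c1 - r2)
    hi <- min(c1, r1)
    dk <- dhyper(lo:hi, r1, r2, c1)
    dobs <- dhyper(m_a[i], r1, r2, c1)
    min(1, sum(dk[dk <= dobs * (1 + 1e-7)]))
  }, numeric(1))
}

# pooled per-window, per-scope counts (contexts plus an all-C "combined")
pool_window_counts <- function(records, lengths, window, step, scopes) {
  base_ctx <- intersect(c("CG", "CHG", "CHH"), unique(records$context))
  records <- filter(records, .data$context %in% base_ctx)
  tiles <- tile_windows(lengths, window, step)
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
  if ("combined" %in% scopes) {
    comb <- pooled |>
      group_by(.data$chrom, .data$start) |>
      summarise(count_m = sum(.data$count_m), count_u = sum(.data$count_u),
                .groups = "drop") |>
      mutate(context = "combined")
    pooled <- bind_rows(pooled, comb)
  }
  pooled <- rename_scope(pooled)
  tidyr::expand_grid(tiles, scope = scopes) |>
    left_join(pooled, by = c("chrom", "start", "scope")) |>
    mutate(count_m = tidyr::replace_na(.data$count_m, 0L),
           count_u = tidyr::replace_na(.data$count_u, 0L))
}

rename_scope <- function(x) {
  names(x)[names(x) == "context"] <- "scope"
  x
}

#' Build per-window 2x2 count tables for two conditions
#'
#' Pools methylated/unmethylated counts of both conditions in sliding
#' windows (default 1,000 bp stepped by 100 bp) per context scope, giving
#' the `[[m_A, u_A], [m_B, u_B]]` table tested by
#' [fisher_window_test()]. Windows where either condition has fewer than
#' `min_coverage` pooled reads are skipped; the number skipped per scope
#' is in the `"skipped"` attribute.
#'
#' @param records_a,records_b Cytosine record tibbles for the two
#'   conditions, on the same genome.
#' @inheritParams window_ml
#' @param scopes Context scopes to test: any of `"CG"`, `"CHG"`, `"CHH"`,
#'   `"combined"` (all contexts pooled).
#' @param min_coverage Minimum pooled reads per window per condition.
#' @return Tibble `chrom`, `start`, `end`, `scope`, `m_a`, `u_a`, `m_b`,
#'   `u_b`, `ml_a`, `ml_b`.
#' @export
window_pair_counts <- function(records_a, records_b, genome = NULL,
                               window = 1000, step = 100,
                               scopes = c("CG", "CHG", "CHH", "combined"),
                               min_coverage = 10) {
  if (!setequal(unique(records_a$chrom), unique(records_b$chrom))) {
    stop("conditions cover different chromosome sets", call. = FALSE)
  }
  if (is.null(genome)) {
    lens <- bind_rows(records_a["chrom"] |> mutate(pos = records_a$pos),
                      records_b["chrom"] |> mutate(pos = records_b$pos)) |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$pos), .groups = "drop")
    lengths <- setNames(lens$len, lens$chrom)
  } else {
    cl <- chrom_lengths(genome)
    lengths <- setNames(cl$length, cl$chrom)
  }
  pa <- pool_window_counts(records_a, lengths, window, step, scopes)
  pb <- pool_window_counts(records_b, lengths, window, step, scopes)
  out <- inner_join(
    pa |> dplyr::rename(m_a = "count_m", u_a = "count_u"),
    pb |> dplyr::rename(m_b = "count_m", u_b = "count_u"),
    by = c("chrom", "start", "end", "scope")
  )
  keep <- (out$m_a + out$u_a) >= min_coverage &
    (out$m_b + out$u_b) >= min_coverage
  res <- out[keep, , drop = FALSE] |>
    mutate(ml_a = compute_ml(.data$m_a, .data$u_a),
           ml_b = compute_ml(.data$m_b, .data$u_b)) |>
    arrange(.data$chrom, .data$start, .data$scope)
  attr(res, "skipped") <- sum(!keep)
  res
}

#' Benjamini-Hochberg adjustment and significance selection
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param alpha FDR threshold.
#' @return Tibble `pvalue`, `qvalue`, `significant` (`qvalue <= alpha`).
#' @export
adjust_and_select <- function(pvalues, alpha = 0.05) {
  q <- p.adjust(pvalues, method = "BH")
  tibble(pvalue = pvalues, qvalue = q, significant = q <= alpha)
}

#' Merge significant windows into differentially methylated regions
#'
#' Significant windows of the same context scope that overlap (or are
#' separated by at most `max_gap` bases) merge into one region. Each
#' merged region re-pools the site counts of both conditions over its full
#' interval and recomputes the Fisher p-value, methylation levels, signed
#' `delta_ml = ML_B - ML_A` and direction (`hyper` when condition B
#' exceeds A). q-values are BH-adjusted across the merged regions.
#'
#' @param windows Significant window tibble (`chrom`, `start`, `end`,
#'   `scope`), e.g. the significant rows of [window_pair_counts()] +
#'   [adjust_and_select()].
#' @inheritParams window_pair_counts
#' @param max_gap Maximum gap (bases) between windows that still merge.
#' @return DMR tibble: `chrom`, `start`, `end`, `scope`, `n_windows`,
#'   counts, `ml_a`, `ml_b`, `delta_ml`, `direction`, `pvalue`, `qvalue`.
#' @export
merge_windows <- function(windows, records_a, records_b, max_gap = 0) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  scope = character(), n_windows = integer(),
                  m_a = integer(), u_a = integer(), m_b = integer(),
                  u_b = integer(), ml_a = double(), ml_b = double(),
                  delta_ml = double(), direction = character(),
                  pvalue = double(), qvalue = double())
  if (!nrow(windows)) return(empty)
  merged <- windows |>
    arrange(.data$scope, .data$chrom, .data$start) |>
    group_by(.data$scope, .data$chrom) |>
    mutate(new_run = cumsum(
      c(TRUE, (.data$start[-1] - cummax(head(.data$end, -1))) > max_gap)
    )) |>
    group_by(.data$scope, .data$chrom, .data$new_run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = n(), .groups = "drop") |>
    select(-"new_run")
  pool_region <- function(records, chrom, start, end, scope) {
    hit <- records$chrom == chrom & records$pos - 1L >= start &
      records$pos - 1L < end
    if (scope != "combined") hit <- hit & records$context == scope
    c(m = sum(records$count_m[hit]), u = sum(records$count_u[hit]))
  }
  counts <- purrr::pmap(merged, function(scope, chrom, start, end, ...) {
    a <- pool_region(records_a, chrom, start, end, scope)
    b <- pool_region(records_b, chrom, start, end, scope)
    tibble(m_a = a[["m"]], u_a = a[["u"]], m_b = b[["m"]], u_b = b[["u"]])
  }) |> bind_rows()
  out <- bind_cols(merged, counts) |>
    mutate(
      ml_a = compute_ml(.data$m_a, .data$u_a),
      ml_b = compute_ml(.data$m_b, .data$u_b),
      delta_ml = .data$ml_b - .data$ml_a,
      direction = dplyr::case_when(.data$delta_ml > 0 ~ "hyper",
                                   .data$delta_ml < 0 ~ "hypo",
                                   TRUE ~ "none"),
      pvalue = fisher_window_test(.data$m_a, .data$u_a,
                                  .data$m_b, .data$u_b),
      qvalue = p.adjust(.data$pvalue, method = "BH")
    ) |>
    select(dplyr::all_of(names(empty))) |>
    arrange(.data$chrom, .data$start, .data$scope)
  out
}

#' Detect differentially methylated regions between two conditions
#'
#' End-to-end sliding-window DMR detection: pool counts in 1,000 bp
#' windows stepped by 100 bp per context scope, test each window with the
#' two-sided Fisher exact test, Benjamini-Hochberg-adjust across windows,
#' and merge significant windows (`q <= alpha`) into regions with
#' recomputed statistics and hyper/hypo direction (hyper = condition B
#' above condition A).
#'
#' @inheritParams window_pair_counts
#' @inheritParams merge_windows
#' @param alpha FDR threshold on window q-values.
#' @return A `dmr_result` object: use [tidy()] for the DMR table,
#'   [glance()] for a one-row summary, `$windows` for per-window tests.
#' @export
detect_dmrs <- function(records_a, records_b, genome = NULL,
                        window = 1000, step = 100, alpha = 0.05,
                        max_gap = 0, min_coverage = 10,
                        scopes = c("CG", "CHG", "CHH", "combined")) {
  wpc <- window_pair_counts(records_a, records_b, genome = genome,
                            window = window, step = step, scopes = scopes,
                            min_coverage = min_coverage)
  sel <- adjust_and_select(fisher_window_test(wpc$m_a, wpc$u_a,
                                              wpc$m_b, wpc$u_b),
                           alpha = alpha)
  windows <- bind_cols(wpc, sel)
  dmrs <- merge_windows(filter(windows, .data$significant),
                        records_a, records_b, max_gap = max_gap)
  structure(
    list(dmrs = dmrs, windows = windows,
         params = list(window = window, step = step, alpha = alpha,
                       max_gap = max_gap, min_coverage = min_coverage,
                       scopes = scopes),
         skipped_windows = attr(wpc, "skipped")),
    class = "dmr_result"
  )
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("<dmr_result>\n")
  cat("  windows tested:", nrow(x$windows),
      sprintf("(%d below coverage threshold skipped)\n", x$skipped_windows))
  cat("  significant windows:", sum(x$windows$significant), "\n")
  cat("  merged DMRs:", nrow(x$dmrs),
      sprintf("(%d hyper / %d hypo)\n",
              sum(x$dmrs$direction == "hyper"),
              sum(x$dmrs$direction == "hypo")))
  invisible(x)
}

#' @rdname detect_dmrs
#' @param x A `dmr_result`.
#' @param ... Unused.
#' @method tidy dmr_result
#' @export
tidy.dmr_result <- function(x, ...) x$dmrs

#' @rdname detect_dmrs
#' @method glance dmr_result
#' @export
glance.dmr_result <- function(x, ...) {
  tibble(
    n_windows = nrow(x$windows),
    n_skipped = x$skipped_windows,
    n_significant_windows = sum(x$windows$significant),
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_hypo = sum(x$dmrs$direction == "hypo"),
    median_length = if (nrow(x$dmrs)) {
      median(x$dmrs$end - x$dmrs$start)
    } else NA_real_
  )
}

#' Per-chromosome DMR count and length distribution
#'
#' @param dmrs DMR tibble (from [tidy()] of a `dmr_result`).
#' @return Tibble per chromosome: `n`, `total_bp`, `min_length`,
#'   `median_length`, `max_length`. Zero rows when `dmrs` is empty.
#' @export
dmr_length_stats <- function(dmrs) {
  if (!nrow(dmrs)) {
    return(tibble(chrom = character(), n = integer(), total_bp = double(),
                  min_length = double(), median_length = double(),
                  max_length = double()))
  }
  dmrs |>
    mutate(length = .data$end - .data$start) |>
    group_by(.data$chrom) |>
    summarise(
      n = n(),
      total_bp = sum(.data$length),
      min_length = min(.data$length),
      median_length = median(.data$length),
      max_length = max(.data$length),
      .groups = "drop"
    )
}
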