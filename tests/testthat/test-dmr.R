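test_that("Fisher p-values match hand and enumeration oracles", {
  expect_equal(fisher_window_test(rbind(c(10, 10), c(10, 10))), 1)
  expect_equal(fisher_window_test(rbind(c(0, 10), c(10, 0))),
               2 / choose(20, 10))

  # exhaustive enumeration over all tables with the observed margins
  enum_fisher <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- vapply(ks, function(k) {
      choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1)
    }, numeric(1))
    pobs <- probs[ks == a]
    sum(probs[probs <= pobs * (1 + 1e-7)])
  }
  expect_lt(abs(fisher_window_test(3, 7, 5, 5) - enum_fisher(3, 7, 5, 5)),
            1e-12)

  # independent implementation cross-check on random tables
  withr::with_seed(31, {
    for (i in 1:100) {
      tab <- matrix(rpois(4, sample(c(2, 20, 60), 1)), 2)
      got <- fisher_window_test(tab)
      want <- stats::fisher.test(tab)$p.value
      expect_lt(abs(got - want), 1e-12)
    }
  })

  expect_error(fisher_window_test(-1, 2, 3, 4), "non-negative")
})

test_that("BH adjustment and selection follow the step-up formula", {
  none <- adjust_and_select(rep(1, 5))
  expect_false(any(none$significant))
  one <- adjust_and_select(0.01)
  expect_equal(one$qvalue, 0.01)
  expect_true(one$significant)
  by_hand <- adjust_and_select(c(0.01, 0.02, 0.9))
  expect_equal(by_hand$qvalue, c(0.03, 0.03, 0.9))
  expect_equal(nrow(adjust_and_select(numeric(0))), 0)
})

test_that("window pair tables pool both conditions consistently", {
  st <- small_study(genome_length = 20000, seed = 41)
  wpc <- window_pair_counts(st$control, st$control, scopes = "CG",
                            min_coverage = 10)
  expect_true(all(wpc$m_a == wpc$m_b & wpc$u_a == wpc$u_b))

  # a condition with no reads in a window drops the window
  a <- tiny_records(pos = c(100, 5000), count_m = 10, count_u = 10)
  b <- tiny_records(pos = c(100, 5000), count_m = c(10L, 0L),
                    count_u = c(10L, 0L))
  wpc2 <- window_pair_counts(a, b, window = 1000, step = 1000,
                             scopes = "CG", min_coverage = 1)
  expect_true(all(wpc2$m_b + wpc2$u_b >= 1))
  expect_gt(attr(wpc2, "skipped"), 0)

  expect_error(
    window_pair_counts(a, dplyr::mutate(b, chrom = "chrX")),
    "different chromosome sets"
  )

  # combined scope equals the sum over contexts
  wpc3 <- window_pair_counts(st$control, st$drought,
                             scopes = c("CG", "CHG", "CHH", "combined"),
                             min_coverage = 0)
  per_win <- wpc3 |>
    dplyr::group_by(chrom, start) |>
    dplyr::summarise(
      ctx = sum(m_a[scope != "combined"]),
      comb = sum(m_a[scope == "combined"]), .groups = "drop"
    )
  expect_equal(per_win$ctx, per_win$comb)
})

test_that("significant windows merge into unions and recover planted truth", {
  st <- small_study(
    genome_length = 60000, coverage_mean = 20, seed = 51,
    planted = tibble::tibble(chrom = "chr1", start = 20000, end = 22000,
                             context = "CG", delta = 0.3)
  )
  res <- detect_dmrs(st$control, st$drought, scopes = "CG")
  dmrs <- tidy(res)
  hit <- dplyr::filter(dmrs, start < 22000, end > 20000)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$direction, "hyper")
  ov <- min(hit$end, 22000) - max(hit$start, 20000)
  expect_gte(ov / 2000, 0.5)
  expect_gte(ov / (hit$end - hit$start), 0.5)

  # swapping the condition order flips direction labels
  res_sw <- detect_dmrs(st$drought, st$control, scopes = "CG")
  hit_sw <- dplyr::filter(tidy(res_sw), start < 22000, end > 20000)
  expect_equal(hit_sw$direction, "hypo")
  expect_equal(hit_sw$delta_ml, -hit$delta_ml, tolerance = 1e-12)

  g <- glance(res)
  expect_equal(g$n_dmrs, nrow(dmrs))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("window merging unions overlaps and respects max_gap", {
  win <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(1000, 1100),
                        scope = "CG")
  a <- tiny_records(pos = c(50, 600), count_m = 10, count_u = 0)
  b <- tiny_records(pos = c(50, 600), count_m = 0, count_u = 10)
  m1 <- merge_windows(win, a, b)
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$start, m1$end), c(0, 1100))
  expect_equal(m1$direction, "hypo")
  expect_equal(m1$m_a, 20)

  far <- tibble::tibble(chrom = "chr1", start = c(0, 6000),
                        end = c(1000, 7000), scope = "CG")
  expect_equal(nrow(merge_windows(far, a, b)), 2)
  expect_equal(nrow(merge_windows(far, a, b, max_gap = 5000)), 1)
})

test_that("DMR length statistics summarise interval widths", {
  expect_equal(nrow(dmr_length_stats(
    tibble::tibble(chrom = character(), start = integer(), end = integer())
  )), 0)
  one <- tibble::tibble(chrom = "chr1", start = 0, end = 1500)
  expect_equal(dmr_length_stats(one)$median_length, 1500)

  withr::with_seed(61, {
    many <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 20, TRUE),
      start = sample(1:10000, 20)
    ) |> dplyr::mutate(end = start + sample(100:2000, 20))
  })
  stats <- dmr_length_stats(many)
  expect_equal(sum(stats$total_bp), sum(many$end - many$start))
  expect_equal(sum(stats$n), 20)
})
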