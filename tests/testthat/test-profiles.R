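test_that("element profiles average corrected ML into 20 oriented bins", {
  ann <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    element = "exon", start = 1001L, end = 2000L
  )
  calls <- tiny_records(pos = seq(1001, 2000, by = 10)) |>
    dplyr::mutate(ml_corrected = 0.4)
  prof <- bin_element_profile(calls, ann, "exon", "CG")
  expect_equal(nrow(prof), 20)
  expect_true(all(prof$mean_ml == 0.4))
  expect_equal(unique(prof$n_elements), 1)

  expect_equal(nrow(bin_element_profile(calls, ann, "intron", "CG")), 0)

  # a planted linear gradient reads TSS->TES on both strands
  grad_calls <- tiny_records(pos = seq(1001, 2000, by = 5)) |>
    dplyr::mutate(ml_corrected = (pos - 1001) / 999)
  up <- bin_element_profile(grad_calls, ann, "exon", "CG")
  down <- bin_element_profile(grad_calls,
                              dplyr::mutate(ann, strand = "-"),
                              "exon", "CG")
  expect_true(all(diff(up$mean_ml) > 0))
  expect_true(all(diff(down$mean_ml) < 0))
  expect_equal(up$mean_ml, rev(down$mean_ml), tolerance = 1e-12)
})

test_that("fractional bin weights conserve element length", {
  for (len in c(7, 20, 53, 1000)) {
    bw <- methwind:::bin_weights(0:(len - 1), len, 20)
    expect_equal(sum(bw$w), len)
    agg <- tapply(bw$w, bw$bin, sum)
    expect_equal(as.numeric(agg), rep(len / 20, 20), tolerance = 1e-9)
  }
})

test_that("expression log-ratio is anchored at the maximum", {
  ex <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                       fpkm = c(1000, 10, 1, 0))
  out <- fpkm_log_ratio(ex)
  expect_equal(out$fpkm_log_ratio, c(1, 1 / 3, 0, NA))
  expect_error(fpkm_log_ratio(tibble::tibble(gene_id = "a", fpkm = 0.9)),
               "exceed 1")
})

test_that("high/low split uses strict context-specific thresholds", {
  calls <- tibble::tibble(
    context = c("CG", "CG", "CHH", "CHG"),
    ml_corrected = c(0.75, 0.76, 0.30, 0.25)
  )
  out <- split_high_low(calls)
  expect_equal(out$meth_class, c("low", "high", "high", "low"))

  withr::with_seed(71, {
    many <- tibble::tibble(
      context = sample(c("CG", "CHG", "CHH"), 500, TRUE),
      ml_corrected = runif(500)
    )
  })
  split <- split_high_low(many)
  expect_equal(sum(split$meth_class == "high") +
                 sum(split$meth_class == "low"), 500)
  expect_equal(nrow(split_high_low(many[0, ])), 0)
})

test_that("position frequency matrices have unit columns and bounded IC", {
  pfm <- build_pfm(rep("TACGA", 5))
  expect_true(all(pfm$freq[cbind(c("T", "A", "C", "G", "A"),
                                 as.character(-2:2))] == 1))
  expect_equal(unname(pfm$ic), rep(2, 5))

  withr::with_seed(81, {
    flanks <- paste0(
      replicate(3000, paste(sample(c("A", "C", "G", "T"), 2, TRUE),
                            collapse = "")),
      "C",
      replicate(3000, paste(sample(c("A", "C", "G", "T"), 2, TRUE),
                            collapse = ""))
    )
  })
  pfm2 <- build_pfm(flanks)
  expect_equal(unname(colSums(pfm2$freq)), rep(1, 5))
  expect_equal(pfm2$freq["C", "0"], 1)
  expect_equal(unname(pfm2$ic[["0"]]), 2)
  expect_true(all(pfm2$ic[c("-2", "-1", "1", "2")] < 0.01))
  expect_true(all(pfm2$ic >= 0 & pfm2$ic <= 2))

  td <- tidy(pfm2)
  expect_equal(nrow(td), 20)
  expect_s3_class(autoplot(pfm2), "ggplot")
  expect_error(build_pfm(c("ACGTA", "ACG")), "same length")
})

test_that("DMRs are labelled with overlapping gene elements", {
  ann <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    element = c("gene", "promoter", "exon", "intron", "exon"),
    start = c(3001L, 1001L, 3001L, 3501L, 4001L),
    end = c(5000L, 3000L, 3500L, 4000L, 5000L)
  )
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(3100L, 2400L, 9000L),
                         end = c(3300L, 2600L, 9500L))
  out <- associate_dmr_genes(dmrs, ann)
  expect_equal(dplyr::filter(out, start == 3100)$element, "exon")
  expect_equal(dplyr::filter(out, start == 2400)$element, "promoter")
  expect_equal(dplyr::filter(out, start == 9000)$element, "intergenic")
  expect_true(is.na(dplyr::filter(out, start == 9000)$gene_id))
})

test_that("CpG-island scan matches a brute-force window evaluation", {
  isl <- predict_cpg_islands(strrep("GC", 200))
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start, isl$end), c(0, 400))
  expect_equal(isl$obs_exp, 199 * 400 / (200 * 200))
  expect_equal(nrow(predict_cpg_islands(strrep("AT", 200))), 0)
  expect_error(predict_cpg_islands("ACGT"), "shorter")

  # oracle: evaluate every window directly and merge passing runs
  seq <- random_seq(10000, 17)
  got <- predict_cpg_islands(seq, window = 200)
  b <- strsplit(seq, "")[[1]]
  pass <- vapply(1:(10000 - 199), function(s) {
    w <- b[s:(s + 199)]
    nc <- sum(w == "C"); ng <- sum(w == "G")
    ncg <- sum(w[-200] == "C" & w[-1] == "G")
    gc <- (nc + ng) / 200
    oe <- if (nc * ng > 0) ncg * 200 / (nc * ng) else 0
    gc > 0.5 && oe > 0.6
  }, logical(1))
  ps <- which(pass)
  if (length(ps)) {
    runs <- split(ps, cumsum(c(TRUE, diff(ps) > 200)))
    want <- do.call(rbind, lapply(runs, function(r) {
      c(start = min(r) - 1L, end = max(r) + 199L)
    }))
    want <- want[want[, "end"] - want[, "start"] > 100, , drop = FALSE]
    expect_equal(got$start, unname(want[, "start"]))
    expect_equal(got$end, unname(want[, "end"]))
  } else {
    expect_equal(nrow(got), 0)
  }
})
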