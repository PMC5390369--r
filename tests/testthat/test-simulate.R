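test_that("genome simulation is deterministic and honours GC settings", {
  cfg <- sim_config(genome_length = 10000, n_chromosomes = 1, seed = 1)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[["chr1"]]), 10000)
  expect_equal(nchar(g1[["lambda"]]), cfg$lambda_length)

  gc1 <- simulate_genome(sim_config(genome_length = 1000, n_chromosomes = 1,
                                    gc_fraction = 1, seed = 2))
  expect_true(all(strsplit(gc1[["chr1"]], "")[[1]] %in% c("G", "C")))

  # observed GC within 3 binomial s.d. of the target
  g <- simulate_genome(sim_config(genome_length = 100000, n_chromosomes = 1,
                                  gc_fraction = 0.5, seed = 3))
  obs <- mean(strsplit(g[["chr1"]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 100000))

  expect_error(sim_config(genome_length = 500), ">= 1000")
  expect_error(sim_config(nonconversion_rate = 1.2))
})

test_that("annotation places non-overlapping genes with strand-aware promoters", {
  g <- simulate_genome(sim_config(genome_length = 100000, n_chromosomes = 1,
                                  seed = 4))
  expect_equal(nrow(simulate_annotation(g, 0)), 0)

  ann <- simulate_annotation(g, 10, seed = 5)
  genes <- dplyr::filter(ann, element == "gene") |> dplyr::arrange(start)
  expect_equal(nrow(genes), 10)
  expect_true(all(genes$start[-1] > genes$end[-nrow(genes)]))
  proms <- dplyr::filter(ann, element == "promoter")
  for (i in seq_len(nrow(proms))) {
    gene <- genes[genes$gene_id == proms$gene_id[i], ]
    if (gene$strand == "+") {
      expect_lt(proms$end[i], gene$start)
    } else {
      expect_gt(proms$start[i], gene$end)
    }
  }
  # every gene's exons/introns tile the gene body exactly
  segs <- dplyr::filter(ann, element %in% c("exon", "intron"))
  tiled <- segs |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(bp = sum(end - start + 1))
  expect_equal(tiled$bp, genes$end - genes$start + 1,
               ignore_attr = TRUE)
  expect_gte(min(table(segs$gene_id[segs$element == "exon"])), 1)

  expect_error(simulate_annotation(g, 1000, seed = 6), "too large")
})

test_that("annotation round-trips through GFF3 unchanged", {
  g <- simulate_genome(sim_config(genome_length = 50000, n_chromosomes = 2,
                                  seed = 7))
  ann <- simulate_annotation(g, 6, seed = 8)
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(ann, tf)
  back <- read_gene_annotation(tf)
  key <- function(x) as.data.frame(dplyr::arrange(x, gene_id, element, start))
  expect_identical(key(ann), key(back))
})

test_that("count simulation matches its binomial model", {
  cfg0 <- sim_config(genome_length = 2000, n_chromosomes = 1,
                     base_rates = c(CG = 0, CHG = 0, CHH = 0),
                     nonconversion_rate = 0, coverage_mean = 10, seed = 9)
  g <- simulate_genome(cfg0)
  sim0 <- simulate_counts(g, cfg0)
  expect_true(all(sim0$records$count_m == 0))

  cfg1 <- sim_config(genome_length = 2000, n_chromosomes = 1,
                     base_rates = c(CG = 1, CHG = 0, CHH = 0),
                     nonconversion_rate = 0, coverage_mean = 10, seed = 9)
  sim1 <- simulate_counts(g, cfg1)
  cg <- dplyr::filter(sim1$records, context == "CG", chrom != "lambda")
  expect_true(all(cg$count_u == 0))

  # pooled fraction per context converges to the base rate (3 s.d.)
  cfg <- sim_config(genome_length = 100000, n_chromosomes = 1,
                    coverage_mean = 20, nonconversion_rate = 0, seed = 10)
  gg <- simulate_genome(cfg)
  rec <- dplyr::filter(simulate_counts(gg, cfg)$records, chrom != "lambda")
  pooled <- rec |>
    dplyr::group_by(context) |>
    dplyr::summarise(frac = sum(count_m) / sum(count_m + count_u),
                     n = sum(count_m + count_u))
  for (ctx in c("CG", "CHG", "CHH")) {
    p <- cfg$base_rates[[ctx]]
    row <- pooled[pooled$context == ctx, ]
    expect_lt(abs(row$frac - p), 3 * sqrt(p * (1 - p) / row$n))
  }

  # determinism of the full table
  rec2 <- dplyr::filter(simulate_counts(gg, cfg)$records, chrom != "lambda")
  expect_identical(rec, rec2)
})

test_that("lambda spike-in carries the configured non-conversion rate", {
  cfg <- sim_config(genome_length = 1000, n_chromosomes = 1,
                    lambda_length = 20000, coverage_mean = 30,
                    nonconversion_rate = 0.01, seed = 12)
  g <- simulate_genome(cfg)
  lam <- dplyr::filter(simulate_counts(g, cfg)$records, chrom == "lambda")
  frac <- sum(lam$count_m) / sum(lam$count_m + lam$count_u)
  n <- sum(lam$count_m + lam$count_u)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("planted DMRs shift the true rate by exactly delta in one condition", {
  cfg0 <- sim_config(genome_length = 20000, n_chromosomes = 1, seed = 13)
  g <- simulate_genome(cfg0)
  pd <- plant_dmrs(g, 2, width = 1500, context = "CG",
                   delta = c(0.3, -0.3), seed = 14)
  cfg <- sim_config(genome_length = 20000, n_chromosomes = 1,
                    planted_dmrs = pd, seed = 13)
  tr_d <- simulate_counts(g, cfg, "drought")$truth$sites
  tr_c <- simulate_counts(g, cfg, "control")$truth$sites
  for (i in 1:2) {
    inside <- tr_d$chrom == pd$chrom[i] & tr_d$context == "CG" &
      tr_d$pos - 1 >= pd$start[i] & tr_d$pos - 1 < pd$end[i]
    expect_true(all(abs(tr_d$true_p[inside] -
                          (cfg$base_rates[["CG"]] + pd$delta[i])) < 1e-12))
    expect_true(all(tr_c$true_p[inside] == cfg$base_rates[["CG"]]))
  }
  expect_error(
    simulate_counts(g, cfg, sites = tibble::tibble(
      chrom = "chr1", pos = 1L, strand = "+", context = "XX",
      trinucleotide = NA)),
    "unknown context"
  )
})
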