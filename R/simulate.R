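#' Simulation configuration for synthetic bisulfite count data
#'
#' Bundles every knob of the synthetic methylome generator. The generator
#' inverts the binomial read-count model used downstream: per cytosine,
#' coverage is Poisson, the methylated count is binomial at the site's true
#' methylation probability, and truly unmethylated reads escape bisulfite
#' conversion (appearing methylated) with probability `nonconversion_rate`.
#' Methylated reads are never deconverted, so the observed methylated-read
#' probability is `p + (1 - p) * r` and the one-parameter correction
#' `(ML - r) / (1 - r)` is its exact inverse in expectation.
#'
#' @param genome_length Bases per chromosome (>= 1000).
#' @param n_chromosomes Number of chromosomes.
#' @param gc_fraction Expected G+C fraction in `[0, 1]`.
#' @param base_rates Named vector of per-context true methylation
#'   probabilities for `CG`, `CHG`, `CHH`.
#' @param coverage_mean Expected reads per cytosine (Poisson mean, > 0).
#' @param planted_dmrs Optional tibble of planted differential intervals:
#'   `chrom`, `start`, `end` (0-based half-open), `context` (`"CG"`,
#'   `"CHG"`, `"CHH"` or `"all"`), `delta` (signed rate shift applied to
#'   the stressed condition only). See [plant_dmrs()].
#' @param nonconversion_rate Bisulfite non-conversion rate in `[0, 1)`.
#' @param lambda_length Length of the unmethylated lambda spike-in contig.
#' @param promoter_chh_delta Additive shift applied to CHH sites inside
#'   annotated promoters (both conditions); emulates promoter-elevated
#'   asymmetric methylation.
#' @param gene_body_gradient If non-zero, an additive linear ramp from
#'   `-g/2` at the TSS to `+g/2` at the TES applied within gene bodies
#'   (strand-aware, both conditions); used to validate metaprofile
#'   orientation.
#' @param seed Integer seed; identical configurations produce identical
#'   tables.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000,
                       n_chromosomes = 2,
                       gc_fraction = 0.5,
                       base_rates = c(CG = 0.6, CHG = 0.5, CHH = 0.2),
                       coverage_mean = 30,
                       planted_dmrs = NULL,
                       nonconversion_rate = 0.005,
                       lambda_length = 5000,
                       promoter_chh_delta = 0,
                       gene_body_gradient = 0,
                       seed = 1) {
  if (genome_length < 1000) stop("`genome_length` must be >= 1000", call. = FALSE)
  if (n_chromosomes < 1) stop("`n_chromosomes` must be >= 1", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("`gc_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (!all(c("CG", "CHG", "CHH") %in% names(base_rates))) {
    stop("`base_rates` needs named entries for CG, CHG and CHH", call. = FALSE)
  }
  if (any(base_rates < 0 | base_rates > 1)) {
    stop("`base_rates` must be probabilities in [0, 1]", call. = FALSE)
  }
  if (coverage_mean <= 0) stop("`coverage_mean` must be > 0", call. = FALSE)
  if (nonconversion_rate < 0 || nonconversion_rate >= 1) {
    stop("`nonconversion_rate` must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted_dmrs)) {
    stopifnot(all(c("chrom", "start", "end", "context", "delta") %in%
                    names(planted_dmrs)))
    if (any(planted_dmrs$end <= planted_dmrs$start)) {
      stop("planted DMR intervals must have end > start", call. = FALSE)
    }
  }
  structure(
    list(genome_length = as.integer(genome_length),
         n_chromosomes = as.integer(n_chromosomes),
         gc_fraction = gc_fraction,
         base_rates = base_rates[c("CG", "CHG", "CHH")],
         coverage_mean = coverage_mean,
         planted_dmrs = planted_dmrs,
         nonconversion_rate = nonconversion_rate,
         lambda_length = as.integer(lambda_length),
         promoter_chh_delta = promoter_chh_delta,
         gene_body_gradient = gene_body_gradient,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# evaluate `code` under `seed`, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a toy genome with an unmethylated lambda spike-in contig
#'
#' Draws i.i.d. bases with the configured GC fraction for each chromosome
#' (`chr1`, `chr2`, ...) plus one extra contig named `"lambda"` of
#' `lambda_length` bases that downstream code treats as the fully
#' unmethylated spike-in.
#'
#' @param config A [sim_config()].
#' @return Named character vector of sequences (chromosomes + `lambda`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gc <- config$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(config$seed, {
    lens <- c(rep(config$genome_length, config$n_chromosomes),
              config$lambda_length)
    names(lens) <- c(paste0("chr", seq_len(config$n_chromosomes)), "lambda")
    vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
}

#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` gene bodies on the non-lambda chromosomes without
#' overlap, assigns each a strand, a strand-aware promoter upstream of the
#' TSS, and 1 or more exons separated by introns. Genes are laid out in
#' equal slots along each chromosome so placement is always feasible or
#' fails loudly.
#'
#' @inheritParams as_genome
#' @param n_genes Number of genes to place.
#' @param seed Integer seed.
#' @param promoter_span Promoter length upstream of the TSS (bases).
#' @param gene_length Two-element range of gene body lengths.
#' @param max_exons Maximum exons per gene.
#' @return Tibble with one row per feature: `gene_id`, `chrom`, `strand`,
#'   `element` (`gene`, `promoter`, `exon`, `intron`), `start`, `end`
#'   (1-based inclusive).
#' @export
simulate_annotation <- function(genome, n_genes, seed = 1,
                                promoter_span = 2000,
                                gene_length = c(1000, 5000),
                                max_exons = 4) {
  g <- as_genome(genome)
  g <- g[names(g) != "lambda"]
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), element = character(),
                  start = integer(), end = integer())
  if (n_genes == 0) return(empty)
  lens <- nchar(g)
  chrom_of <- rep(names(g), length.out = n_genes)
  with_seed(seed, {
    rows <- purrr::map(seq_len(n_genes), function(i) {
      chrom <- chrom_of[i]
      n_here <- sum(chrom_of == chrom)
      slot <- floor(lens[[chrom]] / n_here)
      rank_here <- sum(chrom_of[seq_len(i)] == chrom)
      slot_start <- (rank_here - 1L) * slot + 1L
      max_len <- min(max(gene_length), slot - 200L)
      if (max_len < min(gene_length)) {
        stop("`n_genes` too large for this genome", call. = FALSE)
      }
      len <- sample(seq(min(gene_length), max_len), 1L)
      start <- slot_start + sample.int(slot - len, 1L) - 1L
      end <- start + len - 1L
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("gene%03d", i)
      # split the body into alternating exon/intron segments
      k <- sample.int(max_exons, 1L)
      n_seg <- 2L * k - 1L
      cuts <- sort(sample.int(len - 1L, n_seg - 1L))
      seg_len <- diff(c(0L, cuts, len))
      seg_start <- start + cumsum(c(0L, head(seg_len, -1L)))
      seg_end <- seg_start + seg_len - 1L
      seg_type <- rep(c("exon", "intron"), length.out = n_seg)
      if (strand == "-") seg_type <- rev(seg_type)
      prom <- if (strand == "+") {
        c(max(1L, start - promoter_span), start - 1L)
      } else {
        c(end + 1L, min(lens[[chrom]], end + promoter_span))
      }
      feats <- tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        element = c("gene", seg_type),
        start = c(start, seg_start), end = c(end, seg_end)
      )
      if (prom[2] >= prom[1]) {
        feats <- bind_rows(feats, tibble(
          gene_id = gene_id, chrom = chrom, strand = strand,
          element = "promoter", start = prom[1], end = prom[2]
        ))
      }
      feats
    })
    bind_rows(rows) |>
      mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
      arrange(.data$chrom, .data$start, .data$gene_id, .data$element)
  })
}

#' Choose random non-overlapping intervals to plant as DMRs
#'
#' Picks `n` intervals of width `width` spread across the non-lambda
#' chromosomes (one per equal-sized slot, so intervals never overlap and
#' are separated by at least the slack in a slot), tagged with a context
#' scope and a signed methylation-rate shift for the stressed condition.
#'
#' @inheritParams simulate_annotation
#' @param n Number of intervals.
#' @param width Interval width in bases.
#' @param context Context scope: `"CG"`, `"CHG"`, `"CHH"` or `"all"`.
#' @param delta Signed rate shift(s), recycled across intervals.
#' @param seed Integer seed.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `context`,
#'   `delta`.
#' @export
plant_dmrs <- function(genome, n, width = 2000, context = "CG",
                       delta = c(0.3, -0.3), seed = 1) {
  g <- as_genome(genome)
  g <- g[names(g) != "lambda"]
  lens <- nchar(g)
  chrom_of <- rep(names(g), length.out = n)
  delta <- rep_len(delta, n)
  with_seed(seed, {
    rows <- purrr::map(seq_len(n), function(i) {
      chrom <- chrom_of[i]
      n_here <- sum(chrom_of == chrom)
      slot <- floor(lens[[chrom]] / n_here)
      if (slot < width + 2L) stop("too many intervals for this genome", call. = FALSE)
      rank_here <- sum(chrom_of[seq_len(i)] == chrom)
      slot_start <- (rank_here - 1L) * slot
      start <- slot_start + sample.int(slot - width, 1L)
      tibble(chrom = chrom, start = start, end = start + width,
             context = context, delta = delta[i])
    })
    bind_rows(rows) |> arrange(.data$chrom, .data$start)
  })
}

#' Simulate a per-cytosine bisulfite count table with known truth
#'
#' For every classifiable cytosine in the genome (lambda included),
#' coverage is drawn from a Poisson with mean `coverage_mean` (sites with
#' zero coverage are emitted with counts 0/0), the true methylation
#' probability is the context base rate shifted by any overlapping planted
#' DMR (stressed condition only) and by the optional promoter/gradient
#' effects, and the observed methylated count is
#' `Binomial(n, p + (1 - p) * r)` where `r` is the non-conversion rate.
#' Lambda cytosines have true probability 0, so their pooled methylated
#' fraction estimates `r`.
#'
#' @inheritParams simulate_genome
#' @inheritParams as_genome
#' @param condition Condition label; planted DMR deltas are applied only
#'   when `condition == dmr_condition`.
#' @param annotation Optional annotation tibble (needed for
#'   `promoter_chh_delta` / `gene_body_gradient`).
#' @param sites Optional precomputed [classify_contexts()] table (reused
#'   across conditions for speed).
#' @param dmr_condition Label of the condition that carries planted deltas.
#' @return List with `records` (tibble: `chrom`, `pos`, `strand`,
#'   `context`, `trinucleotide`, `count_m`, `count_u`, `condition`) and
#'   `truth` (list: per-site `sites` tibble with `true_p`, planted `dmrs`,
#'   `nonconversion_rate`).
#' @export
simulate_counts <- function(genome, config, condition = "control",
                            annotation = NULL, sites = NULL,
                            dmr_condition = "drought") {
  stopifnot(inherits(config, "sim_config"))
  g <- as_genome(genome)
  if (is.null(sites)) sites <- classify_contexts(g)
  bad <- setdiff(unique(sites$context), c("CG", "CHG", "CHH", "unknown"))
  if (length(bad)) {
    stop("unknown context symbol: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sites <- filter(sites, .data$context != "unknown")
  p <- unname(config$base_rates[sites$context])
  p[sites$chrom == "lambda"] <- 0
  if (!is.null(config$planted_dmrs) && identical(condition, dmr_condition)) {
    pd <- config$planted_dmrs
    for (i in seq_len(nrow(pd))) {
      hit <- sites$chrom == pd$chrom[i] &
        sites$pos - 1L >= pd$start[i] & sites$pos - 1L < pd$end[i] &
        (pd$context[i] == "all" | sites$context == pd$context[i])
      p[hit] <- p[hit] + pd$delta[i]
    }
  }
  if (!is.null(annotation) && nrow(annotation)) {
    if (config$promoter_chh_delta != 0) {
      prom <- filter(annotation, .data$element == "promoter")
      for (i in seq_len(nrow(prom))) {
        hit <- sites$chrom == prom$chrom[i] & sites$context == "CHH" &
          sites$pos >= prom$start[i] & sites$pos <= prom$end[i]
        p[hit] <- p[hit] + config$promoter_chh_delta
      }
    }
    if (config$gene_body_gradient != 0) {
      genes <- filter(annotation, .data$element == "gene")
      for (i in seq_len(nrow(genes))) {
        hit <- which(sites$chrom == genes$chrom[i] &
                       sites$pos >= genes$start[i] & sites$pos <= genes$end[i])
        if (!length(hit)) next
        frac <- (sites$pos[hit] - genes$start[i]) /
          (genes$end[i] - genes$start[i])
        if (genes$strand[i] == "-") frac <- 1 - frac
        p[hit] <- p[hit] + config$gene_body_gradient * (frac - 0.5)
      }
    }
  }
  p <- pmin(1, pmax(0, p))
  r <- config$nonconversion_rate
  p_obs <- p + (1 - p) * r
  seed_used <- (config$seed + sum(utf8ToInt(condition))) %% 2147483647L
  with_seed(seed_used, {
    n <- rpois(nrow(sites), config$coverage_mean)
    m <- rbinom(nrow(sites), n, p_obs)
    records <- sites |>
      mutate(count_m = m, count_u = n - m, condition = condition)
    truth_sites <- sites |> mutate(true_p = p)
    list(records = records,
         truth = list(sites = truth_sites,
                      dmrs = config$planted_dmrs,
                      nonconversion_rate = r))
  })
}

#' Simulate a complete two-condition methylome study
#'
#' Convenience wrapper: genome + lambda spike-in, gene annotation, and one
#' cytosine count table per condition, with the planted truth attached.
#'
#' @inheritParams simulate_genome
#' @param conditions Condition labels; the second (default `"drought"`)
#'   carries the planted DMR deltas.
#' @param n_genes Genes to place in the annotation.
#' @param promoter_span Promoter length for the annotation.
#' @return A `methylome_sim` list: `genome`, `annotation`, `counts` (named
#'   list of record tibbles), `truth`, `config`.
#' @export
simulate_methylome <- function(config, conditions = c("control", "drought"),
                               n_genes = 20, promoter_span = 2000) {
  genome <- simulate_genome(config)
  annotation <- simulate_annotation(genome, n_genes, seed = config$seed + 1L,
                                    promoter_span = promoter_span)
  sites <- classify_contexts(genome)
  counts <- list()
  truth <- NULL
  for (cond in conditions) {
    sim <- simulate_counts(genome, config, condition = cond,
                           annotation = annotation, sites = sites,
                           dmr_condition = conditions[min(2L, length(conditions))])
    counts[[cond]] <- sim$records
    if (is.null(truth)) truth <- sim$truth
    truth$sites_by_condition[[cond]] <- sim$truth$sites
  }
  structure(list(genome = genome, annotation = annotation, counts = counts,
                 truth = truth, config = config),
            class = "methylome_sim")
}

#' Write a simulated methylome study to disk
#'
#' Emits `genome.fa` (lambda as an extra contig), `annotation.gff3`, one
#' `cytosine_report_<condition>.tsv` per condition (Bismark-style, no
#' header) and `truth_dmrs.bed` (0-based half-open). Every file is
#' re-readable by the package's own readers.
#'
#' @param sim A `methylome_sim` from [simulate_methylome()].
#' @param dir Output directory; must not exist unless `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing directory.
#' @return `dir`, invisibly.
#' @export
write_methylome <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "methylome_sim"))
  if (dir.exists(dir) && !overwrite) {
    stop("output directory exists; use `overwrite = TRUE`", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gene_annotation(sim$annotation, file.path(dir, "annotation.gff3"))
  for (cond in names(sim$counts)) {
    write_cytosine_report(
      sim$counts[[cond]],
      file.path(dir, paste0("cytosine_report_", cond, ".tsv"))
    )
  }
  if (!is.null(sim$truth$dmrs)) {
    write_truth_bed(sim$truth$dmrs, file.path(dir, "truth_dmrs.bed"))
  }
  invisible(dir)
}
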