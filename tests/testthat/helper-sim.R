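# shared fixture builders (everything generated in code at test time)

tiny_records <- function(chrom = "chr1", pos, context = "CG",
                         count_m = 10L, count_u = 10L, strand = "+") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    context = context, trinucleotide = NA_character_,
    count_m = as.integer(count_m), count_u = as.integer(count_u)
  )
}

# small simulated two-condition study reused across tests
small_study <- function(genome_length = 50000, coverage_mean = 20,
                        planted = NULL, seed = 11, r = 0.005, ...) {
  cfg <- sim_config(genome_length = genome_length, n_chromosomes = 1,
                    coverage_mean = coverage_mean, planted_dmrs = planted,
                    nonconversion_rate = r, seed = seed, ...)
  genome <- simulate_genome(cfg)
  sites <- classify_contexts(genome)
  a <- simulate_counts(genome, cfg, "control", sites = sites)$records
  b <- simulate_counts(genome, cfg, "drought", sites = sites)$records
  list(config = cfg, genome = genome, sites = sites,
       control = dplyr::filter(a, chrom != "lambda"),
       drought = dplyr::filter(b, chrom != "lambda"),
       lambda = dplyr::filter(a, chrom == "lambda"))
}

# brute-force context classifier used as an oracle: walks every position
# of both strands explicitly
oracle_contexts <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b <- strsplit(toupper(seq), "")[[1]]
  n <- length(b)
  rows <- list()
  classify <- function(tri) {
    if (any(!strsplit(tri, "")[[1]] %in% c("A", "C", "G", "T"))) {
      return("unknown")
    }
    if (substr(tri, 2, 2) == "G") "CG"
    else if (substr(tri, 3, 3) == "G") "CHG"
    else "CHH"
  }
  for (i in seq_len(n)) {
    if (b[i] == "C") {
      tri <- paste0(b[i], if (i + 1 <= n) b[i + 1] else "N",
                    if (i + 2 <= n) b[i + 2] else "N")
      rows[[length(rows) + 1]] <-
        data.frame(pos = i, strand = "+", context = classify(tri))
    }
    if (b[i] == "G") {
      tri <- paste0("C", if (i - 1 >= 1) comp[[b[i - 1]]] else "N",
                    if (i - 2 >= 1) comp[[b[i - 2]]] else "N")
      rows[[length(rows) + 1]] <-
        data.frame(pos = i, strand = "-", context = classify(tri))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$pos, out$strand), ]
}

random_seq <- function(n, seed, letters = c("A", "C", "G", "T")) {
  withr::with_seed(seed, paste(sample(letters, n, TRUE), collapse = ""))
}
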