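#' Classify every genomic cytosine into CG/CHG/CHH context
#'
#' Scans both strands of a genome and emits one record per cytosine: every
#' `C` on the plus strand and every `G` on the plus strand read as a `C` on
#' the reverse complement. The context is a pure function of the
#' trinucleotide starting at the cytosine in its strand's 5'->3' direction:
#' `CG*` is CG, `CHG` is CHG and `CHH` is CHH, where H is A, C or T.
#' Cytosines whose two downstream bases run off the chromosome end or
#' contain an ambiguity code are emitted with context `"unknown"` and an
#' `NA` trinucleotide; downstream summaries exclude them.
#'
#' @inheritParams as_genome
#' @return A tibble with columns `chrom`, `pos` (1-based position of the C
#'   on the plus-strand coordinate system), `strand` (`"+"`/`"-"`),
#'   `context` (`"CG"`, `"CHG"`, `"CHH"` or `"unknown"`) and
#'   `trinucleotide`.
#' @examples
#' classify_contexts(c(chr1 = "ACGTA"))
#' @export
classify_contexts <- function(genome) {
  g <- as_genome(genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  per_chrom <- purrr::map(names(g), function(chrom) {
    b <- strsplit(g[[chrom]], "", fixed = TRUE)[[1]]
    nb <- length(b)
    at <- function(i) {
      out <- rep(NA_character_, length(i))
      ok <- i >= 1L & i <= nb
      out[ok] <- b[i[ok]]
      out
    }
    plus <- which(b == "C")
    p1 <- at(plus + 1L)
    p2 <- at(plus + 2L)
    minus <- which(b == "G")
    m1 <- unname(comp[at(minus - 1L)])
    m2 <- unname(comp[at(minus - 2L)])
    tibble(
      chrom = chrom,
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      down1 = c(p1, m1),
      down2 = c(p2, m2)
    )
  })
  sites <- bind_rows(per_chrom)
  valid <- c("A", "C", "G", "T")
  ok <- sites$down1 %in% valid & sites$down2 %in% valid
  context <- rep("unknown", nrow(sites))
  context[ok & sites$down1 == "G"] <- "CG"
  context[ok & sites$down1 != "G" & sites$down2 == "G"] <- "CHG"
  context[ok & sites$down1 != "G" & sites$down2 != "G"] <- "CHH"
  sites$context <- context
  sites$trinucleotide <- ifelse(ok, paste0("C", sites$down1, sites$down2),
                                NA_character_)
  sites |>
    select("chrom", "pos", "strand", "context", "trinucleotide") |>
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Extract aligned flanking sequences around cytosine sites
#'
#' For each site, returns the `2k + 1`-mer centred on the cytosine in the
#' site strand's 5'->3' orientation (minus-strand flanks are
#' reverse-complemented so the central offset is always the C). Sites
#' closer than `k` bases to a chromosome end are dropped; the number
#' dropped is stored in the `"dropped"` attribute.
#'
#' @param sites Tibble of cytosine sites (`chrom`, `pos`, `strand`), e.g.
#'   from [classify_contexts()].
#' @inheritParams as_genome
#' @param k Flank radius in bases (`k >= 1`).
#' @return A tibble with `chrom`, `pos`, `strand`, `flank`; attribute
#'   `dropped` counts edge sites that were removed.
#' @export
extract_flanks <- function(sites, genome, k) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  g <- as_genome(genome)
  lens <- setNames(nchar(g), names(g))
  keep <- sites$pos - k >= 1L & sites$pos + k <= lens[sites$chrom]
  out <- sites[keep, c("chrom", "pos", "strand"), drop = FALSE]
  flank <- substring(g[out$chrom], out$pos - k, out$pos + k)
  minus <- out$strand == "-"
  if (any(minus)) flank[minus] <- revcomp(flank[minus])
  out$flank <- unname(flank)
  out <- as_tibble(out)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Pool symmetric CG sites across strands
#'
#' A plus-strand CG cytosine at position `p` and the minus-strand cytosine
#' at `p + 1` interrogate the same CpG dyad. This utility sums their
#' methylated/unmethylated counts into one record per dyad, reported at the
#' plus-strand coordinate with strand `"*"`. Non-CG records pass through
#' unchanged. Context classification itself stays per-strand; pooling is
#' opt-in.
#'
#' @param records Cytosine record tibble with `chrom`, `pos`, `strand`,
#'   `context`, `count_m`, `count_u`.
#' @return Tibble with CG dyads pooled.
#' @export
merge_cg_strands <- function(records) {
  cg <- filter(records, .data$context == "CG")
  rest <- filter(records, .data$context != "CG")
  pooled <- cg |>
    mutate(dyad = ifelse(.data$strand == "-", .data$pos - 1L, .data$pos)) |>
    group_by(.data$chrom, .data$dyad) |>
    summarise(
      count_m = sum(.data$count_m),
      count_u = sum(.data$count_u),
      .groups = "drop"
    ) |>
    mutate(pos = .data$dyad, strand = "*", context = "CG",
           trinucleotide = NA_character_) |>
    select("chrom", "pos", "strand", "context", "trinucleotide",
           "count_m", "count_u")
  cols <- intersect(names(records), names(pooled))
  bind_rows(pooled[cols], rest[cols]) |>
    arrange(.data$chrom, .data$pos)
}
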