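#' Coerce a genome to a named character vector
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector of
#' sequences, or the path to a FASTA file. Sequences are upper-cased.
#'
#' @param genome A `DNAStringSet`, named character vector, or FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L &&
             is.null(names(genome)) && file.exists(genome)) {
    out <- as.character(Biostrings::readDNAStringSet(genome))
    names(out) <- sub("\\s.*$", "", names(out))
  } else if (is.character(genome)) {
    out <- genome
  } else {
    stop("`genome` must be a DNAStringSet, named character vector or FASTA path",
         call. = FALSE)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("genome sequences must be named", call. = FALSE)
  }
  toupper(out)
}

#' Chromosome lengths of a genome
#'
#' @inheritParams as_genome
#' @return A tibble with columns `chrom` and `length`.
#' @export
chrom_lengths <- function(genome) {
  g <- as_genome(genome)
  tibble(chrom = names(g), length = nchar(g))
}

#' Write a genome to FASTA
#'
#' @inheritParams as_genome
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  g <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), path)
  invisible(path)
}

# reverse complement for a character vector of sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round half up to `digits` decimals (matches manuscript-style percentage
# formatting; base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
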