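#' Reverse-complement a nucleotide sequence
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a coding sequence
#'
#' Translates an in-frame CDS with the standard genetic code. A terminal stop
#' codon is rendered as `*`.
#'
#' @param cds A single CDS string, length divisible by 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  codons <- codon_split(cds)
  paste(codon_to_aa(codons), collapse = "")
}

# codon string -> aa lookup built once from the standard genetic code
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

codon_to_aa <- function(codons) {
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

codon_split <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

is_stop <- function(codon) codon %in% c("TAA", "TAG", "TGA")

has_internal_stop <- function(cds) {
  codons <- codon_split(cds)
  if (length(codons) < 2) return(FALSE)
  any(is_stop(codons[-length(codons)]))
}

#' Read a FASTA file into a named character vector
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write a named character vector of sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  expr
}

# Random DNA of length n from the current RNG stream.
rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Random sense (non-stop) codons.
rand_codons <- function(n) {
  sense <- names(.codon_table)[.codon_table != "*"]
  sample(sense, n, replace = TRUE)
}

# 0-based half-open substring helpers (internal coordinate convention).
substr0 <- function(x, start, end) substr(x, start + 1L, end)

`%||%` <- function(a, b) if (is.null(a)) b else a
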