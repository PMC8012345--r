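# Multiple alignment surface. The heavy lifting is delegated to MAFFT
# (progressive profile alignment), which must be on the PATH.

#' Progressive multiple sequence alignment
#'
#' Aligns nucleotide sequences with MAFFT's default progressive strategy
#' (`--retree 2 --maxiterate 0`), which builds a k-mer-distance guide tree and
#' performs profile-profile alignment with affine gaps. Output columns
#' preserve the input residues exactly; only gaps are introduced.
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @param guide Optional guide tree; MAFFT recomputes its own guide tree, so a
#'   supplied tree is ignored with a message.
#' @return Named character vector of aligned sequences (equal lengths,
#'   uppercase, gaps as `-`), in the input order.
#' @export
progressive_align <- function(seqs, guide = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 2)
  if (any(!nzchar(seqs))) stop("empty sequence supplied to progressive_align")
  if (!is.null(guide)) message("guide tree ignored: MAFFT builds its own")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  mafft <- Sys.which("mafft")
  if (!nzchar(mafft)) stop("MAFFT binary not found on PATH")
  tmp_in <- tempfile(fileext = ".fasta")
  tmp_out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  safe_names <- paste0("s", seq_along(seqs))
  write_fasta(stats::setNames(unname(seqs), safe_names), tmp_in)
  status <- system2(mafft, c("--retree", "2", "--maxiterate", "0", "--quiet",
                             shQuote(tmp_in)), stdout = tmp_out, stderr = FALSE)
  if (status != 0) stop("MAFFT failed with status ", status)
  out <- read_fasta(tmp_out)
  stats::setNames(toupper(unname(out[safe_names])), names(seqs))
}
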