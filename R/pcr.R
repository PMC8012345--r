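# In-silico PCR: primer binding-site search and amplicon prediction.

check_primer <- function(primer) {
  if (nchar(primer) < 10) stop("primer must be at least 10 nt")
  if (grepl("[^ACGT]", primer))
    stop("degenerate or non-ACGT bases in primer are unsupported (IUPAC codes not handled)")
  invisible(primer)
}

#' Find primer binding sites on a template
#'
#' Reports every position where the primer anneals with at most `max_mismatch`
#' mismatches (no indels), on either strand. The 3'-terminal base of the
#' primer must match exactly (mismatches there abolish extension).
#'
#' @param template Template sequence (single string).
#' @param primer Primer sequence, 5'->3', A/C/G/T only, >= 10 nt.
#' @param max_mismatch Maximum number of mismatches tolerated (default 1).
#' @return Tibble with `position` (0-based start of the site on the plus
#'   strand) and `strand` ("+" = primer extends rightwards, "-" = primer binds
#'   the minus strand and extends leftwards).
#' @export
#' @examples
#' find_binding_sites("ACGTACGTACGTACGTACGT", "ACGTACGTAC", max_mismatch = 0)
find_binding_sites <- function(template, primer, max_mismatch = 1) {
  check_primer(primer)
  stopifnot(is.character(template), length(template) == 1, nchar(template) > 0)
  m <- nchar(primer)
  subj <- Biostrings::DNAString(template)

  hits_fwd <- Biostrings::matchPattern(primer, subj, max.mismatch = max_mismatch)
  pos_f <- BiocGenerics::start(hits_fwd) - 1L
  # 3' base of a forward-binding primer sits at site end
  if (length(pos_f) > 0) {
    keep <- substring(template, pos_f + m, pos_f + m) == substr(primer, m, m)
    pos_f <- pos_f[keep]
  }

  rc <- revcomp(primer)
  hits_rev <- Biostrings::matchPattern(rc, subj, max.mismatch = max_mismatch)
  pos_r <- BiocGenerics::start(hits_rev) - 1L
  # 3' base of a minus-strand primer pairs with the first base of the
  # plus-strand site
  if (length(pos_r) > 0) {
    keep <- substring(template, pos_r + 1L, pos_r + 1L) == substr(rc, 1L, 1L)
    pos_r <- pos_r[keep]
  }

  dplyr::arrange(
    tibble::tibble(position = c(pos_f, pos_r),
                   strand = rep(c("+", "-"), c(length(pos_f), length(pos_r)))),
    .data$position)
}

#' Predict PCR amplicons for a primer pair
#'
#' Pairs every forward-primer site with every compatible downstream
#' reverse-primer site within the maximum product length, in both template
#' orientations (forward primer on the plus or on the minus strand). Product
#' length includes both primers.
#'
#' @param template Template sequence (single string).
#' @param pair One primer pair: a one-row data frame or list with `forward`,
#'   `reverse` (both 5'->3') and `max_product`.
#' @param max_mismatch Mismatch tolerance per primer site (3' base exact).
#' @return Tibble with `start`, `end` (0-based half-open on the plus strand),
#'   `length` and `orientation` ("F+/R-" or "R+/F-"). Empty when no product.
#' @export
predict_amplicons <- function(template, pair, max_mismatch = 1) {
  fwd <- pair$forward; rev <- pair$reverse
  max_product <- pair$max_product %||% 10000L
  m_f <- nchar(fwd); m_r <- nchar(rev)
  sites_f <- find_binding_sites(template, fwd, max_mismatch)
  sites_r <- find_binding_sites(template, rev, max_mismatch)

  pair_up <- function(left_pos, left_len, right_pos, right_len, orientation) {
    if (length(left_pos) == 0 || length(right_pos) == 0) return(NULL)
    grid <- expand.grid(p = left_pos, q = right_pos)
    grid <- grid[grid$q >= grid$p + left_len, , drop = FALSE]
    len <- grid$q + right_len - grid$p
    ok <- len <= max_product
    if (!any(ok)) return(NULL)
    tibble::tibble(start = grid$p[ok], end = grid$q[ok] + right_len,
                   length = len[ok], orientation = orientation)
  }
  out <- dplyr::bind_rows(
    pair_up(sites_f$position[sites_f$strand == "+"], m_f,
            sites_r$position[sites_r$strand == "-"], m_r, "F+/R-"),
    pair_up(sites_r$position[sites_r$strand == "+"], m_r,
            sites_f$position[sites_f$strand == "-"], m_f, "R+/F-"))
  if (nrow(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer(), orientation = character()))
  }
  dplyr::arrange(out, .data$start, .data$length)
}

#' Run a primer panel over a region and collect the band set
#'
#' Applies [predict_amplicons()] for every pair of a primer table and returns
#' the electrophoresis-style band set: deduplicated, sorted product lengths
#' per primer pair.
#'
#' @param region A `vat_region` or a plain sequence string.
#' @param primers Primer table as in [default_primers()].
#' @param max_mismatch Mismatch tolerance per site.
#' @param accession Accession id used when `region` is a plain string.
#' @return Tibble with `accession`, `primer`, `class`, `length` (one row per
#'   distinct band).
#' @export
region_bands <- function(region, primers = default_primers(), max_mismatch = 1,
                         accession = "A1") {
  if (inherits(region, "vat_region")) {
    accession <- region$accession
    template <- region$sequence
  } else template <- region
  dplyr::bind_rows(lapply(seq_len(nrow(primers)), function(i) {
    amp <- predict_amplicons(template, primers[i, ], max_mismatch)
    lens <- sort(unique(amp$length))
    if (length(lens) == 0) return(NULL)
    tibble::tibble(accession = accession, primer = primers$name[i],
                   class = primers$class[i], length = lens)
  }))
}
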