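# Decoding band patterns into homolog counts and repeat-number digit strings.

#' Default flank constants of the primer classes
#'
#' Amplicon length is `constant + unit_nt * k` for the repeat-spanning and
#' exon-2-internal classes, `constant + unit_nt * k (+ 2345 with the intron-1
#' insertion)` for the exon1-exon2 class, and the constant itself
#' (k-independent) for the reverse-strand pair.
#'
#' @return Named numeric vector.
#' @export
default_flank_constants <- function() {
  c(repeat_spanning = 598, exon2_internal = 272, exon1_exon2 = 1307,
    reverse_strand_exon1 = 933)
}

INSERTION_SHIFT <- 2345  # intron-1 insertion class: 1502 -> 3847 at k = 1

decode_band <- function(length, flank, unit_nt, tol) {
  k <- round((length - flank) / unit_nt)
  if (abs(length - (flank + unit_nt * k)) > tol) return(NA_integer_)
  as.integer(k)
}

#' Infer homolog count and repeat digits of one accession from its bands
#'
#' Decodes the band set of the four primer classes into an
#' `AccessionInference`: each repeat-spanning band of length L yields one
#' homolog with `round((L - f) / unit_nt)` repeat copies (one "digit"); a
#' product of the exon-2-internal pair marks a single-repeat homolog (digit 1,
#' appended unless already implied); a product of the reverse-strand pair
#' marks a reverse-strand homolog (also single-repeat); a long exon1-exon2
#' product (shifted by ~2345 nt) flags an insertion pseudogene without adding
#' a digit. Because co-migrating bands are indistinguishable, homologs sharing
#' a repeat count collapse into one digit: the count is a minimum.
#'
#' @param bands Tibble of bands with columns `class` and `length` (as from
#'   [region_bands()]); an `accession` column, if present, must be constant.
#' @param unit_nt Repeat-unit length (default 195).
#' @param flank_constants Named vector of per-class flank constants.
#' @param tol Band-length tolerance in nt (default 5).
#' @param accession Accession id (defaults to the bands' column).
#' @return One-row tibble of class `vat_inference`: `accession`, `digits`
#'   (sorted digit string), `n_homologs`, `has_single_repeat_homolog`,
#'   `has_reverse_homolog`, `has_insertion_pseudo`.
#' @export
infer_accession <- function(bands, unit_nt = 195,
                            flank_constants = default_flank_constants(),
                            tol = 5, accession = NULL) {
  stopifnot(all(c("class", "length") %in% names(bands)))
  if (is.null(accession)) {
    accession <- if ("accession" %in% names(bands) && nrow(bands) > 0) {
      u <- unique(bands$accession)
      if (length(u) > 1) stop("bands of several accessions supplied; split first")
      u
    } else "A1"
  }
  get_lens <- function(cl) sort(unique(bands$length[bands$class == cl]))

  digits <- integer(0)
  for (L in get_lens("repeat_spanning")) {
    k <- decode_band(L, flank_constants[["repeat_spanning"]], unit_nt, tol)
    if (is.na(k)) {
      stop(sprintf("repeat-spanning band of %d nt is not within %g nt of any integer repeat count",
                   L, tol))
    }
    if (k < 1 || k > 7) {
      stop(sprintf("repeat-spanning band of %d nt decodes to k = %d, outside 1..7", L, k))
    }
    digits <- c(digits, k)
  }
  digits <- sort(unique(digits))

  has_single <- any(vapply(get_lens("exon2_internal"), function(L)
    !is.na(decode_band(L, flank_constants[["exon2_internal"]], unit_nt, tol)) &&
      decode_band(L, flank_constants[["exon2_internal"]], unit_nt, tol) == 1L,
    logical(1)))
  has_reverse <- any(abs(get_lens("reverse_strand_exon1") -
                           flank_constants[["reverse_strand_exon1"]]) <= tol)
  if ((has_single || has_reverse) && !(1L %in% digits)) digits <- c(1L, digits)

  has_insertion <- FALSE
  for (L in get_lens("exon1_exon2")) {
    f <- flank_constants[["exon1_exon2"]]
    plain <- decode_band(L, f, unit_nt, tol)
    if (!is.na(plain) && plain >= 1 && plain <= 7) next
    if (!is.na(decode_band(L, f + INSERTION_SHIFT, unit_nt, tol))) {
      has_insertion <- TRUE
    } else {
      stop(sprintf("exon1-exon2 band of %d nt matches neither the plain nor the insertion-shifted series", L))
    }
  }

  n_homologs <- length(digits)
  out <- tibble::tibble(
    accession = accession,
    digits = paste(sort(digits), collapse = ""),
    n_homologs = n_homologs,
    has_single_repeat_homolog = has_single || 1L %in% digits,
    has_reverse_homolog = has_reverse,
    has_insertion_pseudo = has_insertion)
  class(out) <- c("vat_inference", class(out))
  out
}

#' Summarise a panel of accession inferences
#'
#' @param inferences Tibble of per-accession inferences (rows from
#'   [infer_accession()], bound together).
#' @return A `vat_panel_summary`: list with `summary` (one row: n_accessions,
#'   total_homologs, n_at_least_4, n_with_digit1, n_with_reverse,
#'   n_with_insertion), `per_accession`, and `spectrum` (count of accessions
#'   containing each digit 1..7).
#' @export
summarize_panel <- function(inferences) {
  stopifnot(nrow(inferences) >= 1)
  if (anyDuplicated(inferences$accession))
    stop("duplicate accession ids in inferences")
  digit_sets <- strsplit(inferences$digits, "")
  spectrum <- tibble::tibble(
    digit = 1:7,
    n_accessions = vapply(1:7, function(d)
      sum(vapply(digit_sets, function(s) as.character(d) %in% s, logical(1))),
      numeric(1)),
    n_bands = vapply(1:7, function(d)
      sum(vapply(digit_sets, function(s) sum(s == as.character(d)), numeric(1))),
      numeric(1)))
  summary <- tibble::tibble(
    n_accessions = nrow(inferences),
    total_homologs = sum(inferences$n_homologs),
    n_at_least_4 = sum(inferences$n_homologs >= 4),
    n_with_digit1 = sum(vapply(digit_sets, function(s) "1" %in% s, logical(1))),
    n_with_reverse = sum(inferences$has_reverse_homolog),
    n_with_insertion = sum(inferences$has_insertion_pseudo))
  structure(list(summary = summary, per_accession = inferences,
                 spectrum = spectrum),
            class = "vat_panel_summary")
}

#' @export
print.vat_panel_summary <- function(x, ...) {
  cat("<vat_panel_summary>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy vat_panel_summary
#' @export
tidy.vat_panel_summary <- function(x, ...) x$per_accession

#' @method glance vat_panel_summary
#' @export
glance.vat_panel_summary <- function(x, ...) x$summary

#' @rdname autoplot.vat_envelope
#' @method autoplot vat_panel_summary
#' @export
autoplot.vat_panel_summary <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = factor(.data$digit), y = .data$n_accessions)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "repeat copies per homolog (digit)",
                  y = "accessions containing the digit",
                  title = "Digit frequency spectrum") +
    ggplot2::theme_minimal()
}
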