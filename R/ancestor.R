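# Construction of the ancestral gene model and locus accessors.
#
# A simulated locus is a list:
#   id, strand ("+"/"-"), class (intact/pseudo_stop/pseudo_insertion/partial),
#   is_retro (reverse-strand retro copy),
#   parts: exon1, intron1, exon2_pre, units (character vector, one 195-nt
#          string per repeat copy), exon2_post, intron2, exon3, intron3,
#          exon4, intron4, exon5,
#   te: list of insertions (intron name, offset, seq, kind),
#   events: tibble(kind, time, lineage, detail).
# Part sequences are stored on the gene's sense strand; emit_region()
# reverse-complements "-" loci when laying out the region.

new_locus <- function(id, parts, strand = "+", class = "intact") {
  loc <- structure(list(id = id, strand = strand, class = class,
                        is_retro = FALSE, parts = parts, te = list(),
                        events = empty_events(), prot = NULL),
                   class = "vat_locus")
  loc$prot <- protected_part_ranges(loc)
  loc
}

# Event logs are accumulated as plain lists during simulation (cheap appends)
# and exposed as a tibble via events_log().
empty_events <- function() list()

add_event <- function(locus, kind, time, detail = "") {
  locus$events[[length(locus$events) + 1L]] <-
    list(kind = kind, time = time, lineage = locus$id, detail = detail)
  locus
}

#' Event log of a simulated locus
#' @param locus A `vat_locus`.
#' @return Tibble with columns `kind`, `time`, `lineage`, `detail`.
#' @export
events_log <- function(locus) {
  if (length(locus$events) == 0) {
    return(tibble::tibble(kind = character(), time = numeric(),
                          lineage = character(), detail = character()))
  }
  dplyr::bind_rows(lapply(locus$events, tibble::as_tibble))
}

#' Number of repeat copies in a simulated locus
#' @param locus A `vat_locus`.
#' @return Integer copy count k.
#' @export
locus_k <- function(locus) length(locus$parts$units)

#' Spliced CDS of a simulated locus
#'
#' Concatenates the exons on the gene's sense strand (exon 2 is the pre-array
#' part, the repeat copies, and the post-array part).
#'
#' @param locus A `vat_locus`.
#' @return CDS string.
#' @export
gene_cds <- function(locus) {
  p <- locus$parts
  paste0(p$exon1, p$exon2_pre, paste(p$units, collapse = ""), p$exon2_post,
         p$exon3, p$exon4, p$exon5)
}

intron_with_te <- function(locus, name) {
  s <- locus$parts[[name]]
  for (te in locus$te) {
    if (te$intron == name) {
      s <- paste0(substr0(s, 0, te$offset), te$seq,
                  substr0(s, te$offset, nchar(s)))
    }
  }
  s
}

#' Genomic sequence of a simulated locus (sense strand)
#' @param locus A `vat_locus`.
#' @return Gene sequence string including introns and any TE insertions.
#' @export
gene_seq <- function(locus) {
  p <- locus$parts
  paste0(p$exon1, intron_with_te(locus, "intron1"),
         p$exon2_pre, paste(p$units, collapse = ""), p$exon2_post,
         intron_with_te(locus, "intron2"), p$exon3,
         intron_with_te(locus, "intron3"), p$exon4,
         intron_with_te(locus, "intron4"), p$exon5)
}

# Exon intervals (0-based half-open) on the locus sense strand, within
# gene_seq() coordinates, plus the repeat-array interval.
locus_layout <- function(locus) {
  p <- locus$parts
  il <- vapply(paste0("intron", 1:4), function(nm) nchar(intron_with_te(locus, nm)),
               numeric(1))
  el <- c(nchar(p$exon1),
          nchar(p$exon2_pre) + sum(nchar(p$units)) + nchar(p$exon2_post),
          nchar(p$exon3), nchar(p$exon4), nchar(p$exon5))
  starts <- cumsum(c(0, el[1] + il[1], el[2] + il[2], el[3] + il[3], el[4] + il[4]))
  exons <- tibble::tibble(exon = paste0("exon", 1:5),
                          start = starts, end = starts + el)
  array_start <- exons$start[2] + nchar(p$exon2_pre)
  list(exons = exons, array = c(array_start, array_start + sum(nchar(p$units))),
       length = exons$end[5])
}

# Replace any internal stop codon by substituting an unprotected base with C
# (every stop codon is T/A/G only, so a C always destroys it). `protected` is
# a logical vector over 0-based CDS positions.
fix_stops <- function(cds, protected) {
  codons <- codon_split(cds)
  n <- length(codons)
  for (i in seq_len(n - 1)[-1]) {
    if (is_stop(codons[i])) {
      base0 <- 3L * (i - 1L)
      free <- base0 + 0:2
      free <- free[!protected[free + 1L]]
      if (length(free) == 0) stop("internal stop codon entirely inside a protected site")
      substr(cds, free[1] + 1L, free[1] + 1L) <- "C"
      codons <- codon_split(cds)
    }
  }
  cds
}

# 0-based protected ranges per part (primer sites extended to whole codons in
# exonic parts, plus the start and stop codons). Returned as a named list of
# 2-column matrices.
protected_part_ranges <- function(locus, g = vat_geometry()) {
  r <- list(
    exon1 = rbind(c(0L, 3L), c(399L, 423L)),
    exon2_pre = rbind(c(111L, 135L)),
    exon2_post = rbind(c(39L, 60L), c(114L, 138L)),
    intron1 = rbind(g$rs_f_intron1),
    intron2 = rbind(g$rs_r_intron2),
    exon5 = rbind(c(nchar(locus$parts$exon5) - 3L, nchar(locus$parts$exon5)))
  )
  if (isTRUE(locus$is_retro)) {
    r$exon1 <- rbind(r$exon1, c(30L, 51L), c(942L, 963L))
  }
  r
}

plant <- function(seq, at0, site) {
  substr(seq, at0 + 1L, at0 + nchar(site)) <- site
  seq
}

#' Build the ancestral gene of a simulated cluster
#'
#' Constructs a five-exon / four-intron gene whose second exon carries
#' `ancestor_repeat_count` identical tandem copies of one 195-nt (65-codon)
#' repeat unit. The spliced CDS is a complete open reading frame; with the
#' default geometry and k = 4 it encodes a 1467-aa protein (65 aa per repeat
#' copy, so 1272 aa at k = 1). Primer sites for the four synthetic pairs of
#' [default_primers()] are embedded at fixed positions so that in-silico PCR
#' on an emitted region reproduces the closed-form amplicon arithmetic.
#'
#' @param config A [sim_config()].
#' @return A `vat_locus` (the ancestor, id "L1", forward strand, intact).
#' @export
#' @examples
#' anc <- make_ancestor(sim_config(seed = 1))
#' nchar(translate_cds(gene_cds(anc))) - 1L  # 1467 aa (minus the stop)
make_ancestor <- function(config) {
  validate_sim_config(config)
  g <- vat_geometry(config$unit_nt)
  k <- config$ancestor_repeat_count
  with_seed(config$seed, {
    unit_codons <- rand_codons(g$unit_nt / 3L)
    n_cod <- (sum(g$exon1, g$exon2_pre, g$exon2_post, g$exon3, g$exon4,
                  g$exon5) + g$unit_nt * k) / 3L
    codons <- rand_codons(n_cod)
    codons[1] <- "ATG"
    codons[n_cod] <- "TAA"
    arr_cod0 <- (g$exon1 + g$exon2_pre) / 3L  # 0-based first array codon
    codons[(arr_cod0 + 1L):(arr_cod0 + (g$unit_nt / 3L) * k)] <-
      rep(unit_codons, k)
    cds <- paste(codons, collapse = "")

    pr <- default_primers()
    site <- function(class, which) {
      row <- pr[pr$class == class, ]
      if (which == "f") row$forward else revcomp(row$reverse)
    }
    arr_nt0 <- g$exon1 + g$exon2_pre
    arr_nt1 <- arr_nt0 + g$unit_nt * k
    cds <- plant(cds, g$e1e2_f_exon1[1], site("exon1_exon2", "f"))
    cds <- plant(cds, g$exon1 + g$int_f_pre[1], site("exon2_internal", "f"))
    cds <- plant(cds, arr_nt1 + g$e1e2_r_post[1], site("exon1_exon2", "r"))
    cds <- plant(cds, arr_nt1 + g$int_r_post[1], site("exon2_internal", "r"))

    protected <- rep(FALSE, nchar(cds))
    for (iv in list(c(g$e1e2_f_exon1[1], g$e1e2_f_exon1[2]),
                    g$exon1 + g$int_f_pre,
                    arr_nt1 + g$e1e2_r_post,
                    arr_nt1 + g$int_r_post)) {
      protected[(iv[1] + 1L):iv[2]] <- TRUE
    }
    cds <- fix_stops(cds, protected)

    make_intron <- function(len) paste0("GT", rand_dna(len - 4L), "AG")
    intron1 <- plant(make_intron(g$intron), g$rs_f_intron1[1],
                     site("repeat_spanning", "f"))
    intron2 <- plant(make_intron(g$intron), g$rs_r_intron2[1],
                     site("repeat_spanning", "r"))

    parts <- list(
      exon1 = substr0(cds, 0L, g$exon1),
      intron1 = intron1,
      exon2_pre = substr0(cds, g$exon1, arr_nt0),
      units = substring(cds, arr_nt0 + 1L + g$unit_nt * (seq_len(k) - 1L),
                        arr_nt0 + g$unit_nt * seq_len(k)),
      exon2_post = substr0(cds, arr_nt1, arr_nt1 + g$exon2_post),
      intron2 = intron2,
      exon3 = substr0(cds, arr_nt1 + g$exon2_post,
                      arr_nt1 + g$exon2_post + g$exon3),
      intron3 = make_intron(g$intron),
      exon4 = substr0(cds, arr_nt1 + g$exon2_post + g$exon3,
                      arr_nt1 + g$exon2_post + g$exon3 + g$exon4),
      intron4 = make_intron(g$intron),
      exon5 = substr0(cds, arr_nt1 + g$exon2_post + g$exon3 + g$exon4,
                      nchar(cds))
    )
    loc <- new_locus("L1", parts)
    stopifnot(identical(gene_cds(loc), cds), !has_internal_stop(cds),
              startsWith(cds, "ATG"))
    loc
  })
}

#' @export
print.vat_locus <- function(x, ...) {
  cat(sprintf("<vat_locus %s> strand %s, class %s, k = %d, %d nt (CDS %d nt), %d events\n",
              x$id, x$strand, x$class, locus_k(x), nchar(gene_seq(x)),
              nchar(gene_cds(x)), length(x$events)))
  invisible(x)
}
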