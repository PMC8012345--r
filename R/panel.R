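# Region emission and panel simulation.

M5_TAG <- "GGACCAAGGCCAAGGACCAACCAAGGACCA"  # 30-nt start anchor (M5-like)
M4_TAG <- "CCTGGTTCCGGTTCCTGGTTGGTTCCTGGA"  # 30-nt end anchor (M4-like)

#' Emit a genomic region containing a set of simulated loci
#'
#' Lays the loci out between an M5-like start anchor and an M4-like end
#' anchor, separated by intergenic spacers. Reverse-strand loci are inserted
#' as the reverse complement of their sense-strand gene sequence. The returned
#' truth table gives, per locus, 0-based half-open region coordinates of the
#' gene, its exons and its repeat array, plus strand, class, repeat count k
#' and the (sense-strand) CDS.
#'
#' @param loci A `vat_locus` or list of them (e.g. from [evolve_cluster()]).
#' @param config A [sim_config()]; supplies spacer length and, when `spacers`
#'   is NULL, the seed for deterministic spacer generation.
#' @param accession Accession identifier.
#' @param spacers Optional character vector of pre-drawn spacer sequences
#'   (recycled in order); used by [simulate_panel()] to share spacers across
#'   accessions.
#' @return A `vat_region`: list with `accession`, `sequence`, `truth` (tibble)
#'   and `anchors`.
#' @export
emit_region <- function(loci, config, accession = "A1", spacers = NULL) {
  if (inherits(loci, "vat_locus")) loci <- list(loci)
  stopifnot(length(loci) >= 1)
  n_sp <- length(loci) + 1L
  if (is.null(spacers)) {
    spacers <- with_seed(config$seed,
                         replicate(n_sp, rand_dna(config$spacer_nt)))
  }
  if (length(spacers) < n_sp) stop("not enough spacers supplied")

  pieces <- character(0)
  offset <- 0L
  push <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    offset <<- offset + nchar(s)
  }
  push(M5_TAG)
  truth <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    push(spacers[[i]])
    loc <- loci[[i]]
    gseq <- gene_seq(loc)
    lay <- locus_layout(loc)
    L <- lay$length
    gstart <- offset
    if (loc$strand == "+") {
      exons <- dplyr::mutate(lay$exons, start = .data$start + gstart,
                             end = .data$end + gstart)
      arr <- lay$array + gstart
      push(gseq)
    } else {
      exons <- tibble::tibble(exon = rev(lay$exons$exon),
                              start = gstart + L - rev(lay$exons$end),
                              end = gstart + L - rev(lay$exons$start))
      arr <- c(gstart + L - lay$array[2], gstart + L - lay$array[1])
      push(revcomp(gseq))
    }
    truth[[i]] <- tibble::tibble(
      locus_id = loc$id, strand = loc$strand, class = loc$class,
      k = locus_k(loc), start = gstart, end = gstart + L,
      array_start = arr[1], array_end = arr[2],
      cds = gene_cds(loc), exons = list(exons))
  }
  push(spacers[[n_sp]])
  push(M4_TAG)
  structure(list(accession = accession,
                 sequence = paste(pieces, collapse = ""),
                 truth = dplyr::bind_rows(truth),
                 anchors = c(M5 = 0L,
                             M4 = offset - nchar(M4_TAG))),
            class = "vat_region")
}

#' @export
print.vat_region <- function(x, ...) {
  cat(sprintf("<vat_region %s> %d nt, %d loci (digits '%s')\n", x$accession,
              nchar(x$sequence), nrow(x$truth), truth_digits(x$truth)))
  invisible(x)
}

# Sorted repeat-count digit string over the loci of a truth table.
truth_digits <- function(truth) paste(sort(truth$k), collapse = "")

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @method tidy vat_region
#' @export
tidy.vat_region <- function(x, ...) x$truth

#' Simulate a panel of accessions
#'
#' Generates one ancestor from the config seed, then evolves and emits an
#' independent cluster region per accession. Intergenic spacers are drawn once
#' and shared across accessions, so with all event rates at zero every
#' accession's region is identical to the ancestor's. The panel truth table
#' encodes, per accession, the homolog count and the sorted repeat-count
#' "digit string" (one digit per locus, each digit that locus's k).
#'
#' @param config A [sim_config()].
#' @return A `vat_panel`: list with `config`, `regions` (list of `vat_region`)
#'   and `truth` (tibble: accession, n_loci, digits, classes, has_reverse,
#'   has_insertion, has_stop).
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  anc <- make_ancestor(config)
  with_seed(config$seed, {
    spacers <- replicate(MAX_LOCI + 2L, rand_dna(config$spacer_nt))
    regions <- vector("list", config$n_accessions)
    for (i in seq_len(config$n_accessions)) {
      res <- evolve_cluster(anc, config)
      regions[[i]] <- emit_region(res$loci, config,
                                  accession = sprintf("A%03d", i),
                                  spacers = spacers)
    }
    truth <- dplyr::bind_rows(lapply(regions, function(r) {
      tibble::tibble(
        accession = r$accession,
        n_loci = nrow(r$truth),
        digits = truth_digits(r$truth),
        classes = paste(r$truth$class[order(r$truth$k)], collapse = ","),
        has_reverse = any(r$truth$strand == "-"),
        has_insertion = any(r$truth$class == "pseudo_insertion"),
        has_stop = any(r$truth$class == "pseudo_stop"))
    }))
    structure(list(config = config, regions = regions, truth = truth),
              class = "vat_panel")
  })
}

#' @export
print.vat_panel <- function(x, ...) {
  cat(sprintf("<vat_panel> %d accessions, %s loci total\n",
              nrow(x$truth), sum(x$truth$n_loci)))
  print(utils::head(x$truth, 5))
  invisible(x)
}

#' @method tidy vat_panel
#' @export
tidy.vat_panel <- function(x, ...) x$truth

#' @method glance vat_panel
#' @export
glance.vat_panel <- function(x, ...) {
  tibble::tibble(n_accessions = nrow(x$truth),
                 total_loci = sum(x$truth$n_loci),
                 mean_loci = mean(x$truth$n_loci),
                 n_with_reverse = sum(x$truth$has_reverse),
                 n_with_insertion = sum(x$truth$has_insertion))
}

#' Write a simulated region and its truth annotation to disk
#'
#' Writes `<accession>.fasta` (region sequence), `<accession>.gff3` (gene and
#' exon features, 1-based inclusive coordinates) and `<accession>_truth.tsv`
#' (one row per locus: locus_id, strand, class, k, start, end, array_start,
#' array_end, cds; coordinates 0-based half-open as used internally).
#'
#' @param region A `vat_region`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_truth <- function(region, dir) {
  stopifnot(inherits(region, "vat_region"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  acc <- region$accession
  fa <- file.path(dir, paste0(acc, ".fasta"))
  gff <- file.path(dir, paste0(acc, ".gff3"))
  tsv <- file.path(dir, paste0(acc, "_truth.tsv"))
  write_fasta(stats::setNames(region$sequence, acc), fa)

  tr <- region$truth
  gene_gr <- GenomicRanges::GRanges(
    seqnames = acc,
    ranges = IRanges::IRanges(start = tr$start + 1L, end = tr$end),
    strand = tr$strand)
  S4Vectors::mcols(gene_gr) <- S4Vectors::DataFrame(
    type = "gene", ID = tr$locus_id, class = tr$class, k = tr$k)
  ex <- tidyr::unnest(dplyr::select(tr, "locus_id", "strand", "exons"), "exons")
  exon_gr <- GenomicRanges::GRanges(
    seqnames = acc,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand)
  S4Vectors::mcols(exon_gr) <- S4Vectors::DataFrame(
    type = "exon", ID = paste(ex$locus_id, ex$exon, sep = "."),
    Parent = ex$locus_id)
  rtracklayer::export(c(gene_gr, exon_gr), gff, format = "gff3")

  utils::write.table(
    dplyr::select(tr, -"exons"), tsv,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gff, tsv = tsv))
}

#' Read back a region truth annotation written by [write_truth()]
#'
#' @param dir Directory containing the files.
#' @param accession Accession identifier used at write time.
#' @return List with `sequence` (named character), `truth` (tibble matching
#'   the in-memory truth table, exon list-column reconstructed from the GFF3).
#' @export
read_truth <- function(dir, accession) {
  fa <- read_fasta(file.path(dir, paste0(accession, ".fasta")))
  tsv <- tibble::as_tibble(utils::read.delim(
    file.path(dir, paste0(accession, "_truth.tsv")),
    colClasses = c(locus_id = "character", strand = "character",
                   class = "character", cds = "character")))
  gr <- rtracklayer::import(file.path(dir, paste0(accession, ".gff3")))
  gdf <- tibble::as_tibble(as.data.frame(gr))
  exdf <- gdf[gdf$type == "exon", ]
  exons <- lapply(tsv$locus_id, function(id) {
    sub <- exdf[vapply(exdf$Parent, function(p) id %in% p, logical(1)), ]
    tibble::tibble(exon = sub("^.*\\.", "", sub$ID),
                   start = as.integer(sub$start - 1L),
                   end = as.integer(sub$end))
  })
  tsv$exons <- exons
  list(sequence = fa, truth = tsv)
}
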