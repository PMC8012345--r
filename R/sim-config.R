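#' Default synthetic primer panel
#'
#' Four primer pairs mirroring the assay design used to type the cluster:
#' a repeat-spanning pair sitting in the introns on either side of the repeat
#' exon (band length = flank constant + 195 k), a pair internal to exon 2
#' (272 + 195 k, i.e. 467 bp at k = 1), a pair from the end of exon 1 into
#' exon 2 (1307 + 195 k, i.e. 1502 bp at k = 1, plus 2345 bp when the intron-1
#' insertion pseudogene class is present), and a reverse-strand-specific pair
#' inside exon 1 of the retro-copied homolog (933 bp, independent of k).
#'
#' The sequences are fixed synthetic 20-mers over A/C/G (T-free, so that a
#' planted site can never spell a stop codon on either strand).
#'
#' @return A tibble with columns `name`, `class`, `forward`, `reverse`,
#'   `max_product`.
#' @export
default_primers <- function() {
  tibble::tibble(
    name = c("RS649", "E12-5895", "E2-6097", "REV5474"),
    class = c("repeat_spanning", "exon1_exon2", "exon2_internal",
              "reverse_strand_exon1"),
    forward = c("AACAGGACGAGAACGAACGG", "GGCAGAAGAGCCGACAGCCG",
                "GCGGAGCCCCGCCAAACGAG", "GGGGAGAACAAGGAAGACAG"),
    # reverse primers given 5'->3' on the minus strand; their reverse
    # complements are what is planted on the plus strand of the template
    reverse = revcomp(c("ACAACGGAGAAAGGCACCAG", "GAAGACCAGCCCCGCACGGC",
                        "GCCGAAAAGCGAAGGGCGGA", "CCGAAACACCACAGGACCCG")),
    max_product = c(6000L, 6000L, 3000L, 2000L)
  )
}

# Fixed gene geometry of the simulated homologs (nt). Exon 2 is
# exon2_pre + k * unit_nt + exon2_post; all introns are `intron` nt
# (GT...AG). With unit_nt = 195 and k = 4 the CDS is 4404 nt, i.e. a
# 1467-aa protein.
vat_geometry <- function(unit_nt = 195L) {
  list(
    exon1 = 999L, exon2_pre = 249L, exon2_post = 249L,
    exon3 = 999L, exon4 = 600L, exon5 = 528L,
    intron = 400L, unit_nt = as.integer(unit_nt),
    # primer-site placements (0-based half-open, primer length 20)
    e1e2_f_exon1 = c(401L, 421L),      # 598 nt upstream of exon1 end
    rs_f_intron1 = c(350L, 370L),      # last 50 nt of intron 1
    rs_r_intron2 = c(30L, 50L),        # first 50 nt of intron 2
    int_f_pre = c(113L, 133L),         # ends 116 nt before the array
    int_r_post = c(116L, 136L),        # starts 116 nt after the array
    e1e2_r_post = c(40L, 60L),
    rev_f_exon1 = c(30L, 50L),         # reverse-strand pair, retro copy only
    rev_r_exon1 = c(943L, 963L),       # 933-bp product
    te_intron1_len = 2345L,            # intron-1 insertion class
    te_intron1_offset = 100L,
    te_line1_len = 2540L,              # LINE-1-like class, intron 2
    te_line1_offset = 100L
  )
}

#' Simulation configuration for a synthetic Vat-like cluster
#'
#' Bundles and validates the parameters of the cluster-evolution simulator.
#' Rates are events per gene lineage per unit time; `sub_rate` is substitutions
#' per site per unit time. Nonsynonymous substitution proposals are accepted
#' with probability `nonsyn_accept`, multiplied by `nonsyn_hot_factor` when the
#' affected codon falls inside `nonsyn_hot_window` of a repeat unit.
#'
#' @param seed Integer seed driving all randomness downstream.
#' @param n_accessions Number of accessions in a simulated panel.
#' @param ancestor_repeat_count Repeat copies k in the ancestral gene (1-7).
#' @param unit_nt Repeat-unit length in nt; must be divisible by 3.
#' @param duplication_rate,crossover_rate,te_insertion_rate,stop_gain_rate
#'   Event rates per lineage per unit time.
#' @param sub_rate Substitutions per site per unit time.
#' @param nonsyn_accept Background acceptance probability for nonsynonymous
#'   proposals (synonymous and non-coding proposals are always accepted).
#' @param nonsyn_hot_window Codon interval (within the 65-codon unit) with
#'   elevated nonsynonymous acceptance.
#' @param nonsyn_hot_factor Multiplier (>= 1) applied inside the hot window.
#' @param tree_height Total simulated time.
#' @param retro_prob Probability that one retro-copy-to-reverse-strand event
#'   occurs during the history (at most one such locus is created).
#' @param amplicon_constants Named numeric map of primer class to flank
#'   constant (nt): amplicon length = constant + `unit_nt` * k for the two
#'   k-dependent classes.
#' @param spacer_nt Intergenic spacer length used when emitting regions.
#' @param te_len_jitter SD of the jitter on the LINE-1-like insert length.
#' @return An object of class `vat_sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_accessions = 4)
#' cfg$ancestor_repeat_count
sim_config <- function(seed = 1L,
                       n_accessions = 80L,
                       ancestor_repeat_count = 4L,
                       unit_nt = 195L,
                       duplication_rate = 1.4,
                       crossover_rate = 1.0,
                       te_insertion_rate = 0.1,
                       stop_gain_rate = 0.05,
                       sub_rate = 0.01,
                       nonsyn_accept = 0.2,
                       nonsyn_hot_window = c(25L, 35L),
                       nonsyn_hot_factor = 4,
                       tree_height = 1,
                       retro_prob = 0.5,
                       amplicon_constants = c(repeat_spanning = 598,
                                              exon2_internal = 272,
                                              exon1_exon2 = 1307,
                                              reverse_strand_exon1 = 933),
                       spacer_nt = 600L,
                       te_len_jitter = 0) {
  cfg <- list(
    seed = as.integer(seed), n_accessions = as.integer(n_accessions),
    ancestor_repeat_count = as.integer(ancestor_repeat_count),
    unit_nt = as.integer(unit_nt),
    duplication_rate = duplication_rate, crossover_rate = crossover_rate,
    te_insertion_rate = te_insertion_rate, stop_gain_rate = stop_gain_rate,
    sub_rate = sub_rate, nonsyn_accept = nonsyn_accept,
    nonsyn_hot_window = as.integer(nonsyn_hot_window),
    nonsyn_hot_factor = nonsyn_hot_factor,
    tree_height = tree_height, retro_prob = retro_prob,
    amplicon_constants = amplicon_constants,
    spacer_nt = as.integer(spacer_nt), te_len_jitter = te_len_jitter
  )
  class(cfg) <- "vat_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg), call. = FALSE)
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) err("seed", "must be a single integer")
  if (cfg$n_accessions < 1) err("n_accessions", "must be >= 1")
  if (cfg$ancestor_repeat_count < 1 || cfg$ancestor_repeat_count > 7)
    err("ancestor_repeat_count", "must be in [1, 7]")
  if (cfg$unit_nt %% 3 != 0) err("unit_nt", "must be divisible by 3")
  for (f in c("duplication_rate", "crossover_rate", "te_insertion_rate",
              "stop_gain_rate", "sub_rate")) {
    if (cfg[[f]] < 0) err(f, "rates must be >= 0")
  }
  w <- cfg$nonsyn_hot_window
  if (length(w) != 2 || w[1] > w[2] || w[1] < 1 || w[2] > cfg$unit_nt / 3)
    err("nonsyn_hot_window", sprintf("must lie within [1, %d]", cfg$unit_nt / 3))
  if (cfg$nonsyn_hot_factor < 1) err("nonsyn_hot_factor", "must be >= 1")
  if (cfg$nonsyn_accept < 0 || cfg$nonsyn_accept > 1)
    err("nonsyn_accept", "must be a probability")
  if (cfg$retro_prob < 0 || cfg$retro_prob > 1)
    err("retro_prob", "must be a probability")
  if (cfg$tree_height < 0) err("tree_height", "must be >= 0")
  needed <- c("repeat_spanning", "exon2_internal", "exon1_exon2",
              "reverse_strand_exon1")
  if (!all(needed %in% names(cfg$amplicon_constants)))
    err("amplicon_constants", paste("must name", paste(needed, collapse = ", ")))
  invisible(cfg)
}

#' @export
print.vat_sim_config <- function(x, ...) {
  cat("<vat_sim_config>\n")
  cat(sprintf("  seed %d | %d accessions | ancestor k = %d (unit %d nt)\n",
              x$seed, x$n_accessions, x$ancestor_repeat_count, x$unit_nt))
  cat(sprintf("  rates: dup %.3g, crossover %.3g, TE %.3g, stop %.3g, sub %.3g/site\n",
              x$duplication_rate, x$crossover_rate, x$te_insertion_rate,
              x$stop_gain_rate, x$sub_rate))
  cat(sprintf("  nonsyn accept %.2f (x%.1f in unit codons %d-%d), height %.2f\n",
              x$nonsyn_accept, x$nonsyn_hot_factor, x$nonsyn_hot_window[1],
              x$nonsyn_hot_window[2], x$tree_height))
  invisible(x)
}
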