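# Cluster evolution: a Gillespie process over gene lineages.
#
# Per-lineage events: duplication (copy the whole locus), unequal crossover
# (gain or loss of one repeat copy, bounded to k in [1, 7]), TE insertion
# (intron-1 class of 2345 nt, matching the 1502 -> 3847 amplicon shift, or a
# LINE-1-like 2540-nt element in intron 2), premature stop gain, and per-site
# substitution. One optional retro-copy event pastes a single-repeat copy of a
# lineage onto the reverse strand. Nonsynonymous substitution proposals are
# accepted with probability nonsyn_accept, multiplied by nonsyn_hot_factor
# when the codon falls in the hot window of a repeat unit; proposals creating
# a stop codon or touching a primer site are rejected, so pseudogenes arise
# only through te_insertion or stop_gain.

MAX_LOCI <- 10L

# Plain-vector table of the mutable parts of a locus (units listed
# individually). Every part starts on a codon boundary (all part lengths are
# multiples of 3), so the codon containing any coding position can be read
# from the part string itself.
part_table <- function(locus) {
  k <- locus_k(locus)
  list(part = c("exon1", "exon2_pre", rep("units", k), "exon2_post",
                "exon3", "exon4", "exon5",
                "intron1", "intron2", "intron3", "intron4"),
       ui = c(NA, NA, seq_len(k), NA, NA, NA, NA, NA, NA, NA, NA),
       coding = c(rep(TRUE, k + 6L), rep(FALSE, 4L)),
       len = c(nchar(locus$parts$exon1), nchar(locus$parts$exon2_pre),
               nchar(locus$parts$units), nchar(locus$parts$exon2_post),
               nchar(locus$parts$exon3), nchar(locus$parts$exon4),
               nchar(locus$parts$exon5),
               nchar(locus$parts$intron1), nchar(locus$parts$intron2),
               nchar(locus$parts$intron3), nchar(locus$parts$intron4)))
}

mutable_len <- function(locus) {
  sum(nchar(unlist(locus$parts, use.names = FALSE)))
}

get_part <- function(locus, part, unit_index = NA) {
  if (!is.na(unit_index)) locus$parts$units[unit_index] else locus$parts[[part]]
}

set_part <- function(locus, part, unit_index, value) {
  if (!is.na(unit_index)) locus$parts$units[unit_index] <- value
  else locus$parts[[part]] <- value
  locus
}

position_protected <- function(locus, part_base, pos0) {
  rngs <- locus$prot[[part_base]]
  if (is.null(rngs)) return(FALSE)
  any(pos0 >= rngs[, 1] & pos0 < rngs[, 2])
}

# Attempt one substitution on a locus at time `tm`; returns the (possibly
# unchanged) locus.
apply_substitution <- function(locus, config, tm) {
  pt <- part_table(locus)
  i <- sample.int(length(pt$len), 1, prob = pt$len)
  part <- pt$part[i]; ui <- pt$ui[i]
  pos0 <- sample.int(pt$len[i], 1) - 1L
  if (position_protected(locus, part, pos0)) return(locus)
  seqs <- get_part(locus, part, ui)
  old <- substr(seqs, pos0 + 1L, pos0 + 1L)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  if (pt$coding[i]) {
    cstart <- pos0 - pos0 %% 3L
    codon <- substr(seqs, cstart + 1L, cstart + 3L)
    new_codon <- codon
    substr(new_codon, pos0 %% 3L + 1L, pos0 %% 3L + 1L) <- new
    if (is_stop(new_codon)) return(locus)   # stop gain only via the dedicated event
    if (.codon_table[[codon]] != .codon_table[[new_codon]]) {
      hot <- FALSE
      if (part == "units") {
        unit_codon <- pos0 %/% 3L + 1L
        hot <- unit_codon >= config$nonsyn_hot_window[1] &&
          unit_codon <= config$nonsyn_hot_window[2]
      }
      p_acc <- min(1, config$nonsyn_accept *
                     (if (hot) config$nonsyn_hot_factor else 1))
      if (stats::runif(1) >= p_acc) return(locus)
      detail <- sprintf("nonsyn %s %s>%s pos %d%s", part, old, new, pos0,
                        if (hot) " hot" else "")
    } else {
      detail <- sprintf("syn %s %s>%s pos %d", part, old, new, pos0)
    }
  } else {
    detail <- sprintf("noncoding %s %s>%s pos %d", part, old, new, pos0)
  }
  substr(seqs, pos0 + 1L, pos0 + 1L) <- new
  locus <- set_part(locus, part, ui, seqs)
  add_event(locus, "substitution", tm, detail)
}

apply_crossover <- function(locus, tm) {
  k <- locus_k(locus)
  # unequal crossover needs at least two units to mispair: k = 1 is absorbing
  if (k < 2L) return(locus)
  gain <- stats::runif(1) < 0.5
  if (gain && k >= 7L) return(locus)
  j <- sample.int(k, 1)
  if (gain) {
    locus$parts$units <- append(locus$parts$units, locus$parts$units[j], after = j)
    locus <- add_event(locus, "crossover_gain", tm, sprintf("dk=+1 copy %d", j))
  } else {
    locus$parts$units <- locus$parts$units[-j]
    locus <- add_event(locus, "crossover_loss", tm, sprintf("dk=-1 copy %d", j))
  }
  locus
}

apply_te_insertion <- function(locus, config, tm) {
  g <- vat_geometry(config$unit_nt)
  line1 <- stats::runif(1) < 0.5
  intron <- if (line1) "intron2" else "intron1"
  if (any(vapply(locus$te, function(te) te$intron == intron, logical(1))))
    return(locus)
  len <- if (line1) {
    max(100L, as.integer(round(g$te_line1_len +
                                 stats::rnorm(1, 0, config$te_len_jitter))))
  } else g$te_intron1_len
  offset <- if (line1) g$te_line1_offset else g$te_intron1_offset
  locus$te[[length(locus$te) + 1L]] <-
    list(intron = intron, offset = offset, seq = rand_dna(len),
         kind = if (line1) "LINE1_like" else "intron1_insert")
  locus$class <- "pseudo_insertion"
  add_event(locus, "te_insertion", tm,
            sprintf("%s len %d in %s", if (line1) "LINE1_like" else "intron1_insert",
                    len, intron))
}

apply_stop_gain <- function(locus, tm) {
  pt <- part_table(locus)
  coding <- which(pt$coding)
  for (try in 1:20) {
    i <- coding[sample.int(length(coding), 1, prob = pt$len[coding])]
    part <- pt$part[i]; ui <- pt$ui[i]
    cod0 <- sample.int(pt$len[i] %/% 3L, 1) - 1L
    pos0 <- cod0 * 3L
    if (part == "exon1" && cod0 == 0L) next                      # keep ATG
    if (part == "exon5" && pos0 + 3L >= pt$len[i]) next          # keep stop
    if (any(vapply(0:2, function(d) position_protected(locus, part, pos0 + d),
                   logical(1)))) next
    seqs <- get_part(locus, part, ui)
    substr(seqs, pos0 + 1L, pos0 + 3L) <- "TAA"
    locus <- set_part(locus, part, ui, seqs)
    if (locus$class == "intact") locus$class <- "pseudo_stop"
    return(add_event(locus, "stop_gain", tm, sprintf("%s codon %d", part, cod0 + 1L)))
  }
  locus
}

apply_retro_copy <- function(loci, config, tm, next_id) {
  intact <- which(vapply(loci, function(l) l$class == "intact" && l$strand == "+",
                         logical(1)))
  if (length(intact) == 0) return(list(loci = loci, next_id = next_id))
  k1 <- intact[vapply(loci[intact], function(l) locus_k(l) == 1L, logical(1))]
  src <- loci[[if (length(k1) > 0) k1[1] else intact[1]]]
  g <- vat_geometry(config$unit_nt)
  new <- src
  new$id <- sprintf("L%d", next_id)
  new$parts$units <- src$parts$units[1]
  new$strand <- "-"
  new$is_retro <- TRUE
  new$te <- list()
  pr <- default_primers()
  rev_row <- pr[pr$class == "reverse_strand_exon1", ]
  new$parts$exon1 <- plant(new$parts$exon1, g$rev_f_exon1[1], rev_row$forward)
  new$parts$exon1 <- plant(new$parts$exon1, g$rev_r_exon1[1], revcomp(rev_row$reverse))
  new$prot <- protected_part_ranges(new)
  cds <- gene_cds(new)
  protected <- rep(FALSE, nchar(cds))
  protected[(g$rev_f_exon1[1] + 1L):g$rev_f_exon1[2]] <- TRUE
  protected[(g$rev_r_exon1[1] + 1L):g$rev_r_exon1[2]] <- TRUE
  fixed <- fix_stops(cds, protected)
  if (!identical(fixed, cds)) {
    # push the repaired exon 1 (all planted sites are in exon 1)
    new$parts$exon1 <- substr0(fixed, 0L, nchar(new$parts$exon1))
  }
  new <- add_event(new, "retro_copy_reverse", tm,
                   sprintf("source %s, k forced to 1", src$id))
  loci[[length(loci) + 1L]] <- new
  list(loci = loci, next_id = next_id + 1L)
}

#' Evolve a cluster of gene lineages from an ancestor
#'
#' Runs the event process (duplication, repeat gain/loss by unequal crossover,
#' TE insertion, stop gain, substitution, and at most one reverse-strand retro
#' copy) for `config$tree_height` time units. With all rates at zero the
#' ancestor is returned unchanged with an empty event log.
#'
#' @param ancestor A `vat_locus` from [make_ancestor()].
#' @param config A [sim_config()].
#' @param seed Optional seed; by default the ambient RNG stream is used (as in
#'   [simulate_panel()], which seeds once per panel).
#' @return A list with `loci` (list of `vat_locus`) and `events` (tibble, the
#'   union of all per-locus logs).
#' @export
evolve_cluster <- function(ancestor, config, seed = NULL) {
  validate_sim_config(config)
  stopifnot(inherits(ancestor, "vat_locus"))
  with_seed(seed, {
    loci <- list(ancestor)
    next_id <- 2L
    t_end <- config$tree_height
    t <- 0
    retro_time <- if (stats::runif(1) < config$retro_prob)
      stats::runif(1, 0, t_end) else Inf
    repeat {
      lens <- vapply(loci, mutable_len, numeric(1))
      per <- config$duplication_rate + config$crossover_rate +
        config$te_insertion_rate + config$stop_gain_rate + config$sub_rate * lens
      total <- sum(per)
      dt <- if (total > 0) stats::rexp(1, total) else Inf
      if (is.finite(retro_time) && t + dt > retro_time) {
        res <- apply_retro_copy(loci, config, retro_time, next_id)
        loci <- res$loci; next_id <- res$next_id
        t <- retro_time
        retro_time <- Inf
        next
      }
      t <- t + dt
      if (!is.finite(t) || t > t_end) break
      i <- sample.int(length(loci), 1, prob = per)
      kind <- sample(c("duplication", "crossover", "te_insertion", "stop_gain",
                       "substitution"), 1,
                     prob = c(config$duplication_rate, config$crossover_rate,
                              config$te_insertion_rate, config$stop_gain_rate,
                              config$sub_rate * lens[i]))
      if (kind == "duplication") {
        if (length(loci) < MAX_LOCI) {
          child <- loci[[i]]
          child$id <- sprintf("L%d", next_id)
          next_id <- next_id + 1L
          loci[[i]] <- add_event(loci[[i]], "duplication", t,
                                 sprintf("child %s", child$id))
          child <- add_event(child, "duplication", t,
                             sprintf("copied from %s", loci[[i]]$id))
          loci[[length(loci) + 1L]] <- child
        }
      } else if (kind == "crossover") {
        loci[[i]] <- apply_crossover(loci[[i]], t)
      } else if (kind == "te_insertion") {
        loci[[i]] <- apply_te_insertion(loci[[i]], config, t)
      } else if (kind == "stop_gain") {
        loci[[i]] <- apply_stop_gain(loci[[i]], t)
      } else {
        loci[[i]] <- apply_substitution(loci[[i]], config, t)
      }
    }
    list(loci = loci,
         events = dplyr::bind_rows(lapply(loci, events_log)))
  })
}
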