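# Detection and excision of the 65-aa (195-nt) tandem repeat unit.

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Fraction of matching positions between two equal-length strings.
str_identity <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  100 * mean(ca == cb)
}

# Majority-vote consensus over equal-length strings.
majority_consensus <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  paste(apply(m, 2, function(col) names(which.max(table(col)))), collapse = "")
}

#' Simulate a CDS carrying a tandem repeat array
#'
#' Builds `flank5 + k copies of one random unit + flank3`, all in frame, with
#' optional independent per-copy substitutions — the standard fixture for
#' exercising repeat detection.
#'
#' @param k Copy count.
#' @param mutation Per-base substitution probability applied independently to
#'   every copy (0 = identical copies).
#' @param unit_nt Unit length (multiple of 3).
#' @param flank5_nt,flank3_nt Flank lengths (multiples of 3).
#' @param seed Optional seed.
#' @return List with `cds`, `array_start`, `array_end` (0-based half-open),
#'   `unit`, `k`.
#' @export
simulate_repeat_cds <- function(k, mutation = 0, unit_nt = 195L,
                                flank5_nt = 300L, flank3_nt = 300L,
                                seed = NULL) {
  stopifnot(unit_nt %% 3 == 0, flank5_nt %% 3 == 0, flank3_nt %% 3 == 0)
  with_seed(seed, {
    unit <- paste(rand_codons(unit_nt / 3L), collapse = "")
    copies <- vapply(seq_len(k), function(i) {
      ch <- seq_chars(unit)
      hit <- stats::runif(length(ch)) < mutation
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1))
    flank5 <- paste(c("ATG", rand_codons(flank5_nt / 3L - 1L)), collapse = "")
    flank3 <- paste(c(rand_codons(flank3_nt / 3L - 1L), "TAA"), collapse = "")
    list(cds = paste0(flank5, paste(copies, collapse = ""), flank3),
         array_start = flank5_nt, array_end = flank5_nt + k * unit_nt,
         unit = unit, k = as.integer(k))
  })
}

#' Detect and count tandem repeat units in a CDS
#'
#' Unsupervised detection of a near-identical tandem array of ~`unit_aa`
#' codons: (1) a period scan over lags `unit_aa*3 +/- 9` locates the
#' self-similar region (best windowed self-match fraction); (2) the array
#' anchor is refined to the codon-aligned offset maximising the identity
#' between adjacent unit-sized blocks; (3) the array is grown copy by copy in
#' both directions, accepting a copy while its identity to the running
#' consensus stays at or above `min_copy_identity`. Copy boundaries are
#' constrained to codon boundaries, so excising copies keeps the CDS in
#' frame. A single isolated copy has no tandem partner and is undetectable in
#' this mode; supply `reference_unit` (e.g. a consensus from multi-copy
#' homologs) to annotate k = 1 arrays.
#'
#' @param cds CDS string (in frame).
#' @param unit_aa Repeat-unit length in amino acids (default 65).
#' @param min_copy_identity Percent identity to the running consensus below
#'   which the array terminates (default 70).
#' @param min_selfmatch Minimum windowed self-match fraction for the period
#'   scan to call an array at all (below it, k = 0).
#' @param reference_unit Optional known unit sequence enabling single-copy
#'   detection.
#' @param cds_id Identifier stored in the annotation.
#' @return A `vat_repeats` object: list with `cds_id`, `k`, `array_start`,
#'   `array_end` (0-based half-open nt), `copies` (tibble: start, end, seq,
#'   identity), `consensus`, `unit_nt`. `k = 0` with an empty copy table when
#'   no array is found.
#' @export
#' @examples
#' sim <- simulate_repeat_cds(4, seed = 1)
#' find_repeats(sim$cds)$k
find_repeats <- function(cds, unit_aa = 65L, min_copy_identity = 70,
                         min_selfmatch = 0.6, reference_unit = NULL,
                         cds_id = "cds") {
  unit_nt <- as.integer(unit_aa) * 3L
  n <- nchar(cds)
  if (n < unit_nt) stop("CDS shorter than one repeat unit")
  if (n %% 3 != 0) stop("CDS length must be divisible by 3 (in-frame CDS required)")
  empty <- structure(list(cds_id = cds_id, k = 0L, array_start = NA_integer_,
                          array_end = NA_integer_,
                          copies = tibble::tibble(start = integer(),
                                                  end = integer(),
                                                  seq = character(),
                                                  identity = numeric()),
                          consensus = NA_character_, unit_nt = unit_nt),
                     class = "vat_repeats")
  x <- seq_chars(cds)

  if (!is.null(reference_unit)) {
    return(find_repeats_ref(cds, x, reference_unit, min_copy_identity, cds_id,
                            empty))
  }

  # (1) period scan
  lags <- seq.int(unit_nt - 9L, unit_nt + 9L)
  lags <- lags[lags < n]
  best <- list(score = -Inf, lag = NA, at = NA)
  for (L in lags) {
    v <- x[seq_len(n - L)] == x[seq_len(n - L) + L]
    if (length(v) < unit_nt) next
    cs <- cumsum(v)
    w <- unit_nt
    sums <- cs[w:length(v)] - c(0, cs[seq_len(length(v) - w)])
    i <- which.max(sums)
    if (sums[i] / w > best$score) best <- list(score = sums[i] / w, lag = L, at = i)
  }
  if (!is.finite(best$score) || best$score < min_selfmatch) return(empty)
  period <- as.integer(round(best$lag / 3) * 3)

  # (2) localize the array start: the best unit-sized window sits somewhere
  # inside the array, so walk a small rolling self-match window back to the
  # run boundary (self-similarity at the repeat lag collapses to background
  # immediately upstream of the first copy)
  v <- x[seq_len(n - period)] == x[seq_len(n - period) + period]
  w2 <- 30L
  cs <- cumsum(v)
  m2 <- (cs[w2:length(v)] - c(0, cs[seq_len(length(v) - w2)])) / w2
  ok <- m2 >= 0.6
  at <- min(best$at, length(ok))
  if (!ok[at]) {
    near <- which(ok)
    if (length(near) == 0) return(empty)
    at <- near[which.min(abs(near - at))]
  }
  run_start <- at
  while (run_start > 1 && ok[run_start - 1]) run_start <- run_start - 1
  approx0 <- run_start - 1L  # 0-based approximate array start

  # (3) anchor refinement: codon-aligned start maximising the identity of the
  # first block to the consensus of the following blocks. Candidates upstream
  # of the true start include flank bases (identity drops); candidates inside
  # the array tie at the maximum, and the leftmost of the tie is the start.
  # A few flank nucleotides can match the unit tail by chance, so the phase
  # of a single noisy CDS carries codon-scale ambiguity; annotate_repeat_set()
  # pins the phase exactly across a set of homologs.
  cand <- unique(pmax(0L, pmin(n - 2L * period,
                               (round((approx0 + seq(-24L, 24L, 3L)) / 3) * 3L))))
  cand <- cand[cand %% 3 == 0 & cand >= 0]
  score <- vapply(cand, function(a) {
    nxt <- c(a + period, a + 2L * period)
    nxt <- nxt[nxt + period <= n]
    blocks <- vapply(nxt, function(b) substr0(cds, b, b + period), character(1))
    ref <- if (length(blocks) == 1) blocks else majority_consensus(blocks)
    str_identity(substr0(cds, a, a + period), ref)
  }, numeric(1))
  a0 <- cand[which.max(score)]

  # (4) grow copies left and right against a running consensus
  starts <- a0
  consensus_of <- function(ss) if (length(ss) == 1) ss else majority_consensus(ss)
  copies <- substr0(cds, a0, a0 + period)
  # right
  repeat {
    nxt <- max(starts) + period
    if (nxt + period > n) break
    cand_seq <- substr0(cds, nxt, nxt + period)
    if (str_identity(cand_seq, consensus_of(copies)) < min_copy_identity) break
    starts <- c(starts, nxt); copies <- c(copies, cand_seq)
  }
  # left
  repeat {
    prv <- min(starts) - period
    if (prv < 0) break
    cand_seq <- substr0(cds, prv, prv + period)
    if (str_identity(cand_seq, consensus_of(copies)) < min_copy_identity) break
    starts <- c(prv, starts); copies <- c(cand_seq, copies)
  }
  if (length(starts) < 2) return(empty)  # no tandem partner: not an array
  starts <- as.integer(sort(starts))
  period <- as.integer(period)
  copies <- vapply(starts, function(s) substr0(cds, s, s + period), character(1))
  cons <- consensus_of(copies)
  structure(list(
    cds_id = cds_id, k = length(starts),
    array_start = starts[1], array_end = starts[length(starts)] + period,
    copies = tibble::tibble(start = starts, end = starts + period,
                            seq = copies,
                            identity = vapply(copies, str_identity, numeric(1),
                                              b = cons, USE.NAMES = FALSE)),
    consensus = cons, unit_nt = period), class = "vat_repeats")
}

# Reference-guided detection (enables k = 1).
find_repeats_ref <- function(cds, x, unit, min_copy_identity, cds_id, empty) {
  period <- nchar(unit)
  n <- nchar(cds)
  starts0 <- seq(0L, n - period, 3L)
  idents <- vapply(starts0, function(a)
    str_identity(substr0(cds, a, a + period), unit), numeric(1))
  hits <- starts0[idents >= min_copy_identity]
  if (length(hits) == 0) return(empty)
  period <- as.integer(period)
  # best anchor, then tandem extension on the exact period grid
  a0 <- hits[which.max(idents[match(hits, starts0)])]
  starts <- a0
  repeat {
    nxt <- max(starts) + period
    if (nxt + period > n ||
        str_identity(substr0(cds, nxt, nxt + period), unit) < min_copy_identity) break
    starts <- c(starts, nxt)
  }
  repeat {
    prv <- min(starts) - period
    if (prv < 0 ||
        str_identity(substr0(cds, prv, prv + period), unit) < min_copy_identity) break
    starts <- c(prv, starts)
  }
  starts <- as.integer(starts)
  copies <- vapply(starts, function(s) substr0(cds, s, s + period), character(1))
  cons <- if (length(copies) == 1) copies else majority_consensus(copies)
  structure(list(
    cds_id = cds_id, k = length(starts),
    array_start = starts[1], array_end = starts[length(starts)] + period,
    copies = tibble::tibble(start = starts, end = starts + period, seq = copies,
                            identity = vapply(copies, str_identity, numeric(1),
                                              b = cons, USE.NAMES = FALSE)),
    consensus = cons, unit_nt = period), class = "vat_repeats")
}

#' @export
print.vat_repeats <- function(x, ...) {
  cat(sprintf("<vat_repeats %s> k = %d%s\n", x$cds_id, x$k,
              if (x$k > 0) sprintf(", array [%d, %d), unit %d nt",
                                   x$array_start, x$array_end, x$unit_nt) else ""))
  invisible(x)
}

#' @method tidy vat_repeats
#' @export
tidy.vat_repeats <- function(x, ...) x$copies

#' @method glance vat_repeats
#' @export
glance.vat_repeats <- function(x, ...) {
  tibble::tibble(cds_id = x$cds_id, k = x$k, array_start = x$array_start,
                 array_end = x$array_end, unit_nt = x$unit_nt,
                 mean_identity = if (x$k > 0) mean(x$copies$identity) else NA_real_)
}

#' Build the virtual CDS (all repeat copies excised)
#'
#' Removes every annotated repeat copy and concatenates the remainder,
#' recording a strictly increasing map from virtual to original coordinates.
#' `nchar(original) == nchar(virtual) + sum(copy lengths)` always holds; a
#' k = 0 annotation returns the CDS unchanged.
#'
#' @param cds The original CDS string.
#' @param annotation A `vat_repeats` from [find_repeats()] on the same CDS.
#' @return A `vat_virtual_cds`: list with `cds_id`, `sequence`, `map`
#'   (integer vector, 1-based original position of each virtual position).
#' @export
build_virtual_cds <- function(cds, annotation) {
  stopifnot(inherits(annotation, "vat_repeats"))
  n <- nchar(cds)
  if (annotation$k > 0 && annotation$array_end > n)
    stop("annotation does not fit the CDS (bounds exceed sequence length)")
  if (annotation$k > 0 &&
      !identical(substr0(cds, annotation$copies$start[1],
                         annotation$copies$end[1]),
                 annotation$copies$seq[1]))
    stop("annotation does not match the CDS (copy sequence mismatch)")
  keep <- rep(TRUE, n)
  for (i in seq_len(annotation$k)) {
    keep[(annotation$copies$start[i] + 1L):annotation$copies$end[i]] <- FALSE
  }
  ch <- seq_chars(cds)
  structure(list(cds_id = annotation$cds_id,
                 sequence = paste(ch[keep], collapse = ""),
                 map = which(keep)),
            class = "vat_virtual_cds")
}

#' @export
print.vat_virtual_cds <- function(x, ...) {
  cat(sprintf("<vat_virtual_cds %s> %d nt\n", x$cds_id, nchar(x$sequence)))
  invisible(x)
}

#' Partition a CDS into pre-LRR2 / LRR2 / post-LRR2 blocks
#'
#' The LRR2 block is the annotated repeat array; the other two blocks are
#' everything before and after it. The three blocks are contiguous, ordered
#' and cover the CDS exactly.
#'
#' @param cds CDS string.
#' @param annotation A `vat_repeats` with `k >= 1`.
#' @return Tibble with `block` (preLRR2/LRR2/postLRR2), `start`, `end`
#'   (0-based half-open).
#' @export
partition_blocks <- function(cds, annotation) {
  stopifnot(inherits(annotation, "vat_repeats"))
  if (annotation$k < 1)
    stop("no repeat array (k = 0): use whole-CDS mode instead of block partitioning")
  n <- nchar(cds)
  tibble::tibble(block = c("preLRR2", "LRR2", "postLRR2"),
                 start = as.integer(c(0L, annotation$array_start, annotation$array_end)),
                 end = as.integer(c(annotation$array_start, annotation$array_end, n)))
}

#' Consensus and per-position variability of a pooled repeat-unit set
#'
#' Pools the copies of one or more repeat annotations, majority-votes a
#' consensus per position (over copies of the modal length; other copies are
#' length-normalised by truncation/padding and logged), and reports the
#' per-position mismatch fraction.
#'
#' @param annotations A `vat_repeats` or list of them.
#' @return List with `consensus_nt`, `consensus_aa`, `profile` (tibble:
#'   position, variability), `n_copies`.
#' @export
repeat_consensus <- function(annotations) {
  if (inherits(annotations, "vat_repeats")) annotations <- list(annotations)
  copies <- unlist(lapply(annotations, function(a) a$copies$seq))
  if (length(copies) < 1) stop("no repeat copies in the annotation set")
  lens <- nchar(copies)
  modal <- as.integer(names(which.max(table(lens))))
  if (any(lens != modal)) {
    message(sprintf("%d copies of non-modal length normalised to %d nt",
                    sum(lens != modal), modal))
    copies <- vapply(copies, function(s) {
      if (nchar(s) >= modal) substr(s, 1, modal)
      else paste0(s, strrep("N", modal - nchar(s)))
    }, character(1), USE.NAMES = FALSE)
  }
  m <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  cons <- apply(m, 2, function(col) {
    col <- col[col != "N"]
    names(which.max(table(col)))
  })
  vari <- vapply(seq_len(modal), function(j) {
    col <- m[, j]; col <- col[col != "N"]
    mean(col != cons[j])
  }, numeric(1))
  cons_nt <- paste(cons, collapse = "")
  list(consensus_nt = cons_nt,
       consensus_aa = if (modal %% 3 == 0) translate_cds(cons_nt) else NA_character_,
       profile = tibble::tibble(position = seq_len(modal), variability = vari),
       n_copies = length(copies))
}

#' Annotate a set of CDSs with a shared repeat-unit consensus
#'
#' Two-pass annotation of homologous CDSs. The first, unsupervised pass runs
#' [find_repeats()] on every CDS; because the anchor of a single CDS carries
#' only a few nucleotides of phase information, occasional annotations can be
#' rotated by a codon or two. The second pass pools all first-pass copies,
#' majority-votes a unit consensus (the dominant phase wins), and re-anchors
#' every CDS with the consensus as `reference_unit`, which pins the phase
#' exactly and also recovers single-copy (k = 1) arrays.
#'
#' @param cds_set Named character vector of CDSs.
#' @param unit_aa Unit length in amino acids.
#' @param min_copy_identity Percent identity threshold, as in [find_repeats()].
#' @return Named list of `vat_repeats` annotations.
#' @export
annotate_repeat_set <- function(cds_set, unit_aa = 65L, min_copy_identity = 70) {
  stopifnot(is.character(cds_set), length(cds_set) >= 1)
  if (is.null(names(cds_set))) names(cds_set) <- paste0("cds", seq_along(cds_set))
  pass1 <- lapply(names(cds_set), function(id)
    find_repeats(cds_set[[id]], unit_aa = unit_aa,
                 min_copy_identity = min_copy_identity, cds_id = id))
  copies <- unlist(lapply(pass1, function(a) a$copies$seq))
  if (length(copies) < 2) return(stats::setNames(pass1, names(cds_set)))
  lens <- nchar(copies)
  modal <- as.integer(names(which.max(table(lens))))
  consensus <- majority_consensus(copies[lens == modal])
  out <- lapply(names(cds_set), function(id)
    find_repeats(cds_set[[id]], unit_aa = unit_aa,
                 min_copy_identity = min_copy_identity,
                 reference_unit = consensus, cds_id = id))
  stats::setNames(out, names(cds_set))
}
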