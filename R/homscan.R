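# Homology scanning: exact k-mer seeding, local alignment extension
# (Biostrings), gene-model assembly with splice-signal refinement, and
# intact/pseudogene classification.

#' Scan a genomic region for homologous segments of exon queries
#'
#' Seed-and-extend homology search on both strands: exact `seed_k`-mer matches
#' are clustered into candidate windows, each window is refined by local
#' pairwise alignment (match +1, mismatch -1, gap open -4, gap extend -1), and
#' hits below the identity or query-coverage thresholds are discarded.
#' Identity is computed over aligned columns (end gaps excluded by the local
#' alignment); coverage is relative to the query length. Alignment ends are
#' extended to the full query extent when at most `extend_slop` query nt were
#' left unaligned, so terminal mismatches do not erode hit boundaries.
#'
#' @param region Genomic region (single string).
#' @param queries Named character vector of query sequences (e.g. the exons of
#'   a reference gene model, in gene order).
#' @param min_identity Minimum percent identity (default 40).
#' @param min_coverage Minimum percent query coverage (default 30).
#' @param seed_k Seed k-mer length (>= 8, default 12).
#' @param extend_slop Maximum unaligned query nt re-attached at each end.
#' @param max_mismatch_cluster_gap Maximum region gap joining seeds into one
#'   candidate window.
#' @return Tibble of hits: `query`, `start`, `end` (0-based half-open),
#'   `strand`, `identity`, `coverage`, `score`, sorted by position.
#' @export
scan_region <- function(region, queries, min_identity = 40, min_coverage = 30,
                        seed_k = 12L, extend_slop = 30L,
                        max_mismatch_cluster_gap = 250L) {
  if (length(region) != 1 || !nzchar(region)) stop("region must be a single non-empty sequence")
  if (length(queries) == 0 || any(!nzchar(queries))) stop("queries must be non-empty sequences")
  if (seed_k < 8) stop("seed_k must be >= 8")
  if (is.null(names(queries))) names(queries) <- paste0("query", seq_along(queries))
  empty <- tibble::tibble(query = character(), start = integer(), end = integer(),
                          strand = character(), identity = numeric(),
                          coverage = numeric(), score = numeric())
  n <- nchar(region)
  if (grepl("^N+$", region)) {
    warning("region is all N; no hits")
    return(empty)
  }
  kmers <- substring(region, seq_len(n - seed_k + 1L),
                     seq_len(n - seed_k + 1L) + seed_k - 1L)
  idx <- split(seq_along(kmers) - 1L, kmers)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  rows <- list()
  for (qname in names(queries)) {
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") queries[[qname]] else revcomp(queries[[qname]])
      m <- nchar(qs)
      if (m < seed_k) next
      qk <- unique(substring(qs, seq_len(m - seed_k + 1L),
                             seq_len(m - seed_k + 1L) + seed_k - 1L))
      pos <- sort(unlist(idx[qk], use.names = FALSE))
      if (length(pos) < 2) next
      grp <- cumsum(c(1L, diff(pos) > max_mismatch_cluster_gap))
      for (g in split(pos, grp)) {
        if (length(g) < 2) next
        w0 <- max(0L, min(g) - m)
        w1 <- min(n, max(g) + seed_k + m)
        aln <- Biostrings::pairwiseAlignment(
          qs, substr0(region, w0, w1), type = "local",
          substitutionMatrix = submat, gapOpening = 3, gapExtension = 1)
        pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
        sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
        identity <- 100 * mean(pa == sa)
        ps <- BiocGenerics::start(Biostrings::pattern(aln))
        pe <- BiocGenerics::end(Biostrings::pattern(aln))
        coverage <- 100 * (pe - ps + 1L) / m
        s0 <- w0 + BiocGenerics::start(Biostrings::subject(aln)) - 1L
        e0 <- w0 + BiocGenerics::end(Biostrings::subject(aln))
        if (ps - 1L <= extend_slop) s0 <- max(0L, s0 - (ps - 1L))
        if (m - pe <= extend_slop) e0 <- min(n, e0 + (m - pe))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          query = qname, start = as.integer(s0), end = as.integer(e0),
          strand = strand, identity = identity, coverage = coverage,
          score = BiocGenerics::score(aln))
      }
    }
  }
  if (length(rows) == 0) return(empty)
  hits <- dplyr::bind_rows(rows)
  hits <- dplyr::filter(hits, .data$identity >= min_identity,
                        .data$coverage >= min_coverage)
  # drop duplicated discoveries of the same segment (same query+strand,
  # overlapping a better-scoring hit)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score))
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j <= i || !keep[j]) next
      same <- hits$query[j] == hits$query[i] && hits$strand[j] == hits$strand[i]
      ovl <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (same && ovl > 0.5 * (hits$end[j] - hits$start[j])) keep[j] <- FALSE
    }
  }
  dplyr::arrange(hits[keep, ], .data$start)
}

# Snap a junction coordinate to the nearest splice signal within +/- window.
refine_junction <- function(region, pos, motif, motif_at = c("right", "left"),
                            window = 30L) {
  motif_at <- match.arg(motif_at)
  n <- nchar(region)
  cand <- (pos - window):(pos + window)
  ok <- vapply(cand, function(p) {
    if (motif_at == "right") p >= 0 && p + 2 <= n &&
      substr0(region, p, p + 2L) == motif
    else p - 2 >= 0 && p <= n && substr0(region, p - 2L, p) == motif
  }, logical(1))
  if (!any(ok)) return(pos)
  cand[ok][which.min(abs(cand[ok] - pos))]
}

#' Assemble homology hits into gene models
#'
#' Groups same-strand hits whose neighbouring gaps do not exceed `max_intron`
#' and whose exon order is collinear with the gene (a repeated or
#' out-of-order exon starts a new locus, so tandem gene copies are not
#' merged). Internal exon boundaries are snapped to the nearest GT/AG splice
#' signals within +/-30 nt. Groups overlapping a higher-scoring group on the
#' other strand are discarded with a message. Each model is classified with
#' [classify_locus()].
#'
#' @param hits Hit tibble from [scan_region()].
#' @param region The scanned region sequence.
#' @param max_intron Maximum intron length joining hits into one locus.
#' @param query_order Query names in 5'->3' gene order (defaults to the sorted
#'   unique query names, which is correct for names like exon1..exon5).
#' @param required_queries Queries whose absence makes a model `partial`
#'   (default: all of `query_order`).
#' @param insert_threshold Inter-exon gap (nt) above which a locus is
#'   classified `pseudo_insertion`.
#' @return Tibble of models: `locus_id`, `strand`, `start`, `end`, `n_exons`,
#'   `score`, `class`, `cds`, `exons` (list of tibbles).
#' @export
assemble_models <- function(hits, region, max_intron = 3000L,
                            query_order = NULL, required_queries = NULL,
                            insert_threshold = 2000L) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(locus_id = character(), strand = character(),
                          start = integer(), end = integer(),
                          n_exons = integer(), score = numeric(),
                          class = character(), cds = character(),
                          exons = list()))
  }
  query_order <- query_order %||% sort(unique(hits$query))
  required_queries <- required_queries %||% query_order
  hits <- dplyr::mutate(dplyr::arrange(hits, .data$start),
                        rank = match(.data$query, query_order))

  groups <- list()
  for (strand in c("+", "-")) {
    hs <- hits[hits$strand == strand, ]
    if (nrow(hs) == 0) next
    cur <- NULL
    flush <- function() if (!is.null(cur)) groups[[length(groups) + 1L]] <<- cur
    for (i in seq_len(nrow(hs))) {
      h <- hs[i, ]
      new_locus <- is.null(cur) ||
        h$start - max(cur$end) > max_intron ||
        (strand == "+" && h$rank <= max(cur$rank)) ||
        (strand == "-" && h$rank >= min(cur$rank))
      if (new_locus) { flush(); cur <- h } else cur <- dplyr::bind_rows(cur, h)
    }
    flush()
  }

  # resolve overlapping conflicting groups: keep the higher total score
  spans <- t(vapply(groups, function(g) c(min(g$start), max(g$end),
                                          sum(g$score)), numeric(3)))
  keep <- rep(TRUE, length(groups))
  if (length(groups) > 1) {
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i == j || !keep[i] || !keep[j]) next
        ovl <- min(spans[i, 2], spans[j, 2]) - max(spans[i, 1], spans[j, 1])
        if (ovl > 0 && spans[j, 3] < spans[i, 3]) {
          keep[j] <- FALSE
          message(sprintf("discarding overlapping lower-scoring group (score %.0f < %.0f)",
                          spans[j, 3], spans[i, 3]))
        }
      }
    }
  }
  groups <- groups[keep]
  if (length(groups) == 0) return(assemble_models(hits[0, ], region))
  groups <- groups[order(vapply(groups, function(g) min(g$start), numeric(1)))]

  models <- lapply(seq_along(groups), function(gi) {
    g <- dplyr::arrange(groups[[gi]], .data$start)
    strand <- g$strand[1]
    exons <- tibble::tibble(query = g$query, start = g$start, end = g$end)
    if (nrow(exons) > 1) {
      for (i in seq_len(nrow(exons) - 1L)) {
        if (strand == "+") {
          exons$end[i] <- refine_junction(region, exons$end[i], "GT", "right")
          exons$start[i + 1] <- refine_junction(region, exons$start[i + 1], "AG", "left")
        } else {
          # minus-strand gene: sense GT..AG intron reads AC..CT on the plus strand
          exons$end[i] <- refine_junction(region, exons$end[i], "CT", "right")
          exons$start[i + 1] <- refine_junction(region, exons$start[i + 1], "AC", "left")
        }
      }
    }
    model <- tibble::tibble(
      locus_id = sprintf("locus%02d", gi), strand = strand,
      start = min(exons$start), end = max(exons$end),
      n_exons = nrow(exons), score = sum(g$score),
      class = NA_character_, cds = NA_character_, exons = list(exons))
    cls <- classify_locus(model, region, max_intron = max_intron,
                          insert_threshold = insert_threshold,
                          required_queries = required_queries)
    model$class <- cls$class
    model$cds <- cls$cds
    model
  })
  dplyr::bind_rows(models)
}

#' Extract the spliced CDS of a gene model
#'
#' Concatenates the exon slices in region order; minus-strand models are
#' reverse-complemented so the result reads 5'->3' on the gene.
#'
#' @param model One model (one-row tibble or list with `exons` and `strand`).
#' @param region Region sequence.
#' @return CDS string (sum of exon lengths).
#' @export
extract_cds <- function(model, region) {
  exons <- if (is.data.frame(model$exons[[1]])) model$exons[[1]] else model$exons
  strand <- model$strand[1] %||% model$strand
  if (any(exons$start < 0) || any(exons$end > nchar(region)))
    stop("exon outside region bounds")
  exons <- exons[order(exons$start), ]
  s <- paste(vapply(seq_len(nrow(exons)), function(i)
    substr0(region, exons$start[i], exons$end[i]), character(1)), collapse = "")
  if (strand == "-") revcomp(s) else s
}

# Evaluate an ORF candidate. Stops in codons spanning an exon-exon junction
# (indices in `junction_codons`, 1-based) are ignored: with homology-derived
# exon boundaries a junction codon is chimeric and a stop there is an
# annotation artifact, not a premature stop.
orf_check <- function(cds, junction_codons = integer(0)) {
  if (nchar(cds) %% 3 != 0 || nchar(cds) < 6) {
    return(list(valid = FALSE, internal_stops = Inf, cds = cds))
  }
  codons <- codon_split(cds)
  internal <- setdiff(seq_len(length(codons) - 1L)[-1], junction_codons)
  n_int <- sum(is_stop(codons[internal]))
  list(valid = startsWith(cds, "ATG") && is_stop(codons[length(codons)]) &&
         n_int == 0,
       internal_stops = n_int, cds = cds,
       has_start = startsWith(cds, "ATG"),
       has_stop = is_stop(codons[length(codons)]))
}

# 1-based indices of codons spanning exon-exon junctions, given exon lengths
# in gene (5'->3') order.
junction_codon_idx <- function(exon_lens) {
  ci <- cumsum(exon_lens[-length(exon_lens)])
  idx <- ifelse(ci %% 3 == 0, NA_integer_, ci %/% 3L + 1L)
  idx[!is.na(idx)]
}

#' Classify a gene model as intact or pseudogene
#'
#' A model is `partial` when a required exon query is unmatched (or no start /
#' terminal stop codon can be found), `pseudo_insertion` when an inter-exon
#' gap exceeds `insert_threshold` (a TE-sized insertion rather than an
#' intron), `pseudo_stop` when the spliced reading frame contains an internal
#' stop, and `intact` otherwise. Because homology boundaries can drift by a
#' few nt inside the repeat exon, frame repair trims up to 2 nt from one
#' exon's end (choosing the variant minimising internal stops) before the ORF
#' test.
#'
#' @param model One model (one-row tibble from [assemble_models()], or a list
#'   with `exons`, `strand`).
#' @param region Region sequence.
#' @param max_intron Maximum plain intron length (informational).
#' @param insert_threshold Gap length above which an insertion is called.
#' @param required_queries Queries that must be present (NULL = skip check).
#' @return List with `class` and the frame-repaired `cds`.
#' @export
classify_locus <- function(model, region, max_intron = 3000L,
                           insert_threshold = 2000L, required_queries = NULL) {
  exons <- if (is.data.frame(model$exons[[1]])) model$exons[[1]] else model$exons
  exons <- exons[order(exons$start), ]
  strand <- model$strand[1] %||% model$strand

  if (!is.null(required_queries) && !all(required_queries %in% exons$query)) {
    return(list(class = "partial", cds = extract_cds(model, region)))
  }
  if (nrow(exons) > 1) {
    gaps <- exons$start[-1] - exons$end[-nrow(exons)]
    if (any(gaps > insert_threshold)) {
      return(list(class = "pseudo_insertion", cds = extract_cds(model, region)))
    }
  }
  # per-exon sequences in gene (5'->3') order
  exon_seqs <- vapply(seq_len(nrow(exons)), function(i)
    substr0(region, exons$start[i], exons$end[i]), character(1))
  if (strand == "-") exon_seqs <- rev(revcomp(exon_seqs))
  rep <- repair_frame(exon_seqs)
  chk <- orf_check(rep$cds, rep$junction_codons)
  cls <- if (chk$valid) "intact"
  else if (isTRUE(chk$has_start) && isTRUE(chk$has_stop) &&
           chk$internal_stops > 0) "pseudo_stop"
  else "partial"
  list(class = cls, cds = rep$cds)
}

# Greedy frame repair over homology-derived exon boundaries. Each exon edge
# may be off the true splice/codon grid by a few nt; off-frame content is
# stop-rich (~1 stop per 20 codons), so for each exon in gene order the
# start/end trims (0-2 nt each) minimising stop codons fully inside the
# exon's contribution are selected, with a total-length mod-3 constraint on
# the last exon. A genuine premature stop survives repair: the in-frame
# variant containing exactly it is still the stop-minimising choice.
repair_frame <- function(exon_seqs) {
  out <- ""
  lens <- integer(length(exon_seqs))
  n <- length(exon_seqs)
  for (j in seq_len(n)) {
    s_len <- nchar(exon_seqs[j])
    best <- NULL
    for (s in 0:2) {
      for (e in 0:2) {
        if (s + e >= s_len) next
        if (j == n && (nchar(out) + s_len - s - e) %% 3 != 0) next
        cand <- substr(exon_seqs[j], 1L + s, s_len - e)
        cat_len <- nchar(out)
        # codons fully within this exon's contribution
        first_cod <- ceiling(cat_len / 3) + 1L
        if (cat_len %% 3 != 0) first_cod <- first_cod + 1L  # skip chimeric codon
        total <- cat_len + nchar(cand)
        last_cod <- total %/% 3L
        if (last_cod < first_cod) { n_stop <- 0L }
        else {
          pref <- paste0(out, cand)
          cods <- codon_split(substr(pref, (first_cod - 1L) * 3L + 1L, last_cod * 3L))
          n_stop <- sum(is_stop(cods))
          # the terminal stop of the last exon is not a defect
          if (j == n && length(cods) > 0) n_stop <- n_stop - is_stop(cods[length(cods)])
        }
        cost <- n_stop * 10L + s + e
        if (is.null(best) || cost < best$cost) best <- list(s = s, e = e, cost = cost)
      }
    }
    cand <- substr(exon_seqs[j], 1L + best$s, s_len - best$e)
    out <- paste0(out, cand)
    lens[j] <- nchar(cand)
  }
  list(cds = out, junction_codons = junction_codon_idx(lens))
}
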