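# Per-site nonsynonymous-change probability: pairwise codon-change counting,
# Gaussian-kernel smoothing and permutation confidence bands.

check_codon_alignment <- function(alignment) {
  stopifnot(is.character(alignment), length(alignment) >= 2)
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  if (L %% 3 != 0) stop("alignment length must be divisible by 3")
  if (is.null(names(alignment))) names(alignment) <- paste0("seq", seq_along(alignment))
  alignment
}

#' Per-codon-site change counts and nonsynonymous probability
#'
#' For every codon site of the alignment, counts the unordered sequence pairs
#' whose codons differ (`n_diff`), and among them those encoding different
#' amino acids (`n_ns`). Pairs with a gap or a stop codon in either sequence
#' at the site are excluded from both counts. The per-site conditional
#' probability of an amino-acid change given a codon change is
#' `p = n_ns / n_diff` (undefined where `n_diff = 0`).
#'
#' @param alignment Named character vector of aligned, in-frame sequences
#'   (gap character `-`).
#' @return Tibble with `site` (1-based codon index), `pos_nt` (nucleotide
#'   midpoint of the codon), `n_diff`, `n_ns`, `p`.
#' @export
#' @examples
#' aln <- c(a = "AAAGAA", b = "AAAGAA", c = "GAAGAG", d = "AAGGAA")
#' site_change_counts(aln)
site_change_counts <- function(alignment) {
  alignment <- check_codon_alignment(alignment)
  L <- nchar(alignment[1])
  n_sites <- L %/% 3L
  cod_mat <- vapply(alignment, codon_split, character(n_sites))
  if (n_sites == 1) cod_mat <- matrix(cod_mat, nrow = 1)
  pairs2 <- function(x) x * (x - 1) / 2
  out <- lapply(seq_len(n_sites), function(i) {
    cods <- cod_mat[i, ]
    cods <- cods[!grepl("-", cods, fixed = TRUE) & !is_stop(cods) &
                   !grepl("[^ACGT]", cods)]
    n <- length(cods)
    if (n < 2) return(c(0, 0))
    tab <- table(cods)
    n_diff <- pairs2(n) - sum(pairs2(tab))
    aa <- codon_to_aa(names(tab))
    same_aa_diff_codon <- sum(vapply(unique(aa), function(a) {
      cnt <- tab[aa == a]
      pairs2(sum(cnt)) - sum(pairs2(cnt))
    }, numeric(1)))
    c(n_diff, n_diff - same_aa_diff_codon)
  })
  m <- do.call(rbind, out)
  tibble::tibble(site = seq_len(n_sites),
                 pos_nt = 3 * (seq_len(n_sites) - 1) + 2,
                 n_diff = m[, 1], n_ns = m[, 2],
                 p = ifelse(m[, 1] > 0, m[, 2] / m[, 1], NA_real_))
}

#' Kernel-smoothed nonsynonymous-probability curve
#'
#' Nadaraya-Watson smoothing of the per-site probabilities on the nucleotide
#' axis: `q(x) = sum_i K_h(x - pos_i) p_i / sum_i K_h(x - pos_i)` over sites
#' with defined `p`; sites with no codon change carry zero weight.
#'
#' @param counts Tibble from [site_change_counts()].
#' @param bandwidth_nt Kernel bandwidth h in nucleotides (20-25 suits the
#'   flanking blocks, 8 the repeat block).
#' @param kernel Kernel name; Gaussian only.
#' @param at Nucleotide positions at which to evaluate (defaults to the codon
#'   midpoints of all sites).
#' @return Tibble with `position`, `q`.
#' @export
smooth_curve <- function(counts, bandwidth_nt, kernel = c("gaussian"),
                         at = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(bandwidth_nt > 0)
  def <- !is.na(counts$p)
  if (!any(def)) stop("no site has a defined nonsynonymous probability")
  at <- at %||% counts$pos_nt
  W <- exp(-0.5 * (outer(at, counts$pos_nt[def], "-") / bandwidth_nt)^2)
  q <- as.numeric(W %*% counts$p[def]) / as.numeric(W %*% rep(1, sum(def)))
  tibble::tibble(position = at, q = q)
}

#' Permutation confidence band for the smoothed curve
#'
#' Permutes the per-site `(n_diff, n_ns)` tuples uniformly across the codon
#' sites of the alignment (destroying positional structure while keeping the
#' marginal distribution of change intensity), recomputes the smoothed curve
#' for each permutation, and takes pointwise `alpha/2` and `1 - alpha/2`
#' empirical quantiles. Positions where the observed curve exceeds the upper
#' (falls below the lower) quantile are flagged as peaks (valleys).
#'
#' @param alignment Codon alignment (named character), or a counts tibble
#'   from [site_change_counts()].
#' @param bandwidth_nt Kernel bandwidth in nt.
#' @param B Number of permutations (>= 100).
#' @param alpha Band level (pointwise).
#' @param seed Seed for the permutation stream.
#' @return A `vat_envelope`: list with `curve` (tibble: position, p, q, lower,
#'   upper, flag), `bandwidth`, `B`, `alpha`, `seed`, `exceedance` (fraction
#'   of positions flagged).
#' @export
permutation_envelope <- function(alignment, bandwidth_nt, B = 1000,
                                 alpha = 0.05, seed = NULL) {
  if (B < 100) stop("B must be >= 100")
  counts <- if (is.data.frame(alignment)) alignment
  else site_change_counts(alignment)
  n_sites <- nrow(counts)
  at <- counts$pos_nt
  W <- exp(-0.5 * (outer(at, counts$pos_nt, "-") / bandwidth_nt)^2)
  p0 <- ifelse(is.na(counts$p), 0, counts$p)
  d0 <- as.numeric(!is.na(counts$p))
  if (sum(d0) == 0) stop("no site has a defined nonsynonymous probability")
  q_obs <- as.numeric(W %*% p0) / as.numeric(W %*% d0)

  perm_q <- with_seed(seed, {
    P <- vapply(seq_len(B), function(b) sample.int(n_sites), integer(n_sites))
    num <- W %*% matrix(p0[P], nrow = n_sites)
    den <- W %*% matrix(d0[P], nrow = n_sites)
    num / den
  })
  lower <- apply(perm_q, 1, stats::quantile, probs = alpha / 2, na.rm = TRUE)
  upper <- apply(perm_q, 1, stats::quantile, probs = 1 - alpha / 2, na.rm = TRUE)
  flag <- dplyr::case_when(q_obs > upper ~ "peak",
                           q_obs < lower ~ "valley",
                           TRUE ~ "none")
  curve <- tibble::tibble(position = at, site = counts$site, p = counts$p,
                          q = q_obs, lower = lower, upper = upper, flag = flag)
  structure(list(curve = curve, bandwidth = bandwidth_nt, B = B, alpha = alpha,
                 seed = seed, exceedance = mean(flag != "none")),
            class = "vat_envelope")
}

#' @export
print.vat_envelope <- function(x, ...) {
  cat(sprintf("<vat_envelope> %d positions, h = %g nt, B = %d, alpha = %g; %d peaks, %d valleys\n",
              nrow(x$curve), x$bandwidth, x$B, x$alpha,
              sum(x$curve$flag == "peak"), sum(x$curve$flag == "valley")))
  invisible(x)
}

#' @method tidy vat_envelope
#' @export
tidy.vat_envelope <- function(x, ...) x$curve

#' @method glance vat_envelope
#' @export
glance.vat_envelope <- function(x, ...) {
  tibble::tibble(n_positions = nrow(x$curve),
                 n_defined = sum(!is.na(x$curve$p)),
                 bandwidth = x$bandwidth, B = x$B, alpha = x$alpha,
                 n_peaks = sum(x$curve$flag == "peak"),
                 n_valleys = sum(x$curve$flag == "valley"),
                 exceedance = x$exceedance)
}

#' Plot methods for vatkit result objects
#'
#' `autoplot.vat_envelope` draws the smoothed nonsynonymous-probability curve
#' with its permutation band and flags peaks/valleys;
#' `autoplot.vat_breakpoint` draws the two-tree fit-improvement profile along
#' the alignment; `autoplot.vat_panel_summary` draws the digit frequency
#' spectrum.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vat_envelope
#' @export
autoplot.vat_envelope <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$q), colour = "black") +
    ggplot2::geom_point(data = cv[cv$flag != "none", ],
                        ggplot2::aes(y = .data$q, colour = .data$flag), size = 1.4) +
    ggplot2::scale_colour_manual(values = c(peak = "firebrick", valley = "steelblue")) +
    ggplot2::labs(x = "position (nt)", y = "P(nonsynonymous | codon change)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Pool repeat copies into a unit-wide codon alignment
#'
#' Stacks every annotated repeat copy (one row per copy) into an alignment of
#' unit width. Copies of the modal length are used as-is; other copies are
#' aligned to the pooled consensus with an end-gap-free pairwise alignment and
#' projected onto the consensus columns (insertions relative to the consensus
#' are dropped).
#'
#' @param annotations A `vat_repeats` or list of them.
#' @return Named character vector (one aligned row per copy).
#' @export
repeat_unit_alignment <- function(annotations) {
  if (inherits(annotations, "vat_repeats")) annotations <- list(annotations)
  rows <- dplyr::bind_rows(lapply(annotations, function(a) {
    if (a$k == 0) return(NULL)
    tibble::tibble(id = paste(a$cds_id, seq_len(a$k), sep = "."),
                   seq = a$copies$seq)
  }))
  if (is.null(rows) || nrow(rows) < 2) stop("need at least 2 repeat copies")
  lens <- nchar(rows$seq)
  modal <- as.integer(names(which.max(table(lens))))
  cons <- majority_consensus(rows$seq[lens == modal])
  aligned <- vapply(seq_len(nrow(rows)), function(i) {
    s <- rows$seq[i]
    if (nchar(s) == modal) return(s)
    aln <- Biostrings::pairwiseAlignment(s, cons, type = "overlap")
    proj <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
    pat <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
    keep <- proj != "-"
    core <- paste(pat[keep], collapse = "")
    left <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
    paste0(strrep("-", left), core,
           strrep("-", modal - left - sum(keep)))
  }, character(1))
  stats::setNames(aligned, rows$id)
}
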