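# Simplified two-segment incongruence scan: a distance-based stand-in for
# genetic-algorithm breakpoint detection. For each candidate codon boundary b
# the alignment is split into [0, b) and [b, L); NJ trees are fitted to each
# segment's p-distances and the improvement of the two-tree fit over the
# single whole-alignment tree is scored by least-squares distance residuals.
# Significance comes from a codon-column permutation null.

# residual of a patristic matrix against observed distances (upper triangle)
ls_residual <- function(D, P) {
  ut <- upper.tri(D)
  sum((D[ut] - P[ut, drop = FALSE])^2)
}

# p-distance matrices for a set of columns, from precomputed per-pair
# cumulative difference/comparable counts
seg_dist <- function(cum_diff, cum_comp, lo, hi, n, labels = NULL) {
  # columns (lo, hi]: cumulative sums indexed 0..L via cbind(0, cums);
  # pair order matches utils::combn = lower triangle, column-major
  d <- (cum_diff[, hi + 1L] - cum_diff[, lo + 1L])
  cc <- (cum_comp[, hi + 1L] - cum_comp[, lo + 1L])
  pd <- ifelse(cc > 0, d / cc, 0)
  D <- matrix(0, n, n)
  D[lower.tri(D)] <- pd
  D <- D + t(D)
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  D
}

# Segment residuals are weighted by segment length: the sampling noise of a
# p-distance over a segment of length L has variance ~ 1/L, so length
# weighting keeps the noise contribution flat across candidate positions
# while a genuine topology change contributes proportionally to the length it
# spans.
scan_scores <- function(cum_diff, cum_comp, cands, L, n) {
  D_full <- seg_dist(cum_diff, cum_comp, 0L, L, n)
  P_full <- nj_patristic(D_full)
  vapply(cands, function(b) {
    D_l <- seg_dist(cum_diff, cum_comp, 0L, b, n)
    D_r <- seg_dist(cum_diff, cum_comp, b, L, n)
    P_l <- nj_patristic(D_l)
    P_r <- nj_patristic(D_r)
    b * (ls_residual(D_l, P_full) - ls_residual(D_l, P_l)) +
      (L - b) * (ls_residual(D_r, P_full) - ls_residual(D_r, P_r))
  }, numeric(1))
}

#' Scan an alignment for a phylogenetic-incongruence breakpoint
#'
#' Evaluates every candidate codon boundary (those with at least one variable
#' site on each side, optionally thinned with `stride`), scoring the
#' improvement of segment-specific NJ trees over the single whole-alignment
#' tree by least-squares distance-fit residuals. The p-value is the fraction
#' of codon-column-permuted alignments whose best score reaches the observed
#' best (permutation destroys positional structure, preserving composition).
#'
#' @param alignment Named character vector of aligned sequences (>= 4 taxa,
#'   length divisible by 3).
#' @param n_perm Number of column permutations for the null (0 = no p-value).
#' @param stride Evaluate every `stride`-th candidate boundary.
#' @param seed Seed for the permutation stream.
#' @return A `vat_breakpoint`: list with `best` (position nt, score, p_value),
#'   `candidates` (tibble: position, score), `tree_left`, `tree_right`
#'   (`ape::phylo` for the best split), `n_perm`, `seed`.
#' @export
breakpoint_scan <- function(alignment, n_perm = 200, stride = 1L, seed = NULL) {
  alignment <- check_codon_alignment(alignment)
  n <- length(alignment)
  if (n < 4) stop("breakpoint scan needs at least 4 taxa")
  labels <- names(alignment)
  L <- nchar(alignment[1])
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  acgt <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  # variable columns (>= 2 distinct non-gap bases)
  variable <- vapply(seq_len(L), function(j) {
    col <- mat[acgt[, j], j]
    length(unique(col)) >= 2
  }, logical(1))
  if (!any(variable)) stop("no variable sites in the alignment")
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  comp <- acgt[pairs[1, ], , drop = FALSE] & acgt[pairs[2, ], , drop = FALSE]
  diffm <- (mat[pairs[1, ], , drop = FALSE] != mat[pairs[2, ], , drop = FALSE]) & comp

  var_pos <- which(variable)
  bounds <- seq(3L, L - 3L, 3L)
  cands <- bounds[vapply(bounds, function(b)
    any(var_pos <= b) && any(var_pos > b), logical(1))]
  if (length(cands) < 2) stop("fewer than 2 candidate breakpoints with flanking variable sites")
  cands <- cands[seq(1, length(cands), by = stride)]

  cum <- function(M) cbind(0, t(apply(M, 1, cumsum)))
  scores <- scan_scores(cum(diffm), cum(comp), cands, L, n)
  best_i <- which.max(scores)
  best_b <- cands[best_i]
  obs <- scores[best_i]

  p_value <- NA_real_
  if (n_perm > 0) {
    n_cod <- L %/% 3L
    hits <- with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        blk <- sample.int(n_cod)
        cols <- as.vector(rbind(3 * blk - 2, 3 * blk - 1, 3 * blk))
        s <- scan_scores(cum(diffm[, cols, drop = FALSE]),
                         cum(comp[, cols, drop = FALSE]),
                         cands, L, n)
        max(s) >= obs
      }, logical(1))
    })
    p_value <- (1 + sum(hits)) / (n_perm + 1)
  }

  cum_d <- cum(diffm); cum_c <- cum(comp)
  tree_left <- nj_tree(seg_dist(cum_d, cum_c, 0L, best_b, n, labels))
  tree_right <- nj_tree(seg_dist(cum_d, cum_c, best_b, L, n, labels))
  structure(list(
    best = tibble::tibble(position = best_b, score = obs, p_value = p_value),
    candidates = tibble::tibble(position = cands, score = scores),
    tree_left = tree_left, tree_right = tree_right,
    n_perm = n_perm, seed = seed), class = "vat_breakpoint")
}

#' @export
print.vat_breakpoint <- function(x, ...) {
  cat(sprintf("<vat_breakpoint> best boundary at %d nt (score %.4g, p = %s; %d candidates, %d permutations)\n",
              x$best$position, x$best$score,
              ifelse(is.na(x$best$p_value), "NA", format(x$best$p_value)),
              nrow(x$candidates), x$n_perm))
  invisible(x)
}

#' @method tidy vat_breakpoint
#' @export
tidy.vat_breakpoint <- function(x, ...) x$candidates

#' @method glance vat_breakpoint
#' @export
glance.vat_breakpoint <- function(x, ...) {
  dplyr::mutate(x$best, n_candidates = nrow(x$candidates), n_perm = x$n_perm)
}

#' @rdname autoplot.vat_envelope
#' @method autoplot vat_breakpoint
#' @export
autoplot.vat_breakpoint <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$best$position,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "candidate boundary (nt)",
                  y = "two-tree fit improvement") +
    ggplot2::theme_minimal()
}
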