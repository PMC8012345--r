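# Distance phylogenetics: TN93 closed form, neighbor joining with documented
# clamping and tie-breaking, bootstrap support, newick I/O.

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Closed-form TN93 distance with empirical base frequencies estimated from
#' the pair, distinguishing the two transition classes (A<->G, C<->T) from
#' transversions. Sites with a gap or ambiguous base in either sequence are
#' excluded. Saturated pairs (a logarithm argument <= 0) are flagged with an
#' infinite distance and a warning.
#'
#' @param seq1,seq2 Aligned sequences of equal length.
#' @return Distance in substitutions per site.
#' @export
tn93_distance <- function(seq1, seq2) {
  stopifnot(nchar(seq1) == nchar(seq2))
  a <- seq_chars(toupper(seq1)); b <- seq_chars(toupper(seq2))
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable (gap-free) sites between the sequences")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  freq <- (table(factor(a, c("A", "C", "G", "T"))) +
             table(factor(b, c("A", "C", "G", "T")))) / (2 * n)
  pA <- freq[["A"]]; pC <- freq[["C"]]; pG <- freq[["G"]]; pT <- freq[["T"]]
  pR <- pA + pG; pY <- pC + pT
  diff <- a != b
  P1 <- mean(diff & ((a == "A" & b == "G") | (a == "G" & b == "A")))
  P2 <- mean(diff & ((a == "C" & b == "T") | (a == "T" & b == "C")))
  Q <- mean(diff) - P1 - P2
  if (!any(diff)) return(0)
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pC * pT / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pC * pT * pR / pY)
  w1 <- 1 - P1 / k1 - Q / (2 * pR)
  w2 <- 1 - P2 / k2 - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    warning("saturated pair: TN93 distance is infinite")
    return(Inf)
  }
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' Pairwise TN93 distance matrix
#' @param seqs Named character vector of aligned sequences.
#' @return Symmetric matrix with zero diagonal (taxa as dimnames).
#' @export
tn93_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- tn93_distance(seqs[[i]], seqs[[j]])
    }
  }
  D
}

# Numeric-only NJ returning just the leaf-to-leaf patristic matrix: the hot
# path of the breakpoint scan (no labels, no newick bookkeeping). Same
# agglomeration and clamping as nj_engine(); ties resolve to the first
# column-major minimum, deterministically.
nj_patristic <- function(D) {
  n <- nrow(D)
  P <- matrix(0, n, n)
  groups <- as.list(seq_len(n))             # leaf indices under each node
  dl <- rep(list(0), n)                     # leaf distances to the node
  Dm <- D
  record <- function(gi, di, gj, dj) {
    cross <- outer(di, dj, "+")
    P[gi, gj] <<- cross
    P[gj, gi] <<- t(cross)
  }
  while (nrow(Dm) > 3) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which.min(Q)                        # column-major: lowest-index pair
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    record(groups[[i]], dl[[i]] + li, groups[[j]], dl[[j]] + lj)
    du <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    groups <- c(groups[keep], list(c(groups[[i]], groups[[j]])))
    dl <- c(dl[keep], list(c(dl[[i]] + li, dl[[j]] + lj)))
  }
  l1 <- max((Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2, 0)
  l2 <- max((Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2, 0)
  l3 <- max((Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2, 0)
  record(groups[[1]], dl[[1]] + l1, groups[[2]], dl[[2]] + l2)
  record(groups[[1]], dl[[1]] + l1, groups[[3]], dl[[3]] + l3)
  record(groups[[2]], dl[[2]] + l2, groups[[3]], dl[[3]] + l3)
  P
}

# Core NJ agglomeration (Saitou-Nei, Studier-Keppler Q). Tie-breaking: the
# joined pair is the lowest-index (row-major) minimum of Q. Negative branch
# lengths are clamped to 0 with the deficit moved to the sister edge.
# Returns the newick string and the leaf-to-leaf patristic matrix.
nj_engine <- function(D) {
  labels <- rownames(D)
  n <- nrow(D)
  stopifnot(n >= 3, identical(labels, colnames(D)))
  P <- matrix(0, n, n, dimnames = list(labels, labels))
  repr <- labels
  dl <- lapply(seq_len(n), function(i) stats::setNames(0, labels[i]))
  Dm <- D
  add_cross <- function(di, dj) {
    # record patristic distances between two leaf groups
    cross <- outer(di, dj, "+")
    P[names(di), names(dj)] <<- cross
    P[names(dj), names(di)] <<- t(cross)
  }
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(repr) > 3) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    min_q <- min(Q)
    hit <- which(Q - min_q <= 1e-12 * max(1, abs(min_q)), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    add_cross(dl[[i]] + li, dl[[j]] + lj)
    new_repr <- sprintf("(%s:%s,%s:%s)", repr[i], fmt(li), repr[j], fmt(lj))
    new_dl <- c(dl[[i]] + li, dl[[j]] + lj)
    du <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    repr <- c(repr[keep], new_repr)
    dl <- c(dl[keep], list(new_dl))
  }
  # resolve the final trifurcation by the three-point equations
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- max((d12 + d13 - d23) / 2, 0)
  l2 <- max((d12 + d23 - d13) / 2, 0)
  l3 <- max((d13 + d23 - d12) / 2, 0)
  add_cross(dl[[1]] + l1, dl[[2]] + l2)
  add_cross(dl[[1]] + l1, dl[[3]] + l3)
  add_cross(dl[[2]] + l2, dl[[3]] + l3)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", repr[1], fmt(l1), repr[2], fmt(l2),
                    repr[3], fmt(l3))
  list(newick = newick, patristic = P)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration with deterministic lowest-index
#' tie-breaking; negative intermediate branch lengths are clamped to zero with
#' the deficit moved to the sister edge. The result is the unique unrooted
#' topology for any additive matrix.
#'
#' @param D Symmetric distance matrix with taxon dimnames (or a `dist`).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (any(!is.finite(D))) stop("distance matrix contains non-finite entries (saturated pairs?)")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  ape::read.tree(text = nj_engine(D)$newick)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Computes the TN93 + NJ point-estimate tree, then resamples alignment
#' columns with replacement (whole codons when the alignment length is a
#' multiple of 3) B times and scores each internal split of the point tree by
#' the percentage of replicate trees containing it (stored in `node.label`).
#' Saturated replicate distances are capped at twice the largest finite entry.
#'
#' @param alignment Named character vector of aligned sequences (>= 4).
#' @param B Number of bootstrap replicates (0 = point tree only).
#' @param seed Seed for resampling.
#' @param codon_block Resample codon triplets instead of single columns.
#' @return `ape::phylo` with node labels = support percentages.
#' @export
bootstrap_support <- function(alignment, B = 500, seed = NULL,
                              codon_block = nchar(alignment[1]) %% 3 == 0) {
  stopifnot(length(alignment) >= 4)
  if (is.null(names(alignment))) names(alignment) <- paste0("seq", seq_along(alignment))
  cap_matrix <- function(M) {
    if (any(!is.finite(M))) {
      mx <- max(M[is.finite(M)])
      M[!is.finite(M)] <- 2 * mx
    }
    M
  }
  point <- nj_tree(cap_matrix(suppressWarnings(tn93_matrix(alignment))))
  if (B <= 0) return(point)
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  L <- ncol(mat)
  trees <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- if (codon_block) {
        blk <- sample.int(L %/% 3L, replace = TRUE)
        as.vector(rbind(3 * blk - 2, 3 * blk - 1, 3 * blk))
      } else sample.int(L, replace = TRUE)
      res <- mat[, cols, drop = FALSE]
      seqs <- stats::setNames(apply(res, 1, paste, collapse = ""), names(alignment))
      nj_tree(cap_matrix(suppressWarnings(tn93_matrix(seqs))))
    })
  })
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  point$node.label <- round(100 * counts / B, 1)
  point
}

#' Write / read trees in newick format
#'
#' Thin wrappers around `ape::write.tree()` / `ape::read.tree()`; supports are
#' carried as internal node labels. Writing then reading is the identity on
#' topology, branch lengths and supports.
#'
#' @param tree An `ape::phylo`.
#' @param file Optional path; when NULL the newick string is returned.
#' @return `write_newick`: the newick string (invisibly when writing to file);
#'   `read_newick`: an `ape::phylo`.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @rdname write_newick
#' @param text Newick string (alternative to `file`).
#' @export
read_newick <- function(file = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("newick parse error: no tree could be read")
  tr
}

#' Simulate sequences along a tree (Jukes-Cantor)
#'
#' Evolves a random root sequence down the tree; on each edge every site is
#' substituted with the Jukes-Cantor probability implied by the edge length
#' (substitutions per site).
#'
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @param n_sites Number of sites.
#' @param seed Optional seed.
#' @param rate Multiplier applied to all branch lengths.
#' @return Named character vector of tip sequences (alignment, gap-free).
#' @export
simulate_alignment <- function(tree, n_sites, seed = NULL, rate = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    n_tip <- length(tree$tip.label)
    seqs <- vector("list", n_tip + tree$Nnode)
    root <- n_tip + 1L
    seqs[[root]] <- sample(bases, n_sites, replace = TRUE)
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      l <- tree$edge.length[e] * rate
      p_sub <- 0.75 * (1 - exp(-4 / 3 * l))
      s <- seqs[[par]]
      hit <- which(stats::runif(n_sites) < p_sub)
      if (length(hit) > 0) {
        s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1),
                         character(1))
      }
      seqs[[child]] <- s
    }
    stats::setNames(vapply(seqs[seq_len(n_tip)], paste, character(1),
                           collapse = ""), tree$tip.label)
  })
}
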