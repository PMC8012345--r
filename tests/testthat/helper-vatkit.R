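# Shared fixtures for the vatkit test suite. Everything is generated in code
# under fixed seeds; no stored data files.

# exon query set taken from an ancestor gene model
queries_from_ancestor <- function(anc) {
  with(anc$parts, c(
    exon1 = exon1,
    exon2 = paste0(exon2_pre, paste(units, collapse = ""), exon2_post),
    exon3 = exon3, exon4 = exon4, exon5 = exon5))
}

# codon alignment with iid columns: per column one ancestral codon, each
# sequence mutated at one random position with probability p_mut
iid_codon_alignment <- function(n_seq, n_codons, p_mut = 0.5, seed = 1) {
  vatkit:::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    cols <- replicate(n_codons, {
      anc <- vatkit:::rand_codons(1)
      vapply(seq_len(n_seq), function(s) {
        cod <- anc
        if (stats::runif(1) < p_mut) {
          p <- sample(3, 1)
          ch <- strsplit(cod, "")[[1]]
          ch[p] <- sample(setdiff(bases, ch[p]), 1)
          cod <- paste(ch, collapse = "")
        }
        cod
      }, character(1))
    })
    stats::setNames(apply(cols, 1, paste, collapse = ""),
                    paste0("s", seq_len(n_seq)))
  })
}

# concatenation of two alignments simulated on different random topologies;
# junction at 3 * n_codons_half nt
two_topology_alignment <- function(n_taxa, n_codons_half, seed,
                                   br = function(n) stats::runif(n, 0.05, 0.3)) {
  vatkit:::with_seed(seed, {
    tr1 <- ape::rtree(n_taxa, br = br)
    tr2 <- ape::rtree(n_taxa, br = br)
    tr2$tip.label <- sample(tr1$tip.label)
    a1 <- simulate_alignment(tr1, 3 * n_codons_half)
    a2 <- simulate_alignment(tr2, 3 * n_codons_half)[names(a1)]
    stats::setNames(paste0(a1, a2), names(a1))
  })
}

has_distinct_digits <- function(digits) {
  vapply(strsplit(digits, ""), function(s) !any(duplicated(s)), logical(1))
}

sorted_unique_digits <- function(digits) {
  vapply(strsplit(digits, ""), function(s)
    paste(sort(unique(s)), collapse = ""), character(1))
}
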