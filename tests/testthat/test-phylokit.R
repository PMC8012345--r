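# TN93 distances, neighbor joining, bootstrap, newick I/O, progressive
# alignment, breakpoint scan.

test_that("TN93 distance matches independent references", {
  set.seed(2)
  s1 <- vatkit:::rand_dna(900)
  expect_identical(tn93_distance(s1, s1), 0)
  # symmetry on random mutated pairs, and agreement with ape::dist.dna
  for (i in 1:5) {
    ch <- vatkit:::seq_chars(s1)
    hit <- which(stats::runif(900) < 0.08)
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    s2 <- paste(ch, collapse = "")
    expect_identical(tn93_distance(s1, s2), tn93_distance(s2, s1))
    bin <- ape::as.DNAbin(do.call(rbind, strsplit(c(s1, s2), "")))
    expect_equal(tn93_distance(s1, s2),
                 as.numeric(ape::dist.dna(bin, model = "TN93")),
                 tolerance = 1e-9)
  }
  # constructed equal-frequency, transition-only pair: K80-limit closed form
  # d = -1/2 log(1 - 2P) - 1/4 log(1)  with Q = 0  =>  TN93 reduces to
  # -2 * (1/8) * log(1 - 4P1) - ... ; evaluate the closed form independently
  base_block <- paste(rep(c("A", "C", "G", "T"), each = 150), collapse = "")
  s3 <- base_block
  # swap m/2 A->G and m/2 G->A: composition stays uniform, transitions only
  m <- 30
  ch <- vatkit:::seq_chars(s3)
  ch[1:(m / 2)] <- "G"                       # A -> G
  ch[301:(300 + m / 2)] <- "A"               # G -> A
  s4 <- paste(ch, collapse = "")
  P1 <- m / 600
  # uniform frequencies, transitions only: k1 = 2*pA*pG/pR = 1/4, Q = 0, so
  # TN93 collapses to -1/4 * log(1 - 4 * P1)
  expect_equal(tn93_distance(s3, s4), -0.25 * log(1 - 4 * P1), tolerance = 1e-9)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(c(s3, s4), "")))
  expect_equal(tn93_distance(s3, s4),
               as.numeric(ape::dist.dna(bin, model = "TN93")), tolerance = 1e-9)
  # saturation flags an infinite distance; no comparable sites is an error
  expect_warning(d_inf <- tn93_distance(strrep("A", 300), strrep("G", 300)),
                 "saturated")
  expect_identical(d_inf, Inf)
  expect_error(tn93_distance("---", "AAA"), "no comparable")
})

test_that("neighbor joining solves small cases exactly", {
  # 3 taxa: unique topology with three-point branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  expect_identical(sort(t3$tip.label), c("a", "b", "c"))
  P <- vatkit:::nj_engine(D3)$patristic
  expect_equal(P[c("a", "b", "c"), c("a", "b", "c")], D3, ignore_attr = TRUE)
  # the additive 4-taxon example: AB|CD with internal edge 1
  D4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  t4 <- nj_tree(D4)
  expect_equal(as.numeric(ape::dist.topo(t4, ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);"))), 0)
  P4 <- vatkit:::nj_engine(D4)$patristic
  expect_equal(P4[rownames(D4), rownames(D4)], D4, ignore_attr = TRUE)
  # taxon-order invariance
  perm <- c("C", "A", "D", "B")
  t4p <- nj_tree(D4[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t4, t4p)), 0)
  expect_error(nj_tree(D4[1:2, 1:2]), "at least 3")
})

test_that("nj_tree recovers random additive trees and agrees with ape::nj", {
  set.seed(12)
  for (i in 1:20) {
    nt <- sample(4:12, 1)
    tr <- ape::rtree(nt, br = function(n) stats::runif(n, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    mine <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), mine)), 0)
    expect_equal(as.numeric(ape::dist.topo(mine, ape::nj(D))), 0)
  }
})

test_that("bootstrap supports separate two diverged clades and are deterministic", {
  set.seed(33)
  anc1 <- vatkit:::rand_dna(600)
  anc2 <- {ch <- vatkit:::seq_chars(anc1)
    hit <- which(stats::runif(600) < 0.35)
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")}
  tweak <- function(s, p) {
    ch <- vatkit:::seq_chars(s)
    hit <- which(stats::runif(nchar(s)) < p)
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }
  aln <- c(a1 = tweak(anc1, 0.02), a2 = tweak(anc1, 0.02),
           b1 = tweak(anc2, 0.02), b2 = tweak(anc2, 0.02))
  tr <- bootstrap_support(aln, B = 100, seed = 5)
  expect_true(any(as.numeric(tr$node.label) >= 95, na.rm = TRUE))
  tr2 <- bootstrap_support(aln, B = 100, seed = 5)
  expect_identical(write_newick(tr), write_newick(tr2))
  # B = 0 returns the point tree without supports
  expect_null(bootstrap_support(aln, B = 0)$node.label)
})

test_that("newick serialisation round-trips", {
  t0 <- read_newick(text = "(A:1,B:2,(C:3,D:4):1);")
  expect_identical(write_newick(t0), "(A:1,B:2,(C:3,D:4):1);")
  # 3-leaf unrooted tree serialises with a trifurcating root
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  txt <- write_newick(nj_tree(D3))
  expect_identical(lengths(regmatches(txt, gregexpr("\\(", txt))), 1L)
  # random trees round-trip on topology, lengths and supports
  set.seed(8)
  for (i in 1:30) {
    tr <- ape::rtree(sample(4:15, 1))
    tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
    back <- read_newick(text = write_newick(tr))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(back))), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-6)
    expect_identical(back$node.label, tr$node.label)
  }
  expect_error(read_newick(text = "(A:1,B:2"), "parse error")
})

test_that("progressive alignment preserves residues and places clean gaps", {
  set.seed(41)
  s <- vatkit:::rand_dna(300)
  aln_id <- progressive_align(c(a = s, b = s, c = s))
  expect_false(any(grepl("-", aln_id, fixed = TRUE)))
  expect_identical(unname(aln_id), c(s, s, s))
  # a single 3-nt deletion yields one 3-column gap, as in an exhaustive
  # pairwise alignment
  s_del <- paste0(substr(s, 1, 150), substr(s, 154, 300))
  aln <- progressive_align(c(full = s, del = s_del))
  expect_identical(unique(nchar(aln)), 300L)
  expect_identical(gsub("-", "", aln[["del"]]), s_del)
  gaps <- gregexpr("-+", aln[["del"]])[[1]]
  expect_length(gaps, 1)
  expect_identical(attr(gaps, "match.length"), 3L)
  # exhaustive pairwise DP places the same-length gap at an equivalent spot
  ref <- Biostrings::pairwiseAlignment(s_del, s, type = "global")
  ref_gaps <- gregexpr("-+", as.character(Biostrings::alignedPattern(ref)))[[1]]
  expect_identical(attr(ref_gaps, "match.length"), 3L)
  expect_lte(abs(as.integer(gaps) - as.integer(ref_gaps)), 3L)
  expect_error(progressive_align(c(a = "", b = "ACGT")), "empty")
})

test_that("virtual CDSs from a simulated panel align compactly", {
  cfg <- sim_config(seed = 52, n_accessions = 6, te_insertion_rate = 0,
                    stop_gain_rate = 0)
  panel <- simulate_panel(cfg)
  cds <- unlist(lapply(panel$regions, function(r) {
    stats::setNames(r$truth$cds, paste(r$accession, r$truth$locus_id, sep = "_"))
  }))
  virt <- vapply(names(cds), function(id) {
    ann <- find_repeats(cds[[id]], cds_id = id)
    build_virtual_cds(cds[[id]], ann)$sequence
  }, character(1))
  aln <- progressive_align(virt[1:6])
  expect_lte(nchar(aln[1]), max(nchar(virt[1:6])) * 1.05)
})

test_that("breakpoint scan finds a simulated junction and stays quiet on nulls", {
  # two-topology concatenation: junction within +/- 30 nt
  hits <- 0L
  for (i in 1:6) {
    cc <- two_topology_alignment(6, 200, seed = 100 + i)
    bp <- breakpoint_scan(cc, n_perm = 0, stride = 3)
    if (abs(bp$best$position - 600) <= 30) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
  # single-topology null: p-value rarely small, deterministic under a seed
  ps <- numeric(6)
  for (i in 1:6) {
    tr <- vatkit:::with_seed(200 + i, ape::rtree(6, br = function(n)
      stats::runif(n, 0.05, 0.3)))
    aln <- simulate_alignment(tr, 1200, seed = 300 + i)
    bp <- breakpoint_scan(aln, n_perm = 49, stride = 6, seed = i)
    ps[i] <- bp$best$p_value
  }
  expect_lte(sum(ps < 0.05), 1)
  bp1 <- breakpoint_scan(two_topology_alignment(6, 100, seed = 9),
                         n_perm = 30, stride = 3, seed = 4)
  bp2 <- breakpoint_scan(two_topology_alignment(6, 100, seed = 9),
                         n_perm = 30, stride = 3, seed = 4)
  expect_identical(bp1$best, bp2$best)
  # error paths: identical sequences have no variable sites; < 4 taxa
  same <- stats::setNames(rep(strrep("ACG", 100), 4), paste0("s", 1:4))
  expect_error(breakpoint_scan(same), "no variable sites")
  expect_error(breakpoint_scan(two_topology_alignment(6, 50, seed = 1)[1:3]),
               "at least 4 taxa")
})

test_that("single- and multi-repeat homologs separate on the simulated truth history", {
  cfg <- sim_config(seed = 66, n_accessions = 10, retro_prob = 1,
                    te_insertion_rate = 0, stop_gain_rate = 0, sub_rate = 0.02)
  panel <- simulate_panel(cfg)
  # pool virtual CDSs of one accession that has both a reverse retro copy
  # (single repeat) and multi-repeat forward homologs
  idx <- which(panel$truth$has_reverse & panel$truth$n_loci >= 4)[1]
  expect_false(is.na(idx))  # seed chosen so such an accession exists
  r <- panel$regions[[idx]]
  labs <- sprintf("%s_%s_k%d", r$truth$strand, r$truth$locus_id, r$truth$k)
  virt <- vapply(seq_len(nrow(r$truth)), function(i) {
    ann <- find_repeats(r$truth$cds[i],
                        reference_unit = make_ancestor(cfg)$parts$units[1])
    build_virtual_cds(r$truth$cds[i], ann)$sequence
  }, character(1))
  names(virt) <- labs
  aln <- progressive_align(virt)
  tr <- nj_tree(tn93_matrix(aln))
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, labs)
})
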