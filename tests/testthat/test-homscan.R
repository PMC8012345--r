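# Homology scanning, model assembly and locus classification.

test_that("scan_region finds exact and mutated planted copies on both strands", {
  set.seed(101)
  region <- vatkit:::rand_dna(4000)
  query <- substr(region, 1001, 1600)
  # query equal to a region slice: full identity and coverage on +
  hits <- scan_region(region, c(q = query))
  h <- hits[hits$identity == 100 & hits$coverage == 100, ]
  expect_gte(nrow(h), 1)
  expect_identical(h$strand[1], "+")
  expect_identical(c(h$start[1], h$end[1]), c(1000L, 1600L))
  # reverse-complement slice: hit on the minus strand at the same interval
  hits_rc <- scan_region(region, c(q = revcomp(query)))
  hrc <- hits_rc[hits_rc$strand == "-", ]
  expect_gte(nrow(hrc), 1)
  expect_identical(c(hrc$start[1], hrc$end[1]), c(1000L, 1600L))
  # planted copy with 5% substitutions recovered with >= 90% overlap
  mut <- vatkit:::seq_chars(query)
  hit_pos <- vatkit:::with_seed(7, which(stats::runif(600) < 0.05))
  mut[hit_pos] <- vapply(mut[hit_pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  region2 <- paste0(substr(region, 1, 2500), paste(mut, collapse = ""),
                    substr(region, 2501, 4000))
  hits2 <- scan_region(region2, c(q = query))
  planted <- c(2500L, 3100L)
  ovl <- pmin(hits2$end, planted[2]) - pmax(hits2$start, planted[1])
  expect_gte(max(ovl) / 600, 0.9)
  # errors and degenerate input
  expect_error(scan_region("", c(q = query)), "non-empty")
  expect_error(scan_region(region, character(0)), "queries")
  expect_warning(expect_identical(
    nrow(scan_region(strrep("N", 1000), c(q = query))), 0L), "all N")
})

test_that("scan is strand-symmetric and monotone in thresholds", {
  cfg <- sim_config(seed = 14)
  anc <- make_ancestor(cfg)
  queries <- queries_from_ancestor(anc)[c("exon1", "exon3")]
  reg <- emit_region(anc, cfg, "S")$sequence
  hits <- scan_region(reg, queries)
  mirrored <- scan_region(revcomp(reg), queries)
  n <- nchar(reg)
  remapped <- dplyr::arrange(
    dplyr::mutate(mirrored,
                  start2 = n - .data$end, end2 = n - .data$start,
                  strand2 = ifelse(.data$strand == "+", "-", "+")),
    .data$start2)
  expect_identical(remapped$start2, hits$start)
  expect_identical(remapped$end2, hits$end)
  expect_identical(remapped$strand2, hits$strand)
  # raising thresholds never adds hits
  for (mi in c(40, 70, 95)) {
    for (mc in c(30, 60, 95)) {
      sub <- scan_region(reg, queries, min_identity = mi, min_coverage = mc)
      expect_lte(nrow(sub), nrow(hits))
      expect_true(all(paste(sub$query, sub$start) %in%
                        paste(hits$query, hits$start)))
    }
  }
})

test_that("assembly groups collinear same-strand hits and splits strands", {
  set.seed(55)
  e1 <- vatkit:::rand_dna(600); e3 <- vatkit:::rand_dna(600)
  # one gene: exon1 + 2 kb 'intron' + exon3 on the plus strand
  region <- paste0(vatkit:::rand_dna(500), e1, vatkit:::rand_dna(2000), e3,
                   vatkit:::rand_dna(500))
  hits <- scan_region(region, c(exon1 = e1, exon3 = e3))
  mods <- assemble_models(hits, region, query_order = c("exon1", "exon3"),
                          required_queries = NULL)
  expect_identical(nrow(mods), 1L)
  expect_identical(mods$n_exons[1], 2L)
  # the same two exons on opposite strands are never merged
  region2 <- paste0(vatkit:::rand_dna(500), e1, vatkit:::rand_dna(2000),
                    revcomp(e3), vatkit:::rand_dna(500))
  hits2 <- scan_region(region2, c(exon1 = e1, exon3 = e3))
  mods2 <- assemble_models(hits2, region2, query_order = c("exon1", "exon3"),
                           required_queries = NULL)
  expect_identical(nrow(mods2), 2L)
  expect_setequal(mods2$strand, c("+", "-"))
})

test_that("classification separates intact, stop, insertion and partial loci", {
  cfg <- sim_config(seed = 16)
  anc <- make_ancestor(cfg)
  queries <- queries_from_ancestor(anc)
  # intact -> intact
  reg <- emit_region(anc, cfg, "C1")
  mods <- assemble_models(scan_region(reg$sequence, queries), reg$sequence,
                          query_order = names(queries))
  expect_identical(mods$class, "intact")
  expect_identical(mods$cds, gene_cds(anc))
  # premature stop at codon 200 -> pseudo_stop
  stopped <- anc
  substr(stopped$parts$exon1, 598, 600) <- "TAA"  # codon 200
  reg2 <- emit_region(stopped, cfg, "C2")
  mods2 <- assemble_models(scan_region(reg2$sequence, queries), reg2$sequence,
                           query_order = names(queries))
  expect_identical(mods2$class, "pseudo_stop")
  # LINE-1-like 2540-nt insertion -> pseudo_insertion
  te <- anc
  te$te <- list(list(intron = "intron2", offset = 100L,
                     seq = vatkit:::with_seed(3, vatkit:::rand_dna(2540L)),
                     kind = "LINE1_like"))
  reg3 <- emit_region(te, cfg, "C3")
  mods3 <- assemble_models(scan_region(reg3$sequence, queries), reg3$sequence,
                           query_order = names(queries))
  expect_identical(mods3$class, "pseudo_insertion")
  # missing required exon -> partial
  part <- mods$exons[[1]]
  part <- part[part$query != "exon5", ]
  cls <- classify_locus(list(exons = part, strand = "+"), reg$sequence,
                        required_queries = names(queries))
  expect_identical(cls$class, "partial")
})

test_that("extract_cds slices and reverse-complements correctly", {
  set.seed(77)
  region <- vatkit:::rand_dna(1000)
  one <- list(exons = tibble::tibble(query = "e", start = 100L, end = 400L),
              strand = "+")
  expect_identical(extract_cds(one, region), vatkit:::substr0(region, 100, 400))
  minus <- list(exons = one$exons, strand = "-")
  expect_identical(extract_cds(minus, region),
                   revcomp(vatkit:::substr0(region, 100, 400)))
  expect_error(extract_cds(list(exons = tibble::tibble(query = "e", start = 900L,
                                                       end = 1200L),
                                strand = "+"), region), "outside")
})

test_that("locus count, strand and class are recovered on evolved regions", {
  cfg <- sim_config(seed = 4)
  anc <- make_ancestor(cfg)
  queries <- queries_from_ancestor(anc)
  set.seed(77)
  n_ok <- 0L; n_tot <- 0L
  for (i in 1:10) {
    res <- evolve_cluster(anc, cfg)
    reg <- emit_region(res$loci, cfg, paste0("R", i))
    mods <- assemble_models(scan_region(reg$sequence, queries), reg$sequence,
                            query_order = names(queries))
    tr <- dplyr::arrange(reg$truth, start)
    n_tot <- n_tot + nrow(tr)
    if (nrow(mods) == nrow(tr)) {
      m <- dplyr::arrange(mods, start)
      n_ok <- n_ok + sum(m$strand == tr$strand & m$class == tr$class)
      # splice-junction wobble under sequence divergence may shift a boundary
      # by a codon; the extracted CDS still matches the truth to >= 99%
      same_k <- which(tr$k == locus_k(anc) & tr$class == "intact")
      for (j in same_k) {
        pid <- Biostrings::pid(Biostrings::pairwiseAlignment(m$cds[j], tr$cds[j],
                                                             type = "global"))
        expect_gte(pid, 99)
      }
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("extracted CDSs equal the truth exactly on noise-free multi-exon loci", {
  cfg <- sim_config(seed = 23, sub_rate = 0, te_insertion_rate = 0,
                    stop_gain_rate = 0, duplication_rate = 2,
                    crossover_rate = 1, retro_prob = 1)
  anc <- make_ancestor(cfg)
  queries <- queries_from_ancestor(anc)
  set.seed(2)
  res <- evolve_cluster(anc, cfg)
  reg <- emit_region(res$loci, cfg, "NF")
  mods <- assemble_models(scan_region(reg$sequence, queries), reg$sequence,
                          query_order = names(queries))
  tr <- dplyr::arrange(reg$truth, start)
  expect_identical(nrow(mods), nrow(tr))
  m <- dplyr::arrange(mods, start)
  expect_identical(m$strand, tr$strand)
  # the exon-2 query carries the ancestor's repeat count, so full-CDS identity
  # is expected exactly where the locus kept that count
  same_k <- tr$k == locus_k(anc)
  expect_gte(sum(same_k), 1)
  expect_identical(m$cds[same_k], tr$cds[same_k])
})
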