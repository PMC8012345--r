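# Cluster-evolution simulator: ancestor construction, event process, region
# emission, truth files.

test_that("ancestral gene encodes the expected protein lengths and is deterministic", {
  anc4 <- make_ancestor(sim_config(seed = 3, ancestor_repeat_count = 4))
  cds4 <- gene_cds(anc4)
  expect_true(startsWith(cds4, "ATG"))
  expect_false(has_internal_stop(cds4))
  # 1467 aa at k = 4; each repeat copy contributes 65 aa
  expect_identical(nchar(translate_cds(cds4)) - 1L, 1467L)
  anc1 <- make_ancestor(sim_config(seed = 3, ancestor_repeat_count = 1))
  expect_identical(nchar(translate_cds(gene_cds(anc1))) - 1L, 1467L - 3L * 65L)
  # exon 2 holds exactly k tandem copies of one unit
  expect_length(anc4$parts$units, 4)
  expect_length(unique(anc4$parts$units), 1)
  expect_identical(nchar(anc4$parts$units[1]), 195L)
  # same seed, same sequence
  expect_identical(gene_cds(make_ancestor(sim_config(seed = 3))), cds4)
  expect_error(sim_config(ancestor_repeat_count = 9), "ancestor_repeat_count")
  expect_error(sim_config(unit_nt = 196), "unit_nt")
  expect_error(sim_config(sub_rate = -1), "sub_rate")
})

test_that("null process leaves the ancestor untouched across the panel", {
  cfg0 <- sim_config(seed = 5, n_accessions = 3, duplication_rate = 0,
                     crossover_rate = 0, te_insertion_rate = 0,
                     stop_gain_rate = 0, sub_rate = 0, retro_prob = 0)
  res <- evolve_cluster(make_ancestor(cfg0), cfg0, seed = 1)
  expect_length(res$loci, 1)
  expect_identical(nrow(res$events), 0L)
  expect_identical(gene_seq(res$loci[[1]]), gene_seq(make_ancestor(cfg0)))
  panel <- simulate_panel(cfg0)
  seqs <- vapply(panel$regions, function(r) r$sequence, character(1))
  expect_length(unique(seqs), 1)
  expect_true(all(panel$truth$digits == panel$truth$digits[1]))
})

test_that("evolution events have the documented structure", {
  cfg <- sim_config(seed = 8, duplication_rate = 2, crossover_rate = 2,
                    te_insertion_rate = 0.6, stop_gain_rate = 0.3,
                    retro_prob = 1)
  anc <- make_ancestor(cfg)
  res <- evolve_cluster(anc, cfg, seed = 42)
  expect_gte(length(res$loci), 2)
  ks <- vapply(res$loci, locus_k, integer(1))
  expect_true(all(ks >= 1 & ks <= 7))
  # at most one reverse-strand retro copy, with k forced to 1
  rev <- Filter(function(l) l$strand == "-", res$loci)
  expect_lte(length(rev), 1)
  if (length(rev) == 1) expect_identical(locus_k(rev[[1]]), 1L)
  # crossover events change k by one unit
  ev <- res$events
  expect_true(all(grepl("dk=[+-]1", ev$detail[grepl("crossover", ev$kind)])))
  # pseudogenes arise only via te_insertion or stop_gain
  for (l in res$loci) {
    log <- events_log(l)
    if (l$class == "pseudo_insertion") expect_true("te_insertion" %in% log$kind)
    if (l$class == "pseudo_stop") expect_true("stop_gain" %in% log$kind)
    if (l$class == "intact")
      expect_false(any(c("te_insertion", "stop_gain") %in% log$kind))
  }
  # TE insert lengths: 2345 (intron-1 class) or 2540 (LINE-1-like)
  te_lens <- unlist(lapply(res$loci, function(l)
    vapply(l$te, function(te) nchar(te$seq), numeric(1))))
  if (length(te_lens) > 0) expect_true(all(te_lens %in% c(2345, 2540)))
  # duplicated lineages share prefix history
  if (length(res$loci) >= 2) {
    expect_true(any(vapply(res$loci[-1], function(l)
      "duplication" %in% events_log(l)$kind, logical(1))))
  }
})

test_that("emitted regions are truth-consistent", {
  cfg <- sim_config(seed = 12, n_accessions = 6)
  panel <- simulate_panel(cfg)
  for (r in panel$regions) {
    tr <- r$truth
    expect_true(all(tr$start >= 0 & tr$end <= nchar(r$sequence)))
    for (i in seq_len(nrow(tr))) {
      arr <- vatkit:::substr0(r$sequence, tr$array_start[i], tr$array_end[i])
      if (tr$strand[i] == "-") arr <- revcomp(arr)
      expect_identical(nchar(arr), 195L * tr$k[i])
      # the array is literally k tandem copies: split into unit-sized blocks,
      # each nearly identical to the first (only point substitutions occurred)
      units <- substring(arr, seq(1, nchar(arr), 195), seq(195, nchar(arr), 195))
      for (u in units) {
        expect_gte(vatkit:::str_identity(u, units[1]), 90)
      }
      # exon slices splice into the recorded CDS
      cds <- extract_cds(list(exons = tr$exons[[i]], strand = tr$strand[i]),
                         r$sequence)
      expect_identical(cds, tr$cds[i])
    }
  }
  # determinism: same config, byte-identical panel
  panel2 <- simulate_panel(cfg)
  expect_identical(vapply(panel2$regions, function(r) r$sequence, character(1)),
                   vapply(panel$regions, function(r) r$sequence, character(1)))
  expect_identical(panel2$truth, panel$truth)
})

test_that("amplicon arithmetic holds on emitted regions", {
  cfg <- sim_config(seed = 2)
  # intact k = 1: 467 internal, 1502 exon1-exon2, 793 repeat-spanning
  anc1 <- make_ancestor(sim_config(seed = 2, ancestor_repeat_count = 1))
  b1 <- region_bands(emit_region(anc1, cfg, "X"))
  expect_identical(b1$length[b1$class == "exon2_internal"], 467L)
  expect_identical(b1$length[b1$class == "exon1_exon2"], 1502L)
  expect_identical(b1$length[b1$class == "repeat_spanning"],
                   as.integer(default_flank_constants()[["repeat_spanning"]] + 195))
  # insertion pseudogene at k = 1: exon1-exon2 product shifts 1502 -> 3847
  ins <- anc1
  ins$te <- list(list(intron = "intron1", offset = 100L,
                      seq = vatkit:::with_seed(1, vatkit:::rand_dna(2345L)),
                      kind = "intron1_insert", len = 2345L))
  ins$class <- "pseudo_insertion"
  bi <- region_bands(emit_region(ins, cfg, "Z"))
  expect_identical(bi$length[bi$class == "exon1_exon2"], 3847L)
  # closed form f + 195 k for every intact locus of an evolved panel
  panel <- simulate_panel(sim_config(seed = 31, n_accessions = 8))
  fl <- default_flank_constants()
  for (r in panel$regions) {
    bands <- region_bands(r)
    rs <- bands$length[bands$class == "repeat_spanning"]
    expect_setequal(rs, unique(fl[["repeat_spanning"]] + 195 * r$truth$k))
    if (any(r$truth$strand == "-")) {
      expect_true(933 %in% bands$length[bands$class == "reverse_strand_exon1"])
    }
  }
})

test_that("truth files round-trip through GFF3/TSV with 1-based GFF coordinates", {
  cfg <- sim_config(seed = 9, duplication_rate = 2)
  res <- evolve_cluster(make_ancestor(cfg), cfg, seed = 4)
  region <- emit_region(res$loci, cfg, "ACC1")
  dir <- withr::local_tempdir()
  paths <- write_truth(region, dir)
  expect_true(all(file.exists(paths)))
  # gene feature count equals locus count; GFF3 start = 0-based start + 1
  gff <- readLines(paths[["gff3"]])
  gene_lines <- grep("\tgene\t", gff, value = TRUE)
  expect_length(gene_lines, nrow(region$truth))
  starts_gff <- as.integer(vapply(strsplit(gene_lines, "\t"), `[`, character(1), 4))
  expect_identical(sort(starts_gff), sort(as.integer(region$truth$start + 1L)))
  back <- read_truth(dir, "ACC1")
  expect_identical(unname(back$sequence[1]), region$sequence)
  for (col in c("locus_id", "strand", "class", "k", "start", "end",
                "array_start", "array_end", "cds")) {
    expect_equal(back$truth[[col]], region$truth[[col]], ignore_attr = TRUE)
  }
  for (i in seq_len(nrow(region$truth))) {
    expect_equal(back$truth$exons[[i]]$start, region$truth$exons[[i]]$start,
                 ignore_attr = TRUE)
    expect_equal(back$truth$exons[[i]]$end, region$truth$exons[[i]]$end,
                 ignore_attr = TRUE)
  }
})
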