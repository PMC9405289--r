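# Junction screening criteria on simulated chimeric reads.

test_that("clean junction reads pass all four criteria with the right junction", {
  cfg <- sim_config(seed = 3, n_reads_junction = 5)
  annset <- sim_annotation(cfg)
  reads <- sim_chimeric_reads(cfg, annset)
  sc <- screen_candidates(reads, annset$ann)
  expect_true(all(sc$passed))
  expect_equal(unique(sc$exon5), cfg$donor_exon)
  expect_equal(unique(sc$exon3), cfg$junction_exon)
  expect_equal(unique(sc$gene3), "RET")
  # breakpoints are exon-boundary transcript coordinates
  expect_equal(unique(sc$bp5), cfg$donor_exon * cfg$exon_length)
  expect_equal(unique(sc$bp3), (cfg$junction_exon - 1) * cfg$exon_length)
})

test_that("boundary offsets pass criterion c3 exactly when within tolerance", {
  for (off in -5:5) {
    cfg <- sim_config(seed = 3, n_reads_junction = 2, boundary_offset = off)
    annset <- sim_annotation(cfg)
    sc0 <- screen_candidates(sim_chimeric_reads(cfg, annset), annset$ann,
                             tolerance_nt = 0)
    sc3 <- screen_candidates(sim_chimeric_reads(cfg, annset), annset$ann,
                             tolerance_nt = 3)
    expect_equal(all(sc0$c3_boundary_match), off == 0,
                 info = paste("offset", off, "tolerance 0"))
    expect_equal(all(sc3$c3_boundary_match), abs(off) <= 3,
                 info = paste("offset", off, "tolerance 3"))
  }
})

test_that("reads with both segments in the same gene fail criterion c1", {
  annset <- sim_annotation(sim_config(seed = 5))
  m3 <- annset$ann$transcripts[["TOYRTK"]]
  read <- list(sample_id = "S", read_id = "r1", sequence = strrep("A", 50),
               seg5_chrom = m3$chrom, seg5_start = m3$exon_starts[1],
               seg5_end = m3$exon_ends[1], seg5_strand = "+", seg5_nhits = 1L,
               seg3_chrom = m3$chrom, seg3_start = m3$exon_starts[2],
               seg3_end = m3$exon_ends[2], seg3_strand = "+", seg3_nhits = 1L)
  res <- screen_read(read, annset$ann)
  expect_false(res$passed)
  expect_false(res$flags[["c1_exon_junction"]])
})

test_that("multi-hit alignments fail c2 and antisense segments fail c4", {
  cfg <- sim_config(seed = 5, n_reads_junction = 1)
  annset <- sim_annotation(cfg)
  read <- sim_chimeric_reads(cfg, annset)[1, ]
  ambiguous <- read; ambiguous$seg3_nhits <- 3L
  res <- screen_read(ambiguous, annset$ann)
  expect_false(res$flags[["c2_unambiguous"]])
  flipped <- read; flipped$seg3_strand <- "-"
  res <- screen_read(flipped, annset$ann)
  expect_false(res$flags[["c4_same_orientation"]])
  # short moiety overhangs cannot be assigned
  short <- read; short$seg5_end <- short$seg5_start + 5L
  expect_false(screen_read(short, annset$ann)$passed)
})

test_that("screening and grouping are order-independent", {
  cfg <- sim_config(seed = 9, n_reads_junction = 6)
  annset <- sim_annotation(cfg)
  reads <- sim_chimeric_reads(cfg, annset)
  sc <- screen_candidates(reads, annset$ann)
  set.seed(42)
  perm <- sample(nrow(reads))
  sc_perm <- screen_candidates(reads[perm, ], annset$ann)
  expect_equal(sc_perm[order(sc_perm$read_id), ]$passed,
               sc[order(sc$read_id), ]$passed)
  expect_equal(length(group_candidates(sc)), length(group_candidates(sc_perm)))
})

test_that("distinct junctions of one gene pair group into separate candidates", {
  cfgA <- sim_config(seed = 13, n_reads_junction = 5, junction_exon = 12)
  annset <- sim_annotation(cfgA)
  cfgB <- sim_config(seed = 14, n_reads_junction = 4, junction_exon = 14)
  readsA <- sim_chimeric_reads(cfgA, annset)
  readsB <- sim_chimeric_reads(cfgB, annset)
  readsB$read_id <- paste0("b_", readsB$read_id)
  sc <- screen_candidates(rbind(readsA, readsB), annset$ann)
  cands <- group_candidates(sc)
  expect_length(cands, 2)
  expect_setequal(vapply(cands, function(x) nrow(x$reads), 0L), c(5L, 4L))
  expect_length(group_candidates(sc[0, ]), 0)
})

test_that("unique read counting collapses exact duplicate sequences only", {
  cfg <- sim_config(seed = 21, n_reads_junction = 10, duplicate_rate = 0.5)
  annset <- sim_annotation(cfg)
  sc <- screen_candidates(sim_chimeric_reads(cfg, annset), annset$ann)
  cand <- group_candidates(sc)[[1]]
  expect_lt(count_unique_reads(cand), 10)
  expect_equal(count_unique_reads(cand), length(unique(cand$reads$sequence)))
  # without duplicate injection all sequences are distinct
  cfg0 <- sim_config(seed = 21, n_reads_junction = 10)
  sc0 <- screen_candidates(sim_chimeric_reads(cfg0, annset), annset$ann)
  expect_equal(count_unique_reads(group_candidates(sc0)[[1]]), 10)
})

test_that("candidate tables round-trip through TSV including the compact segment form", {
  cfg <- sim_config(seed = 2, n_reads_junction = 3)
  reads <- sim_chimeric_reads(cfg)
  path <- tempfile(fileext = ".tsv")
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_candidates(path), reads)
  compact <- data.frame(
    sample_id = reads$sample_id, read_id = reads$read_id,
    sequence = reads$sequence,
    seg5 = sprintf("%s:%d-%d:%s", reads$seg5_chrom, reads$seg5_start,
                   reads$seg5_end, reads$seg5_strand),
    seg3 = sprintf("%s:%d-%d:%s", reads$seg3_chrom, reads$seg3_start,
                   reads$seg3_end, reads$seg3_strand))
  path2 <- tempfile(fileext = ".tsv")
  write.table(compact, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- read_candidates(path2)
  expect_equal(parsed$seg5_start, reads$seg5_start)
  expect_equal(parsed$seg3_end, reads$seg3_end)
})
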