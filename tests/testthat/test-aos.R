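# Pileup observation model, the two classification gates, and repair.

test_that("build_pileup: matching 10M read gives 10 concordant columns", {
  refstr <- "ACGTACGTACGTACGT"
  ref <- make_ref(c(chr1 = refstr))
  reads <- perfect_reads(refstr, 2L, 10L)
  p <- build_pileup(reads, ref)
  expect_equal(nrow(p), 10L)
  expect_equal(unique(p$category), "concordant")
  expect_equal(p$ref_pos, 2:11)
})

test_that("build_pileup: 4M2D4M places deletion gaps at columns 4,5 of span", {
  refstr <- "AACCGGTTAACC"
  ref <- make_ref(c(chr1 = refstr))
  rd <- make_read("d1", pos = 0L, cigar = "4M2D4M",
                  seq = paste0(substr(refstr, 1, 4), substr(refstr, 7, 10)))
  p <- build_pileup(read_set(rd), ref)
  gaps <- p[category == "gap"]
  expect_equal(gaps$ref_pos, c(4L, 5L))
  expect_equal(unique(gaps$gap_kind), "deletion")
  expect_equal(p[gap_kind == "none"]$ref_pos, c(0:3, 6:9))
  # deleted columns still compare read-free: no read_base recorded
  expect_true(all(is.na(gaps$read_base)))
})

test_that("build_pileup: 5M1I5M anchors the insertion gap at column 4", {
  refstr <- "AACCGGTTAACC"
  ref <- make_ref(c(chr1 = refstr))
  rd <- make_read("i1", pos = 0L, cigar = "5M1I5M",
                  seq = paste0(substr(refstr, 1, 5), "G",
                               substr(refstr, 6, 10)))
  p <- build_pileup(read_set(rd), ref)
  ins <- p[gap_kind == "insertion"]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$ref_pos, 4L)     # column immediately left of insertion
  expect_equal(ins$qpos, 5L)        # first inserted base's query offset
  # the read also keeps its base observation at the anchor column
  expect_equal(nrow(p[ref_pos == 4L]), 2L)
  # all ten aligned bases remain concordant
  expect_equal(sum(p$category == "concordant"), 10L)
})

test_that("column triggering: gaps and mismatches trigger, concordance not", {
  refstr <- "AAAAAAAAAA"
  ref <- make_ref(c(chr1 = refstr))
  clean <- build_pileup(perfect_reads(refstr, 0L, 10L), ref)
  expect_false(column_is_triggered(clean[ref_pos == 3L]))
  rd <- make_read("x", pos = 0L, cigar = "4M1D5M",
                  seq = strrep("A", 9L))
  p <- build_pileup(read_set(rd), ref)
  expect_true(column_is_triggered(p[ref_pos == 4L]))
})

test_that("gap_ratio counts gaps over all observations", {
  refstr <- strrep("ACGT", 10L)
  ref <- make_ref(c(chr1 = refstr))
  rows <- lapply(1:9, function(i)
    make_read(sprintf("c%02d", i), pos = 0L, cigar = "12M",
              seq = substr(refstr, 1, 12)))
  rows <- c(rows, list(make_read("g1", pos = 0L, cigar = "6M1D5M",
                                 seq = paste0(substr(refstr, 1, 6),
                                              substr(refstr, 8, 12)))))
  p <- build_pileup(read_set(data.table::rbindlist(rows)), ref)
  expect_equal(gap_ratio(p[ref_pos == 6L]), 0.1)
  expect_equal(gap_ratio(p[ref_pos == 1L]), 0)
  expect_error(gap_ratio(p[ref_pos == 99L]), "empty")
})

test_that("homopolymer gate: reference side, read side, and neither", {
  # reference ...TAAAG...: middle A sits in a 3-run -> TRUE regardless of reads
  ref1 <- make_ref(c(chr1 = "GCTAAAGCTA"))
  rd1 <- make_read("m", pos = 2L, cigar = "6M", seq = "TACAGC")  # mismatch at A
  p1 <- build_pileup(read_set(rd1), ref1)
  expect_true(has_homopolymer_context(p1[ref_pos == 4L], ref1,
                                      read_set(rd1), 3L))
  # reference ACGTACGT (no run), read carries GGG across the column -> TRUE
  ref2 <- make_ref(c(chr1 = "ACGTACGTAC"))
  rd2 <- make_read("r", pos = 0L, cigar = "8M", seq = "ACGGGCGT")
  rs2 <- read_set(rd2)
  p2 <- build_pileup(rs2, ref2)
  expect_true(has_homopolymer_context(p2[ref_pos == 4L], ref2, rs2, 3L))
  # no run >= 3 anywhere -> FALSE
  rd3 <- make_read("n", pos = 0L, cigar = "8M", seq = "ACGTTCGT")
  rs3 <- read_set(rd3)
  p3 <- build_pileup(rs3, ref2)
  expect_false(has_homopolymer_context(p3[ref_pos == 4L], ref2, rs3, 3L))
})

test_that("homopolymer gate matches the run-length oracle exhaustively", {
  # every 5-base reference window x single-read 7-base context
  bases <- c("A", "C")   # two letters exhaust the run structure
  combos5 <- do.call(expand.grid, rep(list(bases), 5L))
  combos7 <- do.call(expand.grid, rep(list(bases), 7L))
  set.seed(9)
  pick7 <- combos7[sample(nrow(combos7), 24L), ]
  for (i in seq_len(nrow(combos5))) {
    refstr <- paste0("GT", paste(unlist(combos5[i, ]), collapse = ""), "TG")
    ref <- make_ref(c(chr1 = refstr))
    for (j in seq_len(nrow(pick7))) {
      readstr <- paste(unlist(pick7[j, ]), collapse = "")
      rd <- make_read("e", pos = 1L, cigar = "7M", seq = readstr)
      rs <- read_set(rd)
      p <- build_pileup(rs, ref)
      col <- p[ref_pos == 4L]     # center of the 5-base window
      got <- has_homopolymer_context(col, ref, rs, 3L)
      # oracle: brute-force run lengths at/adjacent in reference, or the
      # run containing the read base at the column (query offset 3)
      ref_run <- ionsnp:::run_length_at(refstr, 3:5) >= 3L
      read_run <- ionsnp:::run_length_at(readstr, 3L) >= 3L
      expect_equal(got, ref_run || read_run,
                   info = sprintf("ref=%s read=%s", refstr, readstr))
    }
  }
})

test_that("classify_improper_gaps honors both gates and the strict threshold", {
  refstr <- paste0(strrep("ACGT", 3L), "AAAA", strrep("CGTA", 3L))  # run at 12..15
  ref <- make_ref(c(chr1 = refstr))
  mk_col <- function(n_clean, n_gap) {
    rows <- lapply(seq_len(n_clean), function(i)
      make_read(sprintf("c%02d", i), pos = 8L, cigar = "10M",
                seq = substr(refstr, 9L, 18L)))
    gaprows <- lapply(seq_len(n_gap), function(i)
      make_read(sprintf("g%02d", i), pos = 8L, cigar = "5M1D4M",
                seq = paste0(substr(refstr, 9L, 13L), substr(refstr, 15L, 18L))))
    read_set(data.table::rbindlist(c(rows, gaprows)))
  }
  # 1 gap in 10 observations at a homopolymer column: improper
  rs <- mk_col(9L, 1L)
  p <- build_pileup(rs, ref)
  col <- p[ref_pos == 13L]
  ev <- classify_improper_gaps(col, ref, rs, aos_config())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gap_kind, "deletion")
  # ratio exactly at the threshold: retained ("under 0.2" is strict)
  rs2 <- mk_col(8L, 2L)
  p2 <- build_pileup(rs2, ref)
  expect_equal(nrow(classify_improper_gaps(p2[ref_pos == 13L], ref, rs2,
                                           aos_config())), 0L)
  # ratio 0.5: retained as a real indel candidate
  rs3 <- mk_col(1L, 1L)
  p3 <- build_pileup(rs3, ref)
  expect_equal(nrow(classify_improper_gaps(p3[ref_pos == 13L], ref, rs3,
                                           aos_config())), 0L)
  # all-gap column (ratio 1) is never improper
  rs4 <- mk_col(0L, 3L)
  p4 <- build_pileup(rs4, ref)
  expect_equal(nrow(classify_improper_gaps(p4[ref_pos == 13L], ref, rs4,
                                           aos_config())), 0L)
})

test_that("no homopolymer context means no events even at low gap ratio", {
  refstr <- strrep("ACGT", 8L)
  ref <- make_ref(c(chr1 = refstr))
  rows <- lapply(1:9, function(i)
    make_read(sprintf("c%02d", i), pos = 0L, cigar = "12M",
              seq = substr(refstr, 1L, 12L)))
  rows <- c(rows, list(make_read("g1", pos = 0L, cigar = "6M1D5M",
                                 seq = paste0(substr(refstr, 1L, 6L),
                                              substr(refstr, 8L, 12L)))))
  rs <- read_set(data.table::rbindlist(rows))
  p <- build_pileup(rs, ref)
  col <- p[ref_pos == 6L]
  expect_equal(gap_ratio(col), 0.1)
  expect_equal(nrow(classify_improper_gaps(col, ref, rs, aos_config())), 0L)
})

test_that("repair_read: deletion becomes match with min-flanking quality", {
  refstr <- "CCCCAAAACCCC"
  ref <- make_ref(c(chr1 = refstr))
  rd <- make_read("d", pos = 2L, cigar = "4M1D4M",
                  seq = "CCAACCCC", qual = "IIII####")   # I=40, #=2
  ev <- data.table::data.table(kind = "deletion", ref_start = 6L, len = 1L)
  rep1 <- repair_read(read_set(rd), ev, ref)
  expect_equal(rep1$cigar, "9M")
  expect_equal(rep1$seq, "CCAAACCCC")                 # gains the deleted A
  expect_equal(rep1$qual, "IIII#####")                # min(40, 2) = 2 -> '#'
  expect_equal(cigar_ref_width(rep1$cigar), cigar_ref_width(rd$cigar))
  expect_equal(rep1$pos, rd$pos)
})

test_that("repair_read: insertion is excised and flanking matches merge", {
  ref <- make_ref(c(chr1 = "CCCCAAAACCCC"))
  rd <- make_read("i", pos = 1L, cigar = "5M1I5M",
                  seq = "CCCAAAAACCC", qual = "ABCDEFGHIJK")
  ev <- data.table::data.table(kind = "insertion", ref_start = 6L, len = 1L)
  rep1 <- repair_read(read_set(rd), ev, ref)
  expect_equal(rep1$cigar, "10M")
  expect_equal(rep1$seq, "CCCAAAACCC")    # inserted base at offset 5 excised
  expect_equal(rep1$qual, "ABCDEGHIJK")
  expect_equal(cigar_ref_width(rep1$cigar), cigar_ref_width(rd$cigar))
  # no events -> identity; bogus event -> consistency error
  expect_equal(as.data.frame(repair_read(read_set(rd),
                                         ev[0], ref)),
               as.data.frame(read_set(rd)))
  bad <- data.table::data.table(kind = "deletion", ref_start = 99L, len = 1L)
  expect_error(repair_read(read_set(rd), bad, ref), "not locatable")
})

test_that("run_aos repairs planted improper gaps and is idempotent", {
  sim <- small_sim()
  dedup <- run_rdast(sim$reads)$reads
  res <- run_aos(dedup, sim$ref)
  expect_gt(res$stats$improper_gap_events, 0L)
  # conservation + reference-span/order preservation in repair mode
  expect_equal(nrow(res$reads), nrow(dedup))
  expect_equal(res$reads$pos, dedup$pos)
  expect_equal(cigar_ref_width(res$reads$cigar), cigar_ref_width(dedup$cigar))
  expect_equal(res$stats$reads_dropped, 0L)
  # locality: untouched reads bit-identical
  touched <- res$events$qname
  same <- setdiff(dedup$qname, touched)
  a <- as.data.table(dedup)[qname %in% same][order(qname)]
  b <- as.data.table(res$reads)[qname %in% same][order(qname)]
  expect_equal(a, b)
  # idempotence: second pass classifies nothing
  second <- run_aos(res$reads, sim$ref)
  expect_equal(second$stats$improper_gap_events, 0L)
  # drop mode removes exactly the carrying reads
  dropped <- run_aos(dedup, sim$ref, aos_config(mode = "drop"))
  expect_equal(nrow(dropped$reads),
               nrow(dedup) - dropped$stats$reads_dropped)
  expect_equal(dropped$stats$reads_repaired, 0L)
})

test_that("run_aos equals the per-column exact route on a small instance", {
  sim <- simulate_run(sim_config(genome_length = 4000L, depth_target = 25,
                                 n_snps = 5L, seed = 12L))
  reads <- sim$reads
  cfg <- aos_config()
  fast <- run_aos(reads, sim$ref, cfg)
  # exact route: classify every column via the observation table
  p <- build_pileup(reads, sim$ref)
  exact_events <- data.table::rbindlist(lapply(
    split(p, by = c("chrom", "ref_pos")), function(col)
      classify_improper_gaps(col, sim$ref, reads, cfg)))
  # same gap observations identified (simulated gaps are single-base)
  fk <- fast$events[, .(qname, kind, col = ref_start)]
  ek <- exact_events[, .(qname = qname,
                         kind = ifelse(gap_kind == "deletion", "deletion",
                                       "insertion"),
                         col = ref_pos + (gap_kind == "deletion") * 0L)]
  ek[kind == "insertion", col := col + 1L]   # event table stores op ref_start
  data.table::setorder(fk, qname, kind, col)
  data.table::setorder(ek, qname, kind, col)
  expect_equal(fk, ek)
})

test_that("a true 1-base deletion present in most reads is retained", {
  refstr <- paste0(strrep("ACGT", 5L), "AAAA", strrep("TGCA", 5L))
  ref <- make_ref(c(chr1 = refstr))
  # 6 of 10 reads carry the deletion of one run base: ratio 0.6 >= 0.2
  rows <- c(
    lapply(1:6, function(i)
      make_read(sprintf("v%02d", i), pos = 16L, cigar = "5M1D4M",
                seq = paste0(substr(refstr, 17L, 21L),
                             substr(refstr, 23L, 26L)))),
    lapply(1:4, function(i)
      make_read(sprintf("w%02d", i), pos = 16L, cigar = "10M",
                seq = substr(refstr, 17L, 26L)))
  )
  rs <- read_set(data.table::rbindlist(rows))
  res <- run_aos(rs, ref)
  expect_equal(res$stats$improper_gap_events, 0L)
  expect_equal(as.data.frame(res$reads), as.data.frame(rs))
})
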