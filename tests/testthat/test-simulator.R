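# Simulator: determinism, the stated error model, duplicate-pile anatomy,
# and recovery of configured parameters from the emitted library.

test_that("reference simulation: determinism, length, composition", {
  cfg <- sim_config(genome_length = 20000L, seed = 5L)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_equal(as.character(r1), as.character(r2))
  expect_equal(unname(ref_lengths(r1)), 20000L)
  expect_error(simulate_reference(sim_config(genome_length = 0L)),
               "positive")
})

test_that("enrichment 0 gives the i.i.d. geometric run-length law", {
  L <- 1000000L
  cfg <- sim_config(genome_length = L, gc_fraction = 0.5,
                    homopolymer_enrichment = 0, seed = 8L)
  s <- as.character(simulate_reference(cfg)[[1]])
  runs <- rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths
  # for equal base frequencies each run is Geometric(3/4) (length >= k with
  # prob (1/4)^(k-1)); expected number of runs: L / E[len] = 3L/4
  n_runs <- length(runs)
  expect_lt(abs(n_runs - 0.75 * L), 3 * sqrt(0.75 * L))
  frac_ge3 <- mean(runs >= 3L)
  p3 <- 1 / 16
  expect_lt(abs(frac_ge3 - p3), 3 * sqrt(p3 * (1 - p3) / n_runs))
  # enrichment raises the long-run mass
  cfg2 <- sim_config(genome_length = L, gc_fraction = 0.5,
                     homopolymer_enrichment = 0.15, seed = 8L)
  s2 <- as.character(simulate_reference(cfg2)[[1]])
  runs2 <- rle(strsplit(s2, "", fixed = TRUE)[[1]])$lengths
  expect_gt(mean(runs2 >= 3L), frac_ge3)
})

test_that("planted variants: placement, zygosity counts, donor alleles", {
  cfg <- sim_config(genome_length = 50000L, n_snps = 100L,
                    het_fraction = 0.5, seed = 3L)
  ref <- simulate_reference(cfg)
  d <- plant_variants(ref, cfg)
  expect_equal(nrow(d$truth), 100L)
  n_het <- sum(d$truth$genotype == "het")
  expect_lt(abs(n_het - 50), 3 * sqrt(100 * 0.25))  # binomial 3-sigma
  refc <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  h1 <- strsplit(d$hap1, "", fixed = TRUE)[[1]]
  h2 <- strsplit(d$hap2, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(d$truth))) {
    p <- d$truth$pos[i] + 1L
    expect_equal(refc[p], d$truth$ref[i])
    carried <- c(h1[p], h2[p])
    if (d$truth$genotype[i] == "hom") {
      expect_equal(carried, rep(d$truth$alt[i], 2L))
    } else {
      expect_setequal(carried, c(d$truth$ref[i], d$truth$alt[i]))
    }
  }
  # n_snps = 0 leaves the donor identical to the reference
  cfg0 <- sim_config(genome_length = 5000L, n_snps = 0L, seed = 3L)
  ref0 <- simulate_reference(cfg0)
  d0 <- plant_variants(ref0, cfg0)
  expect_equal(d0$hap1, as.character(ref0[[1]]))
  expect_equal(nrow(d0$truth), 0L)
  expect_error(plant_variants(ref0, sim_config(genome_length = 5000L,
                                               n_snps = 5000L)),
               "below genome_length")
})

test_that("read simulation is deterministic and internally consistent", {
  cfg <- sim_config(genome_length = 30000L, depth_target = 30, n_snps = 20L,
                    seed = 21L)
  a <- simulate_run(cfg)
  b <- simulate_run(cfg)
  expect_equal(as.data.frame(a$reads), as.data.frame(b$reads))
  expect_equal(a$truth, b$truth)
  validate_reads(a$reads)   # CIGAR/seq/qual lengths agree by construction
})

test_that("empirical gap rate is within 3 sigma of the configured rate", {
  # pcr_gap_rate 0 isolates the per-copy sequencer gap rate being measured
  cfg <- sim_config(genome_length = 100000L, depth_target = 25,
                    n_snps = 0L, pcr_gap_rate = 0, seed = 13L)
  sim <- simulate_run(cfg)
  expect_gte(sim$aligned_bases, 1e5)
  n_gaps <- nrow(sim$gap_events)
  # events are drawn per interior base at the configured rate
  interior <- sim$aligned_bases - 2L * nrow(sim$reads)
  rate <- cfg$per_base_gap_error_rate
  expect_lt(abs(n_gaps - interior * rate), 3 * sqrt(interior * rate))
  # and they are enriched in homopolymer runs
  refc <- strsplit(as.character(sim$ref[[1]]), "", fixed = TRUE)[[1]]
  r <- rle(refc)
  hp <- rep(r$lengths >= 3L, r$lengths)
  frac_in_hp <- mean(hp[sim$gap_events$ref_pos + 1L])
  expect_gt(frac_in_hp, mean(hp) * 2)
})

test_that("duplicate piles share the 5' key and survive permissive dedup", {
  sim <- small_sim()
  g <- group_duplicates(sim$reads)
  tmpl <- sub("_c\\d+$", "", g$qname)
  # every template's copies land in one duplicate group
  expect_true(all(tapply(g$group_id, tmpl, data.table::uniqueN) == 1L))
  key <- duplicate_key(sim$reads)
  m <- merge(data.table::data.table(qname = sim$reads$qname,
                                    got = key$five_prime_pos),
             sim$truth_reads[, .(qname, five_prime_pos)], by = "qname")
  expect_equal(m$got, m$five_prime_pos)
  # threshold 0: every read passes, nothing is removed
  res <- run_rdast(sim$reads, rdast_config(0L))
  expect_equal(res$stats$reads_removed, 0L)
})

test_that("error-free configuration gives AS = match score x length", {
  cfg <- sim_config(genome_length = 30000L, depth_target = 20, n_snps = 0L,
                    per_base_gap_error_rate = 0, per_base_substitution_rate = 0,
                    pcr_substitution_rate = 0, pcr_gap_rate = 0, seed = 4L)
  sim <- simulate_run(cfg)
  expect_equal(sim$reads$as_score, as.numeric(nchar(sim$reads$seq)))
  expect_true(all(sim$reads$cigar == paste0(nchar(sim$reads$seq), "M")))
  # reads reproduce the reference exactly
  refstr <- as.character(sim$ref[[1]])
  idx <- sample(nrow(sim$reads), 50L)
  expect_equal(sim$reads$seq[idx],
               substring(refstr, sim$reads$pos[idx] + 1L,
                         sim$reads$pos[idx] + nchar(sim$reads$seq[idx])))
})

test_that("configured parameters are recoverable from the library", {
  # template-level rates 0: isolates the per-copy parameters being measured
  cfg <- sim_config(genome_length = 80000L, depth_target = 50, n_snps = 0L,
                    depth_lognorm_sd = 0, pcr_substitution_rate = 0,
                    pcr_gap_rate = 0, seed = 17L)
  sim <- simulate_run(cfg)
  # mean depth (lognormal sd 0 -> flat target)
  depth <- sim$aligned_bases / cfg$genome_length
  expect_lt(abs(depth - 50) / 50, 0.1)
  # mean pile size of the geometric model: 1/p copies per template
  mean_pile <- nrow(sim$reads) /
    data.table::uniqueN(sim$truth_reads$template_id)
  expect_lt(abs(mean_pile - 1 / cfg$duplicate_group_geometric_p) *
              cfg$duplicate_group_geometric_p, 0.05)
  # substitution rate
  n_sub <- sum(sim$truth_reads$n_sub)
  interior <- sim$aligned_bases - 2L * nrow(sim$reads)
  rate <- cfg$per_base_substitution_rate
  expect_lt(abs(n_sub - interior * rate), 4 * sqrt(interior * rate))
})
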