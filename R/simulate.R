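# Deterministic simulator of an ion-semiconductor-like exome library:
# a homopolymer-enriched reference, a diploid SNP donor, and variable-length
# single-end reads emitted pre-aligned (true placement known, alignment
# itself is out of scope) with
#   * PCR-duplicate piles: each template is copied 1 + Geometric(p) times;
#     all copies share the template's 5' reference coordinate and its
#     pre-amplification (PCR) errors, and add independent per-copy errors —
#     the mechanism that makes duplicate-aware filtering matter;
#   * homopolymer over/undercall gap errors at a configurable per-base rate
#     (default 0.01 — one gap per 100 aligned bases), biased into reference
#     runs of >= 3 identical bases;
#   * per-read integer alignment scores computed from the generative event
#     list under an affine scheme, so error-laden duplicates score lower;
#   * window-level depth variation (lognormal) emulating uneven exome
#     capture, which is where both the false-positive piles and the
#     gap-starved borderline sites live.
# Indel errors are single-base (one unit of a homopolymer run), reads are
# emitted on one chromosome, and sequences are stored forward-oriented
# (strand affects only the flag and the 5' duplicate key).

#' Simulation configuration
#'
#' Defaults state the emulated platform: ~150 bp mean read length (sheared
#' library size), one gap error per 100 aligned bases, lognormal capture
#' depth, geometric duplicate piles, and an affine alignment score with
#' match +1 so a perfect read scores its own length.
#'
#' @param genome_length reference length in bases.
#' @param depth_target mean raw aligned depth (duplicates included).
#' @param n_snps number of planted SNPs.
#' @param chrom_name chromosome name.
#' @param gc_fraction reference GC content.
#' @param homopolymer_enrichment probability that a reference base copies
#'   its predecessor (0 = i.i.d. bases; raises homopolymer run mass).
#' @param het_fraction fraction of planted SNPs that are heterozygous.
#' @param ti_prob probability a planted SNP is a transition.
#' @param read_length_mean,read_length_sd,read_length_min read length model
#'   (normal, truncated below).
#' @param depth_window,depth_lognorm_sd capture-depth model: per-window
#'   depth factors are lognormal with this log-sd around `depth_target`.
#' @param per_base_gap_error_rate per-copy gap (over/undercall) error rate
#'   per aligned base.
#' @param hp_gap_weight sampling weight of homopolymer-run positions
#'   relative to other positions when placing gap errors.
#' @param per_base_substitution_rate per-copy substitution error rate.
#' @param pcr_substitution_rate,pcr_gap_rate template-level (PCR) error
#'   rates shared by all copies of a template.
#' @param duplicate_group_geometric_p geometric parameter of pile sizes
#'   (`1 + rgeom(p)`; mean pile size `1/p`).
#' @param score_match,score_mismatch,score_gap_open,score_gap_extend affine
#'   alignment-score scheme for the emitted AS tag.
#' @param qual_mean,qual_sd base-quality model (normal, clamped to [2,40]).
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000L, depth_target = 60,
                       n_snps = 50L, chrom_name = "sim1",
                       gc_fraction = 0.41, homopolymer_enrichment = 0.15,
                       het_fraction = 0.565, ti_prob = 0.73,
                       read_length_mean = 150, read_length_sd = 35,
                       read_length_min = 50,
                       depth_window = 20000L, depth_lognorm_sd = 0.8,
                       per_base_gap_error_rate = 0.01, hp_gap_weight = 8,
                       per_base_substitution_rate = 0.002,
                       pcr_substitution_rate = 3e-4, pcr_gap_rate = 1e-4,
                       duplicate_group_geometric_p = 0.65,
                       score_match = 1L, score_mismatch = -2L,
                       score_gap_open = -3L, score_gap_extend = -1L,
                       qual_mean = 28, qual_sd = 6, seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(gc_fraction, homopolymer_enrichment, het_fraction, ti_prob,
             per_base_gap_error_rate, per_base_substitution_rate,
             pcr_substitution_rate, pcr_gap_rate,
             duplicate_group_geometric_p)
  stopifnot(all(rates >= 0 & rates <= 1), depth_target >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a reference chromosome
#'
#' First-order Markov base chain: with probability `homopolymer_enrichment`
#' a base copies its predecessor, otherwise it is drawn i.i.d. with the
#' configured GC content. Enrichment 0 gives i.i.d. bases (geometric
#' run-length law).
#'
#' @param config a [sim_config()].
#' @return Named `DNAStringSet` with one chromosome.
#' @export
simulate_reference <- function(config) {
  if (config$genome_length <= 0) stop("genome_length must be positive")
  set.seed(config$seed)
  L <- as.integer(config$genome_length)
  p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
         G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
  stay <- runif(L) < config$homopolymer_enrichment
  stay[1L] <- FALSE
  innov <- which(!stay)
  draws <- sample(names(p), length(innov), replace = TRUE, prob = p)
  seq <- rep(draws, diff(c(innov, L + 1L)))
  ref <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(ref) <- config$chrom_name
  ref
}

#' Plant donor SNPs
#'
#' Places `n_snps` biallelic SNPs uniformly (without collision), a
#' `het_fraction` of them heterozygous (the alt allele on one random
#' haplotype), the rest homozygous (alt on both). Transitions are drawn
#' with probability `ti_prob`.
#'
#' @param ref reference `DNAStringSet`.
#' @param config a [sim_config()].
#' @return `list(truth = variant_set, hap1 =, hap2 = character donor
#'   haplotypes)`.
#' @export
plant_variants <- function(ref, config) {
  set.seed(config$seed + 1L)
  chrom <- config$chrom_name
  L <- ref_lengths(ref)[[chrom]]
  n <- as.integer(config$n_snps)
  if (n >= L) stop("n_snps must be below genome_length")
  refchars <- strsplit(as.character(ref[[chrom]]), "", fixed = TRUE)[[1L]]
  pos <- sort(sample.int(L, n)) - 1L
  rb <- refchars[pos + 1L]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
             T = c("A", "G"))
  is_ti <- runif(n) < config$ti_prob
  alt <- ifelse(is_ti, transition[rb],
                vapply(seq_len(n), function(i)
                  sample(tv[[rb[i]]], 1L), character(1)))
  het <- runif(n) < config$het_fraction
  hap_of_het <- sample(1:2, n, replace = TRUE)
  hap1 <- refchars; hap2 <- refchars
  on1 <- !het | hap_of_het == 1L
  on2 <- !het | hap_of_het == 2L
  hap1[pos[on1] + 1L] <- alt[on1]
  hap2[pos[on2] + 1L] <- alt[on2]
  truth <- variant_set(data.table(
    chrom = chrom, pos = pos, ref = rb, alt = alt,
    genotype = ifelse(het, "het", "hom")))
  list(truth = truth,
       hap1 = paste(hap1, collapse = ""),
       hap2 = paste(hap2, collapse = ""))
}

# Weighted placement of gap errors: offsets are drawn uniformly and accepted
# with probability 1 inside a homopolymer run (>= 3) and 1/weight outside,
# i.e. run positions carry `weight`-fold sampling mass.
.sample_gap_offsets <- function(read_row, tlen, start, hp_mask, weight) {
  n <- length(read_row)
  off <- integer(n)
  pending <- seq_len(n)
  guard <- 0L
  while (length(pending) && guard < 50L) {
    cand <- 1L + floor(runif(length(pending)) * (tlen[pending] - 2L))
    in_hp <- hp_mask[start[pending] + cand + 1L]
    acc <- in_hp | (runif(length(pending)) < 1 / weight)
    off[pending[acc]] <- as.integer(cand[acc])
    pending <- pending[!acc]
    guard <- guard + 1L
  }
  if (length(pending))  # give up on the bias for stragglers
    off[pending] <- 1L + floor(runif(length(pending)) * (tlen[pending] - 2L))
  off
}

#' Simulate an aligned single-end library with duplicate piles
#'
#' See the module description at the top of this file for the generative
#' model. Every copy of a template shares its 5' coordinate, strand and PCR
#' errors; per-copy substitution and homopolymer gap errors are added on
#' top; the AS tag is computed from the realized event list.
#'
#' @param donor result of [plant_variants()].
#' @param ref reference `DNAStringSet`.
#' @param config a [sim_config()].
#' @return `list(reads = read_set, truth_reads = data.table(qname,
#'   template_id, copy, five_prime_pos, strand, n_pcr_sub, n_sub, n_gap),
#'   gap_events = data.table(qname, ref_pos, kind), aligned_bases = total
#'   reference bases consumed)`.
#' @export
simulate_reads <- function(donor, ref, config) {
  stopifnot(config$depth_target > 0)
  set.seed(config$seed + 2L)
  chrom <- config$chrom_name
  L <- ref_lengths(ref)[[chrom]]
  refchars <- strsplit(as.character(ref[[chrom]]), "", fixed = TRUE)[[1L]]
  r <- rle(refchars)
  hp_mask <- rep(r$lengths >= 3L, r$lengths)

  # templates: per capture window, lognormal depth around the target
  wstart <- seq(0L, L - 1L, by = config$depth_window)
  wlen <- pmin(config$depth_window, L - wstart)
  mu <- log(config$depth_target) - config$depth_lognorm_sd^2 / 2
  wdepth <- exp(rnorm(length(wstart), mu, config$depth_lognorm_sd))
  pile_mean <- 1 / config$duplicate_group_geometric_p
  lambda <- wdepth * wlen / (config$read_length_mean * pile_mean)
  n_tpl_w <- stats::rpois(length(wstart), lambda)
  n_tpl <- sum(n_tpl_w)
  if (n_tpl == 0L) stop("no templates drawn; raise depth_target")
  tpl <- data.table(
    template_id = seq_len(n_tpl),
    wstart = rep(wstart, n_tpl_w), wlen = rep(wlen, n_tpl_w)
  )
  tpl[, tlen := pmax(config$read_length_min,
                     as.integer(round(rnorm(.N, config$read_length_mean,
                                            config$read_length_sd))))]
  tpl[, start := wstart + floor(runif(.N) * wlen)]
  tpl[, tlen := pmin(tlen, L - start)]
  tpl <- tpl[tlen >= config$read_length_min]
  tpl[, template_id := seq_len(.N)]
  tpl[, strand := ifelse(runif(.N) < 0.5, "+", "-")]
  tpl[, hap := sample(1:2, .N, replace = TRUE)]
  tpl[, copies := 1L + rgeom(.N, config$duplicate_group_geometric_p)]

  # template-level (PCR) events, inherited by every copy. The substituted
  # base is drawn once per template event: all PCR copies of a molecule
  # carry the *same* wrong base, which is exactly why duplicate piles can
  # push a spurious allele over the caller's frequency threshold.
  hapseq <- c(donor$hap1, donor$hap2)
  tpl_events <- .draw_events(tpl$template_id, tpl$start, tpl$tlen,
                             sub_rate = config$pcr_substitution_rate,
                             gap_rate = config$pcr_gap_rate,
                             hp_mask = hp_mask, weight = config$hp_gap_weight,
                             level = "pcr")
  tpl_events[, newbase := NA_character_]
  if (nrow(tpl_events)) {
    p <- tpl$start[tpl_events$id] + tpl_events$off + 1L
    cur <- substring(hapseq[tpl$hap[tpl_events$id]], p, p)
    sub_idx <- which(tpl_events$type == "sub")
    set(tpl_events, sub_idx, "newbase", .other_base(cur[sub_idx]))
  }

  reads <- tpl[rep(seq_len(.N), copies)]
  reads[, copy := seq_len(.N), by = template_id]
  reads[, read_id := seq_len(.N)]
  reads[, qname := sprintf("t%07d_c%d", template_id, copy)]

  copy_events <- .draw_events(reads$read_id, reads$start, reads$tlen,
                              sub_rate = config$per_base_substitution_rate,
                              gap_rate = config$per_base_gap_error_rate,
                              hp_mask = hp_mask,
                              weight = config$hp_gap_weight, level = "copy")

  # expand template events to copies, merge, resolve same-offset collisions
  # (template events win; a single event per read offset)
  tpl_map <- reads[, .(read_id, template_id)]
  ev_t <- if (nrow(tpl_events))
    merge(tpl_map, tpl_events, by.x = "template_id", by.y = "id",
          allow.cartesian = TRUE)[, .(read_id, off, type, level, newbase)]
  else data.table(read_id = integer(), off = integer(), type = character(),
                  level = character(), newbase = character())
  ev_c <- copy_events[, .(read_id = id, off, type, level,
                          newbase = NA_character_)]
  ev <- rbind(ev_t, ev_c)
  # same-offset collisions: gaps beat substitutions (keeps the emitted gap
  # rate at its configured binomial value), template events beat per-copy
  ev[, prio := (type == "sub") * 2L + (level != "pcr")]
  setorder(ev, read_id, off, prio)
  ev <- unique(ev, by = c("read_id", "off"))

  # sequences from the donor haplotype, then event surgery (right to left)
  seqs <- substring(hapseq[reads$hap], reads$start + 1L,
                    reads$start + reads$tlen)
  set.seed(config$seed + 3L)
  ev[, cur := substring(seqs[read_id], off + 1L, off + 1L)]
  ev[type == "sub" & is.na(newbase), newbase := .other_base(cur)]
  if (nrow(ev)) {
    evs <- ev[order(read_id, -off)]
    e_rid <- evs$read_id; e_off <- evs$off
    e_type <- evs$type; e_new <- evs$newbase
    for (j in seq_along(e_rid)) {
      rid <- e_rid[j]; o <- e_off[j]; s <- seqs[rid]
      seqs[rid] <- switch(e_type[j],
        sub = paste0(substr(s, 1L, o), e_new[j],
                     substr(s, o + 2L, nchar(s))),
        del = paste0(substr(s, 1L, o), substr(s, o + 2L, nchar(s))),
        ins = paste0(substr(s, 1L, o + 1L), substr(s, o + 1L, o + 1L),
                     substr(s, o + 2L, nchar(s))))
    }
  }

  # CIGARs: M segments split by single-base del (D) / ins (I) events. A
  # deletion at template offset o consumes reference base o via D (M segment
  # ends at o-1); an insertion after offset o leaves base o in the M segment.
  gaps <- ev[type %chin% c("del", "ins")][order(read_id, off)]
  cigars <- paste0(reads$tlen, "M")
  if (nrow(gaps)) {
    gaps[, tlen := reads$tlen[read_id]]
    gaps[, cut := off + (type == "ins")]
    gaps[, mseg := cut - shift(off + 1L, fill = 0L), by = read_id]
    gaps[, piece := paste0(fifelse(mseg > 0L, paste0(mseg, "M"), ""),
                           fifelse(type == "del", "1D", "1I"))]
    cig_gap <- gaps[, .(body = paste(piece, collapse = ""),
                        tailM = tlen[1L] - off[.N] - 1L), by = read_id]
    cigars[cig_gap$read_id] <- paste0(
      cig_gap$body, fifelse(cig_gap$tailM > 0L,
                            paste0(cig_gap$tailM, "M"), ""))
  }

  # alignment scores from the realized events + donor-vs-reference SNPs
  n_sub <- tabulate(ev[type == "sub"]$read_id, nbins = nrow(reads))
  n_del <- tabulate(ev[type == "del"]$read_id, nbins = nrow(reads))
  n_ins <- tabulate(ev[type == "ins"]$read_id, nbins = nrow(reads))
  snp_mis <- .count_snp_mismatches(reads, donor, ref, config)
  final_len <- reads$tlen - n_del + n_ins
  n_mis <- pmin(n_sub + snp_mis, final_len - n_ins)
  as_score <- config$score_match * (final_len - n_ins - n_mis) +
    config$score_mismatch * n_mis +
    (config$score_gap_open) * (n_del + n_ins)

  # base qualities, generated in read blocks to bound transient memory
  set.seed(config$seed + 4L)
  qual <- character(nrow(reads))
  block <- 100000L
  for (b in seq(1L, nrow(reads), by = block)) {
    ri <- b:min(b + block - 1L, nrow(reads))
    fl <- final_len[ri]
    qn <- pmin(40L, pmax(2L, as.integer(round(
      rnorm(sum(fl), config$qual_mean, config$qual_sd)))))
    qstr <- intToUtf8(qn + 33L)
    qual[ri] <- substring(qstr, cumsum(fl) - fl + 1L, cumsum(fl))
  }

  out <- data.table(
    qname = reads$qname, chrom = chrom, pos = reads$start,
    strand = reads$strand, mapq = 60L, cigar = cigars, seq = seqs,
    qual = qual, as_score = as.numeric(as_score))
  rs <- read_set(out, sq = setNames(L, chrom))

  truth_reads <- reads[, .(qname, template_id, copy,
                           five_prime_pos = ifelse(strand == "-",
                                                   start + tlen - 1L, start),
                           strand,
                           n_sub = n_sub[read_id],
                           n_gap = n_del[read_id] + n_ins[read_id])]
  gap_events <- gaps[, .(qname = reads$qname[read_id],
                         ref_pos = reads$start[read_id] + off, kind = type)]
  list(reads = rs, truth_reads = truth_reads, gap_events = gap_events,
       aligned_bases = sum(reads$tlen))
}

.ALT_BASES <- matrix(c("C", "G", "T",  "A", "G", "T",
                       "A", "C", "T",  "A", "C", "G"),
                     nrow = 3L, dimnames = list(NULL, c("A", "C", "G", "T")))

.other_base <- function(cur) {
  if (!length(cur)) return(character(0))
  k <- 1L + floor(runif(length(cur)) * 3L)
  .ALT_BASES[cbind(k, match(cur, .BASES))]
}

# Count per-read donor-vs-reference mismatches (planted SNP alt alleles on
# the read's haplotype inside its span).
.count_snp_mismatches <- function(reads, donor, ref, config) {
  hap1 <- strsplit(donor$hap1, "", fixed = TRUE)[[1L]]
  hap2 <- strsplit(donor$hap2, "", fixed = TRUE)[[1L]]
  refc <- strsplit(as.character(ref[[config$chrom_name]]), "",
                   fixed = TRUE)[[1L]]
  d1 <- which(hap1 != refc) - 1L
  d2 <- which(hap2 != refc) - 1L
  cnt <- integer(nrow(reads))
  for (h in 1:2) {
    dpos <- if (h == 1L) d1 else d2
    if (!length(dpos)) next
    idx <- which(reads$hap == h)
    if (!length(idx)) next
    ir_reads <- IRanges::IRanges(reads$start[idx] + 1L,
                                 reads$start[idx] + reads$tlen[idx])
    ir_snp <- IRanges::IRanges(dpos + 1L, dpos + 1L)
    cnt[idx] <- IRanges::countOverlaps(ir_reads, ir_snp)
  }
  cnt
}

# Draw per-interval substitution and gap error events. Returns
# data.table(id, off, type, level); offsets are interior (1..len-2) so reads
# begin and end with aligned bases.
.draw_events <- function(id, start, len, sub_rate, gap_rate, hp_mask,
                         weight, level) {
  n <- length(id)
  empty <- data.table(id = integer(), off = integer(), type = character(),
                      level = character())
  if (!n) return(empty)
  interior <- pmax(len - 2L, 0L)
  n_sub <- rbinom(n, interior, sub_rate)
  n_gap <- rbinom(n, interior, gap_rate)
  subs <- NULL
  if (sum(n_sub)) {
    i <- rep(seq_len(n), n_sub)
    subs <- data.table(id = id[i],
                       off = 1L + floor(runif(length(i)) * interior[i]),
                       type = "sub", level = level)
  }
  gaps <- NULL
  if (sum(n_gap)) {
    i <- rep(seq_len(n), n_gap)
    off <- .sample_gap_offsets(i, len[i], start[i], hp_mask, weight)
    kind <- ifelse(runif(length(i)) < 0.5, "del", "ins")
    gaps <- data.table(id = id[i], off = off, type = kind, level = level)
  }
  out <- rbindlist(list(subs, gaps))
  if (is.null(out) || !nrow(out)) empty else out
}

#' Simulate a full scenario
#'
#' Reference, donor SNPs, reads and truth files in one call; optionally
#' writes `ref.fa`, `reads.sam`, `truth.vcf`, `target.bed` and
#' `truth_reads.tsv` to a directory. Fixed seed means byte-identical
#' outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return `list(ref, truth, hap1, hap2, reads, truth_reads, gap_events,
#'   aligned_bases, target)`.
#' @export
simulate_run <- function(config = sim_config(), out_dir = NULL) {
  ref <- simulate_reference(config)
  donor <- plant_variants(ref, config)
  lib <- simulate_reads(donor, ref, config)
  target <- region(config$chrom_name, 0L, config$genome_length)
  res <- c(list(ref = ref, truth = donor$truth, hap1 = donor$hap1,
                hap2 = donor$hap2, target = target), lib)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reference(ref, file.path(out_dir, "ref.fa"))
    write_alignments(lib$reads, file.path(out_dir, "reads.sam"))
    write_variants(donor$truth, file.path(out_dir, "truth.vcf"),
                   contigs = ref_lengths(ref))
    write_regions(target, file.path(out_dir, "target.bed"))
    fwrite(lib$truth_reads, file.path(out_dir, "truth_reads.tsv"),
           sep = "\t")
  }
  res
}
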