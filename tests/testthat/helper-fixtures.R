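# Fixture builders shared across the suite. Everything is constructed in
# code; no binary fixtures.

# One aligned read with sensible defaults; seq/qual lengths derived from the
# CIGAR so fixtures stay valid by construction.
make_read <- function(qname = "r1", chrom = "chr1", pos = 0L, strand = "+",
                      cigar = "10M", seq = NULL, qual = NULL, mapq = 60L,
                      as_score = 100) {
  qw <- cigar_query_width(cigar)
  if (is.null(seq)) seq <- strrep("A", qw)
  if (is.null(qual)) qual <- strrep("I", qw)   # Phred 40
  data.table::data.table(qname = qname, chrom = chrom, pos = as.integer(pos),
                         strand = strand, mapq = mapq, cigar = cigar,
                         seq = seq, qual = qual,
                         as_score = as.numeric(as_score))
}

make_reads <- function(...) {
  read_set(data.table::rbindlist(list(...)))
}

# Reference from explicit chromosome strings.
make_ref <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(x)
}

# A read set aligned perfectly to `refstr` at the given starts.
perfect_reads <- function(refstr, starts, len, chrom = "chr1",
                          strand = "+", as_score = len, prefix = "p") {
  rows <- lapply(seq_along(starts), function(i) {
    make_read(qname = sprintf("%s%03d", prefix, i), chrom = chrom,
              pos = starts[i], strand = strand, cigar = paste0(len, "M"),
              seq = substr(refstr, starts[i] + 1L, starts[i] + len),
              as_score = as_score)
  })
  read_set(data.table::rbindlist(rows),
           sq = stats::setNames(nchar(refstr), chrom))
}

# Standard small simulated scenario reused by several files (cached per
# session; ~6k reads, 50 kb).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_run(sim_config(genome_length = 50000L,
                                        depth_target = 40, n_snps = 40L,
                                        seed = 42L))
    cache
  }
})
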