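# Duplicate filtering by alignment score.
#
# Single-end flow-sequencer reads are trimmed to variable lengths, so
# duplicates cannot be recognized by identical end points: what stays fixed
# across PCR copies of one template is the 5' mapped reference coordinate.
# Reads sharing that coordinate (and strand) form a pile; within each pile,
# reads whose alignment score (AS tag) exceeds a threshold are kept, and if
# none passes, the single best-scoring read is kept so no locus is stripped
# of all coverage (repeat regions gather many short low-AS reads that would
# otherwise vanish entirely).

#' Duplicate-filter configuration
#'
#' @param as_threshold integer alignment-score threshold; reads scoring
#'   strictly above it are kept (default 160).
#' @param keep_at_or_above if `TRUE`, the comparison is `>=` instead of the
#'   default strict `>` (sensitivity-analysis flag).
#' @return An `rdast_config` list.
#' @export
rdast_config <- function(as_threshold = 160L, keep_at_or_above = FALSE) {
  stopifnot(as_threshold >= 0)
  structure(list(as_threshold = as.numeric(as_threshold),
                 keep_at_or_above = isTRUE(keep_at_or_above)),
            class = "rdast_config")
}

#' 5'-end duplicate key of mapped reads
#'
#' For a forward read the key coordinate is the leftmost aligned reference
#' position; for a reverse read it is the rightmost reference base consumed
#' by the CIGAR (M/=/X/D/N ops). Soft/hard clips consume no reference and so
#' never shift the key.
#'
#' @param reads a `read_set` (all reads mapped, non-empty CIGAR).
#' @return `data.table(chrom, five_prime_pos, strand)`, one row per read.
#' @export
duplicate_key <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.table(chrom = character(), five_prime_pos = integer(),
                      strand = character()))
  if (any(reads$cigar == "*" | is.na(reads$pos)))
    stop("duplicate_key: unmapped read in input")
  rw <- cigar_ref_width(reads$cigar)
  data.table(
    chrom = reads$chrom,
    five_prime_pos = ifelse(reads$strand == "-",
                            reads$pos + rw - 1L, reads$pos),
    strand = reads$strand
  )
}

#' Group reads into duplicate piles
#'
#' @param reads a coordinate-sorted `read_set`.
#' @return The reads with `five_prime_pos` and an integer `group_id` column
#'   added; every input read lands in exactly one group (singletons are
#'   valid groups).
#' @export
group_duplicates <- function(reads) {
  key <- duplicate_key(reads)
  out <- copy(as.data.table(reads))
  out[, five_prime_pos := key$five_prime_pos]
  out[, group_id := .GRP, by = .(chrom, five_prime_pos, strand)]
  out[]
}

#' Filter one duplicate pile by alignment score
#'
#' Keeps every member scoring above the threshold; when none does, keeps the
#' single member with the maximal score (ties broken by lexicographically
#' smallest read name, making output deterministic).
#'
#' @param group `data.table` of pile members (non-empty).
#' @param config an [rdast_config()].
#' @return `list(kept=, removed=)`; `kept` is never empty and
#'   `kept` + `removed` partition the members.
#' @export
rdast_filter <- function(group, config = rdast_config()) {
  stopifnot(nrow(group) >= 1L)
  pass <- if (config$keep_at_or_above) group$as_score >= config$as_threshold
          else group$as_score > config$as_threshold
  if (!any(pass)) {
    best <- order(-group$as_score, group$qname)[1L]
    pass <- seq_len(nrow(group)) == best
  }
  list(kept = group[pass], removed = group[!pass])
}

#' Run duplicate filtering over a read set
#'
#' Vectorized whole-library equivalent of applying [rdast_filter()] to every
#' duplicate pile. Output remains coordinate-sorted and is a field-for-field
#' subset of the input; a second pass removes nothing (each surviving pile
#' either passes the threshold or is a singleton).
#'
#' @param reads a coordinate-sorted `read_set`.
#' @param config an [rdast_config()].
#' @return `list(reads = filtered read_set, stats = list(reads_in,
#'   reads_kept, reads_removed, duplication_rate, groups, fallback_groups))`.
#' @export
run_rdast <- function(reads, config = rdast_config()) {
  g <- group_duplicates(reads)
  if (nrow(g) == 0L) {
    stats <- list(reads_in = 0L, reads_kept = 0L, reads_removed = 0L,
                  duplication_rate = NA_real_, groups = 0L,
                  fallback_groups = 0L)
    return(list(reads = reads, stats = stats))
  }
  thr <- config$as_threshold
  g[, pass := if (config$keep_at_or_above) as_score >= thr else as_score > thr]
  g[, any_pass := any(pass), by = group_id]
  # fallback piles: keep single best by (score desc, name asc)
  g[, keep := pass]
  g[any_pass == FALSE,
    keep := seq_len(.N) == order(-as_score, qname)[1L], by = group_id]
  stats <- list(
    reads_in = nrow(g),
    reads_kept = sum(g$keep),
    reads_removed = sum(!g$keep),
    duplication_rate = sum(!g$keep) / nrow(g),
    groups = uniqueN(g$group_id),
    fallback_groups = uniqueN(g$group_id[!g$any_pass])
  )
  kept <- g[keep == TRUE,
            .(qname, chrom, pos, strand, mapq, cigar, seq, qual, as_score)]
  list(reads = read_set(kept, sq = attr(reads, "sq")), stats = stats)
}
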