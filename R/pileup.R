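# Exact pileup observation table.
#
# One row per (read, reference column) observation, each categorized as
# concordant, discordant, or gap — the three cases the gap filter examines.
# Deletions contribute a gap observation at every deleted column; an
# insertion contributes a gap observation anchored to the reference column
# immediately left of the insertion point (and the read's aligned base at
# that column remains a separate base observation, matching htslib pileup
# counting). Soft clips and reference skips contribute nothing.
#
# This path is O(aligned bases) in R and is meant for moderate instances and
# as the reference ("exact") route the vectorized pipeline paths are tested
# against.

.QUAL_MAP <- setNames(0:93, vapply(33:126, function(i) rawToChar(as.raw(i)),
                                   character(1)))

#' Build the pileup observation table
#'
#' @param reads a coordinate-sorted `read_set`.
#' @param ref reference genome (`DNAStringSet`).
#' @param region optional single [region()] restricting the columns.
#' @return `data.table` with one row per observation: `chrom`, `ref_pos`
#'   (0-based), `ref_base`, `read_id` (row index into `reads`), `qname`,
#'   `category` ("concordant"/"discordant"/"gap"), `gap_kind`
#'   ("none"/"deletion"/"insertion"), `read_base` (`NA` for gaps),
#'   `base_qual` (`NA` for gaps), `qpos` (0-based query offset; for gaps,
#'   the offset of the junction / first inserted base), `gap_len`.
#' @export
build_pileup <- function(reads, ref, region = NULL) {
  empty <- data.table(chrom = character(), ref_pos = integer(),
                      ref_base = character(), read_id = integer(),
                      qname = character(), category = character(),
                      gap_kind = character(), read_base = character(),
                      base_qual = integer(), qpos = integer(),
                      gap_len = integer())
  if (nrow(reads) == 0L) return(empty)
  missing_chrom <- setdiff(unique(reads$chrom), names(ref))
  if (length(missing_chrom))
    stop("reference has no chromosome ", missing_chrom[1L])
  ct <- cigar_table(reads$cigar, reads$pos, seq_len(nrow(reads)))
  ct[, chrom := reads$chrom[read_id]]

  m <- ct[op %chin% c("M", "=", "X")]
  obs_m <- NULL
  if (nrow(m)) {
    idx <- rep(seq_len(nrow(m)), m$len)
    off <- sequence(m$len) - 1L
    obs_m <- data.table(
      chrom = m$chrom[idx],
      ref_pos = m$ref_start[idx] + off,
      read_id = m$read_id[idx],
      qpos = m$q_start[idx] + off,
      gap_kind = "none", gap_len = 0L
    )
    k <- obs_m$qpos + 1L
    obs_m[, read_base := substring(reads$seq[read_id], k, k)]
    obs_m[, base_qual := .QUAL_MAP[substring(reads$qual[read_id], k, k)]]
  }

  d <- ct[op == "D"]
  obs_d <- NULL
  if (nrow(d)) {
    idx <- rep(seq_len(nrow(d)), d$len)
    off <- sequence(d$len) - 1L
    obs_d <- data.table(
      chrom = d$chrom[idx], ref_pos = d$ref_start[idx] + off,
      read_id = d$read_id[idx], qpos = d$q_start[idx],
      gap_kind = "deletion", gap_len = d$len[idx],
      read_base = NA_character_, base_qual = NA_integer_
    )
  }

  i <- ct[op == "I" & ref_start - 1L >= reads$pos[read_id]]
  obs_i <- NULL
  if (nrow(i)) {
    obs_i <- data.table(
      chrom = i$chrom, ref_pos = i$ref_start - 1L, read_id = i$read_id,
      qpos = i$q_start, gap_kind = "insertion", gap_len = i$len,
      read_base = NA_character_, base_qual = NA_integer_
    )
  }

  obs <- rbindlist(list(obs_m, obs_d, obs_i), use.names = TRUE)
  if (!is.null(region))
    obs <- obs[chrom == region$chrom & ref_pos >= region$start &
                 ref_pos < region$end]
  if (nrow(obs) == 0L) return(empty)
  # reference base per column, chromosome by chromosome
  obs[, ref_base := {
    cs <- strsplit(ref_slice(ref, .BY[[1L]], min(ref_pos), max(ref_pos) + 1L),
                   "", fixed = TRUE)[[1L]]
    cs[ref_pos - min(ref_pos) + 1L]
  }, by = chrom]
  obs[, category := fifelse(gap_kind != "none", "gap",
                            fifelse(read_base == ref_base,
                                    "concordant", "discordant"))]
  obs[, qname := reads$qname[read_id]]
  setcolorder(obs, c("chrom", "ref_pos", "ref_base", "read_id", "qname",
                     "category", "gap_kind", "read_base", "base_qual",
                     "qpos", "gap_len"))
  setorder(obs, chrom, ref_pos, read_id)
  obs[]
}

#' Is a pileup column triggered for examination?
#'
#' A column is examined further when at least one observation disagrees with
#' the reference (a mismatch or a gap).
#'
#' @param col observation `data.table` rows of a single column.
#' @return Logical flag.
#' @export
column_is_triggered <- function(col) {
  any(col$category != "concordant")
}

#' Gap ratio of a pileup column
#'
#' Fraction of the column's observations that are gaps.
#'
#' @param col observation rows of a single (non-empty) column.
#' @return Real in `[0, 1]`.
#' @export
gap_ratio <- function(col) {
  if (nrow(col) == 0L) stop("gap_ratio: empty column")
  mean(col$category == "gap")
}

#' Homopolymer context check (Step 1)
#'
#' TRUE when the examined position sits in (or immediately adjacent to) a
#' run of at least `min_len` identical bases in the reference, or when any
#' aligned read's base at the column belongs to a run of at least `min_len`
#' identical bases in the read sequence (inserted bases count through their
#' query offsets). Deletion observations carry no base and contribute no
#' read-side run.
#'
#' @param col observation rows of a single column.
#' @param ref reference genome.
#' @param reads the `read_set` the observations index into.
#' @param min_len minimal run length (default 3).
#' @return Logical flag.
#' @export
has_homopolymer_context <- function(col, ref, reads, min_len = 3L) {
  stopifnot(nrow(col) >= 1L)
  chrom <- col$chrom[1L]; p <- col$ref_pos[1L]
  L <- ref_lengths(ref)[[chrom]]
  win_a <- max(0L, p - (min_len + 1L))
  win_b <- min(L, p + min_len + 2L)
  slice <- ref_slice(ref, chrom, win_a, win_b)
  at <- intersect((p - 1L):(p + 1L), win_a:(win_b - 1L)) - win_a
  if (run_length_at(slice, at) >= min_len) return(TRUE)
  base_obs <- col[gap_kind == "none"]
  for (j in seq_len(nrow(base_obs))) {
    if (run_length_at(reads$seq[base_obs$read_id[j]],
                      base_obs$qpos[j]) >= min_len)
      return(TRUE)
  }
  ins_obs <- col[gap_kind == "insertion"]
  for (j in seq_len(nrow(ins_obs))) {
    at <- ins_obs$qpos[j] + seq_len(ins_obs$gap_len[j]) - 1L
    if (run_length_at(reads$seq[ins_obs$read_id[j]], at) >= min_len)
      return(TRUE)
  }
  FALSE
}

#' Classify improper gaps at one column (Step 2)
#'
#' Returns the column's gap observations when — and only when — the column
#' is triggered, has homopolymer context, and its gap ratio is strictly
#' between 0 and the threshold. A ratio of exactly the threshold (or above)
#' retains the gaps as real indel candidates; a column whose observations
#' are all gaps (ratio 1) is likewise never improper.
#'
#' @param col observation rows of a single column.
#' @param ref reference genome.
#' @param reads the `read_set`.
#' @param config an [aos_config()].
#' @return Gap-observation rows (possibly zero rows).
#' @export
classify_improper_gaps <- function(col, ref, reads, config = aos_config()) {
  gaps <- col[category == "gap"]
  if (nrow(gaps) == 0L) return(gaps)
  r <- gap_ratio(col)
  if (!(r > 0 && r < config$gap_ratio_threshold)) return(gaps[0L])
  if (!column_is_triggered(col)) return(gaps[0L])
  if (!has_homopolymer_context(col, ref, reads, config$min_homopolymer))
    return(gaps[0L])
  gaps
}
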