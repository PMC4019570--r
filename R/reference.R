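# Reference genome access. A reference is a named Biostrings::DNAStringSet;
# all lookups use 0-based half-open coordinates.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet` (one entry per chromosome).
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Write a reference genome to FASTA
#'
#' @param ref named `DNAStringSet` or named character vector.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  if (is.character(ref)) ref <- Biostrings::DNAStringSet(ref)
  Biostrings::writeXStringSet(ref, path)
  invisible(path)
}

#' Extract reference bases over a half-open interval
#'
#' `ref_slice(ref, "chr1", a, b)` returns exactly `b - a` bases.
#'
#' @param ref named `DNAStringSet`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Character scalar of length `end - start`.
#' @export
ref_slice <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) stop("reference has no chromosome ", chrom)
  stopifnot(start >= 0, end <= length(ref[[chrom]]), start <= end)
  as.character(Biostrings::subseq(ref[[chrom]], start + 1L, end))
}

#' @rdname ref_slice
#' @param pos 0-based position.
#' @return `ref_base`: single base at `pos`.
#' @export
ref_base <- function(ref, chrom, pos) {
  ref_slice(ref, chrom, pos, pos + 1L)
}

#' Reference sequence lengths
#'
#' @param ref named `DNAStringSet`.
#' @return Named integer vector of chromosome lengths.
#' @export
ref_lengths <- function(ref) {
  setNames(Biostrings::width(ref), names(ref))
}

# Per-position homopolymer context for one chromosome: for each 0-based
# position p, the length of the longest run of identical bases that contains
# p or is immediately adjacent to it (the run ending at p-1 or starting at
# p+1). Used by the Step-1 homopolymer gate.
hp_context_lengths <- function(ref, chrom) {
  s <- strsplit(as.character(ref[[chrom]]), "", fixed = TRUE)[[1]]
  r <- rle(s)
  runlen <- rep(r$lengths, r$lengths)        # run length at each position
  run_id <- rep(seq_along(r$lengths), r$lengths)
  n <- length(s)
  left <- c(0L, runlen[-n])                  # run length at p-1
  right <- c(runlen[-1L], 0L)                # run length at p+1
  same_left <- c(FALSE, run_id[-n] == run_id[-1L])
  same_right <- c(run_id[-n] == run_id[-1L], FALSE)
  left[same_left] <- 0L                      # only *adjacent* (different) runs
  right[same_right] <- 0L
  pmax(runlen, left, right)
}

# Longest run of identical characters in `x` (character scalar) that
# contains any of the 0-based offsets in `at`. Brute-force helper shared by
# the read-side homopolymer check; also serves tests as the run-length oracle.
run_length_at <- function(x, at) {
  s <- strsplit(x, "", fixed = TRUE)[[1]]
  if (!length(s)) return(0L)
  r <- rle(s)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  at <- at[at >= 0L & at < length(s)]
  if (!length(at)) return(0L)
  max(r$lengths[unique(run_id[at + 1L])])
}
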