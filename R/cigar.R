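# CIGAR utilities. Ops follow the SAM spec: M/=/X consume both reference and
# query, I/S consume query only, D/N consume reference only, H consumes
# neither. All coordinates 0-based.

.REF_OPS <- c("M", "=", "X", "D", "N")
.QRY_OPS <- c("M", "=", "X", "I", "S")

#' Parse CIGAR strings into an op table
#'
#' Explodes a vector of CIGAR strings into one row per op with cumulative
#' reference and query offsets, the form every pileup/repair routine in the
#' package works from.
#'
#' @param cigar character vector of CIGAR strings.
#' @param pos integer vector of 0-based leftmost reference coordinates,
#'   recycled along `cigar`.
#' @param read_id optional identifier column (defaults to `seq_along(cigar)`).
#' @return A `data.table` with columns `read_id`, `op`, `len`,
#'   `ref_start`/`ref_end` (0-based half-open reference span of the op;
#'   zero-width for ops that do not consume reference) and
#'   `q_start`/`q_end` (0-based half-open query span; zero-width for ops that
#'   do not consume query).
#' @export
cigar_table <- function(cigar, pos = 0L, read_id = seq_along(cigar)) {
  stopifnot(length(cigar) > 0L)
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  n_ops <- lengths(ops)
  pos <- rep(as.integer(pos), length.out = length(cigar))
  dt <- data.table(
    read_id = rep(read_id, n_ops),
    op = unlist(ops, use.names = FALSE),
    len = unlist(lens, use.names = FALSE),
    pos0 = rep(pos, n_ops)
  )
  rc <- dt$len * (dt$op %chin% .REF_OPS)
  qc <- dt$len * (dt$op %chin% .QRY_OPS)
  # per-read cumulative walk via one global cumsum (rows are grouped by
  # read): subtract each read's running total at its first row
  first <- which(!duplicated(dt$read_id))
  cs_r <- cumsum(rc); cs_q <- cumsum(qc)
  base_r <- rep(cs_r[first] - rc[first], diff(c(first, nrow(dt) + 1L)))
  base_q <- rep(cs_q[first] - qc[first], diff(c(first, nrow(dt) + 1L)))
  dt[, `:=`(
    ref_start = as.integer(pos0 + (cs_r - rc) - base_r),
    q_start = as.integer((cs_q - qc) - base_q)
  )]
  dt[, `:=`(ref_end = ref_start + as.integer(rc),
            q_end = q_start + as.integer(qc))]
  dt[, pos0 := NULL]
  dt[]
}

#' Reference and query widths of CIGAR strings
#'
#' @param cigar character vector of CIGAR strings.
#' @return Integer vector: number of reference (resp. query) bases consumed.
#' @export
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' @rdname cigar_ref_width
#' @export
cigar_query_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
}

# Collapse an op/len table (in order) back into a CIGAR string, merging
# adjacent ops of equal type and dropping zero-length ops.
collapse_cigar <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (!length(op)) return("")
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  len <- as.vector(tapply(len, grp, sum))
  op <- op[!duplicated(grp)]
  paste0(len, op, collapse = "")
}
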