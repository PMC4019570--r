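# Aligned-read container and SAM/BAM I/O.
#
# Reads live in a data.table ("read_set") with one row per primary mapped
# read and columns:
#   qname   read name
#   chrom   reference sequence name
#   pos     0-based leftmost aligned reference coordinate
#   strand  "+" or "-"
#   mapq    mapping quality
#   cigar   CIGAR string
#   seq     read bases
#   qual    Phred+33 quality string
#   as_score integer alignment score (SAM AS tag); -Inf when absent
# A named integer vector of reference sequence lengths is carried in the
# "sq" attribute so headers can be regenerated on write.

.SAM_UNMAPPED <- 4L
.SAM_REVERSE <- 16L
.SAM_SECONDARY <- 256L
.SAM_SUPPLEMENTARY <- 2048L

#' Construct a read set
#'
#' @param dt data.frame/data.table with the read-set columns (see Details).
#' @param sq named integer vector of reference sequence lengths.
#' @return A `read_set` (data.table) sorted by `(chrom, pos)`.
#' @details Required columns: `qname`, `chrom`, `pos` (0-based), `strand`,
#'   `mapq`, `cigar`, `seq`, `qual`, `as_score`. Each read's query-consuming
#'   CIGAR width must equal `nchar(seq)` and `nchar(qual)`.
#' @export
read_set <- function(dt, sq = NULL) {
  dt <- as.data.table(dt)
  need <- c("qname", "chrom", "pos", "strand", "mapq", "cigar", "seq", "qual",
            "as_score")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("read_set: missing columns: ", paste(miss, collapse = ", "))
  dt[, pos := as.integer(pos)]
  dt[, as_score := as.numeric(as_score)]
  setcolorder(dt, need)
  # canonical order: qname breaks coordinate ties, so any round-trip
  # (including through samtools sort) restores an identical table
  setorder(dt, chrom, pos, qname)
  setattr(dt, "sq", sq)
  setattr(dt, "class", c("read_set", class(dt)))
  validate_reads(dt)
  dt
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads on %d reference sequence(s)\n",
              nrow(x), data.table::uniqueN(x$chrom)))
  NextMethod()
}

#' Validate read-set invariants
#'
#' Checks that every read's query-consuming CIGAR width equals its sequence
#' and quality lengths and that strands are "+"/"-".
#'
#' @param reads a `read_set`.
#' @return `reads`, invisibly; errors on violation.
#' @export
validate_reads <- function(reads) {
  if (nrow(reads) == 0L) return(invisible(reads))
  if (!all(reads$strand %chin% c("+", "-")))
    stop("read_set: strand must be '+' or '-'")
  qw <- cigar_query_width(reads$cigar)
  bad <- which(qw != nchar(reads$seq) | qw != nchar(reads$qual))
  if (length(bad))
    stop("read_set: CIGAR/seq length mismatch for read(s) ",
         paste(head(reads$qname[bad], 5L), collapse = ", "))
  invisible(reads)
}

.check_sorted <- function(chrom, pos, what = "input") {
  if (length(pos) < 2L) return(invisible(TRUE))
  new_chrom <- chrom != shift(chrom)
  new_chrom[1L] <- TRUE
  bad <- which(!new_chrom & pos < shift(pos))
  if (length(bad))
    stop(sprintf("%s is not coordinate-sorted: record %d (%s:%d) after %s:%d",
                 what, bad[1L], chrom[bad[1L]], pos[bad[1L]],
                 chrom[bad[1L] - 1L], pos[bad[1L] - 1L]))
  # a chromosome block must not reappear later
  blocks <- rle(chrom)$values
  if (anyDuplicated(blocks))
    stop(what, " is not coordinate-sorted: chromosome ",
         blocks[anyDuplicated(blocks)], " occurs in disjoint blocks")
  invisible(TRUE)
}

#' Read primary mapped alignments from SAM or BAM
#'
#' Unmapped, secondary and supplementary records are dropped (counts
#' reported via `message()`). Reads without an `AS` tag get score `-Inf`.
#' Positions are converted to the package's 0-based convention. Input must be
#' coordinate-sorted; a decreasing position is a hard error naming the record.
#'
#' @param path SAM (text) or BAM file.
#' @param region optional single [region()]; only reads whose aligned span
#'   overlaps it are returned (BAM access uses the index when present).
#' @return A `read_set`.
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    out <- .read_bam(path, region)
  } else {
    out <- .read_sam_text(path, region)
  }
  out
}

.read_sam_text <- function(path, region) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  sq <- .parse_sq(hdr)
  if (!length(body)) {
    return(read_set(.empty_reads(), sq = sq))
  }
  f <- tstrsplit(body, "\t", fixed = TRUE, names = FALSE, keep = 1:11)
  flag <- as.integer(f[[2]])
  as_tag <- rep(NA_integer_, length(body))
  has <- grepl("\tAS:i:", body, fixed = TRUE)
  as_tag[has] <- as.integer(sub(".*\tAS:i:(-?[0-9]+).*", "\\1", body[has]))
  dt <- data.table(
    qname = f[[1]], flag = flag, chrom = f[[3]],
    pos = as.integer(f[[4]]) - 1L, mapq = as.integer(f[[5]]),
    cigar = f[[6]], seq = f[[10]], qual = f[[11]], as_tag = as_tag
  )
  .finish_reads(dt, sq, region, path)
}

.parse_sq <- function(hdr) {
  sq_lines <- hdr[startsWith(hdr, "@SQ")]
  if (!length(sq_lines)) return(NULL)
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq_lines)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq_lines))
  setNames(ln, sn)
}

.read_bam <- function(path, region) {
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (!is.null(region) && file.exists(paste0(path, ".bai"))) {
    which <- GenomicRanges::GRanges(region$chrom,
                                    IRanges::IRanges(region$start + 1L, region$end))
    param <- Rsamtools::ScanBamParam(what = what, tag = "AS", which = which)
  } else {
    param <- Rsamtools::ScanBamParam(what = what, tag = "AS")
  }
  res <- Rsamtools::scanBam(path, param = param)
  dt <- rbindlist(lapply(res, function(x) {
    as_tag <- if (is.null(x$tag$AS)) rep(NA_integer_, length(x$qname))
              else as.integer(x$tag$AS)
    data.table(
      qname = as.character(x$qname), flag = as.integer(x$flag),
      chrom = as.character(x$rname), pos = as.integer(x$pos) - 1L,
      mapq = as.integer(x$mapq), cigar = as.character(x$cigar),
      seq = as.character(x$seq), qual = as.character(x$qual),
      as_tag = as_tag)
  }))
  .finish_reads(dt, hdr, region, path)
}

.finish_reads <- function(dt, sq, region, path) {
  drop_unmapped <- bitwAnd(dt$flag, .SAM_UNMAPPED) > 0L | is.na(dt$pos) |
    dt$cigar == "*"
  drop_nonprimary <- bitwAnd(dt$flag, .SAM_SECONDARY + .SAM_SUPPLEMENTARY) > 0L
  if (any(drop_unmapped))
    message(sum(drop_unmapped), " unmapped record(s) dropped")
  if (any(drop_nonprimary & !drop_unmapped))
    message(sum(drop_nonprimary & !drop_unmapped),
            " secondary/supplementary record(s) dropped")
  dt <- dt[!(drop_unmapped | drop_nonprimary)]
  .check_sorted(dt$chrom, dt$pos, what = path)
  if (anyNA(dt$as_tag) && nrow(dt))
    message(sum(is.na(dt$as_tag)), " read(s) lack an AS tag; scored -Inf")
  dt[, as_score := ifelse(is.na(as_tag), -Inf, as.numeric(as_tag))]
  dt[, strand := ifelse(bitwAnd(flag, .SAM_REVERSE) > 0L, "-", "+")]
  dt[, c("flag", "as_tag") := NULL]
  if (!is.null(region)) {
    rw <- cigar_ref_width(dt$cigar)
    dt <- dt[chrom == region$chrom & pos < region$end & pos + rw > region$start]
  }
  read_set(dt, sq = sq)
}

.empty_reads <- function() {
  data.table(qname = character(), chrom = character(), pos = integer(),
             strand = character(), mapq = integer(), cigar = character(),
             seq = character(), qual = character(), as_score = numeric())
}

#' Write alignments to SAM or BAM
#'
#' Emits a coordinate-sorted SAM (or BAM, via samtools conversion through
#' `Rsamtools::asBam`, with index) that round-trips through
#' [read_alignments()] field-for-field. An unsorted read set is a hard error.
#'
#' @param reads a `read_set`.
#' @param path output path ending in `.sam` or `.bam`.
#' @param sq named integer vector of reference lengths for the header;
#'   defaults to the read set's `sq` attribute.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path, sq = attr(reads, "sq")) {
  .check_sorted(reads$chrom, reads$pos, what = "read stream")
  if (is.null(sq)) {
    rw <- if (nrow(reads)) cigar_ref_width(reads$cigar) else integer()
    ends <- if (nrow(reads)) tapply(reads$pos + rw, reads$chrom, max) else NULL
    sq <- setNames(as.integer(ends), names(ends))
  }
  as_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  sam_path <- if (as_bam) tempfile(fileext = ".sam") else path
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  con <- file(sam_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (nrow(reads)) {
    flag <- ifelse(reads$strand == "-", .SAM_REVERSE, 0L)
    tag <- ifelse(is.finite(reads$as_score),
                  sprintf("\tAS:i:%d", as.integer(reads$as_score)), "")
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                       reads$qname, flag, reads$chrom, reads$pos + 1L,
                       reads$mapq, reads$cigar, reads$seq, reads$qual, tag),
               con)
  }
  if (as_bam) {
    close(con); on.exit()
    Rsamtools::asBam(sam_path, sub("\\.bam$", "", path),
                     overwrite = TRUE, indexDestination = TRUE)
    unlink(sam_path)
  }
  invisible(path)
}
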