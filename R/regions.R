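# Target regions. Internally a region set is a data.table(chrom, start, end)
# in 0-based half-open coordinates (the BED convention, kept as-is).

#' Construct a region
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval, `start < end`.
#' @return A one-row region `data.table`.
#' @export
region <- function(chrom, start, end) {
  stopifnot(all(start < end), all(start >= 0))
  data.table(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end))
}

#' Read target regions from BED
#'
#' BED intervals are 0-based half-open and are kept in that convention.
#' Overlapping or bookended intervals are merged with a warning.
#'
#' @param path BED file (3+ columns, tab-separated).
#' @return A region `data.table` sorted by `(chrom, start)`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = FALSE, select = 1:3,
              col.names = c("chrom", "start", "end"))
  if (nrow(dt) == 0L) return(region("chr0", 0, 1)[0])
  stopifnot(all(dt$start < dt$end))
  merged <- merge_regions(dt)
  if (nrow(merged) < nrow(dt))
    warning(sprintf("%d overlapping BED interval(s) merged into %d",
                    nrow(dt), nrow(merged)))
  merged
}

#' Merge overlapping intervals in a region set
#'
#' @param regions region `data.table`.
#' @return Disjoint, sorted region `data.table`.
#' @export
merge_regions <- function(regions) {
  regions <- as.data.table(regions)
  out <- regions[, {
    ir <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }, by = chrom]
  setorder(out, chrom, start)
  out[]
}

#' Write a region set to BED
#'
#' @param regions region `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  fwrite(regions[, .(chrom, start, end)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Which positions fall inside a region set?
#'
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @param regions region `data.table`, or `NULL` (everything is inside).
#' @return Logical vector.
#' @export
in_regions <- function(chrom, pos, regions) {
  if (is.null(regions)) return(rep(TRUE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (cc in unique(regions$chrom)) {
    r <- regions[chrom == cc]
    ir <- IRanges::IRanges(r$start + 1L, r$end)
    idx <- which(chrom == cc)
    if (length(idx))
      out[idx] <- IRanges::overlapsAny(
        IRanges::IRanges(pos[idx] + 1L, pos[idx] + 1L), ir)
  }
  out
}
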