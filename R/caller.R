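# Minimal pileup-frequency SNP caller.
#
# A deliberately simple stand-in for a full variant caller so the
# dedup -> gap-repair pipeline has a testable downstream consumer: a site is
# called when enough quality-passing base observations exist and some
# non-reference allele reaches a frequency threshold. Users with a real
# caller can point it at the written alignments instead (see
# `run_pipeline(caller_hook=)`).
#
# Allele fractions divide by base observations only: gap observations are
# not bases and appear in neither numerator nor denominator (the same
# convention under which a depth-11 column with 3 alt reads is a 27.27%
# site). Site depth is likewise the quality-passing base-observation count,
# which is how deletion repair can rescue borderline-depth sites.

#' Caller configuration
#'
#' @param min_depth minimal quality-passing base depth (default 8).
#' @param min_alt_fraction minimal alt-allele fraction to call (default 0.2).
#' @param min_base_quality bases with Phred quality below this are ignored
#'   (default 10).
#' @param hom_fraction alt fraction at or above which the genotype is
#'   called homozygous (default 0.75).
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_depth = 8L, min_alt_fraction = 0.2,
                          min_base_quality = 10L, hom_fraction = 0.75) {
  stopifnot(min_alt_fraction > 0, min_alt_fraction < hom_fraction,
            hom_fraction <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_fraction = min_alt_fraction,
                 min_base_quality = as.integer(min_base_quality),
                 hom_fraction = hom_fraction),
            class = "caller_config")
}

#' Allele fraction at one pileup column
#'
#' Percentage of quality-passing base observations carrying `allele`.
#'
#' @param col observation rows ([build_pileup()]) of a single column.
#' @param allele base whose fraction is wanted.
#' @param min_base_quality quality cutoff (observations below are ignored).
#' @return Percentage in `[0, 100]`; error when no observation qualifies.
#' @export
allele_fraction <- function(col, allele, min_base_quality = 10L) {
  bases <- col[gap_kind == "none" & base_qual >= min_base_quality]
  if (nrow(bases) == 0L)
    stop("allele_fraction: no qualifying base observations")
  100 * mean(bases$read_base == allele)
}

#' Call SNPs from a pileup observation table
#'
#' Emits at most one biallelic SNP per column: the highest-fraction
#' non-reference allele (ties broken by base order) where quality-passing
#' base depth reaches `min_depth` and the fraction reaches
#' `min_alt_fraction`; fractions at or above `hom_fraction` are genotyped
#' "hom", otherwise "het".
#'
#' @param pileup observation `data.table` from [build_pileup()].
#' @param config a [caller_config()].
#' @return A variant `data.table` ([variant_set()]).
#' @export
call_snps <- function(pileup, config = caller_config()) {
  bases <- pileup[gap_kind == "none" & base_qual >= config$min_base_quality &
                    read_base %chin% .BASES]
  if (nrow(bases) == 0L) return(variant_set(data.table()))
  counts <- bases[, .N, by = .(chrom, ref_pos, ref_base, read_base)]
  counts[, depth := sum(N), by = .(chrom, ref_pos)]
  alts <- counts[read_base != ref_base & depth >= config$min_depth]
  if (nrow(alts) == 0L) return(variant_set(data.table()))
  alts[, frac := N / depth]
  setorder(alts, chrom, ref_pos, -frac, read_base)
  best <- alts[, .SD[1L], by = .(chrom, ref_pos)]
  best <- best[frac >= config$min_alt_fraction]
  variant_set(best[, .(chrom, pos = ref_pos, ref = ref_base, alt = read_base,
                       genotype = ifelse(frac >= config$hom_fraction,
                                         "hom", "het"),
                       depth = depth, alt_fraction = frac)])
}

#' Call SNPs from a read set (fast path)
#'
#' Pipeline-scale equivalent of [build_pileup()] + [call_snps()]: the reads
#' are written to an indexed BAM and counted with `Rsamtools::pileup`
#' (htslib), then the same thresholds are applied. The two routes are
#' cross-checked in the test suite.
#'
#' @param reads a coordinate-sorted `read_set`.
#' @param ref reference genome (`DNAStringSet`).
#' @param config a [caller_config()].
#' @param regions optional region `data.table` restricting calls.
#' @return A variant `data.table`.
#' @export
call_snps_fast <- function(reads, ref, config = caller_config(),
                           regions = NULL) {
  if (nrow(reads) == 0L) return(variant_set(data.table()))
  bam <- tempfile(fileext = ".bam")
  write_alignments(reads, bam, sq = ref_lengths(ref)[unique(reads$chrom)])
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  pp <- Rsamtools::PileupParam(
    max_depth = 250000L, min_base_quality = config$min_base_quality,
    min_mapq = 0L, min_nucleotide_depth = 0L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE, include_deletions = FALSE,
    include_insertions = FALSE)
  counts <- as.data.table(Rsamtools::pileup(bam, pileupParam = pp))
  if (nrow(counts) == 0L) return(variant_set(data.table()))
  counts <- counts[nucleotide %in% .BASES,
                   .(chrom = as.character(seqnames), ref_pos = pos - 1L,
                     read_base = as.character(nucleotide), N = count)]
  counts[, depth := sum(N), by = .(chrom, ref_pos)]
  counts[, ref_base := {
    cs <- strsplit(ref_slice(ref, .BY[[1L]], min(ref_pos), max(ref_pos) + 1L),
                   "", fixed = TRUE)[[1L]]
    cs[ref_pos - min(ref_pos) + 1L]
  }, by = chrom]
  alts <- counts[read_base != ref_base & depth >= config$min_depth]
  if (nrow(alts) == 0L) return(variant_set(data.table()))
  alts[, frac := N / depth]
  setorder(alts, chrom, ref_pos, -frac, read_base)
  best <- alts[, .SD[1L], by = .(chrom, ref_pos)]
  best <- best[frac >= config$min_alt_fraction]
  calls <- variant_set(best[, .(chrom, pos = ref_pos, ref = ref_base,
                                alt = read_base,
                                genotype = ifelse(frac >= config$hom_fraction,
                                                  "hom", "het"),
                                depth = depth, alt_fraction = frac)])
  if (!is.null(regions)) calls <- calls[in_regions(chrom, pos, regions)]
  calls
}
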