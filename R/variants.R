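# SNP call sets. A variant set is a data.table with one row per biallelic
# SNP: chrom, pos (0-based), ref, alt (single bases), genotype ("het"/"hom"),
# depth, alt_fraction. VCF files are 1-based; conversion happens here only.

.BASES <- c("A", "C", "G", "T")

#' Construct a variant (SNP) set
#'
#' @param dt data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`;
#'   optionally `genotype` ("het"/"hom"), `depth`, `alt_fraction`.
#' @return Sorted, de-duplicated variant `data.table`.
#' @export
variant_set <- function(dt) {
  dt <- as.data.table(dt)
  if (!nrow(dt)) {
    dt <- data.table(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), genotype = character(),
                     depth = integer(), alt_fraction = numeric())
    return(dt)
  }
  for (col in c("genotype", "depth", "alt_fraction"))
    if (!col %in% names(dt)) dt[, (col) := NA]
  dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
               ref = as.character(ref), alt = as.character(alt),
               genotype = as.character(genotype), depth = as.integer(depth),
               alt_fraction = as.numeric(alt_fraction))]
  stopifnot(all(dt$ref %chin% .BASES), all(dt$alt %chin% .BASES),
            all(dt$ref != dt$alt))
  bad_af <- !is.na(dt$alt_fraction) &
    (dt$alt_fraction < 0 | dt$alt_fraction > 1)
  if (any(bad_af)) stop("alt_fraction outside [0,1]")
  dt <- unique(dt, by = c("chrom", "pos", "ref", "alt"))
  setorder(dt, chrom, pos, alt)
  dt[]
}

#' Read SNPs from a VCF file
#'
#' Multi-allelic records are split into biallelic rows; non-SNP records
#' (indels, MNVs, symbolic alleles) are skipped with a reported count.
#' Positions are converted to 0-based. Genotype class is taken from the
#' first sample's `GT` (all non-reference alleles identical and no reference
#' allele present => "hom", otherwise "het"); `DP` and `AF` are carried
#' through when present.
#'
#' @param path VCF 4.x file.
#' @param regions optional region `data.table`; only SNPs inside are kept.
#' @return A variant `data.table`.
#' @export
read_variants <- function(path, regions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  is_snp <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %chin% .BASES & alt %chin% .BASES
  n_skip <- sum(!is_snp)
  if (n_skip) message(n_skip, " non-SNP record(s) skipped")
  geno <- rep(NA_character_, length(ref))
  depth <- rep(NA_integer_, length(ref))
  af <- rep(NA_real_, length(ref))
  g <- VariantAnnotation::geno(vcf)
  if ("GT" %in% names(g) && ncol(g$GT) >= 1L) {
    gt <- as.character(g$GT[, 1L])
    alleles <- strsplit(gt, "[/|]")
    geno <- vapply(alleles, function(a) {
      a <- a[a != "."]
      if (!length(a)) return(NA_character_)
      if (all(a != "0") && length(unique(a)) == 1L) "hom" else "het"
    }, character(1))
  }
  if ("DP" %in% names(g) && ncol(g$DP) >= 1L) depth <- as.integer(g$DP[, 1L])
  if ("AF" %in% names(g) && ncol(g$AF) >= 1L) af <- as.numeric(g$AF[, 1L])
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,   # VCF is 1-based
    ref = ref, alt = alt, genotype = geno, depth = depth, alt_fraction = af
  )[is_snp]
  if (!is.null(regions)) dt <- dt[in_regions(chrom, pos, regions)]
  variant_set(dt)
}

#' Write a variant set to VCF
#'
#' Writes a minimal single-sample VCF 4.2 (1-based positions) with
#' `GT:DP:AF` genotypes that round-trips through [read_variants()].
#'
#' @param calls variant `data.table`.
#' @param path output path.
#' @param sample_name sample column name.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variants <- function(calls, path, sample_name = "SAMPLE",
                           contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alt allele fraction">'
  )
  if (is.null(contigs) && nrow(calls))
    contigs <- setNames(as.integer(tapply(calls$pos + 1L, calls$chrom, max)),
                        sort(unique(calls$chrom)))
  if (length(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_name, sep = "\t"))
  lines <- hdr
  if (nrow(calls)) {
    calls <- variant_set(calls)
    gt <- ifelse(is.na(calls$genotype), "./.",
                 ifelse(calls$genotype == "hom", "1/1", "0/1"))
    dp <- ifelse(is.na(calls$depth), ".", as.character(calls$depth))
    af <- ifelse(is.na(calls$alt_fraction), ".",
                 sprintf("%.6g", calls$alt_fraction))
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AF\t%s:%s:%s",
                              calls$chrom, calls$pos + 1L, calls$ref,
                              calls$alt, gt, dp, af))
  }
  writeLines(lines, path)
  invisible(path)
}

# Site-level key used by the comparison metrics: chrom:pos:alt.
site_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$alt, sep = ":")
}
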