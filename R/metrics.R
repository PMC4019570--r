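# Call-set evaluation: FP/FN rates against control sets, Ti/Tv, het/hom,
# known-site rate, overlap, genotype consensus, sensitivity/specificity and
# depth-saturation curves. All site-level comparisons key on
# (chrom, pos, alt); consensus additionally compares the genotype class.

#' False-positive rate against a control call set
#'
#' Percentage of calls absent (by site) from the control, both sets first
#' restricted to the target regions.
#'
#' @param calls,control variant `data.table`s.
#' @param regions optional region `data.table` both sets are restricted to.
#' @return Percentage.
#' @export
fp_rate <- function(calls, control, regions = NULL) {
  calls <- restrict_calls(calls, regions)
  control <- restrict_calls(control, regions)
  if (nrow(calls) == 0L) stop("fp_rate: empty call set")
  100 * mean(!site_key(calls) %chin% site_key(control))
}

#' False-negative rate against a genotyping control
#'
#' Percentage of control sites (inside the regions) missing from the calls.
#'
#' @inheritParams fp_rate
#' @return Percentage.
#' @export
fn_rate <- function(calls, control, regions = NULL) {
  calls <- restrict_calls(calls, regions)
  control <- restrict_calls(control, regions)
  if (nrow(control) == 0L) stop("fn_rate: empty control set")
  100 * mean(!site_key(control) %chin% site_key(calls))
}

#' Site-level overlap with a control set
#'
#' Percentage of calls also present in the control; at site level this is
#' the complement of [fp_rate()].
#'
#' @inheritParams fp_rate
#' @return Percentage.
#' @export
overlap_rate <- function(calls, control, regions = NULL) {
  100 - fp_rate(calls, control, regions)
}

#' Known-site (database) rate
#'
#' Percentage of calls present in a known-sites set.
#'
#' @param calls variant `data.table`.
#' @param known_sites variant `data.table` of known SNPs.
#' @return Percentage.
#' @export
db_rate <- function(calls, known_sites) {
  if (nrow(calls) == 0L) stop("db_rate: empty call set")
  100 * mean(site_key(calls) %chin% site_key(known_sites))
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; every other ref/alt pairing is a
#' transversion. With zero transversions the ratio is undefined and `NA`
#' is returned (flagged, not a division error).
#'
#' @param calls variant `data.table`.
#' @return Real, or `NA_real_` when undefined.
#' @export
titv_ratio <- function(calls) {
  if (nrow(calls) == 0L) return(NA_real_)
  ti <- is_transition(calls$ref, calls$alt)
  if (all(ti)) return(NA_real_)
  sum(ti) / sum(!ti)
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Heterozygous/homozygous ratio
#'
#' @param calls variant `data.table` with genotype classes.
#' @return Real, or `NA_real_` when there are no homozygous calls.
#' @export
het_hom_ratio <- function(calls) {
  n_het <- sum(calls$genotype == "het", na.rm = TRUE)
  n_hom <- sum(calls$genotype == "hom", na.rm = TRUE)
  if (n_hom == 0L) return(NA_real_)
  n_het / n_hom
}

#' Genotype consensus at shared sites
#'
#' Percentage of sites present in both sets (by chrom/pos/alt) whose
#' genotype class agrees.
#'
#' @param calls,genotyped variant `data.table`s with genotype classes.
#' @return Percentage, or `NA_real_` when no site is shared.
#' @export
consensus_rate <- function(calls, genotyped) {
  m <- merge(calls[, .(chrom, pos, alt, genotype)],
             genotyped[, .(chrom, pos, alt, genotype)],
             by = c("chrom", "pos", "alt"), suffixes = c("", ".ctl"))
  if (nrow(m) == 0L) return(NA_real_)
  100 * mean(m$genotype == m$genotype.ctl)
}

#' Sensitivity and specificity against a truth set
#'
#' Sensitivity is the percentage of truth-positive sites detected.
#' Specificity here is the percentage of calls that are truth sites
#' (100 - FP rate over the evaluated call set) — the formula is recorded in
#' the result so numbers are never silently incomparable.
#'
#' @param calls variant `data.table`.
#' @param truth truth variant `data.table` (positives).
#' @param regions optional region restriction.
#' @return `list(sensitivity=, specificity=, specificity_definition=)`.
#' @export
sensitivity_specificity <- function(calls, truth, regions = NULL) {
  calls <- restrict_calls(calls, regions)
  truth <- restrict_calls(truth, regions)
  if (nrow(truth) == 0L) stop("sensitivity_specificity: empty truth set")
  sens <- 100 * mean(site_key(truth) %chin% site_key(calls))
  spec <- if (nrow(calls)) 100 * mean(site_key(calls) %chin% site_key(truth))
          else NA_real_
  list(sensitivity = sens, specificity = spec,
       specificity_definition = "100 - FP rate over the evaluated call set")
}

restrict_calls <- function(calls, regions) {
  if (is.null(regions) || nrow(calls) == 0L) return(calls)
  calls[in_regions(chrom, pos, regions)]
}

#' Full evaluation report
#'
#' Bundles the call-set statistics into one report: total SNPs, known-site
#' rate, Ti/Tv, het/hom, FN rate vs a genotyping control, FP rate and
#' overlap vs a sequencing control, and genotype consensus.
#'
#' @param calls variant `data.table`.
#' @param wgs_control control call set for FP/overlap (or `NULL`).
#' @param genotyping_control control set for FN/consensus (or `NULL`).
#' @param known_sites known-SNP set for db rate (or `NULL`).
#' @param regions optional region restriction applied to all comparisons.
#' @return An `eval_report` list.
#' @export
eval_report <- function(calls, wgs_control = NULL, genotyping_control = NULL,
                        known_sites = NULL, regions = NULL) {
  calls <- restrict_calls(calls, regions)
  rep <- list(
    total_snps = nrow(calls),
    db_rate = if (!is.null(known_sites)) db_rate(calls, known_sites)
              else NA_real_,
    titv = titv_ratio(calls),
    het_hom = het_hom_ratio(calls),
    fn_rate = if (!is.null(genotyping_control))
                fn_rate(calls, genotyping_control, regions) else NA_real_,
    fp_rate = if (!is.null(wgs_control)) fp_rate(calls, wgs_control, regions)
              else NA_real_,
    overlap_with_control = if (!is.null(wgs_control))
                             overlap_rate(calls, wgs_control, regions)
                           else NA_real_,
    consensus = if (!is.null(genotyping_control))
                  consensus_rate(calls, genotyping_control) else NA_real_
  )
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("SNP call-set evaluation\n")
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4g", v)
  cat(sprintf("  total SNPs     %d\n", x$total_snps))
  cat(sprintf("  db rate        %s%%\n", fmt(x$db_rate)))
  cat(sprintf("  Ti/Tv          %s\n", fmt(x$titv)))
  cat(sprintf("  het/hom        %s\n", fmt(x$het_hom)))
  cat(sprintf("  FN rate        %s%%\n", fmt(x$fn_rate)))
  cat(sprintf("  FP rate        %s%%\n", fmt(x$fp_rate)))
  cat(sprintf("  overlap        %s%%\n", fmt(x$overlap_with_control)))
  cat(sprintf("  consensus      %s%%\n", fmt(x$consensus)))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  dt <- data.table(metric = names(unclass(report)),
                   value = vapply(unclass(report), function(v)
                     if (is.na(v)) NA_real_ else as.numeric(v), numeric(1)))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Depth-saturation curve
#'
#' Randomly subsamples the library to a grid of target mean depths (seeded,
#' so the table is reproducible), reruns the dedup -> gap-repair -> call
#' pipeline at each depth, and records total SNPs plus FP/FN against a truth
#' set — the procedure behind saturation-by-depth plots (rapid growth to
#' ~40X, slow growth to ~100X, plateau beyond).
#'
#' @param reads full-depth `read_set`.
#' @param ref reference genome.
#' @param truth truth variant `data.table`.
#' @param depth_grid increasing vector of target mean depths (X).
#' @param regions optional region restriction for the metrics.
#' @param rdast_cfg,aos_cfg,caller_cfg stage configurations.
#' @param seed integer seed for the subsampling.
#' @return `data.table(target_depth, mean_depth, reads_used, total_snps,
#'   fp_rate, fn_rate)`.
#' @export
saturation_curve <- function(reads, ref, truth, depth_grid,
                             regions = NULL,
                             rdast_cfg = rdast_config(),
                             aos_cfg = aos_config(),
                             caller_cfg = caller_config(),
                             seed = 1L) {
  stopifnot(!is.unsorted(depth_grid))
  span <- sum(ref_lengths(ref)[unique(reads$chrom)])
  full_depth <- sum(nchar(reads$seq)) / span
  out <- vector("list", length(depth_grid))
  for (k in seq_along(depth_grid)) {
    d <- depth_grid[k]
    frac <- if (full_depth > 0) min(1, d / full_depth) else 0
    if (d > full_depth)
      message(sprintf("saturation_curve: target %gX above available %.1fX; truncated",
                      d, full_depth))
    set.seed(seed + k)
    take <- runif(nrow(reads)) < frac
    sub <- read_set(as.data.table(reads)[take], sq = attr(reads, "sq"))
    if (nrow(sub) == 0L) {
      out[[k]] <- data.table(target_depth = d, mean_depth = 0,
                             reads_used = 0L, total_snps = 0L,
                             fp_rate = NA_real_, fn_rate = 100)
      next
    }
    dd <- run_rdast(sub, rdast_cfg)$reads
    aa <- run_aos(dd, ref, aos_cfg, regions)$reads
    calls <- call_snps_fast(aa, ref, caller_cfg, regions)
    fp <- if (nrow(calls)) fp_rate(calls, truth, regions) else NA_real_
    out[[k]] <- data.table(
      target_depth = d,
      mean_depth = sum(nchar(sub$seq)) / span,
      reads_used = nrow(sub),
      total_snps = nrow(restrict_calls(calls, regions)),
      fp_rate = fp,
      fn_rate = fn_rate(calls, truth, regions)
    )
  }
  rbindlist(out)
}
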