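---
title: "Duplicate filtering and homopolymer gap repair for ion semiconductor SNP calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplicate filtering and homopolymer gap repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionsnp)
```

## The problem

Ion semiconductor (flow-based) sequencers produce single-end reads whose
lengths vary after trimming, and whose dominant error mode is the
homopolymer over/undercall: an extra or missing base inside or next to a
run of identical bases, visible in alignments as roughly one gap per 100
aligned bases. Two downstream consequences matter for SNP calling:

* **Duplicate piles inflate false positives.** PCR copies of one template
  all map to the same 5' reference coordinate (the read *lengths* differ
  after trimming, the 5' end does not), and they share the template's
  pre-amplification errors. Where coverage is thin, a pile of three copies
  carrying the same wrong base can push a spurious allele over a frequency
  threshold.
* **Low-frequency gaps inflate false negatives.** A sprinkle of
  homopolymer gaps at and around a true SNP column removes base
  observations, dragging borderline sites under the caller's depth
  requirement, and confusing SNP/indel discrimination in model-based
  callers.

This package implements the two preprocessing passes that address these,
an intentionally minimal frequency caller as a downstream consumer, an
evaluation suite, and a simulator that generates the whole stated world so
every stage is testable without external data.

## Duplicate filtering by alignment score

Reads are grouped by `(chromosome, 5' mapped coordinate, strand)`. For a
forward read the 5' coordinate is the leftmost aligned reference position;
for a reverse read, the rightmost reference base consumed by the CIGAR.
Soft and hard clips consume no reference and never shift the key.

Within each pile, every read whose integer alignment score (the SAM `AS`
tag) is **strictly above** the threshold (default 160) is kept. If no read
passes, the single best-scoring read is kept — hard-to-sequence regions
(repeats) gather short, low-scoring reads, and deleting all of them would
make variation there undetectable. The keep-at-least-one rule means the
removable fraction is bounded by the duplicate fraction.

Design choices where the method description is silent:

* The grouping key includes **strand**: forward and reverse piles at
  mirrored coordinates are different templates under the 5'-end argument.
* "Higher than the threshold" is implemented as strict `>`; `>=` is
  available as a configuration flag for sensitivity analysis.
* Ties at the maximal score in a fallback pile break by lexicographically
  smallest read name, so output is deterministic.

## Improper homopolymer gap classification and repair

Every reference column carrying a non-concordant observation (mismatch or
gap) is examined. Observations are categorized per read as *concordant*,
*discordant*, or *gap*; a deletion contributes a gap observation at every
deleted column, an insertion contributes a gap observation at the column
immediately left of the insertion point (left-anchoring, the common pileup
convention; the inserting read's aligned base at that column remains its
own base observation, matching htslib-style counting).

Two gates must pass:

1. **Homopolymer confirmation.** A run of at least 3 identical bases
   (configurable) must contain or be immediately adjacent to the column in
   the reference, or the read base at the column must sit inside such a run
   in any covering read. Adjacent runs are included because an undercall at
   a run boundary leaves the examined base just outside the run.
2. **Gap ratio.** The gap fraction among the column's observations must be
   positive and **strictly below** 0.2 (configurable). A ratio of exactly
   0.2 or more is treated as a real indel candidate and left alone; the
   degenerate all-gap column (ratio 1) is likewise never touched.

Classification is per CIGAR op: a multi-column deletion op is removed only
when every spanned column qualifies. (The simulator's error model produces
single-base indels, so the partial-op case does not arise in the stated
world; the behavior is defined for completeness.)

"Removing" a gap is ambiguous in the method's original description — it
never says whether reads are dropped or alignments edited. The default here
is **repair**: an improper insertion is excised from sequence and
qualities; an improper deletion op becomes a match, with the deleted
reference bases copied into the read at the minimum of the two flanking
base qualities (a conservative confidence for inferred bases). Repair
preserves read count, position and reference span, so duplicate keys and
downstream pileups shift nowhere. Whole-read `drop` mode is available as a
configuration alternative; it was rejected as the default because discarding
reads reduces depth, which contradicts the false-negative-reduction goal.

A consequence of these gates worth stating: gaps at columns that fail a
gate are never edited, so a second pass classifies zero events —
the pass is idempotent on its own output.

## The naive caller

The caller exists so the preprocessing has a testable consumer without an
external variant-caller installation; `run_pipeline(caller_hook=)` is the
documented substitution point for a real caller. A site is called when the
quality-passing base observations number at least `min_depth` (8) and the
top non-reference allele reaches `min_alt_fraction` (0.2); fractions at or
above `hom_fraction` (0.75) are genotyped homozygous. Allele fractions
divide by **base observations only** — gap observations are not bases and
enter neither numerator nor denominator; this is the convention under which
a depth-11 column with 3 alternate reads is a 27.27% site and a depth-8
column with one is 12.5%. Site depth uses the same base-observation count,
which is exactly how deletion repair can rescue borderline-depth sites.

## The simulator's stated world

Defaults are chosen once, from the platform description and library
protocol, and are not tuned to test outcomes:

| parameter | default | why |
|---|---|---|
| read length | normal, mean 150, sd 35, min 50 | library sheared to ~150 bp; trimmed single-end lengths vary |
| gap error rate | 0.01 / aligned base | the observed one-gap-per-100-bp average |
| homopolymer bias | weight 8 into runs >= 3 | over/undercalls are a run phenomenon; placement is weighted, the *rate* stays binomial |
| substitution rate (per copy) | 0.002 | small relative to the indel channel |
| PCR error rates (per template) | 3e-4 sub, 1e-4 gap | accumulated polymerase error; shared by all copies of a template, including the substituted base |
| pile sizes | 1 + Geometric(p = 0.65) | matches the observed ~35% duplication fraction; the real pile-size law is unpublished, geometric is a recorded modeling choice |
| capture depth | lognormal across 20 kb windows, log-sd 0.8 | exome capture is uneven: with a 60X mean this leaves roughly a fifth of the target under 20X, as real capture summaries show; the thin windows are where both FP piles and rescue-able FN sites live |
| alignment score | match +1, mismatch -2, gap open -3, extend -1 | the real aligner's AS scheme is not published; under match +1 a perfect read scores its own length, which makes a threshold of 160 bite for ~150 bp reads the way the published duplication-vs-threshold curve implies |
| donor SNPs | transition prob 0.73, het fraction 0.565 | reproduce exome-scale Ti/Tv (~2.7) and het/hom (~1.3) |

Reads are emitted pre-aligned at their true coordinates (alignment itself is
out of scope), forward-oriented, on a single chromosome; strand affects
only the flag and the 5' key. Base qualities are normal (mean 28, sd 6,
clamped to [2, 40]). Indel errors are single-base. A fixed seed makes every
output byte-identical.

What the simulator does **not** emulate — and hence what a green test does
not establish: flowgram-level signal artifacts, quality miscalibration,
capture-kit-specific bias, misalignment around indels (reads are placed at
truth), multi-base indels, and real pile-size laws. Directional claims
(the duplicate filter buys specificity, gap repair never costs
sensitivity) are the tested reproductions; published magnitudes are not.

## Numerical conventions

* Internal coordinates are 0-based half-open everywhere; SAM and VCF are
  converted at file boundaries, BED is taken as-is.
* Reads lacking an `AS` tag score `-Inf` (logged), so the fallback rule
  still functions for aligners that omit the tag.
* Only primary mapped alignments are processed; secondary/supplementary
  and unmapped records are dropped with logged counts.
* Site-level set comparisons (FP, FN, overlap, known-site rate) key on
  `(chrom, pos, alt)`; consensus additionally compares the genotype class
  at shared sites. "Specificity" is recorded in the result as
  100 minus the FP rate over the evaluated call set, because the original
  definition is not published.
* Quality filtering keeps bases with Phred quality `>= min_base_quality`,
  in both the exact observation-table route and the htslib counting route
  (the two are cross-checked in the test suite).

## A worked example

```{r worked, eval = FALSE}
cfg <- sim_config(genome_length = 100000, depth_target = 40,
                  n_snps = 60, seed = 1)
sim <- simulate_run(cfg)
dedup <- run_rdast(sim$reads, rdast_config(as_threshold = 160))
repaired <- run_aos(dedup$reads, sim$ref, aos_config())
calls <- call_snps_fast(repaired$reads, sim$ref, caller_config(),
                        sim$target)
eval_report(calls, wgs_control = sim$truth,
            genotyping_control = sim$truth, known_sites = sim$truth,
            regions = sim$target)
```

## Known limitations

* The gap-filter examines gap proportions under the 0.2 threshold only;
  sites where gaps exceed ~0.5 of observations defeat this approach by
  construction and are out of scope.
* The per-op classification leaves partially-qualified multi-column
  deletions untouched rather than splitting them.
* The caller is a frequency threshold, not a genotype-likelihood model;
  its numbers are for pipeline comparison, not production calling.
* Paired-end duplicate keys, CRAM, optical duplicates and local
  realignment are intentionally absent.
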