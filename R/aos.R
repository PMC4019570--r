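# Improper homopolymer gap classification and repair.
#
# Flow-sequencer indel errors concentrate in homopolymer runs. For every
# reference column carrying a non-concordant observation, two gates decide
# whether its gaps are sequencing artifacts: (1) a homopolymer of >= 3
# identical bases must exist at/adjacent to the column in the reference or
# in the reads; (2) the gap fraction among the column's observations must be
# positive but strictly under a threshold (default 0.2) — frequent gaps are
# treated as real indel candidates and left alone.
#
# Classification is per CIGAR op: a deletion op spanning several columns is
# removed only when every spanned column qualifies. "Removal" defaults to
# repairing the alignment in place (deletions become matches filled with
# reference bases at the minimum flanking base quality; insertions are
# excised), which preserves read count, position, and reference span; a
# "drop" mode discards the carrying reads instead.

#' Gap-filter configuration
#'
#' @param min_homopolymer minimal homopolymer run length for Step 1
#'   (default 3).
#' @param gap_ratio_threshold gaps are improper only when their column
#'   fraction is strictly below this (default 0.2).
#' @param mode `"repair"` (edit alignments in place, the default) or
#'   `"drop"` (discard reads carrying improper gaps).
#' @return An `aos_config` list.
#' @export
aos_config <- function(min_homopolymer = 3L, gap_ratio_threshold = 0.2,
                       mode = c("repair", "drop")) {
  stopifnot(min_homopolymer >= 2L,
            gap_ratio_threshold > 0, gap_ratio_threshold <= 1)
  structure(list(min_homopolymer = as.integer(min_homopolymer),
                 gap_ratio_threshold = gap_ratio_threshold,
                 mode = match.arg(mode)),
            class = "aos_config")
}

# Per-chromosome column statistics from the op table: observation depth
# (reads whose aligned span covers the column, plus insertion anchors) and
# gap count (deleted columns plus insertion anchors).
.aos_column_stats <- function(reads, ct) {
  spans <- data.table(chrom = reads$chrom, start = reads$pos,
                      end = reads$pos + cigar_ref_width(reads$cigar))
  dels <- ct[op == "D"]
  ins <- ct[op == "I" & ref_start - 1L >= reads$pos[read_id]]
  stats <- list()
  for (cc in unique(spans$chrom)) {
    sp <- spans[chrom == cc]
    lo <- min(sp$start); hi <- max(sp$end)
    n <- hi - lo
    cov <- as.integer(IRanges::coverage(
      IRanges::IRanges(sp$start - lo + 1L, sp$end - lo), width = n))
    gap <- integer(n); ins_n <- integer(n)
    dcc <- dels[chrom == cc]
    if (nrow(dcc)) {
      idx <- rep(seq_len(nrow(dcc)), dcc$len)
      cols <- dcc$ref_start[idx] + sequence(dcc$len) - 1L - lo
      tab <- tabulate(cols + 1L, nbins = n)
      gap <- gap + tab
    }
    icc <- ins[chrom == cc]
    if (nrow(icc)) {
      ins_n <- tabulate(icc$ref_start - 1L - lo + 1L, nbins = n)
      gap <- gap + ins_n
    }
    stats[[cc]] <- list(offset = lo, depth = cov + ins_n, gaps = gap)
  }
  stats
}

# Vectorized check: does the read base at 0-based query offset `q` of
# `seqs[i]` sit inside a run of >= L identical bases? Slides an L-wide
# window across the offset (L shifts, L-1 adjacent equalities each).
.offset_in_run <- function(seqs, q, L, n = nchar(seqs)) {
  ok <- rep(FALSE, length(q))
  for (s in 0:(L - 1L)) {
    start <- q - s                         # 0-based window start
    valid <- start >= 0L & start + L <= n
    if (!any(valid)) next
    all_eq <- valid
    for (i in seq_len(L - 1L)) {
      p1 <- start + i                      # 1-based positions p1, p1+1
      all_eq <- all_eq &
        substring(seqs, p1, p1) == substring(seqs, p1 + 1L, p1 + 1L)
    }
    ok <- ok | (valid & all_eq)
  }
  ok
}

# Read-side homopolymer check for candidate columns that fail the
# reference-side gate. `cand` = data.table(chrom, col). Returns logical per
# row of `cand`.
.read_side_hp <- function(cand, reads, ct, min_len) {
  ok <- rep(FALSE, nrow(cand))
  if (!nrow(cand)) return(ok)
  m <- ct[op %chin% c("M", "=", "X")]
  m[, chrom := reads$chrom[read_id]]
  ins <- ct[op == "I" & ref_start - 1L >= reads$pos[read_id]]
  ins[, chrom := reads$chrom[read_id]]
  for (cc in unique(cand$chrom)) {
    ci <- which(cand$chrom == cc)
    mcc <- m[chrom == cc]
    if (nrow(mcc)) {
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(cand$col[ci] + 1L, cand$col[ci] + 1L),
        IRanges::IRanges(mcc$ref_start + 1L, mcc$ref_end))
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      # blocks bound the transient substring vectors on large libraries
      block <- 400000L
      if (length(qh)) for (b in seq(1L, length(qh), by = block)) {
        ii <- b:min(b + block - 1L, length(qh))
        qpos <- mcc$q_start[sh[ii]] + (cand$col[ci][qh[ii]] -
                                         mcc$ref_start[sh[ii]])
        in_run <- .offset_in_run(reads$seq[mcc$read_id[sh[ii]]], qpos,
                                 min_len)
        ok[ci[unique(qh[ii][in_run])]] <- TRUE
      }
    }
    icc <- ins[chrom == cc]
    if (nrow(icc)) {
      # inserted bases: check each inserted offset against failing columns
      idx <- rep(seq_len(nrow(icc)), icc$len)
      qpos <- icc$q_start[idx] + sequence(icc$len) - 1L
      anchor <- icc$ref_start[idx] - 1L
      mm <- match(anchor, cand$col[ci])
      sub <- which(!is.na(mm))
      if (length(sub)) {
        in_run <- .offset_in_run(reads$seq[icc$read_id[idx[sub]]],
                                 qpos[sub], min_len)
        ok[ci[mm[sub][in_run]]] <- TRUE
      }
    }
  }
  ok
}

#' Run improper-gap classification and repair over a read set
#'
#' Whole-library, vectorized equivalent of applying
#' [classify_improper_gaps()] at every column and [repair_read()] to every
#' affected read. In repair mode the output has the same number of reads,
#' every read keeps its position and reference span (so duplicate keys and
#' downstream pileups shift nowhere), and untouched reads are bit-identical.
#' A second pass classifies zero improper gaps.
#'
#' @param reads a coordinate-sorted `read_set`.
#' @param ref reference genome (`DNAStringSet`).
#' @param config an [aos_config()].
#' @param regions optional region `data.table`; columns outside are not
#'   examined.
#' @return `list(reads=, stats=, events=)` where `stats` carries
#'   `columns_examined` (covered columns), `columns_homopolymer_confirmed`
#'   (low-gap-ratio columns passing Step 1), `improper_gap_events`
#'   (gap observations removed), `reads_repaired`, `reads_dropped`, and
#'   `events` lists one row per removed gap op
#'   (`qname`, `chrom`, `kind`, `ref_start`, `len`).
#' @export
run_aos <- function(reads, ref, config = aos_config(), regions = NULL) {
  stats <- list(columns_examined = 0L, columns_homopolymer_confirmed = 0L,
                improper_gap_events = 0L, reads_repaired = 0L,
                reads_dropped = 0L)
  events0 <- data.table(qname = character(), chrom = character(),
                        kind = character(), ref_start = integer(),
                        len = integer())
  if (nrow(reads) == 0L)
    return(list(reads = reads, stats = stats, events = events0))
  missing_chrom <- setdiff(unique(reads$chrom), names(ref))
  if (length(missing_chrom))
    stop("reference has no chromosome ", missing_chrom[1L])

  ct <- cigar_table(reads$cigar, reads$pos, seq_len(nrow(reads)))
  ct[, chrom := reads$chrom[read_id]]
  colstats <- .aos_column_stats(reads, ct)
  stats$columns_examined <- sum(vapply(colstats, function(s)
    sum(s$depth > 0L), integer(1)))

  # candidate columns: some gaps, ratio strictly inside (0, threshold)
  cand <- rbindlist(lapply(names(colstats), function(cc) {
    s <- colstats[[cc]]
    idx <- which(s$gaps > 0L & s$gaps < config$gap_ratio_threshold * s$depth)
    if (!length(idx)) return(NULL)
    data.table(chrom = cc, col = idx - 1L + s$offset)
  }))
  if (!is.null(regions) && nrow(cand))
    cand <- cand[in_regions(chrom, col, regions)]

  # improper membership as one logical vector per chromosome (cheap lookups)
  imp <- list()
  n_improper <- 0L
  if (nrow(cand)) {
    ref_ok <- logical(nrow(cand))
    for (cc in unique(cand$chrom)) {
      hp <- hp_context_lengths(ref, cc) >= config$min_homopolymer
      idx <- which(cand$chrom == cc)
      ref_ok[idx] <- hp[cand$col[idx] + 1L]
    }
    need <- which(!ref_ok)
    read_ok <- logical(nrow(cand))
    if (length(need))
      read_ok[need] <- .read_side_hp(cand[need], reads, ct,
                                     config$min_homopolymer)
    pass <- ref_ok | read_ok
    stats$columns_homopolymer_confirmed <- sum(pass)
    n_improper <- sum(pass)
    for (cc in unique(cand$chrom)) {
      s <- colstats[[cc]]
      v <- logical(length(s$depth))
      sel <- which(cand$chrom == cc & pass)
      v[cand$col[sel] - s$offset + 1L] <- TRUE
      imp[[cc]] <- v
    }
  }
  is_imp <- function(chroms, cols) {
    out <- logical(length(cols))
    for (cc in unique(chroms)) {
      v <- imp[[cc]]
      i <- which(chroms == cc)
      if (is.null(v)) next
      j <- cols[i] - colstats[[cc]]$offset + 1L
      inb <- j >= 1L & j <= length(v)
      out[i[inb]] <- v[j[inb]]
    }
    out
  }

  if (n_improper == 0L) {
    return(list(reads = reads, stats = stats, events = events0))
  }

  # per-op classification: every spanned column must be improper
  dels <- ct[op == "D"]
  del_imp <- logical(nrow(dels))
  if (nrow(dels)) {
    idx <- rep(seq_len(nrow(dels)), dels$len)
    hit <- is_imp(dels$chrom[idx], dels$ref_start[idx] + sequence(dels$len) - 1L)
    agg <- data.table(idx = idx, hit = hit)[, .(all_hit = all(hit)), by = idx]
    del_imp[agg$idx] <- agg$all_hit
    stats$improper_gap_events <- stats$improper_gap_events +
      sum(dels$len[del_imp])
  }
  ins <- ct[op == "I" & ref_start - 1L >= reads$pos[read_id]]
  ins_imp <- logical(nrow(ins))
  if (nrow(ins)) {
    ins_imp <- is_imp(ins$chrom, ins$ref_start - 1L)
    stats$improper_gap_events <- stats$improper_gap_events + sum(ins_imp)
  }

  ev <- rbind(
    dels[del_imp, .(read_id, kind = "deletion", ref_start, len, q_start)],
    ins[ins_imp, .(read_id, kind = "insertion", ref_start, len, q_start)]
  )
  rm(dels, ins, cand); gc(verbose = FALSE)
  events <- data.table(qname = reads$qname[ev$read_id],
                       chrom = reads$chrom[ev$read_id],
                       kind = ev$kind, ref_start = ev$ref_start, len = ev$len)
  if (nrow(ev) == 0L)
    return(list(reads = reads, stats = stats, events = events0))

  if (config$mode == "drop") {
    drop_ids <- unique(ev$read_id)
    stats$reads_dropped <- length(drop_ids)
    out <- as.data.table(reads)[-drop_ids]
    return(list(reads = read_set(out, sq = attr(reads, "sq")),
                stats = stats, events = events))
  }

  out <- copy(as.data.table(reads))
  # sequence/quality surgery, high query offsets first within each read
  setorder(ev, read_id, -q_start)
  e_rid <- ev$read_id; e_q <- ev$q_start; e_len <- ev$len
  e_kind <- ev$kind; e_refstart <- ev$ref_start
  seqs <- out$seq; quals <- out$qual
  refstr <- lapply(setNames(nm = unique(out$chrom[e_rid])),
                   function(cc) as.character(ref[[cc]]))
  for (j in seq_along(e_rid)) {
    r <- e_rid[j]; q <- e_q[j]; l <- e_len[j]
    s <- seqs[r]; qu <- quals[r]; n <- nchar(s)
    if (e_kind[j] == "deletion") {
      fill <- substr(refstr[[out$chrom[r]]], e_refstart[j] + 1L,
                     e_refstart[j] + l)
      flanks <- c(if (q >= 1L) substr(qu, q, q),
                  if (q < n) substr(qu, q + 1L, q + 1L))
      qc <- flanks[which.min(.QUAL_MAP[flanks])]
      seqs[r] <- paste0(substr(s, 1L, q), fill, substr(s, q + 1L, n))
      quals[r] <- paste0(substr(qu, 1L, q), strrep(qc, l),
                         substr(qu, q + 1L, n))
    } else {
      seqs[r] <- paste0(substr(s, 1L, q), substr(s, q + l + 1L, n))
      quals[r] <- paste0(substr(qu, 1L, q), substr(qu, q + l + 1L, n))
    }
  }
  out[, seq := seqs]
  out[, qual := quals]
  # CIGAR rebuild for affected reads
  affected <- unique(ev$read_id)
  stats$reads_repaired <- length(affected)
  ct2 <- ct[read_id %in% affected]
  ct2[, new_op := op]
  dkeys <- ev[kind == "deletion", .(read_id, ref_start, q_start, op = "D")]
  if (nrow(dkeys))
    ct2[dkeys, on = .(read_id, ref_start, q_start, op), new_op := "M"]
  ikeys <- ev[kind == "insertion", .(read_id, ref_start, q_start, op = "I")]
  if (nrow(ikeys))
    ct2 <- ct2[!ikeys, on = .(read_id, ref_start, q_start, op)]
  # vectorized merge of adjacent equal ops across all affected reads
  ct2 <- ct2[len > 0L]
  ct2[, grp := cumsum(read_id != shift(read_id, fill = -1L) |
                        new_op != shift(new_op, fill = ""))]
  agg <- ct2[, .(read_id = read_id[1L], piece = paste0(sum(len), new_op[1L])),
             by = grp]
  new_cig <- agg[, .(cigar = paste(piece, collapse = "")), by = read_id]
  out$cigar[new_cig$read_id] <- new_cig$cigar
  res <- read_set(out, sq = attr(reads, "sq"))
  list(reads = res, stats = stats, events = events)
}

#' Repair (or drop) one read's improper gap ops
#'
#' Single-read form of the repair `run_aos()` applies library-wide: an
#' improper deletion op becomes a match filled with the deleted reference
#' bases at the minimum flanking base quality; an improper insertion op is
#' excised from sequence and qualities. Both repairs leave the read's
#' position and reference span unchanged.
#'
#' @param read one-row `read_set` slice.
#' @param events `data.table(kind, ref_start, len)` of this read's improper
#'   ops (`kind` in `"deletion"`/`"insertion"`).
#' @param ref reference genome.
#' @param mode `"repair"` or `"drop"`.
#' @return The repaired one-row read table, or `NULL` in drop mode when
#'   events are present.
#' @export
repair_read <- function(read, events, ref, mode = "repair") {
  stopifnot(nrow(read) == 1L)
  if (nrow(events) == 0L) return(read)
  if (mode == "drop") return(NULL)
  ct <- cigar_table(read$cigar, read$pos, 1L)
  ev <- as.data.table(events)[, .(kind, ref_start, len)]
  ev <- merge(ev,
              ct[, .(op, ref_start, len, q_start)],
              by = c("ref_start", "len"), all.x = TRUE)
  ev <- ev[(kind == "deletion" & op == "D") | (kind == "insertion" & op == "I")]
  if (nrow(ev) != nrow(events))
    stop("repair_read: event not locatable in CIGAR")
  out <- copy(as.data.table(read))
  setorder(ev, -q_start)
  for (j in seq_len(nrow(ev))) {
    q <- ev$q_start[j]; l <- ev$len[j]
    s <- out$seq[1L]; qu <- out$qual[1L]; n <- nchar(s)
    if (ev$kind[j] == "deletion") {
      fill <- ref_slice(ref, out$chrom[1L], ev$ref_start[j],
                        ev$ref_start[j] + l)
      flanks <- c(if (q >= 1L) substr(qu, q, q),
                  if (q < n) substr(qu, q + 1L, q + 1L))
      qc <- flanks[which.min(.QUAL_MAP[flanks])]
      out$seq[1L] <- paste0(substr(s, 1L, q), fill, substr(s, q + 1L, n))
      out$qual[1L] <- paste0(substr(qu, 1L, q), strrep(qc, l),
                             substr(qu, q + 1L, n))
    } else {
      out$seq[1L] <- paste0(substr(s, 1L, q), substr(s, q + l + 1L, n))
      out$qual[1L] <- paste0(substr(qu, 1L, q), substr(qu, q + l + 1L, n))
    }
  }
  ekey <- paste(ev$ref_start, ev$q_start,
                ifelse(ev$kind == "deletion", "D", "I"))
  ct[, new_op := op]
  ckey <- paste(ct$ref_start, ct$q_start, ct$op)
  ct[ckey %chin% ekey & op == "D", new_op := "M"]
  ct <- ct[!(ckey %chin% ekey & op == "I")]
  out$cigar[1L] <- collapse_cigar(ct$new_op, ct$len)
  read_set(out, sq = attr(read, "sq"))
}
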