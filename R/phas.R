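# Per-library phasing detection and cross-library consensus.

#' Select high-accumulation candidate regions from one library's alignments
#'
#' Covered positions are merged into islands across gaps of at most
#' `island_gap` nt; islands are ranked by total fractional abundance and the
#' top `ceiling(top_fraction * n_islands)` are returned (at least one when
#' any island exists, and at least `min_regions` when that floor is set).
#' Ties at the cutoff are broken toward lower (chrom, start).
#'
#' @param alignments data.frame from [map_reads()] for one library.
#' @param top_fraction fraction of islands retained (default 0.15).
#' @param min_regions floor on the number of retained islands (default 0;
#'   the pipeline default raises this so small candidate sets are analysed
#'   in full).
#' @param island_gap maximum gap bridged when merging covered runs
#'   (default 21 nt, one duplex cycle).
#' @return data.frame with chrom, start, end, total_abundance.
#' @export
select_candidate_regions <- function(alignments, top_fraction = 0.15,
                                     min_regions = 0L, island_gap = 21L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), total_abundance = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty)
  islands <- lapply(split(alignments, alignments$chrom), function(a) {
    ir <- IRanges::reduce(IRanges::IRanges(a$start, a$end),
                          min.gapwidth = island_gap + 1L)
    ov <- IRanges::findOverlaps(IRanges::IRanges(a$start, a$end), ir,
                                select = "first")
    ab <- rowsum(a$fractional_count, group = ov)
    data.frame(chrom = a$chrom[1], start = IRanges::start(ir),
               end = IRanges::end(ir),
               total_abundance = as.numeric(ab[order(as.integer(rownames(ab))), 1]),
               stringsAsFactors = FALSE)
  })
  isl <- do.call(rbind, islands)
  rownames(isl) <- NULL
  isl <- isl[order(-isl$total_abundance, isl$chrom, isl$start), , drop = FALSE]
  n_keep <- max(ceiling(top_fraction * nrow(isl)),
                min(min_regions, nrow(isl)), 1L)
  out <- isl[seq_len(min(n_keep, nrow(isl))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phasing score over sliding windows of a candidate region
#'
#' Windows of `window_cycles * cycle` nt slide in steps of `cycle` nt.  In a
#' window, 21-nt alignments are assigned to 21 registers by their
#' duplex-corrected effective 5' ends modulo 21 relative to the window
#' start.  With `k` the number of distinct occupied cycle positions in the
#' most abundant register, `P` the fractional abundance in that register and
#' `U` the fractional abundance of 21-nt reads outside it, the window score
#' is `S = (k - 2) * ln(1 + 10 P / (1 + U))` for `k >= 3`, else 0 --- a
#' standard phasing statistic, monotone in both register occupancy and
#' signal-to-noise.
#'
#' @param region one row (chrom, start, end) of a candidate region table.
#' @param alignments alignments for the library.
#' @param cycle phase length in nt (21).
#' @param window_cycles window span in cycles (11).
#' @return data.frame with window_start, window_end, dominant_register
#'   (0-20), k, P, U, score.
#' @export
phasing_score <- function(region, alignments, cycle = 21L, window_cycles = 11L) {
  a <- alignments[alignments$chrom == region$chrom, , drop = FALSE]
  wlen <- cycle * window_cycles
  # windows step one cycle and may run past the region end (phasing at the
  # island tail would otherwise never dominate a window); every window must
  # overlap the region by at least two cycles
  starts <- seq(region$start, max(region$start, region$end - 2L * cycle + 1L),
                by = cycle)
  ends <- starts + wlen - 1L
  rows <- lapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- ends[i]
    win <- a[a$length == 21L & a$eff5 >= s & a$eff5 <= e, , drop = FALSE]
    if (nrow(win) == 0L)
      return(data.frame(window_start = s, window_end = e,
                        dominant_register = NA_integer_, k = 0L, P = 0, U = 0,
                        score = 0))
    reg <- (win$eff5 - s) %% cycle
    ab <- rowsum(win$fractional_count, group = reg)
    dom <- as.integer(rownames(ab))[which.max(ab[, 1])]
    in_dom <- reg == dom
    P <- sum(win$fractional_count[in_dom])
    U <- sum(win$fractional_count[!in_dom])
    k <- length(unique((win$eff5[in_dom] - s) %/% cycle))
    score <- if (k >= 3L) (k - 2) * log(1 + 10 * P / (1 + U)) else 0
    data.frame(window_start = s, window_end = e, dominant_register = dom,
               k = k, P = P, U = U, score = score)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call PHAS loci in one library
#'
#' Windows scoring at least `min_score` are merged into maximal runs; each
#' run becomes one call whose boundaries are trimmed to the outermost 21/22
#' nt reads lying in a qualifying window's dominant register (or an
#' immediately adjacent register, so 22-nt products and shifted registers
#' stay inside the call).
#'
#' @param alignments one library's alignments.
#' @param regions candidate regions from [select_candidate_regions()].
#' @param min_score phasing score threshold (default 15).
#' @param cycle,window_cycles see [phasing_score()].
#' @return data.frame with library_id, chrom, start, end, score,
#'   dominant_register.
#' @export
call_phas_loci <- function(alignments, regions, min_score = 15,
                           cycle = 21L, window_cycles = 11L) {
  empty <- data.frame(library_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      dominant_register = integer(0), stringsAsFactors = FALSE)
  if (is.null(regions) || nrow(regions) == 0L) return(empty)
  lid <- if (nrow(alignments)) alignments$library_id[1] else NA_character_
  calls <- list()
  for (ri in seq_len(nrow(regions))) {
    rg <- regions[ri, ]
    sc <- phasing_score(rg, alignments, cycle, window_cycles)
    q <- sc[sc$score >= min_score, , drop = FALSE]
    if (nrow(q) == 0L) next
    runs <- IRanges::reduce(IRanges::IRanges(q$window_start, q$window_end))
    for (k in seq_along(runs)) {
      rs <- IRanges::start(runs)[k]; re <- IRanges::end(runs)[k]
      qw <- q[q$window_start >= rs & q$window_end <= re, , drop = FALSE]
      a <- alignments[alignments$chrom == rg$chrom &
                        alignments$length %in% c(21L, 22L) &
                        alignments$eff5 >= rs & alignments$eff5 <= re, ,
                      drop = FALSE]
      sel <- rep(FALSE, nrow(a))
      for (wi in seq_len(nrow(qw))) {
        reg <- (a$eff5 - qw$window_start[wi]) %% cycle
        sel <- sel | (a$eff5 >= qw$window_start[wi] &
                        a$eff5 <= qw$window_end[wi] &
                        reg == qw$dominant_register[wi])
      }
      if (!any(sel)) next
      cs <- min(a$start[sel]); ce <- max(a$end[sel])
      if (ce - cs + 1L < 2L * cycle) next
      best <- which.max(qw$score)
      calls[[length(calls) + 1L]] <- data.frame(
        library_id = lid, chrom = rg$chrom, start = cs, end = ce,
        score = max(qw$score),
        dominant_register = qw$dominant_register[best],
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-library calls into consensus PHAS loci
#'
#' Overlapping calls (any strand) are merged to their union interval
#' (maximum length); `n_detections` counts the distinct libraries whose
#' calls overlap the merged interval; loci detected in fewer than
#' `min_libraries` libraries are discarded.
#'
#' @param calls data.frame of calls pooled across libraries.
#' @param min_libraries minimum distinct detecting libraries (default 3).
#' @return data.frame with locus_id, chrom, start, end, n_detections,
#'   polarity (NA until trigger assignment).
#' @export
merge_consensus <- function(calls, min_libraries = 3L) {
  empty <- data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_detections = integer(0), polarity = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0L) return(empty)
  merged <- lapply(split(calls, calls$chrom), function(cc) {
    ir <- IRanges::reduce(IRanges::IRanges(cc$start, cc$end))
    ov <- IRanges::findOverlaps(IRanges::IRanges(cc$start, cc$end), ir,
                                select = "first")
    nd <- vapply(seq_along(ir), function(i)
      length(unique(cc$library_id[ov == i])), integer(1))
    data.frame(chrom = cc$chrom[1], start = IRanges::start(ir),
               end = IRanges::end(ir), n_detections = nd,
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, merged)
  m <- m[m$n_detections >= min_libraries, , drop = FALSE]
  m <- m[order(m$chrom, m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  if (nrow(m) == 0L) return(empty)
  data.frame(locus_id = sprintf("PHAS%03d", seq_len(nrow(m))), m,
             polarity = NA_character_, stringsAsFactors = FALSE)
}

#' Extend consensus loci for the trigger search
#'
#' @param loci consensus locus table.
#' @param pad extension on each side in nt (default 220).
#' @param chrom_lengths named vector of chromosome lengths for clamping.
#' @return loci with `extended_start` and `extended_end` columns.
#' @export
extend_loci <- function(loci, pad = 220L, chrom_lengths) {
  loci$extended_start <- pmax(1L, loci$start - as.integer(pad))
  loci$extended_end <- pmin(as.integer(chrom_lengths[loci$chrom]),
                            loci$end + as.integer(pad))
  loci
}

#' Export consensus loci as BED-like TSV
#' @param loci consensus locus table.
#' @param path output path.
#' @export
write_loci_tsv <- function(loci, path) {
  write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
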