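# Trigger assignment, 21-bin phase tables with duplex correction, bin
# ranking, phasiRNA extraction, recursive trigger discovery, nomenclature
# and genomic feature assignment.

# transcript coordinate of genomic position g for a stranded interval
locus_t <- function(g, strand, start, end) {
  if (strand == "-") end - g + 1L else g - start + 1L
}

#' Phase bin of a genomic 5' anchor on a given strand
#'
#' Bin 1 is anchored at the consensus locus start.  The effective position
#' of a plus-strand 5' anchor is the position itself; a minus-strand anchor
#' (the 5' end of a 21-nt read whose leftmost coordinate is `g - 20`) is
#' shifted by the duplex-overhang correction to `g - 22`, so the two reads
#' of a 2-nt 3'-overhang duplex share a bin.
#'
#' @param g genomic coordinate of the 5' anchor.
#' @param strand strand carrying the anchor.
#' @param locus_start consensus locus start.
#' @param cycle phase length (21).
#' @return integer bin in 1..21.
#' @export
phase_bin <- function(g, strand, locus_start, cycle = 21L) {
  eff <- ifelse(strand == "-", g - (cycle + 1L), g)
  ((eff - locus_start) %% cycle) + 1L
}

#' Build per-library phase-bin tables for one locus
#'
#' Only 21/22-nt alignments whose duplex-corrected effective 5' position
#' lies inside the original (pre-extension) locus interval contribute.
#' Bins are populated with fractional abundance; reads from both genomic
#' strands are tabulated separately and pooled (duplex correction makes the
#' two members of a duplex share a bin index).
#'
#' @param locus one consensus-locus row (chrom, start, end).
#' @param alignments pooled alignments across libraries (with library_id).
#' @param cycle phase length (21).
#' @return list with `pooled` (21 x n_libraries matrix), `by_strand`
#'   (same shape per genomic strand) and `reads` (the contributing rows
#'   with `bin` added).
#' @export
build_phase_bins <- function(locus, alignments, cycle = 21L) {
  a <- alignments[alignments$chrom == locus$chrom &
                    alignments$length %in% c(21L, 22L) &
                    alignments$eff5 >= locus$start &
                    alignments$eff5 <= locus$end, , drop = FALSE]
  libs <- sort(unique(alignments$library_id))
  mk <- function(rows) {
    m <- matrix(0, nrow = cycle, ncol = length(libs),
                dimnames = list(seq_len(cycle), libs))
    if (nrow(rows)) {
      tab <- rowsum(rows$fractional_count,
                    group = paste(rows$bin, rows$library_id, sep = "\r"))
      key <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
      m[cbind(as.integer(key[, 1]), match(key[, 2], libs))] <- tab[, 1]
    }
    m
  }
  if (nrow(a)) a$bin <- ((a$eff5 - locus$start) %% cycle) + 1L
  else a$bin <- integer(0)
  list(pooled = mk(a),
       by_strand = list(`+` = mk(a[a$strand == "+", , drop = FALSE]),
                        `-` = mk(a[a$strand == "-", , drop = FALSE])),
       reads = a)
}

#' Rank phase bins across libraries
#'
#' Per library, the most abundant bin scores 5, the second 2 and the third
#' 0.5; scores are summed over libraries.  Abundance ties rank the lower
#' bin index first.
#'
#' @param bin_matrix 21 x n_libraries abundance matrix.
#' @param weights rank weights (default 5, 2, 0.5).
#' @return named numeric vector of per-bin rank scores.
#' @export
rank_bins <- function(bin_matrix, weights = c(5, 2, 0.5)) {
  nb <- nrow(bin_matrix)
  scores <- setNames(numeric(nb), rownames(bin_matrix))
  for (j in seq_len(ncol(bin_matrix))) {
    col <- bin_matrix[, j]
    ord <- order(-col, seq_len(nb))
    top <- ord[col[ord] > 0]
    top <- top[seq_len(min(length(weights), length(top)))]
    scores[top] <- scores[top] + weights[seq_along(top)]
  }
  scores
}

# bins with positive rank score, best first (ties toward lower index)
top_ranked_bins <- function(rank_scores, n = 3L) {
  ord <- order(-rank_scores, as.integer(names(rank_scores)))
  ord <- ord[rank_scores[ord] > 0]
  as.integer(names(rank_scores)[ord[seq_len(min(n, length(ord)))]])
}

wrap_bins <- function(bins, cycle = 21L) {
  sort(unique(((bins - 1L) %% cycle) + 1L))
}

adjacent_bins <- function(bins, cycle = 21L) {
  wrap_bins(c(bins - 1L, bins, bins + 1L), cycle)
}

#' Select the primary trigger for a locus from scored cleavage events
#'
#' The highest-scoring event (ties: lower complementarity penalty, then the
#' 5'-most slice site on the targeted strand) is selected if its score
#' reaches `min_score`; the locus polarity is then the strand the trigger
#' base-pairs to.
#'
#' @param events data.frame of events for one locus (columns deg_score,
#'   allen_score, target_strand, slice_genomic, ...).
#' @param min_score minimum summed degradome score (default 10).
#' @return the selected event row, or `NULL` when none qualifies.
#' @export
assign_primary_trigger <- function(events, min_score = 10) {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  ev <- events[events$deg_score >= min_score, , drop = FALSE]
  if (nrow(ev) == 0L) return(NULL)
  key5 <- ifelse(ev$target_strand == "+", ev$slice_genomic, -ev$slice_genomic)
  ev <- ev[order(-ev$deg_score, ev$allen_score, key5), , drop = FALSE]
  ev[1, , drop = FALSE]
}

#' Accept secondary/tertiary triggers for a trigger-bearing locus
#'
#' Candidates must score at least `min_score`, target the strand of the
#' primary trigger (the locus polarity), and slice within the three
#' top-ranked sRNA bins or their immediate (-1/+1) neighbours.
#'
#' @param events scored events for the locus.
#' @param polarity locus polarity strand.
#' @param rank_scores per-bin rank scores from [rank_bins()].
#' @param locus_start consensus locus start (bin anchor).
#' @param existing data.frame of already assigned triggers (for
#'   deduplication by sequence + slice).
#' @param min_score minimum score (default 10).
#' @return data.frame of newly accepted events (possibly empty).
#' @export
find_secondary_triggers <- function(events, polarity, rank_scores, locus_start,
                                    existing = NULL, min_score = 10) {
  if (is.null(events) || nrow(events) == 0L) return(events[0, , drop = FALSE])
  allowed <- adjacent_bins(top_ranked_bins(rank_scores, 3L))
  ev <- events[events$deg_score >= min_score &
                 events$target_strand == polarity, , drop = FALSE]
  if (nrow(ev) == 0L) return(ev)
  bins <- phase_bin(ev$slice_genomic + slice_anchor_shift(ev$target_strand),
                    ev$target_strand, locus_start)
  ev <- ev[bins %in% allowed, , drop = FALSE]
  if (!is.null(existing) && nrow(existing) && nrow(ev)) {
    key <- paste(ev$srna_sequence, ev$slice_genomic)
    ev <- ev[!key %in% paste(existing$srna_sequence, existing$slice_genomic), ,
             drop = FALSE]
  }
  ev
}

# the register anchor is the nucleotide paired to sRNA position 10 (the 5'
# end of the downstream fragment) -- already what slice_genomic stores, so
# no shift; kept as a named function to document the convention.
slice_anchor_shift <- function(strand) 0L

#' Extract phasiRNAs for a locus from its phase bins
#'
#' All 21/22-nt reads whose bin falls in the register set by a confirmed
#' triggering event or an immediately adjacent (-1/+1) bin become phasiRNA
#' records; for loci without a trigger the most abundant bin and its
#' neighbours are used and the forward genomic orientation is kept.
#' Offsets are signed distances (in -10..+10) from the main register
#' anchor in transcript coordinates, with antisense reads corrected for
#' the 2-nt duplex overhang so both duplex members share register and
#' offset.
#'
#' @param locus consensus-locus row with `polarity` (may be NA) filled in.
#' @param bin_reads contributing reads from [build_phase_bins()]
#'   (`$reads`).
#' @param anchors genomic register-anchor coordinates of accepted triggers
#'   (or the fallback top-bin anchor).
#' @param main_anchor genomic coordinate of the main (primary) register
#'   anchor.
#' @param locus_name display name used in phasiRNA names.
#' @param cycle phase length (21).
#' @return data.frame of phasiRNA records (name, locus_id, register_index,
#'   offset, strand, length, sequence, bin, combined_count).
#' @export
extract_phasirnas <- function(locus, bin_reads, anchors, main_anchor,
                              locus_name = locus$locus_id, cycle = 21L) {
  empty <- data.frame(name = character(0), locus_id = character(0),
                      register_index = integer(0), offset = integer(0),
                      strand = character(0), length = integer(0),
                      sequence = character(0), bin = integer(0),
                      combined_count = numeric(0), stringsAsFactors = FALSE)
  if (is.null(bin_reads) || nrow(bin_reads) == 0L || length(anchors) == 0L)
    return(empty)
  s <- if (is.na(locus$polarity)) "+" else locus$polarity
  allowed <- adjacent_bins(phase_bin(anchors, s, locus$start, cycle), cycle)
  a <- bin_reads[bin_reads$bin %in% allowed, , drop = FALSE]
  if (nrow(a) == 0L) return(empty)

  ta <- pmin(locus_t(a$start, s, locus$start, locus$end),
             locus_t(a$end, s, locus$start, locus$end))
  sense <- a$strand == s
  t5 <- ifelse(sense, ta, ta - 2L)          # duplex-corrected anchor position
  anchor_t <- locus_t(main_anchor, s, locus$start, locus$end)
  offset <- signed_offset(t5 - anchor_t, cycle)
  register_index <- pmax(1L, (t5 - 1L) %/% cycle + 1L)
  rel_strand <- ifelse(sense, "+", "-")

  # raw combined counts per sequence: one count per (library, sequence)
  u <- unique(a[, c("library_id", "sequence", "count")])
  comb <- rowsum(u$count, group = u$sequence)

  rec <- data.frame(locus_id = locus$locus_id, register_index = register_index,
                    offset = as.integer(offset), strand = rel_strand,
                    length = a$length, sequence = a$sequence, bin = a$bin,
                    t5 = t5, stringsAsFactors = FALSE)
  rec <- unique(rec)
  rec$combined_count <- comb[rec$sequence, 1]
  rec$name <- name_phasirna(locus_name, s, rec$register_index, rec$strand,
                            rec$offset, rec$length)
  rec[, c("name", "locus_id", "register_index", "offset", "strand",
          "length", "sequence", "bin", "combined_count", "t5")]
}

#' Canonical phasiRNA nomenclature
#'
#' `name_phasirna()` builds names of the form
#' `LOCUS(locus_strand)_REGISTER read_strand (offset)[_22]`, e.g.
#' `AT2G39675(-)_20-(+1)` or `AT3G17185(+)_18+(-1)_22`; the parenthesised
#' offset is omitted when 0 and the `_22` suffix marks 22-nt products.
#' `parse_phasirna_name()` is its exact inverse (it also accepts unsigned
#' positive offsets such as `(2)`).
#'
#' @param locus locus or gene identifier.
#' @param locus_strand strand of the locus transcript (`+`/`-`).
#' @param register_index 21-nt register count from the transcript 5' end.
#' @param read_strand `+` if the phasiRNA derives from the mRNA strand,
#'   `-` if from the complementary strand.
#' @param offset signed offset to the main phased register (0 = canonical
#'   position).
#' @param length 21 or 22.
#' @return `name_phasirna()`: character vector of names;
#'   `parse_phasirna_name()`: data.frame of fields.
#' @export
name_phasirna <- function(locus, locus_strand, register_index, read_strand,
                          offset = 0L, length = 21L) {
  off <- ifelse(offset == 0, "",
                sprintf("(%s%d)", ifelse(offset > 0, "+", ""), offset))
  suf <- ifelse(length == 22L, "_22", "")
  sprintf("%s(%s)_%d%s%s%s", locus, locus_strand, register_index,
          read_strand, off, suf)
}

#' @rdname name_phasirna
#' @param name character vector of phasiRNA names.
#' @export
parse_phasirna_name <- function(name) {
  pat <- "^(.*)\\(([+-])\\)_([0-9]+)([+-])(?:\\((\\+?-?[0-9]+)\\))?(_22)?$"
  m <- regmatches(name, regexec(pat, name))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stopf("malformed phasiRNA name: %s", name[bad][1])
  f <- do.call(rbind, m)
  data.frame(locus = f[, 2], locus_strand = f[, 3],
             register_index = as.integer(f[, 4]), read_strand = f[, 5],
             offset = ifelse(f[, 6] == "", 0L,
                             as.integer(sub("^\\+", "", f[, 6]))),
             length = ifelse(f[, 7] == "_22", 22L, 21L),
             stringsAsFactors = FALSE)
}

#' Classify phasiRNAs as canonical or non-canonical
#'
#' Canonical phasiRNAs are 21 nt and sit exactly in the main phased
#' register (offset 0); 22-nt products and products from shifted registers
#' are non-canonical.
#'
#' @param records phasiRNA record table.
#' @return data.frame tabulating counts and fractions by length and class.
#' @export
classify_phasirnas <- function(records) {
  canonical <- records$length == 21L & records$offset == 0L
  cls <- ifelse(canonical, "canonical", "non-canonical")
  tab <- as.data.frame(table(length = records$length, class = cls),
                       stringsAsFactors = FALSE)
  tab$length <- as.integer(tab$length)
  names(tab)[3] <- "n"
  tab$fraction <- if (nrow(records)) tab$n / nrow(records) else numeric(nrow(tab))
  tab
}

#' Assign consensus loci to annotated genomic features
#'
#' A locus is assigned to a feature when their overlap exceeds
#' `min_overlap` of the locus length (interval lengths and overlaps are
#' measured as `end - start`).  With known polarity the feature strand must
#' match (confirmed assignment); without a trigger-derived polarity the
#' strand check is waived and the assignment is tentative, notated in
#' lowercase.  Loci matching no feature are named by their coordinates.
#' When several features match, all are reported and the one with greatest
#' overlap is principal.
#'
#' @param loci consensus loci with `polarity`.
#' @param features feature table (chrom, start, end, strand, type, ID).
#' @param min_overlap minimum overlap fraction (default 0.70, strict).
#' @return data.frame with locus_id, assigned_name, confidence
#'   (confirmed/tentative/unassigned), overlap_fraction, feature_type,
#'   all_features.
#' @export
assign_locus_feature <- function(loci, features, min_overlap = 0.70) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    coord_name <- sprintf("%s:%d-%d", lc$chrom, lc$start, lc$end)
    f <- features[features$chrom == lc$chrom, , drop = FALSE]
    out <- data.frame(locus_id = lc$locus_id, assigned_name = coord_name,
                      confidence = "unassigned", overlap_fraction = 0,
                      feature_type = NA_character_,
                      all_features = NA_character_, stringsAsFactors = FALSE)
    if (nrow(f) == 0L) return(out)
    ov <- overlap_length(lc$start, lc$end, f$start, f$end)
    frac <- ov / (lc$end - lc$start)
    cand <- frac > min_overlap
    if (!any(cand)) return(out)
    f <- f[cand, , drop = FALSE]; ov <- ov[cand]; frac <- frac[cand]
    if (!is.na(lc$polarity)) {
      match_pol <- f$strand == lc$polarity
      if (!any(match_pol)) return(out)
      f <- f[match_pol, , drop = FALSE]; ov <- ov[match_pol]; frac <- frac[match_pol]
      pick <- which.max(ov)
      out$assigned_name <- f$ID[pick]
      out$confidence <- "confirmed"
    } else {
      pick <- which.max(ov)
      out$assigned_name <- tolower(f$ID[pick])
      out$confidence <- "tentative"
    }
    out$overlap_fraction <- frac[pick]
    out$feature_type <- f$type[pick]
    out$all_features <- paste(f$ID[order(-ov)], collapse = ";")
    out
  })
  do.call(rbind, rows)
}

#' Fraction of locus-region read abundance captured by annotated registers
#'
#' Over all consensus loci, the fractional abundance of 21/22-nt reads
#' whose bin belongs to an annotated register (trigger registers plus
#' adjacent bins, or the top bin for trigger-less loci) divided by the
#' total fractional abundance mapping inside locus regions.
#'
#' @param annotation result of [iterate_annotation()].
#' @param alignments pooled alignments across libraries.
#' @return numeric fraction in 0..1.
#' @export
evaluate_annotation_recall <- function(annotation, alignments) {
  tot <- 0; hit <- 0
  for (i in seq_len(nrow(annotation$loci))) {
    lc <- annotation$loci[i, ]
    br <- annotation$bins[[lc$locus_id]]$reads
    if (is.null(br) || nrow(br) == 0L) next
    anchors <- annotation$anchors[[lc$locus_id]]
    s <- if (is.na(lc$polarity)) "+" else lc$polarity
    allowed <- adjacent_bins(phase_bin(anchors, s, lc$start))
    tot <- tot + sum(br$fractional_count)
    hit <- hit + sum(br$fractional_count[br$bin %in% allowed])
  }
  if (tot == 0) stopf("no reads map inside locus regions")
  hit / tot
}
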