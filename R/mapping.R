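# Exact-match read mapping with fractional multimapper counting.

#' Map collapsed reads to a reference with exact full-length matches
#'
#' Only reads whose length is in `allowed_lengths` are mapped; matching is
#' exact on both strands (via [Biostrings::matchPDict()]); reads hitting
#' more than `max_locations` sites are dropped entirely; each retained
#' read's count is divided evenly between its locations
#' (`fractional_count = count / n_locations`).  The leftmost reference
#' coordinate is reported for both strands (1-based inclusive).  The
#' duplex-corrected effective 5' position (`eff5`) used for phase binning is
#' `start` for plus-strand hits and `start - 2` for minus-strand hits, which
#' places both members of a 2-nt 3'-overhang duplex in the same 21-nt bin.
#'
#' @param lib collapsed library (list with `library_id`, `reads`).
#' @param reference named character vector of reference sequences.
#' @param allowed_lengths read lengths accepted for mapping (default 21, 22).
#' @param max_locations maximum mapping locations retained (default 10).
#' @param normalize if `TRUE` (default) U is normalized to T before matching.
#' @return data.frame with library_id, sequence, length, count, chrom,
#'   start, end, strand, n_locations, fractional_count, eff5.
#' @export
map_reads <- function(lib, reference, allowed_lengths = c(21L, 22L),
                      max_locations = 10L, normalize = TRUE) {
  if (length(reference) == 0L || all(!nzchar(reference)))
    stopf("reference is empty")
  empty <- data.frame(library_id = character(0), sequence = character(0),
                      length = integer(0), count = numeric(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), n_locations = integer(0),
                      fractional_count = numeric(0), eff5 = integer(0),
                      stringsAsFactors = FALSE)
  reads <- lib$reads
  if (is.null(reads) || nrow(reads) == 0L) return(empty)
  seqs <- if (normalize) normalize_ut(reads$sequence) else reads$sequence
  len <- nchar(seqs)
  keep <- len %in% allowed_lengths & !grepl("[^ACGT]", seqs)
  reads <- reads[keep, , drop = FALSE]; seqs <- seqs[keep]; len <- len[keep]
  if (nrow(reads) == 0L) return(empty)

  # collapse duplicate (post-normalization) sequences before matching
  agg <- collapse_counts(seqs, reads$count)
  seqs <- agg$sequence; cnts <- agg$count; len <- nchar(seqs)

  ref_fwd <- Biostrings::DNAStringSet(reference)
  names(ref_fwd) <- names(reference)
  ref_rev <- Biostrings::reverseComplement(ref_fwd)
  ref_len <- Biostrings::width(ref_fwd)

  hits <- list()
  for (w in sort(unique(len))) {
    idx <- which(len == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    for (ci in seq_along(ref_fwd)) {
      chrom <- names(ref_fwd)[ci]
      mf <- Biostrings::matchPDict(pd, ref_fwd[[ci]])
      sf <- Biostrings::startIndex(mf)
      mr <- Biostrings::matchPDict(pd, ref_rev[[ci]])
      sr <- Biostrings::startIndex(mr)
      for (k in seq_along(idx)) {
        p_f <- sf[[k]]; p_r <- sr[[k]]
        if (length(p_f))
          hits[[length(hits) + 1L]] <- data.frame(
            ri = idx[k], chrom = chrom, start = p_f, strand = "+",
            stringsAsFactors = FALSE)
        if (length(p_r)) {
          # position p on the reverse-complement strand corresponds to
          # leftmost genomic coordinate L - p - w + 2
          hits[[length(hits) + 1L]] <- data.frame(
            ri = idx[k], chrom = chrom,
            start = ref_len[ci] - p_r - w + 2L, strand = "-",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) return(empty)
  h <- do.call(rbind, hits)
  nl <- table(h$ri)
  h$n_locations <- as.integer(nl[as.character(h$ri)])
  h <- h[h$n_locations <= max_locations, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  out <- data.frame(
    library_id = lib$library_id,
    sequence = seqs[h$ri],
    length = len[h$ri],
    count = cnts[h$ri],
    chrom = h$chrom,
    start = h$start,
    end = h$start + len[h$ri] - 1L,
    strand = h$strand,
    n_locations = h$n_locations,
    fractional_count = cnts[h$ri] / h$n_locations,
    stringsAsFactors = FALSE)
  out$eff5 <- ifelse(out$strand == "+", out$start, out$start - 2L)
  out <- out[order(out$chrom, out$start, out$strand, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an alignment table as TSV
#' @param alignments data.frame from [map_reads()].
#' @param path output path.
#' @export
write_alignments_tsv <- function(alignments, path) {
  write.table(alignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
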