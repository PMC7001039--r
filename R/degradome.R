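# sRNA-transcript complementarity search, degradome profiles, cleavage
# category assignment and the weighted multi-library scoring systems.

#' Complementarity penalty between an sRNA and a target site
#'
#' Ungapped, equal-length scoring: position `i` of the sRNA (1 = 5' end)
#' pairs with position `L - i + 1` of the target window.  A mismatch costs
#' 1.0, a G:U wobble 0.5, and both are doubled for positions 2-13 (the
#' functionally critical core); perfect pairs cost 0.
#'
#' @param srna sRNA sequence (5'->3').
#' @param site target site sequence (5'->3', same length).
#' @return numeric penalty.
#' @export
allen_score <- function(srna, site) {
  q <- normalize_ut(srna); w <- normalize_ut(site)
  if (nchar(q) != nchar(w)) stopf("sRNA and site lengths differ")
  allen_score_windows(q, w)[1]
}

# Vectorized window scoring: penalty of `q` against every window of
# `subject`; returns numeric vector of length nchar(subject) - L + 1.
allen_score_windows <- function(q, subject) {
  L <- nchar(q)
  n <- nchar(subject)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  qc <- strsplit(q, "")[[1]]
  ss <- strsplit(subject, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "x")
  pen <- numeric(nw)
  for (j in seq_len(L)) {
    i <- L - j + 1L                      # sRNA position pairing window pos j
    wt <- if (i >= 2L && i <= 13L) 2 else 1
    wch <- ss[j:(j + nw - 1L)]
    mism <- wch != comp[[qc[i]]]
    wob <- (qc[i] == "G" & wch == "T") | (qc[i] == "T" & wch == "G")
    pj <- numeric(nw)
    pj[mism] <- 1
    pj[wob] <- 0.5
    pen <- pen + wt * pj
  }
  pen
}

#' Find complementary target alignments of an sRNA on a transcript
#'
#' Every ungapped window with penalty at most `max_allen` is reported; the
#' slice position is the transcript coordinate paired to sRNA position 10
#' (the cut falls between the target nucleotides paired to positions 10 and
#' 11, so the slice position is the 5' nucleotide of the downstream
#' cleavage fragment, where degradome tags accumulate).
#'
#' @param srna sRNA sequence.
#' @param transcript transcript sequence (5'->3').
#' @param max_allen maximum penalty retained (default 7.0).
#' @param srna_id,transcript_id identifiers echoed in the output.
#' @return data.frame with srna_id, srna_sequence, transcript_id, start,
#'   end, allen_score, slice_position (transcript coordinates).
#' @export
find_target_alignments <- function(srna, transcript, max_allen = 7.0,
                                   srna_id = srna, transcript_id = "transcript") {
  q <- normalize_ut(srna)
  subject <- normalize_ut(transcript)
  L <- nchar(q)
  if (nchar(subject) < L)
    return(data.frame(srna_id = character(0), srna_sequence = character(0),
                      transcript_id = character(0), start = integer(0),
                      end = integer(0), allen_score = numeric(0),
                      slice_position = integer(0), stringsAsFactors = FALSE))
  pen <- allen_score_windows(q, subject)
  hit <- which(pen <= max_allen)
  data.frame(srna_id = rep(srna_id, length(hit)),
             srna_sequence = rep(srna, length(hit)),
             transcript_id = rep(transcript_id, length(hit)),
             start = hit, end = hit + L - 1L,
             allen_score = pen[hit],
             slice_position = hit + L - 10L,
             stringsAsFactors = FALSE)
}

#' Build per-transcript degradome 5'-tag profiles for one library
#'
#' Tags are matched to transcripts by exact alignment of their first
#' `prefix` nt; duplicate placements accumulate counts.
#'
#' @param deg_lib degradome library (list with `tags`).
#' @param transcripts named character vector of transcript sequences.
#' @param prefix prefix length used for matching (default 20).
#' @return named list of numeric count vectors (one per transcript,
#'   1-based transcript coordinates).
#' @export
build_degradome_profiles <- function(deg_lib, transcripts, prefix = 20L) {
  profs <- lapply(transcripts, function(tr) numeric(nchar(tr)))
  tags <- deg_lib$tags
  if (is.null(tags) || nrow(tags) == 0L) return(profs)
  seqs <- normalize_ut(tags$sequence)
  keep <- nchar(seqs) >= prefix & !grepl("[^ACGT]", seqs)
  seqs <- substr(seqs[keep], 1L, prefix)
  cnts <- tags$count[keep]
  if (length(seqs) == 0L) return(profs)
  agg <- collapse_counts(seqs, cnts)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(agg$sequence))
  for (ti in seq_along(transcripts)) {
    if (nchar(transcripts[[ti]]) < prefix) next
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(normalize_ut(transcripts[[ti]])))
    st <- Biostrings::startIndex(m)
    for (k in seq_along(st)) {
      if (length(st[[k]]))
        profs[[ti]][st[[k]]] <- profs[[ti]][st[[k]]] + agg$count[k]
    }
  }
  profs
}

#' Assign the degradome category of a slice site in a profile
#'
#' Categories follow the standard degradome prominence classification:
#' with `c` the tag count at the queried position, `none` when `c == 0`;
#' 4 when `c == 1`; 0 when `c > 1` equals the unique transcript-wide
#' maximum; 1 when `c > 1` equals a tied maximum; 2 when `c > 1` exceeds
#' the median of occupied positions; 3 otherwise.
#'
#' @param profile numeric tag-count vector for one transcript.
#' @param slice_position 1-based transcript coordinate.
#' @return integer category 0-4, or `NA` when no tag is present.
#' @export
categorize_cleavage <- function(profile, slice_position) {
  if (slice_position < 1L || slice_position > length(profile)) return(NA_integer_)
  c0 <- profile[slice_position]
  if (c0 == 0) return(NA_integer_)
  if (c0 == 1) return(4L)
  mx <- max(profile)
  if (c0 == mx) {
    if (sum(profile == mx) == 1L) return(0L) else return(1L)
  }
  med <- median(profile[profile > 0])
  if (c0 > med) return(2L) else return(3L)
}

#' Weighted multi-library degradome score for one cleavage event
#'
#' Sums category weights across libraries: category 0 scores 5, category 1
#' scores 4, category 2 scores 0.5; categories 3 and 4 are uninformative
#' and score 0.  The same weight table drives both the trigger search
#' (deg_score) and target validation (target_deg_score).
#'
#' @param categories integer vector of per-library categories (NAs are
#'   ignored).
#' @param weights named weight table.
#' @return numeric summed score.
#' @export
weighted_score <- function(categories,
                           weights = c(`0` = 5, `1` = 4, `2` = 0.5,
                                       `3` = 0, `4` = 0)) {
  categories <- categories[!is.na(categories)]
  if (length(categories) == 0L) return(0)
  sum(weights[as.character(categories)])
}

#' Empirical-CDF score threshold
#'
#' Returns the smallest observed score `s` whose left-limit ECDF (the
#' fraction of scores strictly below `s`) reaches `quantile`; when no score
#' qualifies (e.g. all scores equal) the maximum is returned.  Used to pick
#' the score cut isolating the top tail of the score distribution.
#'
#' @param scores numeric vector (non-empty).
#' @param quantile target ECDF level (default 0.99, the top 1% tail).
#' @return numeric threshold.
#' @export
ecdf_threshold <- function(scores, quantile = 0.99) {
  if (length(scores) == 0L) stopf("no scores supplied")
  v <- sort(unique(scores))
  frac_below <- vapply(v, function(s) mean(scores < s), numeric(1))
  ok <- which(frac_below >= quantile)
  if (length(ok) == 0L) return(max(scores))
  v[ok[1]]
}
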