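#' @importFrom stats median rbinom rpois runif setNames pt cor phyper p.adjust
#'   quantile lm coef
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA character strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors (U is normalized to T first).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(normalize_ut(x))))
}

#' Normalize RNA-style sequences to DNA alphabet
#'
#' Uppercases and converts U to T.
#'
#' @param x character vector.
#' @return character vector over A/C/G/T/N.
#' @export
normalize_ut <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so simulation stages are independently
# reproducible.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Random DNA strings
#'
#' Uniform i.i.d. bases; handy for building fixtures and decoy sequences.
#'
#' @param n number of strings.
#' @param len length of each string (nt).
#' @return character vector of length `n`.
#' @export
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
    character(1))
}

# Symmetric modular mapping of a phase difference to a signed offset in
# -10..+10 (21-nt cycle).
signed_offset <- function(delta, cycle = 21L) {
  ((delta %% cycle) + (cycle %/% 2)) %% cycle - (cycle %/% 2)
}

# Interval intersection length under the end - start convention used for
# locus/feature overlaps (see assign_locus_feature()).
overlap_length <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
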