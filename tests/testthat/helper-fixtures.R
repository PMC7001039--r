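# Small deterministic configurations used across tests.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(seed = 7, n_chromosomes = 1, chrom_length = 9000,
         n_phas_loci = 4, n_cycles_per_locus = 8,
         n_target_genes = 2, n_srna_libraries = 3,
         n_degradome_libraries = 3, locus_expression_rate = 1,
         noise_fraction = 0, poisson_jitter = FALSE),
    list(...))
  do.call(simulation_config, args)
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(seed = 11, n_chromosomes = 2, chrom_length = 12000,
         n_phas_loci = 8, n_cycles_per_locus = 10,
         n_target_genes = 4, n_srna_libraries = 4,
         n_degradome_libraries = 4, locus_expression_rate = 1,
         noise_fraction = 0.2),
    list(...))
  do.call(simulation_config, args)
}

# brute-force exact mapper: scans every window of both strands
brute_force_map <- function(seqs, reference) {
  hits <- list()
  for (s in seqs) {
    L <- nchar(s)
    for (chrom in names(reference)) {
      ref <- reference[[chrom]]
      n <- nchar(ref)
      if (n < L) next
      wins <- substring(ref, 1:(n - L + 1L), L:n)
      fw <- which(wins == s)
      rv <- which(wins == rev_comp(s))
      if (length(fw))
        hits[[length(hits) + 1L]] <- data.frame(sequence = s, chrom = chrom,
                                                start = fw, strand = "+")
      if (length(rv))
        hits[[length(hits) + 1L]] <- data.frame(sequence = s, chrom = chrom,
                                                start = rv, strand = "-")
    }
  }
  if (!length(hits))
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), strand = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$sequence, out$chrom, out$start, out$strand), ]
}

# independent term-by-term complementarity penalty (simple double loop)
oracle_allen <- function(srna, site) {
  q <- strsplit(toupper(chartr("U", "T", srna)), "")[[1]]
  w <- strsplit(toupper(chartr("U", "T", site)), "")[[1]]
  L <- length(q)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  total <- 0
  for (i in seq_len(L)) {
    tgt <- w[L - i + 1L]
    pen <- if (tgt == comp[[q[i]]]) 0
           else if ((q[i] == "G" && tgt == "T") || (q[i] == "T" && tgt == "G")) 0.5
           else 1
    if (i >= 2 && i <= 13) pen <- pen * 2
    total <- total + pen
  }
  total
}

# independent re-statement of the degradome category rule table
oracle_category <- function(profile, pos) {
  c0 <- profile[pos]
  if (c0 == 0) return(NA_integer_)
  if (c0 == 1) return(4L)
  mx <- max(profile)
  nmax <- sum(profile == mx)
  med <- stats::median(profile[profile > 0])
  if (c0 > 1 && c0 == mx && nmax == 1) return(0L)
  if (c0 > 1 && c0 == mx && nmax > 1) return(1L)
  if (c0 > 1 && c0 > med) return(2L)
  3L
}
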