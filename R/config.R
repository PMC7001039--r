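#' Simulation configuration for the synthetic phasiRNA cascade generator
#'
#' Defines the study conditions emulated by the generator: a small multi-
#' chromosome genome carrying planted PHAS loci, each with a trigger slice
#' site that sets a 21-nt phased register, duplex-paired phased sRNAs on both
#' strands (2-nt 3' overhangs), abundance decaying per cycle, optional 22-nt
#' products that shift the register by +1 downstream, cross-locus (trans)
#' triggering, plain target genes carrying phasiRNA-complementary sites,
#' degradome 5'-end peaks at every planted slice site, and uniform genomic
#' background noise in both data types.
#'
#' @param seed integer seed; identical config implies byte-identical outputs.
#' @param n_chromosomes,chrom_length genome shape (nt).
#' @param n_phas_loci number of planted PHAS loci.
#' @param n_cycles_per_locus phased 21-nt duplex cycles per locus.
#' @param trigger_length trigger sRNA length (21 or 22) for cis triggers.
#' @param shift_cycle optional cycle index at which a 22-nt phasiRNA is
#'   emitted; all later cycles carry a +1 register offset.  Applies to the
#'   loci listed in `shift_loci`.
#' @param shift_loci integer indices of loci subject to `shift_cycle`.
#' @param trans_edges list of `c(source, target)` locus index pairs; the
#'   target locus's register is set by a phasiRNA of the source locus and it
#'   receives no miRNA trigger of its own.
#' @param n_target_genes plain genes carrying one phasiRNA-complementary
#'   target site each (sources assigned round-robin over loci).
#' @param n_srna_libraries,n_degradome_libraries library counts.
#' @param locus_expression_rate per-(locus, library) Bernoulli expression
#'   probability.
#' @param abundance_decay per-cycle multiplicative abundance factor in (0,1].
#' @param base_abundance reads for the first phased cycle.
#' @param noise_fraction fraction of sRNA library read mass drawn uniformly
#'   from the genome (lengths 20-40 nt, random strand), in [0,1).
#' @param degradome_background_rate background 5'-tag probability per
#'   transcript position.
#' @param degradome_tag_abundance tag count at an expressed slice site.
#' @param poisson_jitter if `FALSE`, counts are exact floors of the decay
#'   series (oracle mode); if `TRUE`, Poisson-jittered.
#' @param trigger_wobble if `TRUE`, each cis trigger carries one G:U wobble
#'   outside the seed region (exercises the complementarity penalty).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 25000L,
                              n_phas_loci = 20L,
                              n_cycles_per_locus = 12L,
                              trigger_length = 22L,
                              shift_cycle = NULL,
                              shift_loci = integer(0),
                              trans_edges = list(),
                              n_target_genes = 10L,
                              n_srna_libraries = 6L,
                              n_degradome_libraries = 4L,
                              locus_expression_rate = 0.8,
                              abundance_decay = 0.9,
                              base_abundance = 500,
                              noise_fraction = 0.3,
                              degradome_background_rate = 0.02,
                              degradome_tag_abundance = 30,
                              poisson_jitter = TRUE,
                              trigger_wobble = FALSE) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_phas_loci = as.integer(n_phas_loci),
              n_cycles_per_locus = as.integer(n_cycles_per_locus),
              trigger_length = as.integer(trigger_length),
              shift_cycle = if (is.null(shift_cycle)) NULL else as.integer(shift_cycle),
              shift_loci = as.integer(shift_loci),
              trans_edges = trans_edges,
              n_target_genes = as.integer(n_target_genes),
              n_srna_libraries = as.integer(n_srna_libraries),
              n_degradome_libraries = as.integer(n_degradome_libraries),
              locus_expression_rate = locus_expression_rate,
              abundance_decay = abundance_decay,
              base_abundance = base_abundance,
              noise_fraction = noise_fraction,
              degradome_background_rate = degradome_background_rate,
              degradome_tag_abundance = degradome_tag_abundance,
              poisson_jitter = isTRUE(poisson_jitter),
              trigger_wobble = isTRUE(trigger_wobble))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (!is.null(cfg$shift_cycle)) {
    if (cfg$shift_cycle < 1L || cfg$shift_cycle >= cfg$n_cycles_per_locus)
      stopf("shift_cycle must satisfy 1 <= shift_cycle < n_cycles_per_locus")
  }
  if (length(cfg$shift_loci) > 0 && is.null(cfg$shift_cycle))
    stopf("shift_loci given but shift_cycle is NULL")
  if (cfg$noise_fraction < 0 || cfg$noise_fraction >= 1)
    stopf("noise_fraction must be in [0, 1)")
  if (cfg$abundance_decay <= 0 || cfg$abundance_decay > 1)
    stopf("abundance_decay must be in (0, 1]")
  if (!cfg$trigger_length %in% c(21L, 22L))
    stopf("trigger_length must be 21 or 22")
  if (cfg$locus_expression_rate < 0 || cfg$locus_expression_rate > 1)
    stopf("locus_expression_rate must be in [0, 1]")
  for (e in cfg$trans_edges) {
    if (length(e) != 2L || any(e < 1L) || any(e > cfg$n_phas_loci))
      stopf("trans_edges entries must be pairs of locus indices in 1..n_phas_loci")
  }
  if (any(cfg$shift_loci < 1L) || any(cfg$shift_loci > cfg$n_phas_loci))
    stopf("shift_loci indices out of range")
  invisible(cfg)
}

# locus design geometry: trigger site occupies transcript positions
# 1..trigger_length; phased cycles follow; 6 nt 3' margin accommodates the
# final duplex overhang.
locus_region_length <- function(cfg, trig_len = cfg$trigger_length) {
  trig_len + 21L * cfg$n_cycles_per_locus + 6L
}

#' Pipeline stage parameters
#'
#' One table holding every stage constant: read filters (counts >= 50,
#' lengths 20-40 nt, >= 100 unique sequences per library), mapping rules
#' (21/22 nt, exact, <= 10 locations, fractional multimapper counts),
#' candidate-region selection (top 15% by abundance), phasing score threshold,
#' >= 3-library consensus, 220 nt extension, degradome category weights
#' (5/4/0.5 for categories 0/1/2), bin rank weights (5/2/0.5), trigger minimum
#' score 10, target validation threshold 15 (ECDF 1% tail), combined raw count
#' >= 50 for target candidates, and the >70% overlap rule for feature
#' assignment.
#'
#' @param ... named overrides of any default.
#' @return named list of parameters.
#' @export
phasinet_params <- function(...) {
  p <- list(
    min_count = 50,
    min_len = 20L,
    max_len = 40L,
    min_unique = 100L,
    allowed_lengths = c(21L, 22L),
    max_locations = 10L,
    top_fraction = 0.15,
    min_regions = 30L,
    island_gap = 21L,
    cycle = 21L,
    window_cycles = 11L,
    min_phasing_score = 15,
    min_libraries = 3L,
    pad = 220L,
    deg_weights = c(`0` = 5, `1` = 4, `2` = 0.5, `3` = 0, `4` = 0),
    bin_weights = c(5, 2, 0.5),
    trigger_min_score = 10,
    target_threshold = 15,
    min_combined = 50,
    min_overlap = 0.70,
    max_rounds = 3L,
    max_allen = 7.0,
    ecdf_quantile = 0.99,
    deg_prefix = 20L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}
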