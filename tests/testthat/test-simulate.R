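test_that("generation is deterministic and respects feature counts", {
  cfg <- tiny_config()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$features, g2$features)
  expect_equal(sum(g1$features$role == "phas_host"), cfg$n_phas_loci)
  expect_setequal(unique(g1$features$strand), c("+", "-"))

  p1 <- plant_phas_cascade(g1, cfg)
  p2 <- plant_phas_cascade(g2, cfg)
  expect_identical(p1$truth$loci, p2$truth$loci)
  l1a <- simulate_srna_library(p1$truth, 1, cfg, p1$genome)
  l1b <- simulate_srna_library(p1$truth, 1, cfg, p1$genome)
  expect_identical(l1a, l1b)
  d1a <- simulate_degradome_library(p1$truth, 2, cfg)
  d1b <- simulate_degradome_library(p1$truth, 2, cfg)
  expect_identical(d1a, d1b)
})

test_that("impossible locus placement raises a sizing error", {
  expect_error(generate_genome(simulation_config(
    seed = 1, n_chromosomes = 1, chrom_length = 500, n_phas_loci = 10,
    n_cycles_per_locus = 8, n_target_genes = 0)),
    "chrom_length")
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(shift_cycle = 12, shift_loci = 1,
                                 n_cycles_per_locus = 12), "shift_cycle")
  expect_error(simulation_config(noise_fraction = 1), "noise_fraction")
  expect_error(simulation_config(abundance_decay = 0), "abundance_decay")
  expect_error(simulation_config(trans_edges = list(c(1, 99))), "trans_edges")
})

test_that("phased records carry the planted registers, offsets and duplex geometry", {
  cfg <- tiny_config(n_cycles_per_locus = 5, shift_cycle = 3, shift_loci = 1)
  pc <- plant_phas_cascade(generate_genome(cfg), cfg)
  for (lt in pc$truth$loci) {
    rc <- lt$phasirna_records
    # register anchor sits one base 3' of the slice position on the transcript
    expect_equal(lt$anchor_t, lt$slice_t + 1L)
    sense <- rc[rc$strand == "+", ]
    # phased 5' ends satisfy (t5 - anchor) mod 21 == offset
    expect_equal((sense$t5 - lt$anchor_t) %% 21, sense$offset %% 21)
    # duplex partner is the reverse complement of the sense window shifted +2
    for (cc in unique(rc$cycle)) {
      sn <- rc[rc$cycle == cc & rc$strand == "+", ]
      an <- rc[rc$cycle == cc & rc$strand == "-", ]
      expect_identical(an$sequence, rev_comp(substr(
        lt$transcript, sn$t5 + 2L, sn$t5 + sn$length + 1L)))
    }
  }
  sh <- pc$truth$loci[[1]]$phasirna_records
  expect_equal(unique(sh$offset[sh$cycle <= 3]), 0L)
  expect_equal(unique(sh$offset[sh$cycle > 3]), 1L)
  expect_equal(unique(sh$length[sh$cycle == 3]), 22L)
  expect_equal(unique(sh$length[sh$cycle != 3]), 21L)
  # no shift planted at the other loci
  other <- pc$truth$loci[[2]]$phasirna_records
  expect_equal(unique(other$offset), 0L)
})

test_that("trans edges plant a perfectly complementary cross-locus site", {
  cfg <- tiny_config(trans_edges = list(c(1, 2)))
  pc <- plant_phas_cascade(generate_genome(cfg), cfg)
  a <- pc$truth$loci[[1]]; b <- pc$truth$loci[[2]]
  phA <- a$phasirna_records$sequence[a$phasirna_records$cycle == 1 &
                                       a$phasirna_records$strand == "+"]
  expect_true(b$is_trans)
  expect_identical(b$trigger_sequence, phA)
  expect_identical(substr(b$transcript, 1, 21), rev_comp(phA))
  expect_identical(a$trans_targets, b$locus_id)
})

test_that("library counts follow the decay series and conserve totals", {
  cfg <- tiny_config(n_cycles_per_locus = 4, abundance_decay = 0.5,
                     base_abundance = 100)
  pc <- plant_phas_cascade(generate_genome(cfg), cfg)
  lt <- pc$truth$loci[[1]]
  expect_equal(lt$phasirna_records$base_count[lt$phasirna_records$strand == "+"],
               c(100, 50, 25, 12))
  lib <- simulate_srna_library(pc$truth, 1, cfg, pc$genome)
  # jitter off, noise 0: every truth read present at its exact count
  for (i in seq_len(nrow(lt$phasirna_records))) {
    r <- lt$phasirna_records[i, ]
    expect_equal(lib$reads$count[lib$reads$sequence == r$sequence], r$base_count)
  }
  # count conservation: library total equals emitted truth totals
  emitted <- sum(vapply(pc$truth$loci, function(l)
    sum(l$phasirna_records$base_count) +
      (!l$is_trans) * cfg$base_abundance, numeric(1)))
  expect_equal(sum(lib$reads$count), emitted)
})

test_that("unexpressed loci leave only noise, and noise obeys its fraction", {
  cfg <- tiny_config(locus_expression_rate = 0)
  pc <- plant_phas_cascade(generate_genome(cfg), cfg)
  lib <- simulate_srna_library(pc$truth, 1, cfg, pc$genome)
  expect_equal(nrow(lib$reads), 0L)

  cfg2 <- tiny_config(noise_fraction = 0.3)
  pc2 <- plant_phas_cascade(generate_genome(cfg2), cfg2)
  lib2 <- simulate_srna_library(pc2$truth, 1, cfg2, pc2$genome)
  truth_seqs <- unlist(lapply(pc2$truth$loci, function(l)
    c(l$phasirna_records$sequence, l$trigger_sequence)))
  noise <- !lib2$reads$sequence %in% truth_seqs
  frac <- sum(lib2$reads$count[noise]) / sum(lib2$reads$count)
  expect_gt(frac, 0.2); expect_lt(frac, 0.4)
  expect_true(all(nchar(lib2$reads$sequence[noise]) %in% 20:40))
})

test_that("degradome tags sit at planted slice sites when background is off", {
  cfg <- tiny_config(degradome_background_rate = 0)
  pc <- plant_phas_cascade(generate_genome(cfg), cfg)
  dl <- simulate_degradome_library(pc$truth, 1, cfg)
  anchors <- c(
    vapply(pc$truth$loci, function(l)
      substr(l$transcript, l$anchor_t, l$anchor_t + 19L), character(1)),
    vapply(seq_len(nrow(pc$truth$target_sites)), function(j)
      substr(pc$truth$target_sites$transcript[j],
             pc$truth$target_sites$anchor_t[j],
             pc$truth$target_sites$anchor_t[j] + 19L), character(1)))
  expect_true(all(dl$tags$sequence %in% anchors))
  # profile maximum sits at the planted slice for an expressed locus
  lt <- pc$truth$loci[[1]]
  prof <- build_degradome_profiles(dl, c(x = lt$transcript))$x
  expect_equal(which.max(prof), lt$anchor_t)
  # a locus unexpressed in this library contributes no tag
  cfg3 <- tiny_config(degradome_background_rate = 0, seed = 12,
                      locus_expression_rate = 0.5)
  pc3 <- plant_phas_cascade(generate_genome(cfg3), cfg3)
  dl3 <- simulate_degradome_library(pc3$truth, 1, cfg3)
  off <- names(which(!pc3$truth$deg_expression[, 1]))
  if (length(off)) {
    lt3 <- pc3$truth$loci[[off[1]]]
    tag <- substr(lt3$transcript, lt3$anchor_t, lt3$anchor_t + 19L)
    expect_false(tag %in% dl3$tags$sequence)
  }
})
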