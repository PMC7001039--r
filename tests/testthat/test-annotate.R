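mk_aln <- function(eff, strand = "+", len = 21L, frac = 1, lib = "L",
                   count = frac, chrom = "c1", seq = NULL) {
  start <- ifelse(strand == "+", eff, eff + 2L)
  data.frame(library_id = lib,
             sequence = if (is.null(seq)) sprintf("R%05d%s", eff, strand) else seq,
             length = len, count = count, chrom = chrom, start = start,
             end = start + len - 1L, strand = strand, n_locations = 1L,
             fractional_count = frac, eff5 = eff, stringsAsFactors = FALSE)
}

test_that("phase bins follow mod-21 arithmetic with the duplex correction", {
  locus <- data.frame(locus_id = "P1", chrom = "c1", start = 1000L, end = 1400L)
  a <- rbind(mk_aln(1000L), mk_aln(1021L), mk_aln(1001L),
             mk_aln(1000L, strand = "-"),        # duplex partner of bin 1
             mk_aln(999L), mk_aln(1500L))        # outside interval
  bt <- build_phase_bins(locus, a)
  pooled <- rowSums(bt$pooled)
  expect_equal(unname(pooled[1]), 3)   # 1000 (+), 1021 (+), duplex partner
  expect_equal(unname(pooled[2]), 1)   # 1001
  expect_equal(sum(pooled), 4)         # eff5 999 and 1500 excluded
  # duplex invariant across random cases: sense at x and antisense partner
  # (leftmost x+2) always share a bin, for both 21- and 22-nt products
  set.seed(10)
  for (i in 1:200) {
    x <- 1000L + sample(0:380, 1)
    len <- sample(c(21L, 22L), 1)
    pair <- rbind(mk_aln(x, "+", len = len), mk_aln(x, "-", len = len))
    bb <- build_phase_bins(locus, pair)
    expect_equal(unname(which(rowSums(bb$pooled) > 0)),
                 ((x - 1000L) %% 21L) + 1L)
    expect_equal(sum(rowSums(bb$pooled) > 0), 1L)
  }
})

test_that("bin ranking assigns 5/2/0.5 with additive libraries and tie-breaks", {
  m <- matrix(0, 21, 1, dimnames = list(1:21, "l1"))
  m[3, 1] <- 100; m[10, 1] <- 50; m[1, 1] <- 10
  rs <- rank_bins(m)
  expect_equal(unname(rs[c(3, 10, 1)]), c(5, 2, 0.5))
  expect_equal(sum(rs), 7.5)
  # two identical libraries double every score
  rs2 <- rank_bins(cbind(m, l2 = m[, 1]))
  expect_equal(unname(rs2[c(3, 10, 1)]), c(10, 4, 1))
  # abundance tie for first: lower bin index ranked first
  mt <- matrix(0, 21, 1, dimnames = list(1:21, "l1"))
  mt[5, 1] <- 100; mt[2, 1] <- 100
  rst <- rank_bins(mt)
  expect_equal(unname(rst[2]), 5)
  expect_equal(unname(rst[5]), 2)
})

test_that("primary trigger selection is argmax with the stated minimum", {
  ev <- data.frame(srna_id = c("a", "b"), srna_sequence = c("A", "B"),
                   locus_id = "P1", target_strand = c("+", "-"),
                   slice_t = c(10L, 20L), slice_genomic = c(110L, 120L),
                   allen_score = c(1, 0), deg_score = c(12, 7),
                   stringsAsFactors = FALSE)
  pt <- assign_primary_trigger(ev)
  expect_equal(pt$srna_id, "a")
  expect_equal(pt$target_strand, "+")
  # best score below 10 -> nothing assigned
  ev$deg_score <- c(9.5, 7)
  expect_null(assign_primary_trigger(ev))
  # ties resolved by lower penalty
  ev$deg_score <- c(12, 12)
  expect_equal(assign_primary_trigger(ev)$srna_id, "b")
})

test_that("secondary triggers require polarity match and a top-ranked bin", {
  rs <- setNames(numeric(21), 1:21)
  rs[c(4, 9, 15)] <- c(10, 7, 3); rs[12] <- 1
  mk_ev <- function(bin, strand, score = 11) {
    g <- 1000L + bin - 1L          # plus-strand anchor in the requested bin
    if (strand == "-") g <- g + 22L
    data.frame(srna_id = "s", srna_sequence = "SEQ", locus_id = "P1",
               target_strand = strand, slice_t = 1L, slice_genomic = g,
               allen_score = 0, deg_score = score, stringsAsFactors = FALSE)
  }
  # slicing in the 2nd-ranked bin, matching polarity, score 11 -> accepted
  expect_equal(nrow(find_secondary_triggers(mk_ev(9, "+"), "+", rs, 1000L)), 1L)
  # adjacent (+1) to a top-3 bin -> accepted
  expect_equal(nrow(find_secondary_triggers(mk_ev(5, "+"), "+", rs, 1000L)), 1L)
  # 4th-ranked bin, not adjacent to the top three -> rejected
  expect_equal(nrow(find_secondary_triggers(mk_ev(12, "+"), "+", rs, 1000L)), 0L)
  # opposite strand -> rejected
  expect_equal(nrow(find_secondary_triggers(mk_ev(9, "-"), "+", rs, 1000L)), 0L)
  # below the score minimum -> rejected
  expect_equal(nrow(find_secondary_triggers(mk_ev(9, "+", score = 9), "+", rs,
                                            1000L)), 0L)
  # duplicates of existing assignments are not re-accepted
  ex <- mk_ev(9, "+")
  expect_equal(nrow(find_secondary_triggers(mk_ev(9, "+"), "+", rs, 1000L,
                                            existing = ex)), 0L)
})

test_that("phasiRNA extraction keeps the register and adjacent bins only", {
  locus <- data.frame(locus_id = "P1", chrom = "c1", start = 1000L, end = 1400L,
                      polarity = "+", stringsAsFactors = FALSE)
  anchor <- 1000L + 3L   # bin 4
  a <- rbind(mk_aln(anchor), mk_aln(anchor + 21L), mk_aln(anchor, "-"),
             mk_aln(anchor - 1L), mk_aln(anchor + 1L),     # bins 3 and 5
             mk_aln(anchor + 2L), mk_aln(anchor + 10L))    # bins 6 and 14
  bt <- build_phase_bins(locus, a)
  rec <- extract_phasirnas(locus, bt$reads, anchors = anchor,
                           main_anchor = anchor)
  expect_setequal(unique(rec$bin), c(3L, 4L, 5L))
  expect_false(any(rec$bin == 6L))
  # offsets: reads in the register have offset 0; neighbours are +/- 1
  expect_equal(rec$offset[rec$bin == 4L], rep(0L, sum(rec$bin == 4L)))
  expect_setequal(rec$offset[rec$bin == 3L], -1L)
  expect_setequal(rec$offset[rec$bin == 5L], 1L)
  # the duplex partner carries the same register and offset as its sense read
  anti <- rec[rec$strand == "-", ]
  expect_equal(anti$offset, 0L)
  expect_equal(anti$register_index,
               rec$register_index[rec$strand == "+" & rec$offset == 0][1])
})

test_that("phasiRNA names reproduce printed exemplars and round-trip", {
  expect_equal(name_phasirna("AT2G39675", "-", 20L, "-", 1L, 21L),
               "AT2G39675(-)_20-(+1)")
  expect_equal(name_phasirna("AT3G17185", "+", 18L, "+", -1L, 22L),
               "AT3G17185(+)_18+(-1)_22")
  expect_equal(name_phasirna("AT1G50055", "+", 7L, "+", 0L, 21L),
               "AT1G50055(+)_7+")
  p <- parse_phasirna_name("AT2G39675(-)_20-(+1)")
  expect_equal(p$register_index, 20L)
  expect_equal(p$offset, 1L)
  expect_equal(p$length, 21L)
  # unsigned positive offsets are accepted on parse
  expect_equal(parse_phasirna_name("AT2G39681(-)_19-(2)")$offset, 2L)
  expect_error(parse_phasirna_name("not-a-name"), "malformed")
  # round-trip on 10,000 random records
  set.seed(123)
  n <- 10000
  rec <- data.frame(locus = sprintf("AT%dG%05d", sample(1:5, n, TRUE),
                                    sample(99999, n, TRUE)),
                    locus_strand = sample(c("+", "-"), n, TRUE),
                    register_index = sample(1:60, n, TRUE),
                    read_strand = sample(c("+", "-"), n, TRUE),
                    offset = sample(-10:10, n, TRUE),
                    length = sample(c(21L, 22L), n, TRUE),
                    stringsAsFactors = FALSE)
  nm <- name_phasirna(rec$locus, rec$locus_strand, rec$register_index,
                      rec$read_strand, rec$offset, rec$length)
  back <- parse_phasirna_name(nm)
  expect_identical(back, rec)
})

test_that("locus-feature assignment uses the >70% overlap and polarity rules", {
  feats <- data.frame(chrom = "c1", start = c(900L, 1100L), end = c(1500L, 1180L),
                      strand = c("+", "-"), type = "gene",
                      ID = c("AT1G00010", "AT1G00020"), stringsAsFactors = FALSE)
  mk_locus <- function(pol) data.frame(locus_id = "P1", chrom = "c1",
                                       start = 1000L, end = 1400L,
                                       n_detections = 3L, polarity = pol,
                                       stringsAsFactors = FALSE)
  # overlap 1.0, polarity match -> confirmed gene ID
  conf <- assign_locus_feature(mk_locus("+"), feats)
  expect_equal(conf$assigned_name, "AT1G00010")
  expect_equal(conf$confidence, "confirmed")
  expect_gt(conf$overlap_fraction, 0.7)
  # no trigger polarity -> tentative, lowercase
  tent <- assign_locus_feature(mk_locus(NA_character_), feats)
  expect_equal(tent$assigned_name, "at1g00010")
  expect_equal(tent$confidence, "tentative")
  # polarity known but only the opposite strand overlaps -> coordinate name
  opp <- assign_locus_feature(mk_locus("-"), feats)
  expect_equal(opp$assigned_name, "c1:1000-1400")
  expect_equal(opp$confidence, "unassigned")
  # no overlapping feature at all -> coordinate name
  none <- assign_locus_feature(mk_locus("+"), feats[feats$chrom == "zz", ])
  expect_equal(none$assigned_name, "c1:1000-1400")
  # overlap just below the threshold is rejected (strict >0.70)
  f71 <- data.frame(chrom = "c1", start = 1000L, end = 1281L, strand = "+",
                    type = "gene", ID = "G", stringsAsFactors = FALSE)
  expect_equal(assign_locus_feature(mk_locus("+"), f71)$confidence, "confirmed")
  f70 <- f71; f70$end <- 1280L   # overlap 280/400 = 0.70 exactly, not > 0.70
  expect_equal(assign_locus_feature(mk_locus("+"), f70)$confidence, "unassigned")
})

test_that("phasiRNA classification separates canonical from non-canonical", {
  rec <- data.frame(length = c(21L, 21L, 22L, 22L, 21L),
                    offset = c(0L, 1L, 0L, -1L, 0L))
  tab <- classify_phasirnas(rec)
  expect_equal(tab$n[tab$length == 21 & tab$class == "canonical"], 2L)
  expect_equal(tab$n[tab$length == 21 & tab$class == "non-canonical"], 1L)
  expect_equal(sum(tab$n[tab$class == "non-canonical"]), 3L)
  expect_equal(sum(tab$n[tab$length == 22 & tab$class == "canonical"]), 0L)
})
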