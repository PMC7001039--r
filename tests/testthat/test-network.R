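stub_annotation <- function(triggers = NULL, phasirnas = NULL) {
  list(triggers = if (is.null(triggers))
    data.frame(srna_id = character(0), locus_id = character(0),
               srna_sequence = character(0), stringsAsFactors = FALSE)
    else triggers,
    phasirnas = if (is.null(phasirnas))
      data.frame(name = character(0), locus_id = character(0),
                 sequence = character(0), stringsAsFactors = FALSE)
    else phasirnas)
}

mirna_tab <- data.frame(name = c("miR1", "miR2"),
                        precursor = c("PRE1", "PRE2"),
                        sequence = c("A", "C"), stringsAsFactors = FALSE)

test_that("candidate selection sums raw counts across libraries inclusively", {
  libs <- list(
    list(library_id = "l1",
         reads = data.frame(sequence = c("AAA", "CCC"), count = c(30, 10))),
    list(library_id = "l2",
         reads = data.frame(sequence = c("AAA", "GGG"), count = c(25, 49))))
  tab <- data.frame(srna_id = c("a", "c", "g", "x"),
                    sequence = c("AAA", "CCC", "GGG", "TTT"),
                    stringsAsFactors = FALSE)
  sel <- select_active_candidates(tab, libs, 50)
  expect_equal(sel$srna_id, "a")            # 30 + 25 = 55 kept
  expect_equal(sel$combined_count, 55)      # 49 and 10 excluded; absent excluded
  sel50 <- select_active_candidates(tab, c(libs, list(
    list(library_id = "l3",
         reads = data.frame(sequence = "GGG", count = 1)))), 50)
  expect_setequal(sel50$srna_id, c("a", "g"))   # exactly 50 retained
})

test_that("a minimal precursor-miRNA-target chain yields 3 nodes and 2 edges", {
  ann <- stub_annotation()
  inter <- data.frame(srna_id = "miR1", transcript_id = "T1",
                      slice_position = 10L, allen_score = 0,
                      target_deg_score = 15, validated = TRUE,
                      stringsAsFactors = FALSE)
  g <- build_network(ann, inter, mirna_tab)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  et <- igraph::E(g)$type
  expect_equal(sort(et), c("biogenesis", "cleavage"))
})

test_that("a miRNA-triggered locus with two active phasiRNAs gives 3+3 edges", {
  trig <- data.frame(srna_id = "miR1", locus_id = "PHAS1",
                     srna_sequence = "A", stringsAsFactors = FALSE)
  ph <- data.frame(name = c("P1", "P2"), locus_id = "PHAS1",
                   sequence = c("AA", "CC"), stringsAsFactors = FALSE)
  inter <- data.frame(srna_id = c("P1", "P2"), transcript_id = c("T1", "T2"),
                      slice_position = 1L, allen_score = 0,
                      target_deg_score = 15, validated = TRUE,
                      stringsAsFactors = FALSE)
  g <- build_network(stub_annotation(trig, ph), inter, mirna_tab)
  expect_equal(sum(igraph::E(g)$type == "biogenesis"), 3)
  expect_equal(sum(igraph::E(g)$type == "cleavage"), 3)
  # bipartite: every edge joins an sRNA and a transcript
  el <- igraph::as_edgelist(g)
  ty <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_true(all(ty[el[, 1]] != ty[el[, 2]]))
  # phasiRNA nodes have exactly one biogenesis in-edge
  for (p in c("P1", "P2")) {
    ie <- igraph::incident(g, p, mode = "in")
    expect_equal(sum(igraph::edge_attr(g, "type", ie) == "biogenesis"), 1)
  }
  # an interaction naming an unknown sRNA fails loudly
  bad <- inter; bad$srna_id[1] <- "mystery"
  expect_error(build_network(stub_annotation(trig, ph), bad, mirna_tab),
               "unknown")
  # empty interactions give an empty network
  g0 <- build_network(stub_annotation(), inter[0, ], mirna_tab)
  expect_equal(igraph::vcount(g0), 0)
})

test_that("network metrics match closed forms on toy graphs", {
  cyc <- igraph::make_graph(c("a", "b", "b", "c", "c", "a"), directed = TRUE)
  igraph::V(cyc)$type <- "sRNA"
  m <- network_metrics(cyc)
  expect_equal(m$density, 0.5)           # 3 / (3 * 2)
  expect_equal(m$n_components, 1)
  tri <- igraph::make_graph(c("a", "b", "b", "c", "a", "c"), directed = TRUE)
  igraph::V(tri)$type <- "sRNA"
  expect_equal(network_metrics(tri)$avg_clustering, 1)
  two <- igraph::make_graph(c("a", "b", "c", "d"), directed = TRUE)
  igraph::V(two)$type <- "sRNA"
  m2 <- network_metrics(two)
  expect_equal(m2$n_components, 2)
  expect_equal(sum(m2$component_sizes), igraph::vcount(two))
  expect_error(network_metrics(igraph::make_empty_graph(1)), "density")
})

test_that("correlation statistics follow the t-distribution formulas", {
  x <- 1:10
  perf <- correlate(x, 2 * x + 1)
  expect_equal(perf$r, 1)
  expect_equal(perf$R2, 1)
  expect_equal(correlate(rnorm(57), rnorm(57))$df, 55)
  expect_error(correlate(rep(1, 5), 1:5), "variance")
  # seeded bivariate sample: agree with cor.test as independent oracle
  set.seed(2025)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    a <- rnorm(n); b <- 0.6 * a + rnorm(n, sd = 0.8)
    ct <- stats::cor.test(a, b)
    ours <- correlate(a, b)
    expect_equal(ours$r, unname(ct$estimate))
    expect_equal(ours$t, unname(ct$statistic))
    expect_equal(ours$df, unname(ct$parameter))
    expect_equal(ours$p, ct$p.value)
    expect_equal(ours$t, ours$r * sqrt(ours$df / (1 - ours$r^2)))
  }
})

test_that("hypergeometric enrichment matches an enumeration oracle with BH control", {
  universe <- sprintf("g%04d", 1:1000)
  tmap <- rbind(
    data.frame(gene_id = universe[1:10], term_id = "T:rich",
               stringsAsFactors = FALSE),
    data.frame(gene_id = universe, term_id = "T:all",
               stringsAsFactors = FALSE),
    data.frame(gene_id = universe[500:700], term_id = "T:mid",
               stringsAsFactors = FALSE))
  genes <- universe[1:10]
  res <- go_enrichment(genes, universe, tmap)
  over <- res[res$direction == "over", ]
  # exact tail for the fully contained term, by direct enumeration
  p_exact <- sum(vapply(10:10, function(i)
    choose(10, i) * choose(990, 10 - i) / choose(1000, 10), numeric(1)))
  expect_equal(over$raw_p[over$term_id == "T:rich"], p_exact)
  expect_lt(over$raw_p[over$term_id == "T:rich"], 1e-10)
  # a term covering the entire universe is never enriched
  expect_equal(over$raw_p[over$term_id == "T:all"], 1)
  expect_false(over$significant[over$term_id == "T:all"])
  # BH: corrected p monotone non-decreasing in raw p order
  o <- over[order(over$raw_p), ]
  expect_true(all(diff(o$corrected_p) >= -1e-12))
  expect_true(all(res$corrected_p >= res$raw_p - 1e-12))
  # under-representation direction is reported
  expect_true(any(res$direction == "under"))
  expect_error(go_enrichment(c(genes, "novel"), universe, tmap), "universe")
})

test_that("transcript-to-genome mapping honors splicing and strand", {
  # single exon, plus strand
  ex1 <- data.frame(chrom = "c1", start = 100L, end = 400L, strand = "+",
                    stringsAsFactors = FALSE)
  feats <- data.frame(start = c(100L, 200L), end = c(199L, 400L),
                      type = c("5UTR", "CDS"), stringsAsFactors = FALSE)
  m <- map_target_site(50L, ex1, feats)
  expect_equal(m$genomic_position, 149L)
  expect_equal(m$label, "5UTR")
  # site 10 nt past a 100-nt first exon lands in exon 2 with intron offset
  ex2 <- data.frame(chrom = "c1", start = c(100L, 300L), end = c(199L, 500L),
                    strand = "+", stringsAsFactors = FALSE)
  expect_equal(map_target_site(110L, ex2)$genomic_position, 309L)
  # minus strand: genomic position decreases as transcript position grows
  ex3 <- data.frame(chrom = "c1", start = 100L, end = 400L, strand = "-",
                    stringsAsFactors = FALSE)
  expect_equal(map_target_site(1L, ex3)$genomic_position, 400L)
  expect_equal(map_target_site(2L, ex3)$genomic_position, 399L)
  expect_error(map_target_site(9999L, ex1), "beyond")
})
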