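# Degradome-validated target calling, bipartite network assembly and
# structural/functional analysis.

#' Select target-search candidates by combined raw abundance
#'
#' An sRNA is a candidate when its raw collapsed counts, summed across all
#' libraries before multimapper division, reach `min_combined` (inclusive).
#'
#' @param srna_table data.frame with `srna_id` and `sequence`.
#' @param libraries list of collapsed sRNA libraries.
#' @param min_combined combined raw count threshold (default 50).
#' @return subset of `srna_table` with a `combined_count` column.
#' @export
select_active_candidates <- function(srna_table, libraries, min_combined = 50) {
  seqs <- normalize_ut(srna_table$sequence)
  comb <- vapply(seqs, function(s) {
    sum(vapply(libraries, function(lb) {
      i <- match(s, normalize_ut(lb$reads$sequence))
      if (is.na(i)) 0 else lb$reads$count[i]
    }, numeric(1)))
  }, numeric(1))
  out <- srna_table[comb >= min_combined, , drop = FALSE]
  out$combined_count <- comb[comb >= min_combined]
  rownames(out) <- NULL
  out
}

#' Validate sRNA-transcript interactions with degradome evidence
#'
#' Every complementarity hit (penalty at most `max_allen`) of a candidate
#' sRNA on a transcript is scored by summing degradome category weights
#' (5/4/0.5 for categories 0/1/2) across libraries at the predicted slice
#' position; interactions scoring at least `threshold` are validated and
#' their sRNAs flagged active.
#'
#' @param candidates data.frame with `srna_id` and `sequence`.
#' @param transcripts named character vector of transcript sequences.
#' @param degradome_libraries list of degradome libraries.
#' @param params parameters ([phasinet_params()]); uses max_allen,
#'   deg_weights, deg_prefix, target_threshold, ecdf_quantile.
#' @return list with `interactions` (srna_id, transcript_id,
#'   slice_position, target_deg_score, validated), `active_srnas` and the
#'   observed `ecdf_threshold` of the score distribution.
#' @export
validate_targets <- function(candidates, transcripts, degradome_libraries,
                             params = phasinet_params()) {
  profiles <- lapply(degradome_libraries, build_degradome_profiles,
                     transcripts = transcripts, prefix = params$deg_prefix)
  rows <- list()
  for (ci in seq_len(nrow(candidates))) {
    q <- normalize_ut(candidates$sequence[ci])
    for (ti in seq_along(transcripts)) {
      hits <- find_target_alignments(q, transcripts[[ti]],
                                     max_allen = params$max_allen,
                                     srna_id = candidates$srna_id[ci],
                                     transcript_id = names(transcripts)[ti])
      if (nrow(hits) == 0L) next
      for (hi in seq_len(nrow(hits))) {
        cats <- vapply(profiles, function(pl)
          categorize_cleavage(pl[[names(transcripts)[ti]]],
                              hits$slice_position[hi]), integer(1))
        rows[[length(rows) + 1L]] <- data.frame(
          srna_id = hits$srna_id[hi], transcript_id = hits$transcript_id[hi],
          slice_position = hits$slice_position[hi],
          allen_score = hits$allen_score[hi],
          target_deg_score = weighted_score(cats, params$deg_weights),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    inter <- data.frame(srna_id = character(0), transcript_id = character(0),
                        slice_position = integer(0), allen_score = numeric(0),
                        target_deg_score = numeric(0), validated = logical(0),
                        stringsAsFactors = FALSE)
    return(list(interactions = inter, active_srnas = character(0),
                ecdf_threshold = NA_real_))
  }
  inter <- do.call(rbind, rows)
  inter$validated <- inter$target_deg_score >= params$target_threshold
  list(interactions = inter,
       active_srnas = unique(inter$srna_id[inter$validated]),
       ecdf_threshold = ecdf_threshold(inter$target_deg_score,
                                       params$ecdf_quantile))
}

#' Convert a transcript position to genomic coordinates through an exon model
#'
#' Honors splicing and strand; optionally labels the position with the
#' overlapping sub-feature (CDS/UTR/...) given child features in transcript
#' coordinates converted ranges.
#'
#' @param position 1-based transcript coordinate.
#' @param exons data.frame of exon genomic intervals (start, end, strand),
#'   in transcript order.
#' @param features optional data.frame of genomic sub-features (start, end,
#'   type) used for labelling.
#' @return list with `chrom` (if present in exons), `genomic_position` and
#'   `label`.
#' @export
map_target_site <- function(position, exons, features = NULL) {
  widths <- exons$end - exons$start + 1L
  if (position < 1L || position > sum(widths))
    stopf("position %d beyond transcript length %d", position, sum(widths))
  cum <- cumsum(widths)
  ei <- which(position <= cum)[1]
  into <- position - (if (ei > 1L) cum[ei - 1L] else 0L)
  gpos <- if (exons$strand[ei] == "-") exons$end[ei] - into + 1L
          else exons$start[ei] + into - 1L
  label <- NA_character_
  if (!is.null(features) && nrow(features)) {
    hit <- features$start <= gpos & features$end >= gpos
    if (any(hit)) label <- features$type[which(hit)[1]]
  }
  list(chrom = if ("chrom" %in% names(exons)) exons$chrom[1] else NA_character_,
       genomic_position = gpos, label = label)
}

#' Assemble the bipartite directed regulatory network
#'
#' Nodes are sRNAs (miRNAs, phasiRNAs) and transcripts (miRNA precursors,
#' PHAS loci, targets); edges are biogenesis (transcript to sRNA) and
#' cleavage (sRNA to transcript).  The network is restricted to active
#' sRNAs -- those with at least one degradome-validated target (including
#' trigger events on PHAS transcripts) -- with known precursors, plus their
#' precursors and validated targets.
#'
#' @param annotation result of [iterate_annotation()].
#' @param interactions validated interaction table from
#'   [validate_targets()] (only `validated` rows are used).
#' @param mirnas known-miRNA table with `name` and `precursor`.
#' @return an [igraph] directed graph with vertex attributes `type`
#'   (sRNA/transcript) and `class`, and edge attribute `type`
#'   (biogenesis/cleavage).
#' @export
build_network <- function(annotation, interactions, mirnas) {
  val <- interactions[interactions$validated, , drop = FALSE]
  trig <- annotation$triggers
  # sRNA nodes are restricted to those with a known precursor: a phasiRNA
  # record or a miRNA with an annotated precursor
  known <- c(annotation$phasirnas$name, mirnas$name)
  trig <- trig[trig$srna_id %in% known, , drop = FALSE]
  active <- unique(c(val$srna_id, trig$srna_id))
  if (length(active) == 0L)
    return(igraph::make_empty_graph(directed = TRUE))

  ph <- annotation$phasirnas
  is_phasi <- active %in% ph$name
  mir_idx <- match(active, mirnas$name)
  known_mir <- !is.na(mir_idx)
  unknown <- active[!is_phasi & !known_mir]
  if (length(unknown))
    stopf("interaction references unknown sRNA node(s): %s",
          paste(head(unknown, 3), collapse = ", "))

  edges <- list(); vclass <- list()
  add_v <- function(id, type, class) {
    vclass[[id]] <<- c(type = type, class = class)
  }
  add_e <- function(from, to, type) {
    edges[[length(edges) + 1L]] <<- c(from, to, type)
  }
  for (i in seq_along(active)) {
    id <- active[i]
    if (is_phasi[i]) {
      add_v(id, "sRNA", "phasiRNA")
      lid <- ph$locus_id[match(id, ph$name)]
      add_v(lid, "transcript", "PHAS_locus")
      add_e(lid, id, "biogenesis")
    } else {
      add_v(id, "sRNA", "miRNA")
      pre <- mirnas$precursor[mir_idx[i]]
      add_v(pre, "transcript", "miRNA_precursor")
      add_e(pre, id, "biogenesis")
    }
  }
  for (j in seq_len(nrow(trig))) {
    add_v(trig$locus_id[j], "transcript", "PHAS_locus")
    add_e(trig$srna_id[j], trig$locus_id[j], "cleavage")
  }
  for (j in seq_len(nrow(val))) {
    if (is.null(vclass[[val$transcript_id[j]]]))
      add_v(val$transcript_id[j], "transcript", "target")
    add_e(val$srna_id[j], val$transcript_id[j], "cleavage")
  }
  em <- do.call(rbind, edges)
  em <- em[!duplicated(paste(em[, 1], em[, 2], em[, 3])), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], type = em[, 3],
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = names(vclass),
                          type = vapply(vclass, `[[`, "", "type"),
                          class = vapply(vclass, `[[`, "", "class"),
                          stringsAsFactors = FALSE))
  g
}

#' Structural metrics of the regulatory network
#'
#' Weakly connected components, directed density `E / (N (N - 1))`,
#' average local clustering coefficient on the undirected projection
#' (nodes of degree < 2 contribute 0), per-class in/outdegree
#' distributions, and a least-squares fit of `log10 p(K)` on `log10 K`
#' over degrees with positive frequency.
#'
#' @param g network from [build_network()].
#' @return list of metrics.
#' @export
network_metrics <- function(g) {
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  if (n < 2L) stopf("density undefined for fewer than 2 nodes")
  comp <- igraph::components(g, mode = "weak")
  gu <- igraph::as_undirected(g, mode = "collapse")
  cc <- igraph::transitivity(gu, type = "localaverage", isolates = "zero")
  if (is.nan(cc)) cc <- 0
  classes <- igraph::vertex_attr(g, "type")
  deg_dist <- function(mode, cls) {
    idx <- which(classes == cls)
    k <- igraph::degree(g, v = idx, mode = mode)
    tab <- table(k)
    data.frame(K = as.integer(names(tab)),
               p = as.numeric(tab) / length(idx), stringsAsFactors = FALSE)
  }
  dists <- list(
    sRNA_in = deg_dist("in", "sRNA"), sRNA_out = deg_dist("out", "sRNA"),
    transcript_in = deg_dist("in", "transcript"),
    transcript_out = deg_dist("out", "transcript"))
  fits <- lapply(dists, function(d) {
    d <- d[d$K > 0 & d$p > 0, , drop = FALSE]
    if (nrow(d) < 3L) return(NULL)
    fit_loglog(d$K, d$p)
  })
  list(n_nodes = n, n_edges = e,
       n_components = comp$no, component_sizes = sort(comp$csize, decreasing = TRUE),
       density = e / (n * (n - 1)),
       avg_clustering = cc,
       degree_distributions = dists, degree_fits = fits)
}

# least-squares regression of log10(y) on log10(x) with Pearson statistics
fit_loglog <- function(x, y) {
  lx <- log10(x); ly <- log10(y)
  ct <- correlate(lx, ly)
  fit <- lm(ly ~ lx)
  c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r = ct$r, R2 = ct$R2, t = ct$t, df = ct$df, p = ct$p)
}

#' Pearson correlation with t statistic
#'
#' Reports both `r` and `R^2` (avoiding sign ambiguity), with
#' `t = r sqrt((n - 2) / (1 - r^2))`, `df = n - 2` and the two-sided p
#' value from the t distribution.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with r, R2, t, df, p.
#' @export
correlate <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L) stopf("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance")
  r <- cor(x, y)
  df <- n - 2L
  t <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t), df)
  list(r = r, R2 = r^2, t = t, df = df, p = p)
}

#' GO-slim hypergeometric enrichment of network genes
#'
#' For every term, one-sided hypergeometric tests for over- and
#' under-representation of the gene set against the universe, each family
#' Benjamini-Hochberg corrected across terms.
#'
#' @param genes character vector of network genes.
#' @param universe character vector of all genes.
#' @param term_map data.frame with `gene_id`, `term_id` (and optionally
#'   `term_name`).
#' @param alpha significance level applied to corrected p values.
#' @return data.frame with term_id, term_name, k, K, n, N, direction,
#'   raw_p, corrected_p, significant.
#' @export
go_enrichment <- function(genes, universe, term_map, alpha = 0.05) {
  genes <- unique(genes); universe <- unique(universe)
  missing <- setdiff(genes, universe)
  if (length(missing))
    stopf("network gene(s) absent from universe: %s",
          paste(head(missing, 3), collapse = ", "))
  nn <- length(genes); NN <- length(universe)
  terms <- unique(term_map$term_id)
  rows <- lapply(terms, function(tm) {
    tg <- unique(term_map$gene_id[term_map$term_id == tm])
    K <- length(intersect(tg, universe))
    k <- length(intersect(tg, genes))
    nm <- if ("term_name" %in% names(term_map))
      term_map$term_name[match(tm, term_map$term_id)] else NA_character_
    data.frame(term_id = tm, term_name = nm, k = k, K = K, n = nn, N = NN,
               direction = c("over", "under"),
               raw_p = c(phyper(k - 1, K, NN - K, nn, lower.tail = FALSE),
                         phyper(k, K, NN - K, nn, lower.tail = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$corrected_p <- NA_real_
  for (d in c("over", "under")) {
    idx <- out$direction == d
    out$corrected_p[idx] <- p.adjust(out$raw_p[idx], method = "BH")
  }
  out$significant <- out$corrected_p <= alpha
  rownames(out) <- NULL
  out
}

#' Export the network as GraphML and SIF
#'
#' @param g igraph network.
#' @param graphml_path,sif_path output paths (either may be `NULL`).
#' @export
export_network <- function(g, graphml_path = NULL, sif_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(sif_path)) {
    el <- igraph::as_edgelist(g)
    ty <- igraph::edge_attr(g, "type")
    writeLines(sprintf("%s\t%s\t%s", el[, 1],
                       if (is.null(ty)) "edge" else ty, el[, 2]), sif_path)
  }
  invisible(NULL)
}
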