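# End-to-end orchestration: preprocess -> map -> detect -> annotate ->
# validate targets -> network -> enrichment.

#' Load pipeline inputs from files
#'
#' @param genome genome FASTA path.
#' @param gff feature GFF3 path.
#' @param srna character vector of collapsed sRNA FASTA paths.
#' @param degradome character vector of degradome FASTA paths.
#' @param mirnas TSV with columns name, precursor, sequence.
#' @param go_map TSV with columns gene_id, term_id (and term_name).
#' @return input bundle usable by [run_pipeline()].
#' @export
phasinet_inputs <- function(genome, gff, srna, degradome, mirnas, go_map = NULL) {
  for (p in c(genome, gff, srna, degradome, mirnas, go_map))
    if (!is.null(p) && !file.exists(p)) stopf("input not found: %s", p)
  g <- read_genome_fasta(genome)
  srna_libs <- lapply(srna, read_collapsed_fasta)
  names(srna_libs) <- vapply(srna_libs, `[[`, "", "library_id")
  deg_libs <- lapply(degradome, function(p) {
    lb <- read_collapsed_fasta(p)
    list(library_id = lb$library_id, tags = lb$reads)
  })
  names(deg_libs) <- vapply(deg_libs, `[[`, "", "library_id")
  list(genome = g, chrom_lengths = setNames(nchar(g), names(g)),
       features = read_features_gff3(gff),
       mirnas = read.table(mirnas, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE),
       srna_libraries = srna_libs, degradome_libraries = deg_libs,
       go_map = if (is.null(go_map)) NULL else
         read.table(go_map, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
}

#' Run the full sRNA regulatory-network pipeline
#'
#' Stages: abundance/size filtering and QC of each sRNA library; exact
#' mapping with fractional multimapper counts; per-library candidate-region
#' selection and phasing-score locus calling; cross-library consensus
#' (union intervals, >= 3 detections) and 220-nt extension; recursive
#' degradome-supported trigger assignment and phasiRNA extraction; genomic
#' feature assignment; degradome-validated genome-wide target calling;
#' bipartite network assembly with structural metrics and GO-slim
#' enrichment.
#'
#' @param input a [simulation_config()] (the synthetic bundle is generated
#'   in memory), the result of [simulate_dataset()], or a bundle from
#'   [phasinet_inputs()].
#' @param params stage parameters ([phasinet_params()]).
#' @param out_dir optional output directory; when given, annotation tables
#'   (TSV/GFF3), the interaction table, network exports (GraphML/SIF),
#'   metrics JSON, enrichment TSV and a JSON-lines log are written with a
#'   provenance header.
#' @return list with every stage result and a `summary` of per-stage
#'   counts.
#' @export
run_pipeline <- function(input, params = phasinet_params(), out_dir = NULL) {
  data <- if (inherits(input, "simulation_config")) simulate_dataset(input)
          else input
  if (is.null(data$genome) || is.null(data$srna_libraries))
    stopf("input bundle lacks genome or sRNA libraries")
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }

  filtered <- lapply(data$srna_libraries, filter_library,
                     min_count = params$min_count, min_len = params$min_len,
                     max_len = params$max_len)
  qc_pass <- vapply(filtered, qc_library, logical(1),
                    min_unique = params$min_unique)
  filtered <- filtered[qc_pass]
  note("preprocess", libraries_in = length(data$srna_libraries),
       libraries_pass = length(filtered))

  alignments <- lapply(filtered, map_reads, reference = data$genome,
                       allowed_lengths = params$allowed_lengths,
                       max_locations = params$max_locations)
  pooled <- do.call(rbind, c(alignments, list(make.row.names = FALSE)))
  note("map", alignments = if (is.null(pooled)) 0L else nrow(pooled))

  calls <- lapply(alignments, function(a) {
    regions <- select_candidate_regions(a, params$top_fraction,
                                        params$min_regions, params$island_gap)
    call_phas_loci(a, regions, params$min_phasing_score,
                   params$cycle, params$window_cycles)
  })
  calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  consensus <- merge_consensus(calls, params$min_libraries)
  note("detect", calls = if (is.null(calls)) 0L else nrow(calls),
       consensus_loci = nrow(consensus))

  annotation <- iterate_annotation(consensus, data$genome, pooled,
                                   data$mirnas, data$degradome_libraries,
                                   data$chrom_lengths, params)
  feature_assign <- if (nrow(consensus))
    assign_locus_feature(annotation$loci, data$features, params$min_overlap)
  else NULL
  note("annotate", triggers = nrow(annotation$triggers),
       phasirnas = if (is.null(annotation$phasirnas)) 0L
                   else nrow(annotation$phasirnas),
       rounds = annotation$rounds)

  srna_table <- rbind(
    data.frame(srna_id = data$mirnas$name, sequence = data$mirnas$sequence,
               class = "miRNA", stringsAsFactors = FALSE),
    if (!is.null(annotation$phasirnas) && nrow(annotation$phasirnas))
      data.frame(srna_id = annotation$phasirnas$name,
                 sequence = annotation$phasirnas$sequence,
                 class = "phasiRNA", stringsAsFactors = FALSE))
  srna_table <- srna_table[!duplicated(srna_table$srna_id), , drop = FALSE]
  candidates <- select_active_candidates(srna_table, data$srna_libraries,
                                         params$min_combined)
  transcripts <- setNames(vapply(seq_len(nrow(data$features)), function(i) {
    f <- data$features[i, ]
    transcript_seq(data$genome, f$chrom, f$start, f$end, f$strand)
  }, character(1)), data$features$ID)
  vt <- validate_targets(candidates, transcripts, data$degradome_libraries,
                         params)
  note("targets", candidates = nrow(candidates),
       interactions = nrow(vt$interactions),
       validated = sum(vt$interactions$validated))

  network <- build_network(annotation, vt$interactions, data$mirnas)
  metrics <- if (igraph::vcount(network) >= 2L) network_metrics(network)
             else NULL
  note("network", nodes = igraph::vcount(network),
       edges = igraph::ecount(network))

  enrichment <- NULL
  if (!is.null(data$go_map) && igraph::vcount(network) > 0L) {
    universe <- unique(data$go_map$gene_id)
    tnodes <- igraph::V(network)$name[igraph::V(network)$type == "transcript"]
    genes <- intersect(unique(c(tnodes,
                                if (!is.null(feature_assign))
                                  toupper(feature_assign$assigned_name))),
                       universe)
    if (length(genes))
      enrichment <- go_enrichment(genes, universe, data$go_map)
  }

  length_trigger_cor <- NULL
  trig <- annotation$triggers
  if (nrow(trig)) {
    nt <- table(trig$locus_id)
    tl <- annotation$loci[annotation$loci$locus_id %in% names(nt), , drop = FALSE]
    lens <- tl$end - tl$start
    cnts <- as.numeric(nt[tl$locus_id])
    if (length(lens) >= 3L && stats::sd(lens) > 0 && stats::sd(cnts) > 0)
      length_trigger_cor <- correlate(lens, cnts)
  }

  recall <- tryCatch(evaluate_annotation_recall(annotation, pooled),
                     error = function(e) NA_real_)

  coreg <- NA_real_
  if (igraph::vcount(network) > 0L) {
    val <- vt$interactions[vt$interactions$validated, , drop = FALSE]
    if (nrow(val)) {
      cls <- setNames(igraph::V(network)$class, igraph::V(network)$name)
      tgt <- unique(val$transcript_id)
      by_mir <- unique(val$transcript_id[cls[val$srna_id] == "miRNA"])
      by_ph <- unique(val$transcript_id[cls[val$srna_id] == "phasiRNA"])
      coreg <- length(intersect(by_mir, by_ph)) / length(tgt)
    }
  }

  res <- list(params = params, data = data, filtered = filtered,
              alignments = pooled, calls = calls, consensus = consensus,
              annotation = annotation, feature_assign = feature_assign,
              candidates = candidates, targets = vt, network = network,
              metrics = metrics, enrichment = enrichment,
              length_trigger_cor = length_trigger_cor,
              annotation_recall = recall, coregulation_fraction = coreg,
              classification = if (!is.null(annotation$phasirnas) &&
                                   nrow(annotation$phasirnas))
                classify_phasirnas(annotation$phasirnas) else NULL,
              log = log)
  res$summary <- list(
    libraries = length(filtered),
    consensus_loci = nrow(consensus),
    triggers = nrow(annotation$triggers),
    phasirnas = if (is.null(annotation$phasirnas)) 0L
                else nrow(annotation$phasirnas),
    validated_interactions = sum(vt$interactions$validated),
    active_srnas = length(vt$active_srnas),
    network_nodes = igraph::vcount(network),
    network_edges = igraph::ecount(network))
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# provenance line prefixed to every table: package version + parameter hash
provenance_line <- function(params) {
  blob <- paste(deparse(params), collapse = "")
  h <- sprintf("%08x", sum(utf8ToInt(blob) * seq_len(nchar(blob))) %%
                 .Machine$integer.max)
  sprintf("# phasinet %s params=%s",
          as.character(utils::packageVersion("phasinet")), h)
}

write_tsv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  writeLines(prov, con)
  if (!is.null(df)) suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  close(con)
  invisible(path)
}

#' Write pipeline outputs to a directory
#' @param res result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance_line(res$params)
  write_tsv_prov(res$consensus, file.path(out_dir, "loci.tsv"), prov)
  write_tsv_prov(res$annotation$triggers, file.path(out_dir, "triggers.tsv"), prov)
  write_tsv_prov(res$annotation$phasirnas, file.path(out_dir, "phasirnas.tsv"), prov)
  write_tsv_prov(res$targets$interactions,
                 file.path(out_dir, "interactions.tsv"), prov)
  write_tsv_prov(res$feature_assign,
                 file.path(out_dir, "features_assigned.tsv"), prov)
  if (!is.null(res$enrichment))
    write_tsv_prov(res$enrichment, file.path(out_dir, "enrichment.tsv"), prov)
  if (nrow(res$consensus)) {
    gff <- data.frame(chrom = res$consensus$chrom,
                      start = res$consensus$start, end = res$consensus$end,
                      strand = ifelse(is.na(res$annotation$loci$polarity), "*",
                                      res$annotation$loci$polarity),
                      type = "phas_locus", ID = res$consensus$locus_id,
                      stringsAsFactors = FALSE)
    write_features_gff3(gff, file.path(out_dir, "loci.gff3"))
  }
  export_network(res$network, file.path(out_dir, "network.graphml"),
                 file.path(out_dir, "network.sif"))
  if (!is.null(res$metrics)) {
    m <- res$metrics
    jsonlite::write_json(
      list(n_nodes = m$n_nodes, n_edges = m$n_edges,
           n_components = m$n_components, density = m$density,
           avg_clustering = m$avg_clustering),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  writeLines(vapply(res$log, function(x)
    jsonlite::toJSON(x, auto_unbox = TRUE), character(1)),
    file.path(out_dir, "log.jsonl"))
  invisible(out_dir)
}
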