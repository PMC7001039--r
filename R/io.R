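# Readers/writers, read collapsing, abundance filters and library QC.

# aggregate (sequence, count) pairs into a collapsed table sorted by sequence
collapse_counts <- function(seqs, counts) {
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(0), count = numeric(0),
                      stringsAsFactors = FALSE))
  agg <- rowsum(as.numeric(counts), group = seqs)
  data.frame(sequence = rownames(agg), count = as.numeric(agg[, 1]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse raw sequences to unique reads with counts
#'
#' @param sequences character vector of raw read sequences.
#' @param normalize if `TRUE`, U is converted to T (and case folded) before
#'   collapsing, so U- and T-spelled copies of the same read merge.
#' @param library_id identifier stored with the library.
#' @return list with `library_id` and `reads` (data.frame with `sequence`,
#'   `count`); counts sum to `length(sequences)`.
#' @export
collapse_reads <- function(sequences, normalize = FALSE, library_id = "lib") {
  if (normalize) sequences <- normalize_ut(sequences)
  list(library_id = library_id,
       reads = collapse_counts(sequences, rep(1, length(sequences))))
}

#' Abundance and size filter for a collapsed library
#'
#' Retains reads with `min_len <= length <= max_len` and `count >=
#' min_count` (reads with fewer than `min_count` copies are removed; the
#' boundary count is kept).
#'
#' @param lib collapsed library (list with `reads`).
#' @param min_count minimum retained count (default 50).
#' @param min_len,max_len retained length range in nt (default 20-40).
#' @return filtered library.
#' @export
filter_library <- function(lib, min_count = 50, min_len = 20, max_len = 40) {
  r <- lib$reads
  len <- nchar(r$sequence)
  lib$reads <- r[len >= min_len & len <= max_len & r$count >= min_count, ,
                 drop = FALSE]
  rownames(lib$reads) <- NULL
  lib
}

#' Library informativeness check
#'
#' A library with fewer than `min_unique` unique sequences is considered
#' non-informative.
#'
#' @param lib collapsed (and typically filtered) library.
#' @param min_unique minimum unique sequences (default 100).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_library <- function(lib, min_unique = 100) {
  nrow(lib$reads) >= min_unique
}

#' Optional exact-prefix 3' adapter trimmer
#'
#' Removes everything from the first exact occurrence of `adapter` onward;
#' reads without the adapter are dropped when `require_adapter` is `TRUE`.
#' Inputs to the pipeline are otherwise assumed pre-trimmed.
#'
#' @param sequences character vector.
#' @param adapter adapter prefix to search for.
#' @param require_adapter drop reads lacking the adapter.
#' @param clip5 number of 5' nucleotides to remove after trimming (for
#'   degradome dialects that prepend library-preparation bases); default 0.
#' @return character vector of trimmed sequences.
#' @export
trim_adapter <- function(sequences, adapter, require_adapter = TRUE, clip5 = 0) {
  pos <- regexpr(adapter, sequences, fixed = TRUE)
  out <- ifelse(pos > 0, substr(sequences, 1L, pos - 1L),
                if (require_adapter) NA_character_ else sequences)
  out <- out[!is.na(out)]
  if (clip5 > 0) out <- substr(out, clip5 + 1L, nchar(out))
  out[nchar(out) > 0]
}

#' Read and write collapsed-read FASTA
#'
#' Header dialect `>id_x<count>`; the count is the collapsed read count.
#'
#' @param path file path.
#' @param lib library list (`library_id`, `reads` or `tags`).
#' @return `read_collapsed_fasta()` returns a library list.
#' @export
read_collapsed_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  cnt <- suppressWarnings(as.numeric(sub(".*_x([0-9.]+)$", "\\1", names(ss))))
  if (anyNA(cnt))
    stopf("headers in %s do not follow the '>id_x<count>' dialect", path)
  list(library_id = sub("\\.[^.]*$", "", basename(path)),
       reads = collapse_counts(as.character(ss), cnt))
}

#' @rdname read_collapsed_fasta
#' @export
write_collapsed_fasta <- function(lib, path) {
  reads <- if (!is.null(lib$reads)) lib$reads else lib$tags
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- sprintf("sim_%d_x%g", seq_len(nrow(reads)), reads$count)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write a genome as FASTA
#' @param genome named character vector.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' GFF3 export/import for feature tables
#'
#' Features travel as a data.frame with chrom/start/end/strand/type/ID (and
#' optional extra columns); I/O goes through [rtracklayer].
#'
#' @param features data.frame.
#' @param path file path.
#' @param source source field for export.
#' @return `read_features_gff3()` returns the features data.frame.
#' @export
write_features_gff3 <- function(features, path, source = "phasinet") {
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"))
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$ID
  S4Vectors::mcols(gr)$source <- source
  extra <- setdiff(names(features),
                   c("chrom", "start", "end", "strand", "type", "ID"))
  for (cn in extra) S4Vectors::mcols(gr)[[cn]] <- features[[cn]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_features_gff3
#' @export
read_features_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   ID = as.character(gr$ID),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  extra <- setdiff(colnames(mc), c("type", "ID", "source", "score", "phase"))
  for (cn in extra) df[[cn]] <- as.character(mc[[cn]])
  df
}

#' Write a simulated dataset to a directory
#'
#' Emits genome FASTA, feature GFF3, collapsed sRNA/degradome FASTA files,
#' miRNA and GO tables (TSV), the truth manifest (JSON) and the config
#' (YAML).
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "srna"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "degradome"), showWarnings = FALSE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_features_gff3(sim$features, file.path(dir, "features.gff3"))
  for (lb in sim$srna_libraries)
    write_collapsed_fasta(lb, file.path(dir, "srna", paste0(lb$library_id, ".fa")))
  for (lb in sim$degradome_libraries)
    write_collapsed_fasta(lb, file.path(dir, "degradome", paste0(lb$library_id, ".fa")))
  write.table(sim$mirnas, file.path(dir, "mirnas.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$go_map, file.path(dir, "go_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
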