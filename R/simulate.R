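# Synthetic-data generator: ground-truthed genomes, sRNA-seq and degradome
# libraries with the statistical structure the pipeline assumes.

transcript_seq <- function(genome, chrom, start, end, strand) {
  s <- substr(genome[[chrom]], start, end)
  if (strand == "-") rev_comp(s) else s
}

# write `value` into the transcript interval [t1, t1+nchar(value)-1] of a
# stranded genomic feature, editing the genome string in place.
write_transcript_window <- function(genome, chrom, start, end, strand, t1, value) {
  n <- nchar(value)
  if (strand == "+") {
    g1 <- start + t1 - 1L
    substr(genome[[chrom]], g1, g1 + n - 1L) <- value
  } else {
    g2 <- end - t1 + 1L            # genomic coord of transcript position t1
    g1 <- g2 - n + 1L
    substr(genome[[chrom]], g1, g2) <- rev_comp(value)
  }
  genome
}

#' Generate a synthetic genome with planted host and target gene features
#'
#' Chromosomes are random DNA of the configured length; gene features are
#' laid out on fixed slots with jitter, alternating strands.  PHAS host
#' features are sized to hold the trigger site plus all phased cycles.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `chrom_lengths`, and `features` (data.frame with chrom,
#'   start, end, strand, type, role, ID).
#' @export
generate_genome <- function(config) {
  cfg <- validate_simulation_config(config)
  region_len <- locus_region_length(cfg)
  gene_len <- 300L
  slot <- max(region_len, gene_len) + 600L
  n_feat <- cfg$n_phas_loci + cfg$n_target_genes

  slots <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(i) {
    starts <- seq(200L, by = slot,
                  length.out = max(0L, (cfg$chrom_length - 300L - region_len) %/% slot))
    if (length(starts) == 0L) return(NULL)
    data.frame(chrom = sprintf("Chr%d", i), slot_start = starts)
  }))
  if (is.null(slots) || nrow(slots) < n_feat)
    stopf(paste0("cannot place %d features on %d chromosome(s) of %d nt ",
                 "(each needs ~%d nt including spacing); increase chrom_length"),
          n_feat, cfg$n_chromosomes, cfg$chrom_length, slot)

  with_seed(cfg$seed, {
    genome <- setNames(random_dna(cfg$n_chromosomes, cfg$chrom_length),
                       sprintf("Chr%d", seq_len(cfg$n_chromosomes)))
    use <- slots[seq_len(n_feat), , drop = FALSE]
    jitter <- sample(0:50, n_feat, replace = TRUE)
    role <- c(rep("phas_host", cfg$n_phas_loci),
              rep("target_gene", cfg$n_target_genes))
    len <- ifelse(role == "phas_host", region_len, gene_len)
    features <- data.frame(
      chrom = use$chrom,
      start = use$slot_start + jitter,
      end = use$slot_start + jitter + len - 1L,
      strand = rep(c("+", "-"), length.out = n_feat),
      type = "gene",
      role = role,
      ID = c(sprintf("PL%02d", seq_len(cfg$n_phas_loci)),
             sprintf("TG%02d", seq_len(cfg$n_target_genes))),
      stringsAsFactors = FALSE)
    list(genome = genome,
         chrom_lengths = setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                                  names(genome)),
         features = features)
  })
}

#' Plant trigger sites and phased sRNA cascades into a synthetic genome
#'
#' For every host feature a trigger with perfect complementarity to the
#' transcript is created; its slice site (between trigger positions 10/11)
#' sets the 21-nt register.  Phased sense/antisense duplexes (2-nt 3'
#' overhangs) follow for `n_cycles_per_locus` cycles with abundance
#' `base_abundance * abundance_decay^(cycle-1)`.  Loci listed in
#' `shift_loci` emit a 22-nt product at `shift_cycle`; all later cycles
#' carry register offset +1.  `trans_edges` make the cycle-1 phasiRNA of the
#' source locus perfectly complementary to the trigger window of the target
#' locus (which then has no miRNA trigger of its own).  Target genes receive
#' one site complementary to a phasiRNA of a source locus.  Because trans
#' edges and target sites require writing designed windows into the genome,
#' the (possibly edited) genome is returned alongside the truth manifest.
#'
#' @param gen result of [generate_genome()].
#' @param config the same [simulation_config()].
#' @return list with `genome` (edited) and `truth` (the manifest: config
#'   echo, per-locus truth records, miRNA table, target-site table and
#'   per-library expression flags).
#' @export
plant_phas_cascade <- function(gen, config) {
  cfg <- validate_simulation_config(config)
  genome <- gen$genome
  hosts <- gen$features[gen$features$role == "phas_host", , drop = FALSE]
  genes <- gen$features[gen$features$role == "target_gene", , drop = FALSE]
  n <- cfg$n_phas_loci

  trans_target <- rep(NA_integer_, n)      # source index per trans-target locus
  for (e in cfg$trans_edges) trans_target[e[2]] <- e[1]

  with_seed(cfg$seed + 1L, {
    # trans edits first: overwrite the target locus's trigger window with the
    # reverse complement of the source's cycle-1 phasiRNA.  Edges are applied
    # in list order; chains must be listed source-first.
    for (e in cfg$trans_edges) {
      a <- e[1]; b <- e[2]
      ha <- hosts[a, ]; hb <- hosts[b, ]
      trig_a <- if (!is.na(trans_target[a])) 21L else cfg$trigger_length
      anchor_a <- trig_a - 9L
      tr_a <- transcript_seq(genome, ha$chrom, ha$start, ha$end, ha$strand)
      src_phasi <- substr(tr_a, anchor_a, anchor_a + 20L)
      genome <- write_transcript_window(genome, hb$chrom, hb$start, hb$end,
                                        hb$strand, 1L, rev_comp(src_phasi))
    }

    loci <- vector("list", n)
    mirna_rows <- list()
    for (i in seq_len(n)) {
      h <- hosts[i, ]
      is_trans <- !is.na(trans_target[i])
      trig_len <- if (is_trans) 21L else cfg$trigger_length
      anchor_t <- trig_len - 9L
      tr <- transcript_seq(genome, h$chrom, h$start, h$end, h$strand)
      trigger <- rev_comp(substr(tr, 1L, trig_len))
      if (!is_trans && cfg$trigger_wobble) {
        # one G:U wobble outside the seed region: trigger position p (A
        # opposite target T) becomes G.
        tc <- strsplit(trigger, "")[[1]]
        p <- which(tc[14:trig_len] == "A")
        if (length(p)) { tc[13L + p[1]] <- "G"; trigger <- paste(tc, collapse = "") }
      }
      shifted <- i %in% cfg$shift_loci
      recs <- lapply(seq_len(cfg$n_cycles_per_locus), function(cc) {
        off <- if (shifted && cc > cfg$shift_cycle) 1L else 0L
        len <- if (shifted && cc == cfg$shift_cycle) 22L else 21L
        t5 <- anchor_t + 21L * (cc - 1L) + off
        sense <- substr(tr, t5, t5 + len - 1L)
        anti <- rev_comp(substr(tr, t5 + 2L, t5 + len + 1L))
        cnt <- floor(cfg$base_abundance * cfg$abundance_decay^(cc - 1L))
        data.frame(sequence = c(sense, anti), strand = c("+", "-"),
                   length = len, cycle = cc, offset = off, base_count = cnt,
                   t5 = t5, stringsAsFactors = FALSE)
      })
      recs <- do.call(rbind, recs)
      # genomic span of each read (leftmost/rightmost genomic coordinates)
      tg <- function(t) if (h$strand == "+") h$start + t - 1L else h$end - t + 1L
      t_lo <- ifelse(recs$strand == "+", recs$t5, recs$t5 + 2L)
      t_hi <- t_lo + recs$length - 1L
      recs$gstart <- pmin(tg(t_lo), tg(t_hi))
      recs$gend <- pmax(tg(t_lo), tg(t_hi))
      recs$gstrand <- ifelse(recs$strand == "+", h$strand,
                             if (h$strand == "+") "-" else "+")
      slice_t <- anchor_t - 1L
      loci[[i]] <- list(
        locus_id = h$ID, chrom = h$chrom, start = h$start, end = h$end,
        strand = h$strand, transcript = tr,
        trigger_sequence = trigger,
        trigger_name = if (is_trans) NA_character_ else sprintf("simmiR-%02d", i),
        is_trans = is_trans,
        trans_source = if (is_trans) hosts$ID[trans_target[i]] else NA_character_,
        trans_targets = hosts$ID[which(trans_target == i)],
        slice_t = slice_t, anchor_t = anchor_t,
        slice_position = tg(slice_t), register_anchor = tg(anchor_t),
        read_start = min(recs$gstart), read_end = max(recs$gend),
        phasirna_records = recs)
      if (!is_trans)
        mirna_rows[[length(mirna_rows) + 1L]] <- data.frame(
          name = sprintf("simmiR-%02d", i),
          precursor = sprintf("PRE-simmiR-%02d", i),
          sequence = trigger, locus_id = h$ID, stringsAsFactors = FALSE)
    }
    # decoy miRNAs exercise the complementarity search without planted sites
    for (k in 1:5)
      mirna_rows[[length(mirna_rows) + 1L]] <- data.frame(
        name = sprintf("decoy-miR-%d", k), precursor = sprintf("PRE-decoy-%d", k),
        sequence = random_dna(1, 21L), locus_id = NA_character_,
        stringsAsFactors = FALSE)
    mirnas <- do.call(rbind, mirna_rows)

    # target genes: every gene gets a phasiRNA-complementary site; genes
    # with even index also get a miRNA site (so some transcripts are
    # co-regulated by a miRNA and a phasiRNA, as observed in real networks)
    target_sites <- NULL
    if (nrow(genes) > 0 && n > 0) {
      rows <- lapply(seq_len(nrow(genes)), function(j) {
        g <- genes[j, ]
        src <- ((j - 1L) %% n) + 1L
        lt <- loci[[src]]
        use_cycle <- if (any(lt$phasirna_records$cycle == 2L &
                             lt$phasirna_records$length == 21L)) 2L else 1L
        phasi <- lt$phasirna_records$sequence[
          lt$phasirna_records$cycle == use_cycle & lt$phasirna_records$strand == "+"][1]
        phasi <- substr(phasi, 1L, 21L)
        out <- data.frame(gene_id = g$ID, source_locus = lt$locus_id,
                          site_type = "phasiRNA", srna_sequence = phasi,
                          site_start = 101L, site_end = 121L,
                          stringsAsFactors = FALSE)
        if (j %% 2L == 0L && !lt$is_trans) {
          ml <- nchar(lt$trigger_sequence)
          out <- rbind(out, data.frame(
            gene_id = g$ID, source_locus = lt$locus_id,
            site_type = "miRNA", srna_sequence = lt$trigger_sequence,
            site_start = 180L, site_end = 180L + ml - 1L,
            stringsAsFactors = FALSE))
        }
        out
      })
      target_sites <- do.call(rbind, rows)
      target_sites$anchor_t <- target_sites$site_end - 9L
      for (j in seq_len(nrow(target_sites))) {
        g <- genes[match(target_sites$gene_id[j], genes$ID), ]
        genome <- write_transcript_window(genome, g$chrom, g$start, g$end,
                                          g$strand, target_sites$site_start[j],
                                          rev_comp(target_sites$srna_sequence[j]))
      }
      target_sites$transcript <- vapply(seq_len(nrow(target_sites)), function(j) {
        g <- genes[match(target_sites$gene_id[j], genes$ID), ]
        transcript_seq(genome, g$chrom, g$start, g$end, g$strand)
      }, character(1))
    }

    expression <- matrix(runif(n * cfg$n_srna_libraries) < cfg$locus_expression_rate,
                         nrow = n,
                         dimnames = list(hosts$ID, sprintf("srna_%02d", seq_len(cfg$n_srna_libraries))))
    deg_expression <- matrix(runif(n * cfg$n_degradome_libraries) < cfg$locus_expression_rate,
                             nrow = n,
                             dimnames = list(hosts$ID, sprintf("deg_%02d", seq_len(cfg$n_degradome_libraries))))
    target_deg_expression <- matrix(
      runif(nrow(genes) * cfg$n_degradome_libraries) < cfg$locus_expression_rate,
      nrow = nrow(genes),
      dimnames = list(genes$ID, sprintf("deg_%02d", seq_len(cfg$n_degradome_libraries))))
    # for genes carrying two sites, per-library dominance decides which site
    # yields the major degradome peak (the other produces a minor one)
    target_site_dominance <- matrix(
      NA_character_, nrow = nrow(genes), ncol = cfg$n_degradome_libraries,
      dimnames = dimnames(target_deg_expression))
    if (!is.null(target_sites)) {
      two_site <- names(which(table(target_sites$gene_id) == 2L))
      for (gid in two_site)
        target_site_dominance[gid, ] <- sample(c("phasiRNA", "miRNA"),
                                               cfg$n_degradome_libraries,
                                               replace = TRUE)
    }

    truth <- list(config = cfg, loci = setNames(loci, hosts$ID),
                  mirnas = mirnas, target_sites = target_sites,
                  features = gen$features,
                  expression = expression, deg_expression = deg_expression,
                  target_deg_expression = target_deg_expression,
                  target_site_dominance = target_site_dominance)
    list(genome = genome, truth = truth)
  })
}

#' Simulate one collapsed sRNA-seq library
#'
#' Loci expressed in the library (per-library Bernoulli flags in the truth
#' manifest) contribute their phased sense/antisense reads with (optionally
#' Poisson-jittered) counts; `noise_fraction` of the total read mass is
#' random 20-40 nt genomic substrings on random strands with counts uniform
#' on 30..90 (straddling the 50-count abundance filter).
#'
#' @param truth truth manifest from [plant_phas_cascade()].
#' @param library_index 1-based library index.
#' @param config the [simulation_config()].
#' @param genome named character vector of chromosome sequences (needed for
#'   noise reads).
#' @return list with `library_id` and `reads` (data.frame sequence/count).
#' @export
simulate_srna_library <- function(truth, library_index, config, genome) {
  cfg <- validate_simulation_config(config)
  lid <- sprintf("srna_%02d", library_index)
  with_seed(cfg$seed + 7919L * library_index, {
    seqs <- character(0); cnts <- numeric(0)
    for (lt in truth$loci) {
      if (!truth$expression[lt$locus_id, lid]) next
      rc <- lt$phasirna_records
      k <- if (cfg$poisson_jitter) rpois(nrow(rc), rc$base_count) else rc$base_count
      keep <- k > 0
      seqs <- c(seqs, rc$sequence[keep]); cnts <- c(cnts, k[keep])
      # expressed cis loci also shed their trigger miRNA into the library
      if (!lt$is_trans) {
        tk <- if (cfg$poisson_jitter) rpois(1, cfg$base_abundance)
              else cfg$base_abundance
        if (tk > 0) { seqs <- c(seqs, lt$trigger_sequence); cnts <- c(cnts, tk) }
      }
    }
    signal <- sum(cnts)
    if (cfg$noise_fraction > 0) {
      # noise mass is tied to the expressed signal; with nothing expressed
      # (a pure-noise library) it is tied to the total planted mass instead
      basis <- if (signal > 0) signal else
        sum(vapply(truth$loci, function(l)
          sum(l$phasirna_records$base_count), numeric(1)))
      target <- floor(basis * cfg$noise_fraction / (1 - cfg$noise_fraction))
      # draw in one batch: expected count 60 per read, then trim to target
      nn <- ceiling(target / 60) + 10L
      ncnt <- sample(30:90, nn, replace = TRUE)
      nn <- which(cumsum(ncnt) >= target)[1]
      if (is.na(nn)) nn <- length(ncnt)
      ncnt <- ncnt[seq_len(nn)]
      len <- sample(20:40, nn, replace = TRUE)
      chrom <- sample(names(genome), nn, replace = TRUE)
      start <- vapply(seq_len(nn), function(i)
        sample.int(nchar(genome[[chrom[i]]]) - len[i] + 1L, 1L), integer(1))
      s <- substring(genome[chrom], start, start + len - 1L)
      flip <- sample(c(TRUE, FALSE), nn, replace = TRUE)
      if (any(flip)) s[flip] <- rev_comp(s[flip])
      seqs <- c(seqs, s); cnts <- c(cnts, ncnt)
    }
    reads <- collapse_counts(seqs, cnts)
    list(library_id = lid, reads = reads)
  })
}

#' Simulate one degradome (PARE) library
#'
#' Expressed trigger/target pairs contribute 20-nt 5'-end tags starting at
#' the slice position (register anchor) of the targeted transcript, with
#' abundance far above background; uniform background tags (count 1) appear
#' at `degradome_background_rate` per transcript position.
#'
#' @inheritParams simulate_srna_library
#' @return list with `library_id` and `tags` (data.frame sequence/count).
#' @export
simulate_degradome_library <- function(truth, library_index, config) {
  cfg <- validate_simulation_config(config)
  lid <- sprintf("deg_%02d", library_index)
  with_seed(cfg$seed + 104729L * library_index + 13L, {
    seqs <- character(0); cnts <- numeric(0)
    add_bg <- function(tr) {
      npos <- nchar(tr) - 19L
      if (npos < 1L || cfg$degradome_background_rate <= 0) return()
      hit <- which(runif(npos) < cfg$degradome_background_rate)
      if (length(hit)) {
        seqs <<- c(seqs, substring(tr, hit, hit + 19L))
        cnts <<- c(cnts, rep(1, length(hit)))
      }
    }
    for (lt in truth$loci) {
      if (truth$deg_expression[lt$locus_id, lid]) {
        tag <- substr(lt$transcript, lt$anchor_t, lt$anchor_t + 19L)
        cnt <- if (cfg$poisson_jitter) max(2, rpois(1, cfg$degradome_tag_abundance))
               else cfg$degradome_tag_abundance
        seqs <- c(seqs, tag); cnts <- c(cnts, cnt)
      }
      add_bg(lt$transcript)
    }
    ts <- truth$target_sites
    if (!is.null(ts)) {
      for (j in seq_len(nrow(ts))) {
        if (truth$target_deg_expression[ts$gene_id[j], lid]) {
          dom <- truth$target_site_dominance[ts$gene_id[j], lid]
          lam <- if (is.na(dom)) cfg$degradome_tag_abundance
                 else if (dom == ts$site_type[j]) 2L * cfg$degradome_tag_abundance
                 else max(2L, ceiling(cfg$degradome_tag_abundance / 3))
          tag <- substr(ts$transcript[j], ts$anchor_t[j], ts$anchor_t[j] + 19L)
          cnt <- if (cfg$poisson_jitter) max(2, rpois(1, lam)) else lam
          seqs <- c(seqs, tag); cnts <- c(cnts, cnt)
        }
      }
      for (tr in unique(ts$transcript)) add_bg(tr)
    }
    list(library_id = lid, tags = collapse_counts(seqs, cnts))
  })
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs [generate_genome()], [plant_phas_cascade()], all sRNA and degradome
#' libraries, and builds a GO-slim style annotation table over the planted
#' genes (target genes are biased toward a stress-response term so that
#' enrichment has signal to find).
#'
#' @param config a [simulation_config()].
#' @return list with config, genome, chrom_lengths, features, truth,
#'   mirnas, srna_libraries, degradome_libraries and go_map.
#' @export
simulate_dataset <- function(config) {
  cfg <- validate_simulation_config(config)
  gen <- generate_genome(cfg)
  pc <- plant_phas_cascade(gen, cfg)
  srna <- lapply(seq_len(cfg$n_srna_libraries), function(i)
    simulate_srna_library(pc$truth, i, cfg, pc$genome))
  names(srna) <- vapply(srna, `[[`, character(1), "library_id")
  deg <- lapply(seq_len(cfg$n_degradome_libraries), function(i)
    simulate_degradome_library(pc$truth, i, cfg))
  names(deg) <- vapply(deg, `[[`, character(1), "library_id")

  terms <- data.frame(
    term_id = sprintf("GO:%07d", c(6950, 9908, 6412, 3700, 9733, 6355,
                                   5975, 6468, 9607, 15979, 6810, 9056)),
    term_name = c("response to stress", "flower development", "translation",
                  "DNA-binding transcription factor activity",
                  "response to auxin", "regulation of transcription",
                  "carbohydrate metabolic process", "protein phosphorylation",
                  "response to biotic stimulus", "photosynthesis",
                  "transport", "catabolic process"),
    stringsAsFactors = FALSE)
  go_map <- with_seed(cfg$seed + 99L, {
    rows <- lapply(seq_len(nrow(gen$features)), function(i) {
      f <- gen$features[i, ]
      k <- sample(1:3, 1L)
      idx <- sample(nrow(terms), k)
      if (f$role == "target_gene" && runif(1) < 0.8)
        idx <- union(idx, 1L)
      data.frame(gene_id = f$ID, term_id = terms$term_id[idx],
                 term_name = terms$term_name[idx], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  list(config = cfg, genome = pc$genome, chrom_lengths = gen$chrom_lengths,
       features = pc$truth$features, truth = pc$truth,
       mirnas = pc$truth$mirnas, srna_libraries = srna,
       degradome_libraries = deg, go_map = go_map)
}
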