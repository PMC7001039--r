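# Recursive miRNA -> PHAS locus -> phasiRNA annotation.

# complementarity + degradome scoring of a query set against both strands of
# every extended locus.  `locus_seqs` is a list locus_id -> list("+", "-") of
# extended-interval sequences; `profiles` is a list (per degradome library)
# of tag-count vectors named "<locus_id>|<strand>".
score_locus_events <- function(queries, ext, locus_seqs, profiles,
                               max_allen = 7.0, deg_weights = c(`0` = 5, `1` = 4,
                                                                `2` = 0.5, `3` = 0,
                                                                `4` = 0)) {
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    q <- queries$sequence[qi]
    for (li in seq_len(nrow(ext))) {
      lid <- ext$locus_id[li]
      for (s in c("+", "-")) {
        hits <- find_target_alignments(q, locus_seqs[[lid]][[s]],
                                       max_allen = max_allen,
                                       srna_id = queries$id[qi],
                                       transcript_id = paste0(lid, "|", s))
        if (nrow(hits) == 0L) next
        slice_g <- if (s == "+") ext$extended_start[li] + hits$slice_position - 1L
                   else ext$extended_end[li] - hits$slice_position + 1L
        for (hi in seq_len(nrow(hits))) {
          cats <- vapply(profiles, function(pl)
            categorize_cleavage(pl[[paste0(lid, "|", s)]],
                                hits$slice_position[hi]), integer(1))
          rows[[length(rows) + 1L]] <- data.frame(
            srna_id = hits$srna_id[hi], srna_sequence = q, locus_id = lid,
            target_strand = s, slice_t = hits$slice_position[hi],
            slice_genomic = slice_g[hi], allen_score = hits$allen_score[hi],
            deg_score = weighted_score(cats, deg_weights),
            n_libraries = sum(!is.na(cats)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(srna_id = character(0), srna_sequence = character(0),
                      locus_id = character(0), target_strand = character(0),
                      slice_t = integer(0), slice_genomic = integer(0),
                      allen_score = numeric(0), deg_score = numeric(0),
                      n_libraries = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Full recursive miRNA-PHAS locus-phasiRNA annotation
#'
#' Round 1 searches known miRNAs against both strands of every extended
#' consensus locus and assigns primary triggers (highest weighted degradome
#' score, minimum 10), which set locus polarity and the main phased
#' register.  PhasiRNAs are then extracted from the register and its
#' immediate neighbours (or from the most abundant bin for trigger-less
#' loci), pooled with the miRNAs, and used as queries in further rounds:
#' loci still lacking a trigger can gain one (e.g. trans-triggered loci),
#' and trigger-bearing loci accept secondary/tertiary triggers that match
#' their polarity and top-ranked bins.  Iteration stops at a fixed point or
#' after `max_rounds` rounds.
#'
#' @param consensus consensus locus table from [merge_consensus()].
#' @param genome named character vector of chromosome sequences.
#' @param alignments pooled per-library alignments (from [map_reads()]).
#' @param mirnas known-miRNA table with `name` and `sequence`.
#' @param degradome_libraries list of degradome libraries.
#' @param chrom_lengths named chromosome lengths.
#' @param params parameter list from [phasinet_params()].
#' @return annotation list: loci (with polarity), extended bounds,
#'   triggers, phasirnas, per-locus bins/rank scores/anchors, events and
#'   the number of rounds run.
#' @export
iterate_annotation <- function(consensus, genome, alignments, mirnas,
                               degradome_libraries, chrom_lengths,
                               params = phasinet_params()) {
  loci <- consensus
  empty_trig <- data.frame(srna_id = character(0), srna_sequence = character(0),
                           locus_id = character(0), target_strand = character(0),
                           slice_t = integer(0), slice_genomic = integer(0),
                           allen_score = numeric(0), deg_score = numeric(0),
                           n_libraries = integer(0), rank = character(0),
                           round = integer(0), sets_polarity = logical(0),
                           stringsAsFactors = FALSE)
  if (nrow(loci) == 0L)
    return(list(loci = loci, extended = loci, triggers = empty_trig,
                phasirnas = extract_phasirnas(NULL, NULL, integer(0), NA),
                bins = list(), rank_scores = list(), anchors = list(),
                events = NULL, rounds = 0L))

  ext <- extend_loci(loci, params$pad, chrom_lengths)
  locus_seqs <- setNames(lapply(seq_len(nrow(ext)), function(i) {
    plus <- substr(genome[[ext$chrom[i]]], ext$extended_start[i],
                   ext$extended_end[i])
    list(`+` = plus, `-` = rev_comp(plus))
  }), ext$locus_id)
  transcripts <- unlist(lapply(names(locus_seqs), function(lid)
    setNames(locus_seqs[[lid]], paste0(lid, "|", c("+", "-")))))
  profiles <- lapply(degradome_libraries, build_degradome_profiles,
                     transcripts = transcripts, prefix = params$deg_prefix)

  bins <- setNames(lapply(seq_len(nrow(loci)), function(i)
    build_phase_bins(loci[i, ], alignments, params$cycle)), loci$locus_id)
  rank_scores <- lapply(bins, function(b) rank_bins(b$pooled, params$bin_weights))

  # fallback anchor for trigger-less loci: 5'-most effective position in the
  # top-ranked bin (forward orientation kept)
  fallback_anchor <- function(lid) {
    rs <- rank_scores[[lid]]
    tb <- top_ranked_bins(rs, 1L)
    if (length(tb) == 0L) return(integer(0))
    br <- bins[[lid]]$reads
    min(br$eff5[br$bin == tb[1]])
  }

  rank_labels <- c("primary", "secondary", "tertiary")
  triggers <- empty_trig
  anchors <- setNames(vector("list", nrow(loci)), loci$locus_id)
  main_anchor <- setNames(rep(NA_integer_, nrow(loci)), loci$locus_id)
  phasirnas <- NULL
  events_all <- NULL
  queried <- character(0)
  rounds_run <- 0L

  for (round in seq_len(params$max_rounds)) {
    if (round == 1L) {
      queries <- data.frame(id = mirnas$name, sequence = normalize_ut(mirnas$sequence),
                            stringsAsFactors = FALSE)
    } else {
      queries <- data.frame(id = phasirnas$name, sequence = phasirnas$sequence,
                            stringsAsFactors = FALSE)
    }
    queries <- queries[!duplicated(queries$sequence) &
                         !queries$sequence %in% queried, , drop = FALSE]
    if (nrow(queries)) {
      ev <- score_locus_events(queries, ext, locus_seqs, profiles,
                               params$max_allen, params$deg_weights)
      events_all <- rbind(events_all, ev)
      queried <- c(queried, queries$sequence)
    }
    changed <- FALSE
    for (i in seq_len(nrow(loci))) {
      lid <- loci$locus_id[i]
      ev <- events_all[events_all$locus_id == lid, , drop = FALSE]
      mine <- triggers[triggers$locus_id == lid, , drop = FALSE]
      if (nrow(mine) == 0L) {
        # a polarity-setting trigger must (i) set a register the sRNA
        # distribution supports -- its slice bin falls in the top-ranked
        # bins or their immediate neighbours, the same consistency rule as
        # for secondary triggers -- and (ii) not be one of the locus's own
        # phasiRNAs: the initiating trigger precedes its products, and
        # self-records targeting the antisense strand would invert
        # polarity.  Self-targeting remains eligible as a secondary
        # trigger, where polarity matching is enforced.
        allowed <- adjacent_bins(top_ranked_bins(rank_scores[[lid]], 3L))
        if (nrow(ev)) {
          bins_ev <- phase_bin(ev$slice_genomic, ev$target_strand, loci$start[i])
          own <- if (!is.null(phasirnas) && nrow(phasirnas))
            phasirnas$sequence[phasirnas$locus_id == lid] else character(0)
          ev <- ev[bins_ev %in% allowed & !ev$srna_sequence %in% own, ,
                   drop = FALSE]
        }
        pt <- assign_primary_trigger(ev, params$trigger_min_score)
        if (!is.null(pt)) {
          loci$polarity[i] <- pt$target_strand
          pt$rank <- rank_labels[min(round, 3L)]
          pt$round <- round
          pt$sets_polarity <- TRUE
          triggers <- rbind(triggers, pt)
          anchors[[lid]] <- pt$slice_genomic
          main_anchor[lid] <- pt$slice_genomic
          changed <- TRUE
        }
      } else if (round > 1L) {
        sec <- find_secondary_triggers(ev, loci$polarity[i], rank_scores[[lid]],
                                       loci$start[i], existing = mine,
                                       min_score = params$trigger_min_score)
        if (nrow(sec)) {
          sec$rank <- rank_labels[min(round, 3L)]
          sec$round <- round
          sec$sets_polarity <- FALSE
          triggers <- rbind(triggers, sec)
          anchors[[lid]] <- c(anchors[[lid]], sec$slice_genomic)
          changed <- TRUE
        }
      }
    }
    # (re-)extract phasiRNAs for every locus
    new_ph <- lapply(seq_len(nrow(loci)), function(i) {
      lid <- loci$locus_id[i]
      anc <- anchors[[lid]]
      main <- main_anchor[lid]
      if (length(anc) == 0L) {
        anc <- fallback_anchor(lid)
        main <- if (length(anc)) anc[1] else NA_integer_
      }
      extract_phasirnas(loci[i, ], bins[[lid]]$reads, anc, main,
                        locus_name = lid, cycle = params$cycle)
    })
    new_ph <- do.call(rbind, new_ph)
    grew <- is.null(phasirnas) || nrow(new_ph) > nrow(phasirnas)
    phasirnas <- new_ph
    rounds_run <- round
    if (!changed && !grew) break
  }
  # record fallback anchors for trigger-less loci so downstream consumers
  # (recall evaluation) see the registers actually annotated
  for (lid in loci$locus_id) {
    if (length(anchors[[lid]]) == 0L) {
      fa <- fallback_anchor(lid)
      anchors[[lid]] <- fa
      if (length(fa)) main_anchor[lid] <- fa[1]
    }
  }
  # phasiRNA-derived triggers may have been queried under a provisional
  # name (before their locus gained polarity); relabel them with the final
  # extraction's names, matched by sequence.  miRNA ids are left alone.
  if (nrow(triggers) && !is.null(phasirnas) && nrow(phasirnas)) {
    stale <- !triggers$srna_id %in% mirnas$name
    m <- match(triggers$srna_sequence[stale], phasirnas$sequence)
    triggers$srna_id[stale][!is.na(m)] <- phasirnas$name[m[!is.na(m)]]
  }
  rownames(triggers) <- NULL
  list(loci = loci, extended = ext, triggers = triggers,
       phasirnas = phasirnas, bins = bins, rank_scores = rank_scores,
       anchors = anchors, main_anchor = main_anchor,
       events = events_all, rounds = rounds_run)
}
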