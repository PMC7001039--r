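---
title: "Methods: phasiRNA locus detection, trigger inference and network assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasiRNA locus detection, trigger inference and network assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phasinet)
```

## The model

phasiRNA biogenesis is modelled as a deterministic geometry on a
transcript: a trigger sRNA pairs antiparallel to a target window and the
transcript is cut between the nucleotides paired to trigger positions 10
and 11.  The nucleotide paired to position 10 — the 5′ end of the
downstream fragment — is the *register anchor*: phased products start
there and at every 21 nt thereafter.  Each product is a duplex whose
antisense strand is the reverse complement of the sense window shifted by
+2 (the 2-nt 3′ overhang).  A 22-nt product consumes one extra
nucleotide, so all later cycles carry a +1 register offset; such
products, and any product away from the main register, are
*non-canonical*.  Degradome (PARE) sequencing observes the 5′ ends of
uncapped cleavage fragments, so a genuine slicing event appears as a tag
peak exactly at the register anchor.

Two coordinate conventions are used deliberately and documented on the
types that carry them: the truth manifest stores `slice_position` as the
nucleotide 5′ of the cut (with `register_anchor = slice_position + 1` in
transcript space), while target alignments report the slice as the
position paired to sRNA position 10 — the coordinate at which degradome
tags accumulate.  Tests compare alignment slices against the truth
anchor.

## Stage parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_count` | 50 | minimum collapsed read count retained per library |
| `min_len`/`max_len` | 20/40 nt | size window after trimming |
| `min_unique` | 100 | minimum unique sequences for an informative library |
| `allowed_lengths` | 21, 22 nt | read lengths mapped |
| `max_locations` | 10 | multimapper cap; counts divided between locations |
| `top_fraction` | 0.15 | fraction of coverage islands analysed for phasing |
| `min_regions` | 30 | floor on analysed islands (see below) |
| `island_gap` | 21 nt | gap bridged when building coverage islands |
| `window_cycles` | 11 | phasing window span, in 21-nt cycles |
| `min_phasing_score` | 15 | per-window call threshold |
| `min_libraries` | 3 | consensus detection floor |
| `pad` | 220 nt | locus extension for the trigger search |
| `deg_weights` | 5/4/0.5 | category 0/1/2 weights (3 and 4 score 0) |
| `bin_weights` | 5/2/0.5 | per-library rank weights for phase bins |
| `trigger_min_score` | 10 | minimum summed deg_score for a trigger |
| `target_threshold` | 15 | validation threshold for target interactions |
| `min_combined` | 50 | combined raw counts to become a target candidate |
| `min_overlap` | 0.70 | locus/feature overlap fraction (strict, end − start) |
| `max_allen` | 7.0 | maximum complementarity penalty retained |
| `max_rounds` | 3 | recursion depth (primary/secondary/tertiary) |

The phasing statistic `S = (k − 2)·ln(1 + 10·P/(1 + U))` (for `k ≥ 3`
occupied cycles) is a standard family for phased-register detection,
monotone in both occupancy and signal-to-noise; the threshold 15 and the
11-cycle window are package defaults, configurable.  The complementarity
penalty (mismatch 1.0, G:U wobble 0.5, doubled at positions 2–13) is the
widely used plant target-prediction convention; `max_allen = 7.0` is a
permissive search cut because validation rests on degradome peaks, not on
alignment subtleties.

## Design choices made where the design was open

* **Reverse-read shift.** Phase bins are anchored at the consensus locus
  start; the effective 5′ position of a minus-strand alignment is its
  leftmost coordinate − 2.  The sign of the duplex correction is fixed by
  a testable invariant — both members of a 2-nt-overhang duplex must land
  in the same bin, for 21- and 22-nt products alike — rather than by an
  aligner-dependent coordinate convention.
* **Windows run past the island edge.** Phasing windows step one cycle
  and may extend beyond the candidate region's end.  Registers populated
  only near the region tail (typically downstream of a 22-nt shift
  product) would otherwise never dominate a window and their reads would
  be trimmed from the call.
* **Candidate-region floor.** The top-15% rule presumes thousands of
  coverage islands, as in deep compendium libraries.  On sparse data the
  ceiling of 0.15 × n can analyse almost nothing, so the pipeline applies
  a floor (`min_regions = 30`, bare function default 0): small candidate
  sets are analysed in full.  This only ever adds candidate regions; the
  phasing score still decides.
* **Boundary trimming.** Call boundaries are trimmed to the outermost
  reads in each qualifying window's dominant register (exact register,
  not ± 1): adjacent-register noise otherwise drags locus ends outward.
* **Trigger recursion and rank.** Rounds pool extracted phasiRNAs with
  known miRNAs and repeat the search.  A locus with no trigger yet can
  gain its polarity-setting trigger in any round (trans-triggered loci
  resolve in round 2); trigger rank labels follow the discovery round.
  Secondary/tertiary triggers must match the primary's polarity and slice
  within the three top-ranked bins ± 1.
* **Polarity-setting triggers need distributional support.** The primary
  trigger's slice bin must itself fall in the top-ranked bins ± 1 — a
  trigger sets the register the reads actually occupy — and a locus's own
  phasiRNAs cannot set its polarity (the initiating trigger precedes its
  products, and wrong-strand self-events would otherwise invert
  polarity).  Both rules matter in trans cascades, where the source
  locus's degradome fragments legitimately align to the antisense strand
  of the target locus and would otherwise outscore the true trans
  trigger.  Self-targeting records remain eligible as secondary triggers,
  where polarity matching is enforced.
* **Offsets.** Signed offsets use the symmetric modular mapping of the
  phase difference into −10..+10, computed in transcript coordinates with
  the duplex correction so both duplex members share register and offset.
  Positive offsets print with an explicit `+` (`(+1)`); the parser also
  accepts the unsigned form `(2)`.
* **Feature assignment.** Interval lengths and overlaps use the
  `end − start` convention; a confirmed assignment needs overlap > 0.70
  and matching polarity; without trigger-derived polarity the strand
  check is waived and the lowercase tentative notation is used; loci
  matching nothing keep the forward orientation and a coordinate name.
  When several features qualify, all are reported and the largest overlap
  is principal.
* **Clustering coefficient.** Average local clustering on the undirected
  projection, nodes of degree < 2 contributing 0 — the common default of
  network toolkits.  Degree-frequency regressions use base-10 logs and
  drop zero-frequency degrees.  GO enrichment runs over- and
  under-representation as two one-sided hypergeometric families, each
  Benjamini–Hochberg corrected.

## What the generator emulates — and what it does not

`simulation_config()` defines the study conditions: 2 chromosomes of
25 kb, 20 planted loci of 12 phased cycles, 6 sRNA and 4 degradome
libraries, per-(locus, library) Bernoulli expression at rate 0.8,
per-cycle abundance decay 0.9 from a base of 500 reads (so the last cycle
still clears the 50-count filter, as in deeply sequenced libraries),
noise fraction 0.3 with lengths uniform on 20–40 nt and counts uniform on
30–90 (straddling the abundance filter), degradome slice peaks of ~30
tags over a per-position background of 0.02.  Trigger complementarity is
perfect (penalty 0) unless the wobble knob is set; trans edges write the
source phasiRNA's complement into the target locus; target genes carry
planted phasiRNA sites, half of them also a miRNA site whose per-library
peak dominance alternates (recorded in the truth manifest), which is what
makes co-regulation of one transcript by two sRNA classes observable.

The generator does **not** model RNA secondary structure, sequencing
error, adapter content, hairpin miRNA biogenesis, bulged target
alignments, or translational repression.  Passing tests therefore show
that the inference machinery is correct under the stated biogenesis
geometry and noise model — not that the thresholds are optimal for any
particular real compendium, where library heterogeneity, repeat content
and incomplete annotations dominate the error budget.

## Numerical and degenerate-input behaviour

Fractional multimapper counts are exact ratios of integers kept as
doubles; conservation (Σ fractional = raw count) is asserted bit-exactly
in tests.  Ties are broken deterministically everywhere: islands and
calls by (chrom, start, end), bin ranks by lower bin index, trigger
selection by lower penalty then 5′-most slice on the targeted strand.
Empty libraries collapse to empty tables rather than errors; an empty
reference, an empty score vector, a position beyond a transcript, and a
sub-2-node graph raise explicit errors.  The ECDF threshold returns the
smallest observed score whose left-limit ECDF reaches the quantile, and
the maximum when no score qualifies (all-equal input).

Problem sizes in the shipped tests (a 50-kb genome, 20 loci, 6 + 4
libraries; smaller for unit fixtures) were chosen so the full suite and
the acceptance script each complete in a few minutes on one CPU while
every stage still sees multi-library, multi-chromosome, both-strand
input.

## Known limitations

Only cleavage-based regulation is considered; triggers acting without
slicing (or below degradome sensitivity) are invisible, and loci without
triggers receive tentative, lowercase or coordinate-based names.  24-nt
reproductive phasiRNAs are out of scope.  The per-library phasing
statistic substitutes for external detection tools and its absolute
scores are not comparable to theirs, only its ranking behaviour.
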