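---
title: "Synteny units, fusion calls and order breakpoints: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny units, fusion calls and order breakpoints: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsukit)
```

## The model

Lepidopteran genomes are compared here through the positions of
single-copy orthologs rather than through sequence alignment. An *anchor*
genome with the presumed ancestral karyotype (31 chromosomes in the
Heteroneura) is scanned with a BUSCO lineage set; each anchor chromosome's
subset of usable markers defines one *synteny unit*. Because the markers
are near-universal and single copy, any other genome's BUSCO table can be
joined to the unit table by marker identity alone. Marker positions are
never compared across genomes — only (a) which chromosome a marker lands
on, and (b) the order of markers along each chromosome. From (a) we read
interchromosomal history (fusions, fissions, transpositions); from (b),
intrachromosomal history (order breakpoints left by inversions and
translocations).

The method's central assumptions are that the markers are orthologous,
effectively single copy, and dense enough that chromosome-scale events
move at least a handful of them. The resolution is bounded by marker
density: rearrangements between adjacent markers are invisible, so all
breakpoint counts are lower bounds on the true rearrangement count.

## Filtering

From every `full_table.tsv` we drop `Missing` lines and *all* lines of any
marker that occurs with status `Duplicated` — BUSCO cannot tell which copy
is orthologous, so keeping either would risk a false homology signal.
`Fragmented` markers still carry reliable positions and are kept by
default (`drop_fragmented = TRUE` tightens this). The same rule is applied
to anchor and target genomes.

## Unit definition and assignment

Anchor markers are grouped by chromosome and sorted by `(start, end,
marker_id)` — the third key only breaks exact coordinate ties, making
ranks deterministic. Units are numbered from the chromosome names' trailing
integers, with any Z-named chromosome placed last
(`naming_policy = "by_sequence_suffix"`); when names are opaque,
`"by_length_desc"` numbers by decreasing chromosome length instead. The
rank of each marker within its unit (`anchor_rank`) is the quantity all
order comparisons use; coordinates are 1-based inclusive, but since only
relative order matters the convention cannot affect any result.

Assignment sorts the target's usable markers along its chromosomes,
attaches `(lsu_id, anchor_rank)` by marker identity, and leaves markers
unknown to the unit table explicitly unassigned.

## Composition calls

The hit-count matrix (target chromosomes × units) is classified with three
thresholds:

* `min_component_markers = 5` and `min_component_fraction = 0.05`: a unit
  is a *component* of a chromosome only with ≥ 5 markers and ≥ 5% of the
  chromosome's assigned markers. Both are needed: the absolute floor
  keeps sparse scatter (and transposed fragments, which are ≤ 3 markers)
  from counting as fusion partners on small chromosomes, the relative
  floor does the same on large ones. On ~170-marker chromosomes a genuine
  fusion partner contributes tens of markers, far above both floors.
* `intact_fraction = 0.95`: a unit is *intact* when ≥ 95% of its recovered
  markers sit on one chromosome. This tolerates the low background of
  single-marker transfers seen even between conserved genomes, while a
  genuine fission (two substantial components) is called *split* and a
  pulverized unit — many chromosomes, each below component size — is
  *dispersed*.

The thresholds are not taken from any measurement; they are defaults
chosen to separate those regimes, are configurable everywhere, and are
echoed in every output header. Classification is monotone: raising
`min_component_fraction` can only remove components.

## Transpositions and breakpoints

Each target chromosome is scanned in marker order for maximal runs of
consecutive markers from a unit that is not one of its components. Runs of
at most `max_run = 3` markers are *small nonreciprocal transpositions*
(reported as single markers vs groups of 2–3); longer foreign runs are
flagged as translocated segments and reported separately. Note the
interplay with the component thresholds: a foreign run of ≥
`min_component_markers` markers that also clears the fraction floor is a
fusion component, not a segment — by design, since at that size "small
transposition" is no longer the parsimonious reading.

Breakpoints are counted per (chromosome × unit) group: transposed markers
are removed first (each event should be counted once, as an event, not
again as up to three breakpoints), the group's remaining markers are taken
in target order, their anchor ranks are re-ranked `1..m` within this
shared set, and every adjacent pair with `|Δrank| ≠ 1` is one breakpoint.
Consequences of this definition, chosen as the minimal rule consistent
with "an inversion leaves 2 breakpoints, a translocation 3":

* Re-ranking makes counts invariant to markers missing from the target:
  deleting markers strictly inside collinear segments never changes the
  count.
* Counting is unsigned, so a whole-group reversal (or a group carried into
  a fusion in reverse orientation) contributes 0 — orientation-free by
  construction. Strand is parsed and the simulator records strand flips,
  but a signed mode is future work.
* Group ends are free: chromosome ends and the junction between two units
  on a fused chromosome are not breakpoints, so clean fusions and fissions
  count 0.
* Groups with fewer than two shared markers contribute 0.

Rates divide the genome totals by the summed length (Mbp) of the
marker-bearing target sequences — assemblies often carry unplaced
fragments without markers, and sequence without markers cannot contribute
events, so this denominator is used consistently. Lengths come from a
`.fai`-style table when supplied; otherwise they are inferred as the last
marker end per sequence, a lower bound, and every downstream report flags
the rates as `inferred`.

## What the simulator emulates

`make_anchor()` defaults describe the study system: 31 chromosomes of
20 Mbp carrying 170 evenly spaced markers each (5,270 usable markers,
matching the scale of a lepidopteran BUSCO run), with ±9% spacing jitter
(`jitter = 0.2`), all `Complete`. `apply_events()` applies an explicit
ordered event list — fusion, fission, inversion, transposition, loss,
duplication — and re-spaces coordinates only on edited chromosomes, so an
empty event list reproduces the anchor byte for byte. One integer seed
drives everything; no wall-clock entropy exists anywhere.

For *non-interacting* event lists the truth log carries an exact analytic
signature (2 breakpoints per internal inversion, one event per moved run,
`fusion_of_k` per fusion, a split unit per fission). Non-interaction is
enforced by construction in `random_events()` (rejection of shared
chromosomes, internal ranges separated by ≥ 2 positions, losses confined
to otherwise untouched chromosomes) and verified conservatively in
`apply_events()`; interacting lists are legal input but carry no
signature, rather than a possibly wrong one.

The simulator deliberately does not emulate: nucleotide-level
rearrangements (invisible to marker order by definition), reciprocal
translocations, marker clustering or density gradients along real
chromosomes, W chromosomes (which carry no BUSCO hits), fragmented
assemblies, or any divergence-time process. Passing the recovery suite
therefore shows that the pipeline reads back chromosome-scale events
exactly under ideal marker density; on real genomes the counts remain
lower bounds and fusion calls depend on assembly contiguity.

## Degenerate inputs and numerical choices

* Anchor chromosomes with zero usable markers are simply absent (one unit
  fewer); a single-chromosome anchor is allowed with a warning.
* A target with no markers in common with the unit table is an error, as
  is an all-`Missing` table.
* Sort ties are broken by `(start, end, marker_id)`; all randomness is
  seeded through one integer; re-running any stage with identical inputs
  and configuration produces byte-identical files (headers echo version
  and configuration, never timestamps).
* Coverage summaries report the span from the first marker start to the
  maximum marker end per chromosome; where a table's convention for "last
  position" is ambiguous, the maximum of start/end is used.

## Problem sizes used by the test suite

The recovery properties run on the default 31 × 170 anchor: 200 seeded
inversion simulations (k = 1..10 × 20 seeds, each read back as exactly
2k breakpoints), 50 fusion/fission mixtures, 50 transposition draws of
1–10 runs, the same 200 inversion runs repeated under 10% marker loss
inside collinear segments, and 1,000 random 50-marker permutations checked
against a brute-force adjacency oracle. These sizes give every event type
dozens of independent replicates while keeping the suite comfortably
interactive.

## Known limitations

Homology is marker identity: paralogy mistakes in the upstream BUSCO run
propagate. Breakpoint counts are unsigned and resolution-limited, so they
under-count true rearrangement, increasingly so for distant genomes where
collinear segments shrink toward single markers. Fusion/fission calls on
highly fragmented assemblies will mistake contig breaks for fissions; the
method presumes chromosome-scale sequences. Reciprocal translocation
inference and nucleotide-level breakpoint localization are out of scope.
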