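# lsukit

Chromosome-scale synteny units from BUSCO marker tables.

Chromosome numbers vary widely across butterflies and moths, so comparing
karyotypes by counting chromosomes says little about which chromosomes are
actually homologous. A robust alternative is to trace homology through the
positions of near-universal single-copy orthologs: BUSCO's
`lepidoptera_odb10` set places 5,286 such markers in any lepidopteran
assembly, densely enough to treat each anchor chromosome's marker subset as
a reusable homology unit. `lsukit` implements this synteny-unit analysis
for anyone with chromosome-scale assemblies and BUSCO `full_table.tsv`
outputs:

* **Define units.** Discard `Missing` and `Duplicated` marker lines from
  the anchor genome's table, sort the rest by chromosome and position, and
  call each chromosome-specific subset a synteny unit (`LSU_1..LSU_n`,
  with the Z chromosome's subset numbered last).
* **Assign targets.** Join any other genome's table to the unit table *by
  marker identity only* and tabulate hit counts per (target chromosome ×
  unit). A unit is a *component* of a chromosome when it contributes ≥ 5
  markers and ≥ 5% of that chromosome's assigned markers; chromosomes are
  then `single` or `fusion_of_k`, units `intact`, `split` or `dispersed`.
* **Count rearrangements.** Within each (chromosome × unit) group, take
  the shared markers in target order, re-rank their anchor ranks
  `1..m`, and count adjacencies with `|Δrank| ≠ 1` — an inversion leaves 2
  such order breakpoints, a translocation 3. Maximal runs of ≤ 3 markers
  from a non-component unit are small nonreciprocal transpositions,
  removed before counting so each is tallied once. Totals are also
  expressed per Mbp of the marker-bearing sequences.
* **Simulate.** A seeded rearrangement simulator emits anchor/descendant
  BUSCO-table pairs with a ground-truth event log, so every stage can be
  validated against known fusions, fissions, inversions, transpositions,
  losses and duplications.

## Worked example

```r
library(lsukit)

# a 31-chromosome anchor (170 markers per ~20 Mbp chromosome) and a
# descendant with 1 fusion, 3 internal inversions and 2 transpositions
anchor <- make_anchor(seed = 42)
events <- random_events(anchor, n_fusions = 1, n_inversions = 3,
                        n_transpositions = 2, seed = 43)
sim <- apply_events(anchor, events)

res <- lsu_analyze(anchor, sim$target, lengths = attr(sim$target, "sim_lengths"))
res
#> Unit composition: 30 target sequences x 31 units, 5270 assigned markers
#> chromosome calls: fusion_of_2=1, single=29
#> unit calls:       intact=31
#> Rearrangement report (target vs anchor units)
#>   breakpoints within units: 6
#>   transpositions: 1 single, 1 groups of 2-3 (0 larger segments)
#>   rates over 620.0 Mbp (supplied lengths): 0.01 breakpoints/Mbp, 0.00 transpositions/Mbp
```

The readout matches the simulated truth exactly: the fused pair appears as
one `fusion_of_2` chromosome, each of the 3 internal inversions leaves 2
order breakpoints (6 in total), and both moved runs are recovered as
transposition events of the right size:

```r
sim$truth
#> Simulation truth: 6 events (fusion=1, inversion=3, transposition=2)
#>   non-interacting; expect 6 breakpoints, 1 single + 1 grouped transpositions
```

`glance(res)` returns the per-genome summary as a one-row tibble
(breakpoints within units, per Mbp, single and 2–3 marker transpositions,
per Mbp), `tidy(res$composition)` the long hit-count table, and
`autoplot(res$composition)` a chromosome-painting style bar chart. For
file-based work the same stages are available as `lsu_define()`,
`lsu_assign()`, `lsu_breakpoints()` and `lsu_simulate()`, or from the
shell via `Rscript inst/cli/lsu.R <define|assign|breakpoints|simulate>`,
all writing plain TSVs with the configuration echoed in `#` header lines.

Real BUSCO v5 tables (and v3/v4 tables, which lack the strand column) are
read with `read_full_table()`; sequence lengths for per-Mbp rates come
from any `.fai`-style table via `load_sequence_lengths()`, or are inferred
from marker coordinates (and flagged as such) when no index is available.

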