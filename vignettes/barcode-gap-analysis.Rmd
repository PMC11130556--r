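---
title: "Barcode-gap analysis with bargap: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-gap analysis with bargap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bargap)
```

## The problem

Single-marker DNA barcoding rests on the *barcode gap*: within a species,
CO1 sequences differ by a small percentage, while between species the
divergence is markedly larger. When the gap holds, three things become
mechanical: a species can be *characterised* by its consensus barcode and
its intra/interspecific distance bounds; specimens can be *delimited*
into putative species by clustering below a distance threshold; and any
molecular partition can be *scored* against an independent (usually
morphological) species hypothesis. `bargap` implements this workflow for
aligned barcode data, together with a codon-aware detector for
clade-diagnostic in-frame deletions and a calibrated simulator used to
test every stage.

## Distances

All distances are uncorrected p-distances: the proportion of differing
sites among the columns a sequence pair can be compared at. No
multiple-hit correction (Jukes-Cantor, K2P, ...) is applied in the
characterisation path, because the quantities reported in barcode
studies — "maximum barcode-distance within species", "minimum
barcode-distance to closest species" — are raw percentages.

What "can be compared" means is an explicit, user-visible policy
(`distance_policy()`):

* `pairwise_deletion_strict` (default): a column is dropped for a pair
  when either sequence carries a gap **or** any non-ACGT IUPAC code.
  Ambiguity codes therefore never influence a distance. This is the
  conservative choice: desktop alignment suites differ in how they score
  ambiguities, and published matrices rarely state the rule. On typical
  consensus barcodes the difference is at most a couple of sites per
  pair.
* `pairwise_deletion_gaps_only`: only gap columns are dropped; an
  ambiguity column counts as a match when the two base sets intersect
  (Y vs C matches, Y vs A differs).

Distances are stored as fractions throughout; conversion to percentages
(one decimal, half-away-from-zero) happens only at the reporting layer,
so rounding never compounds.

## Characterisation

`species_profiles()` produces, per species: the sample size *n*, the
maximum intraspecific distance (reported "not applicable" when *n* = 1),
the minimum distance to any record of another species together with that
species' name (ties between species broken alphabetically, which the
report states), and an IUPAC consensus barcode.

The consensus rule (`consensus_sequence()`) works per column: gaps are
ignored (all-gap columns are dropped); input ambiguity codes contribute
their base sets; if one base is the unique most frequent plain call and
reaches the majority threshold it is emitted, otherwise the minimal
IUPAC code covering all observed bases is emitted. The default majority
of 0.5 means "at least half wins, ties become ambiguity codes": an even
C/T column yields Y. This reproduces the sparse, isolated ambiguity
codes seen in published consensus barcodes; a strict 100% rule would
flood a variable species (a few percent internal divergence across
dozens of specimens) with ambiguity codes, and quality-weighted calling
is impossible without trace data.

Report percentages round half away from zero to one decimal; values of
10% or more with a zero decimal print as integers ("12%", matching how
such values are typically typeset).

## Delimitation

`single_linkage_clusters()` is objective clustering: clusters are the
connected components of the graph with an edge wherever *d* < *t*. The
comparison is strict, so a pair at exactly the threshold does **not**
merge; conventions differ between tools, and a documented strict rule
avoids boundary ambiguity. Single linkage matches the transitive "3%
cluster" behaviour of the objective-clustering literature; the
conventional default threshold is 0.03.

`ranked_partitions()` generalises the single threshold: single-linkage
merge heights `h_1 < ... < h_K` bound intervals inside which the
clustering is constant, and each interval's partition is scored by the
relative width of the distance gap above it,

```
gap_score_i = (h_{i+1} - h_i) / h_{i+1}
```

with the maximum observed distance standing in for `h_{K+1}` at the top.
Partitions are ranked by decreasing score, ties broken toward fewer
clusters. This is intentionally a *transparent analogue* of automatic
hierarchical partitioning methods such as ASAP — it ranks partitions
purely by barcode-gap width and does **not** implement the published
ASAP probability score, whose reimplementation belongs with its own
publication. Outputs are labelled accordingly, and
`read_partition_tsv()` lets partitions from external tools (ASAP web
service, mPTP, ...) enter the same congruence comparison instead.

`compare_partition()` classifies every reference species as congruent
(one pure cluster), split (several pure clusters), lumped (one shared
cluster) or mixed (anything else) — the four ways a molecular partition
can relate to a prior species hypothesis.

## Diagnostic deletions

A deletion shared by every member of a clade and absent outside it is a
rare, near-binary character in a barcode alignment. `diagnose_genus()`
tests for one: `detect_shared_deletions()` finds maximal runs of
alignment columns gapped in at least `min_share` of the non-reference
records while the full-length reference keeps bases, and reports each
run with its frame context. The default `min_share = 1` encodes that a
diagnostic character must be universal in the ingroup; the verdict
function internally relaxes it so that records *lacking* a
near-universal gap can be named in the negative verdict.

Frame inference (`detect_reading_frame()`) picks the offset minimising
internal stop codons under NCBI translation table 5 (invertebrate
mitochondrial: ATA = Met, TGA = Trp, AGA/AGG = Ser); a clean CO1 barcode
has exactly one stop-free frame. Translation resolves ambiguity codes
when every resolution yields the same amino acid and emits X otherwise.
The table is configurable for reuse on other markers.

The expected location of a diagnostic gap is matched as a *window*
(default alignment columns 450–510) rather than a point: the flanking
region of such gaps is typically highly variable, so a printed position
like "around bp 476" cannot be pinned to one column, and the window also
sidesteps whether the position was counted in amplicon or alignment
coordinates.

## The simulator

`simulate_alignment()` generates the statistical structure the analysis
assumes, with full truth labels:

* a near-star ultrametric species tree (random-order caterpillar whose
  internal nodes all sit within 2% of the root depth), so every species
  pair diverges at essentially the same depth; the depth is calibrated
  so the expected pairwise p-distance equals `inter_divergence` under
  Jukes-Cantor, via `p = 3/4 (1 - exp(-4/3 b))` and its inverse;
* sites i.i.d. under Jukes-Cantor along each branch;
* star-shaped intraspecific sampling: each record evolves independently
  from its species' ancestor on a leg calibrated so two conspecific
  records diverge by `intra_divergence` in expectation;
* optional IUPAC noise (a base becomes a two-base code containing it,
  at `ambiguity_rate` per site) and an optional clade-restricted
  deletion, applied as gap columns so frame bookkeeping is exercised.

Defaults (7 species × 5 records, 658 bp, 1% intra, 8% inter, ambiguity
rate 0.001, deletion off) mirror a small-genus barcoding study: a
handful of species, a wide barcode gap, occasional ambiguity codes, and
the standard full-length animal barcode. These sizes also set the
problem scale used by the test suite.

What the simulator deliberately does **not** emulate: within-species
coalescent structure, rate heterogeneity across sites or lineages,
indel evolution beyond the single configured deletion, and sequencing
error. Consequently, passing recovery tests show the pipeline is
correct *when the barcode gap assumption holds*; they say nothing about
taxa with para/polyphyletic barcodes, introgression or very recent
splits, where distance-threshold delimitation fails for biological, not
algorithmic, reasons. The generator refuses configurations with
`intra_divergence >= inter_divergence` for the same reason: without a
gap there is no ground truth to recover.

## Numerical choices and degenerate inputs

* Merge heights are deduplicated at 1e-12; candidate partitions are
  realised at `h + 1e-12`, safely inside the constant interval for
  barcode-scale distances (well above 1/658).
* An all-equal distance matrix yields a single ranked candidate with
  gap score 0; a pair with no comparable sites yields an undefined
  (`NA`) distance, which clustering refuses rather than guessing.
* Nearest-species and ranked-partition ties break deterministically
  (alphabetical species; fewer clusters first).
* Cluster ids are assigned in first-seen record order, so identical
  inputs give byte-identical outputs.
* Thresholds on the command line accept `3%` and `0.03` alike and are
  converted once at the boundary.

## Interpreting the published-fixture results

The package ships the seven full-length (652 bp) species consensus
barcodes printed in the source study as a plain-text fixture, plus a
*synthetic* full-length reference — the *P. villosa* sequence with six
neutral bases re-inserted at alignment position 476 — used by the
deletion detector; no full-length relative's barcode is published, and
the reference's id labels it synthetic. On this fixture the pipeline
reproduces the published species count at the 3% threshold, the closest
published species pair and all nearest-neighbour identities, and the
6 bp / two-amino-acid diagnostic deletion. Published *minimum*
interspecific percentages were computed over individual specimens,
which are not printed in the paper; consensus-to-consensus recomputation
matches them only up to the species' internal variation (two pairs land
0.1–0.5 percentage points away at printed precision). The per-specimen
supplementary matrix can be dropped into `inst/extdata/` to extend the
checks to specimen level.

## Limitations

* Distance-threshold delimitation inherits all known failure modes of
  the barcode gap; this package makes the rules explicit rather than
  the inference robust.
* The gap-ranked partition score is a transparent stand-in, not the
  published ASAP score; ranks can differ from the web service's.
* Consensus calling is unweighted; it cannot reproduce quality-weighted
  consensuses from trace-aware assemblers.
* The deletion detector reasons in alignment coordinates and assumes
  the supplied reference is genuinely full-length over the region of
  interest.
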