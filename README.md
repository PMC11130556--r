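# bargap

Barcode-gap analysis for single-marker DNA barcoding studies: per-species
molecular characterisation, distance-threshold species delimitation with
congruence scoring, and codon-aware detection of clade-diagnostic
in-frame deletions. Written for taxonomists running the molecular half
of an integrative-taxonomy workflow on aligned CO1 (COI) barcodes, and
for anyone who needs those steps reproducible and scriptable rather than
buried in desktop suites.

## What it computes

For an aligned set of barcodes with species labels:

* **Uncorrected p-distances** `p = n_diff / n_comparable` under an
  explicit pairwise-deletion policy (strict: a column is dropped for a
  pair when either sequence has a gap or a non-ACGT IUPAC code).
* **Species profiles** — sample size *n*, maximum intraspecific distance
  (`not applicable` when *n* = 1), minimum interspecific distance with
  the nearest species, and an IUPAC majority consensus barcode (ties
  become ambiguity codes: an even C/T column yields Y).
* **Objective clustering** — putative species as connected components of
  the graph with an edge wherever `d < t` (single linkage, default
  `t = 0.03`), plus ranked partitions scored by relative barcode-gap
  width `(h_next − h) / h_next` over the single-linkage merge heights — a
  transparent analogue of automatic gap-based partition ranking (not the
  published ASAP probability score).
* **Congruence** of any partition (own or imported from external tools)
  with reference species labels: each species classified congruent /
  split / lumped / mixed.
* **Diagnostic indels** — maximal gap runs shared by the ingroup against
  a full-length reference, with reading frame inferred by minimising
  stop codons under the invertebrate mitochondrial code (NCBI table 5)
  and a verdict on whether a single in-frame deletion of the expected
  length sits in the expected region in every record.
* **Synthetic data** — a Jukes-Cantor simulator
  (`p = 3/4 (1 − e^{−4b/3})`) with known labels, controlled intra/inter
  divergence, IUPAC noise and an optional clade-restricted deletion.

## Worked example

The package ships the seven published full-length (652 bp) species
consensus barcodes of the hyperparasitoid wasp genus *Phaenoglyphis*
(Figitidae: Charipinae) as a plain-text fixture, plus a synthetic
full-length reference for the deletion detector.

```r
library(bargap)

fx  <- fixture_paper_dataset()          # 7 barcodes + synthetic reference
ids <- names(fx$labels)
aln <- barcode_alignment(fx$alignment$seqs[ids], ids = ids,
                         species = fx$labels, normalize = FALSE)

m <- distance_matrix(aln)               # strict pairwise deletion
round(100 * m$d["P_salicis", "P_longicornis"], 1)
#> [1] 4.9                               # the closest published species pair

single_linkage_clusters(m, t = 0.03)
#> Partition: 7 records in 7 clusters (threshold 0.03)

profiles <- species_profiles(aln)
cat(characterisation_report(profiles)[1:7], sep = "\n")
#> ## Phaenoglyphis belizini
#>
#> Maximum barcode-distance within species: not applicable (1).
#> Minimum barcode-distance to closest species: 6.6% (Phaenoglyphis villosa).
#>
#> Consensus barcode sequence (652 bp):
#> AATTTTATATTTTATTTTTGGAATTTGGTCAGG...

diagnose_genus(fx$alignment, "REF_synthetic_fulllength")
#> Diagnostic-indel verdict: POSITIVE
#> diagnostic 6 bp in-frame deletion (2 aa) at column 476 shared by all 7 records
```

Seven clusters at the 3% threshold means the molecular data recover
exactly the seven morphologically identified species; the positive
verdict confirms a single shared two-amino-acid (6 bp) in-frame deletion
— the genus-diagnostic character — in every barcode. `run_pipeline()`
executes all stages in one call and writes the distance CSV, profile
TSV/report, partition and congruence TSVs and the diagnostic report;
`inst/cli/bargap.R` exposes the same steps as shell subcommands
(`distances`, `characterise`, `delimit`, `diagnose`, `simulate`, `run`).

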