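# somamotif

Motif-centered analysis of somatic mutation catalogues from low-burden
normal tissues — clonally expanded cells, single-cell-derived clones, or
single-cell sequencing.

Catalogues from such samples carry a few hundred substitutions per
genome, too few for agnostic signature extraction to resolve mechanisms.
`somamotif` instead scores a registry of experimentally validated
trinucleotide mutation motifs, each tied to a known mutagenic process:

| motif | process |
|---|---|
| `nCg>nTg` (sub-motifs `rCg`, `yCg`) | spontaneous deamination of methylated CpG |
| `aTn>aCn` (sub-motif `aTr`) | small epoxides / SN2 electrophiles |
| `yCn>yTn` (sub-motif `yCh`), `nTt>nCt` | UV photolesions (CPD resolution) |
| `tCw>tTw`, `tCw>tGw` | APOBEC cytidine deamination |
| `hTg` | MMS-type alkylation |

For each (sample-or-donor, motif) pair the package computes, over the
*scattered* mutations of the motif's base-change class (clusters within
10 bp are excluded as complex events), the enrichment

E = (mut_motif × ctx_base) / (mut_class × ctx_motif),

where context is the unmutated sequence in the ±20 bp windows around each
class mutation, counted strand-symmetrically. Significance is a one-sided
Fisher's exact test with Benjamini–Hochberg correction, and significant
enrichment (E > 1, q ≤ 0.05) is converted into the enrichment-adjusted
**minimum estimate of mutation load**,

MEML = mut_motif × (E − 1) / E, else 0.

Around this core the package provides clonal allele-fraction filtering
(45–55% / ≥90% gates; SV junction gates), transcription-strand asymmetry
(exact conditional binomial test on the 192-channel stranded matrix),
COSMIC ID83-style indel classification with homonucleotide-run and
microhomology groupings, cross-donor structural-variant hotspot detection
(1 Mb rule) with common-fragile-site association, telomere-based
mutation-rate-per-division estimates, cohort statistics (one-sided
Spearman age correlations, Wilcoxon comparisons), and a synthetic-cohort
generator with ground-truth labels that makes every stage testable
without controlled-access data.

## Worked example

```r
library(somamotif)

ref   <- generate_reference(200000, gc = 0.41, cpg_factor = 0.25, seed = 42)
sim   <- simulate_snv_catalogue(ref, n_background = 600,
                                process_counts = c(nCg = 200), seed = 43)
catal <- filter_clonal_snvs(sim$catalogue)
panel <- motif_panel(catal, ref,
                     registry = motif_registry()[c("nCg", "aTn", "yCn")])
panel[, c("unit","motif","mut_motif","mut_class","enrichment","p","q","meml")]
```

```
  unit motif mut_motif mut_class enrichment        p        q meml
1   S1   nCg       135       208       6.34 3.04e-72 3.04e-72  114
2   S1   aTn        24        72       1.04 4.57e-01 4.57e-01    0
3   S1   yCn       106       208       1.05 2.79e-01 2.79e-01    0
```

The clonal gate keeps 551 of the 800 simulated records (the rest fall in
the simulated subclonal tail). The injected meCpG-deamination process is
detected with enrichment 6.3 and a MEML of 114 mutations attributed to
it — a deliberate *minimum*: part of the 200 injections is lost to the
subclonal AF tail and cluster exclusion, and the estimator subtracts the
local context rate for all class mutations (see the methods vignette for
the exact bias decomposition). The two inactive motifs are correctly
flat (E ≈ 1, MEML 0). Telomere-based normalisation:

```r
estimate_divisions(4.4)                       # 36 divisions since birth
mutation_rates(444, 74)$per_genome_per_division   # 6
mutation_rates(444, 74)$per_nt_per_division       # 1e-09
```

## Command line

```sh
Rscript -e 'somamotif::somamotif_cli()' filter \
  --catalogue calls.tsv --af-windows 0.45:0.55,0.9:1.0 --out clonal.tsv
Rscript -e 'somamotif::somamotif_cli()' enrich \
  --catalogue clonal.tsv --ref genome.fa --level donor --out enrich.tsv
```

Subcommands: `filter`, `enrich`, `indels`, `sv`, `simulate` (an
executable wrapper is installed under `inst/cli/somamotif`).

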