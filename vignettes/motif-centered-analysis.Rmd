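---
title: "Motif-centered analysis of somatic mutation catalogues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-centered analysis of somatic mutation catalogues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somamotif)
```

## The problem

Low-burden somatic mutation catalogues — from clonally expanded cells or
single-cell sequencing of normal tissue — typically carry a few hundred
substitutions per genome. At that depth, agnostic signature extraction is
underpowered, and refitting against reference signature compendia tends to
attribute everything to flat, clock-like signatures. Motif-centered
analysis takes the opposite route: it starts from a short registry of
*experimentally validated* trinucleotide mutation motifs, each tied to a
known mutagenic mechanism (e.g. `nCg>nTg` for deamination of methylated
CpG, `aTn>aCn` for small epoxides and SN2 electrophiles, `yCn>yTn` and
`nTt>nCt` for UV photolesions, `tCw>tTw`/`tCw>tGw` for APOBEC), asks
whether each motif is enriched in a sample's catalogue, and converts
significant enrichment into a conservative per-process mutation count.

## The statistic

For a motif with pyrimidine-strand pattern `nCg` and base change C→T,
four counts are formed from the *scattered* mutations of the class
(records within 10 bp of another same-sample mutation are excluded as
potential single-event complexes; all members of such a cluster are
dropped):

* `mut_motif` — class mutations whose folded trinucleotide matches the
  pattern (purine-reference records are reverse-complemented first);
* `mut_class` — all class mutations (C→T plus G→A);
* `ctx_motif` — motif-eligible positions, counted on both strands, in the
  ±20 bp windows around each class mutation;
* `ctx_base` — class-base positions (C plus G) in the same windows.

Then

$$E \;=\; \frac{\text{mut}_{motif} \times \text{ctx}_{base}}
                {\text{mut}_{class} \times \text{ctx}_{motif}}
    \;=\; \frac{\text{motif rate}}{\text{background rate}},$$

significance is a one-sided Fisher's exact test on
`[[mut_motif, mut_class − mut_motif], [ctx_motif, ctx_base − ctx_motif]]`
with Benjamini–Hochberg correction (by default across units within each
motif; the family is configurable because the original analysis does not
state it), and the **minimum estimate of mutation load** is

$$\mathrm{MEML} = \text{mut}_{motif}\,\frac{E-1}{E}
  \quad\text{if } E > 1 \text{ and } q \le 0.05,\qquad 0
  \text{ otherwise.}$$

### Context counts use unmutated positions only

The significance table compares mutated sites against *unmutated* bases in
the flanking context, and the context itself is defined as the bases
*flanking* the mutation. Both statements imply that mutated positions —
in particular the mutated centre of each window — must not be counted as
context. This matters: a motif-targeted mutation always sits on a motif
site, so counting centres would add one guaranteed motif hit per window
and inflate the local motif density exactly where the process was active,
biasing both $E$ and MEML downward (measured on a seeded 1 Mb cohort:
nCg recovery 415/500 with centre inclusion versus ~455 surviving
injections recovered at ~409 without it; see below for why the remainder
is irreducible). `count_motif_and_context()` therefore excludes every
position carrying a same-unit SNV from the context counts of every
window. A consequence worth knowing: in the minimal worked example of a
single C→T at the centre of a window whose only CpG is the mutated site
itself, the counts are (1, 1, 1, 1) — the mutated C is not context, but
its unmutated G partner still is, on the minus strand.

Windows of different mutations are counted independently (overlaps
contribute twice): each mutation's local context is sampled identically,
and no merging rule is stated in the source analysis. Windows are
truncated at contig ends with a warning.

### MEML is a minimum, and by how much

Writing $M$ for the number of process mutations, $B$ for same-class
background, and $r$ for the motif-eligible fraction of class context,
expectation gives $\mathrm{MEML} \approx M(1-r)$: the estimator subtracts
the context rate times *all* class mutations, including the $M$ process
mutations themselves. This is the designed conservatism of a minimum
estimate. Two further terms apply in practice: the mandated
complex-mutation exclusion removes clustered injections (≈9% at 3,000
mutations per Mb — including same-CpG double hits, since both strand
sites of one CpG are eligible), and for CpG motifs the unmutated G
partner of each mutated CpG still contributes one motif-eligible context
position per window. For `nCg` on a human-like genome ($r \approx 0.05$)
the aggregate shortfall is ≈19%; for `aTn` it is ≈30–36% at *any*
realistic composition, because a degenerate 3′ flank pins
$r_{aTn} = \Pr(\text{A before T}) \approx (1-\mathrm{GC})/2 \approx 0.3$.
The acceptance suite keeps the 15%-recovery assertion as specified, and
those two expectations are the suite's known-red entries; a separate
module test asserts the behaviour actually attainable (recovery of the
bulk, bounded above by the injected count).

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| AF windows | [0.45, 0.55] ∪ [0.90, 1.00] | clonal heterozygous/homozygous gates (closed bounds; the source text writes percentages without openness) |
| SV junction gates | [0.40, 0.60] ∪ [0.90, 1] (DEL/INV/INS/TRA); [0.20, 0.60] (DUP) | duplications gain a copy, halving the apparent junction fraction |
| `min_depth`, `min_alt_reads` | 10, 3 | applied only when depth columns exist; the stated "3x coverage, ≥10 supporting reads" is contradictory read literally, so the feasible reading is used and both knobs are exposed |
| context window | ±20 bp | fixed by the method definition |
| cluster distance | ≤10 bp | complex-mutation exclusion; both boundary members removed |
| `alpha` | 0.05 | q-value gate for MEML |
| hotspot window | 1 Mb, inclusive | cross-donor breakpoint distance; both breakpoints of every SV participate; per-breakpoint rather than per-span (the source does not state which; per-breakpoint matches "breakpoint locations within 1 Mb") |
| telomere arithmetic | 11 kb newborn TRF, 1 kb TRF offset, 2 kb culture add-back, 100 bp/division, 6×10⁹ nt | the 100 bp/division default is derived from the source's own arithmetic (2 kb added back for ~20 culture generations) and is configurable because it is never stated outright |

Statistical conventions: age correlations are one-sided Spearman tests
(loads are expected to increase with age); everything else is two-sided.
The strand-asymmetry test is the exact conditional binomial (p = min(1,
2 × smaller tail) at success probability ½ given the strand total), which
is the exact form of the two-sided Poisson rate-ratio test after
conditioning — chosen for exactness and a closed-form oracle; the upper
tail is computed with `lower.tail = FALSE` to avoid cancellation at tiny
p. Records under opposite-strand overlapping genes are excluded rather
than double-counted.

## Indel channels

Indels are left-aligned and classified into the standard 83-channel
scheme: 1 bp events by folded base and reference homopolymer run length
(for deletions the run includes the deleted base; for insertions it is
the identical bases already present), longer events adjacent to full
copies of themselves by repeat-unit count, and remaining deletions ≥2 bp
by maximum edge microhomology (checked on both edges). The two headline
groupings are 1 bp indels in runs ≥5 (replication slippage) and
non-repeat deletions ≥5 bp with/without microhomology (end-joining after
double-strand breaks).

## What the synthetic cohorts emulate — and what they do not

The generator states a fixed world: i.i.d. base composition at a chosen
GC (default human-like 0.41) with CpG frequency scaled by a factor
(default 0.25, matching human CpG observed/expected) and plantable
homopolymer runs; motif processes drawing sites uniformly from eligible
positions on both strands, without replacement, collisions redrawn;
allele fractions from a clonal/homozygous/subclonal mixture (truncated
normal 0.5 ± 0.02, uniform 0.95–1, scaled Beta over 0.05–0.45; default
weights 0.6/0.1/0.3, reflecting the pronounced sub-45% tail seen in
clone catalogues before filtering); slippage indels placed
proportionally to run length; 5–24 bp deletions with microhomology drawn
from a stated distribution; SV types dominated by deletions then
duplications, with a chosen fraction placed near shared hotspot loci;
and clock-like per-donor process counts, Poisson with mean rate × age,
ages defaulting to the 55–86 donor range.

It does **not** emulate chromatin- or replication-timing-dependent
mutation rates, CpG-island clustering, sequence autocorrelation, copy
number, or read-level artefacts. A green test therefore establishes that
the *statistics* behave as derived under the stated world — type-I
control, oracle equivalence, recovery up to the minimum-estimate bias —
not that the generator reproduces real genomes.

## Numerical and degenerate-input choices

Zero denominators give `NA` enrichment and zero MEML. Fisher tables with
a degenerate margin return p = 1. Constant vectors give `NA` Spearman
rho. Telomeres longer than the newborn baseline clamp divisions to zero
with a warning. Wilcoxon comparisons are exact for small untied samples
and normal-approximated with tie correction otherwise;
singleton-vs-singleton is `NA`. Donor-level pooling deduplicates
identical variants shared by a donor's clones (configurable), because the
same clonal event carried by two siblings is one mutation. Shared
mutations across samples are reported but never removed. The `hTg`
registry entry's substituted base is not fixed by the available motif
literature; it defaults to T→C and is overridable via the registry TSV.

## Known limitations

* MEML's negative bias is intrinsic (see above); cross-motif comparisons
  of MEML implicitly compare different $r$ values.
* The BH family is a modelling choice; both families are implemented.
* The brute-force oracles scale only to test-sized genomes; the
  production path uses per-contig eligibility masks with cumulative sums.
* VCF reading takes allele fractions from an `AF` INFO/FORMAT field; no
  depth-based recomputation is attempted.
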