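---
title: "Methods: mutation profiling and translocation mapping at induced DSBs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation profiling and translocation mapping at induced DSBs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imutseq)
```

## The assay and its computational model

The package analyses multiplexed amplicon deep sequencing around
endonuclease-induced DNA double-strand breaks (DSBs). A single PCR with a
pool of primer pairs amplifies 25 loci — 10 prone to homologous
recombination (HR) repair, 10 prone to non-homologous end joining (NHEJ),
and 5 uncut controls — each as a ~250–290 bp product with the cut near the
middle and at least 100 bp of primer-free sequence on either side of it.
Because all primers sit in one reaction, a molecule whose two DSB ends were
ligated across loci (a translocation) is amplified by the forward primer of
one locus and the reverse primer of another; every read pair therefore
carries its own provenance in its first bases.

Three computational ideas carry the analysis:

1. **Primer-identity classification.** Each mate's 5' prefix is matched
   against all pool primers (both sides, both orientations) with a bounded
   Hamming distance. One forward plus one reverse primer from the same
   locus is a correctly repaired (cis) pair; from two loci, a trans
   (translocated) pair; anything else is unmatched. This is sound only if
   the primer set is collision-free at the match radius, which pool
   validation enforces up front.
2. **Per-nucleotide mutation rates from pileup text.** Aligned reads are
   summarised position by position in samtools pileup dialect; the caller
   decodes it exactly (substitutions with strand case, `+N`/`-N` indels,
   `*` deletion coverage, `^X`/`$` read boundaries) and expresses every
   mutation type as a percentage of the reads covering that position.
3. **Per-nucleotide background subtraction.** Natural variants and
   PCR/sequencing errors are position-specific, so the undamaged (−DSB)
   sample's rate of each mutation type at each nucleotide is subtracted
   from the damaged (+DSB) sample's. Treatment effects are isolated by the
   chained delta `(treat⁺ − treat⁻) − (ctrl⁺ − ctrl⁻)`. Negative deltas
   are meaningful (a treatment can suppress a mutation class) and are
   never floored.

## Coordinates and conventions

All internal coordinates are 0-based half-open; the pileup parser converts
from the dialect's 1-based positions at the boundary. `cut_offset` is the
offset of the first base 3' of the cut midpoint, so cut-relative position
0 is that base and negative positions lie upstream. The AsiSI recognition
motif (`GCGATCGC`) is centred on the cut midpoint at cut loci; the 2-nt
overhang the enzyme leaves is a property of the molecule, not of the
coordinate system, and is not modelled separately.

Deletion events follow pileup semantics: the `-N` event is anchored on the
last aligned base before the deletion and each deleted position shows `*`.
Per-position deletion *rates* use the `*` coverage (percent of reads
deleted at that nucleotide); event-level classification (size classes,
microhomology) uses the anchored events. Both views are emitted because
per-position rates match the "percent of reads at the position" rule while
classes need discrete events.

## Deletion annotation

Sizes classify as small (1 bp), mid (2–5 bp) and large (>5 bp). A deletion
is *adjacent* when its nearest deleted base lies within `adjacency_bp`
(default 10 bp) of the cut, else *distant*. The published profiles
contrast break-adjacent against distant mutations without printing the
threshold; 10 bp sits inside the observed ~20 bp mutation peak while
leaving homopolymer slippage sites (tens of bp out) clearly distant, and
it is a plain argument for anyone who prefers another value.

Junction microhomology is the ambiguity length of the deletion: the
largest `k ≤ min(deletion length, remaining right flank)` with the first
`k` deleted bases equal to the first `k` bases after the deletion. The cap
at the deletion length matters: without it every 1-bp deletion inside a
homopolymer would carry homology as long as the run, and slippage products
would masquerade as microhomology-mediated end joining (MMEJ). The MMEJ
flag therefore requires the large class *and* homology ≥ 2 bp; observed
MMEJ junctions run 2–7 bp, and the 7 bp ceiling is reported but not
enforced. The slippage flag requires ≤ 2 bp deleted inside a homopolymer
run of ≥ 3.

## The synthetic data generator

The generator is first-class, tested code: it defines the study conditions
under which every stochastic guarantee of the package is stated. Two
simulators share one generative model, so a spectrum implies the same
per-position event probabilities whether reads (`simulate_sample()`) or
pileup columns (`simulate_pileup()`) are emitted. The second bypasses
alignment entirely, which is what makes the caller testable without an
external aligner.

`mutation_spectrum()` defaults encode the observed phenomenology at
deep-sequenced restriction-enzyme DSBs, at the printed order of magnitude:

| parameter | default | meaning |
|---|---|---|
| `sub_rate_peak` | 2.5e-4 | per-read, per-position substitution probability at the cut; with the 20 bp decay this integrates to ~1% of reads substituted per DSB |
| `sub_decay_bp` | 20 | exponential spatial decay of the substitution peak |
| `sub_floor` | 2e-7 | distant floor; the only induced term at uncut loci |
| `sub_signature` | C>T 0.35, C>G 0.22, C>A 0.18, T>C 0.10, T>A 0.08, T>G 0.07 | pyrimidine-collapsed class weights, C>T-dominated |
| `del_small_rate` | 0.0022 | 1 bp break-adjacent deletions (0.22% per DSB) |
| `del_mid_rate` | 0.00094 | 2–5 bp deletions (0.094% per DSB) |
| `del_large_rate` | 0.0017 | >5 bp cut-spanning deletions (0.17% per DSB) |
| `distant_slip_rate` | 0.001 | 1 bp deletions at homopolymer runs ≥ 3, ≥ 16 bp from the cut |
| `mmej_rate` | 0.00068 | cut-spanning 6–70 bp deletions whose junction carries 2–7 bp homology (0.068% per DSB) |
| `ins_rate` | 5e-4 | 1–3 bp insertions near the cut (0.05% per DSB) |
| `transloc_rate` | 1e-4 | chimeric read pairs (~0.01%) |
| `seq_error_rate` | 0.001 | uniform per-base error, the Q30 regime |

Reads are 2×150: R1 is the molecule's first 150 bases (so it begins with a
forward primer), R2 the reverse complement of its last 150 (so it begins
with a reverse primer); shorter molecules give shorter reads, unpadded,
and qualities are constant Q30 because quality modelling is out of scope.
One mutational event per molecule is the default — it keeps the truth
table unambiguous under read-vs-reference diffing — with independent
per-class draws available via `multi_event = TRUE`. MMEJ deletions are
constructed from the locus's own sequence: all cut-spanning intervals of
6–70 bp whose junction ambiguity is 2–7 bp are enumerated deterministically
and drawn uniformly.

What the generator does **not** emulate: PCR duplicates and non-chimeric
PCR artefacts, platform error profiles and quality decay, enzyme
re-cutting, sister-chromatid and cell-cycle structure, and real genomic
flanking context. Passing tests therefore certify the *computational*
chain — classification, decoding, counting, subtraction — under a faithful
abstraction of the data, not the biology of any particular cell system.

The packaged 25-locus pool is likewise synthetic (the real primer panel is
not part of the package) but obeys every structural constraint of the
assay design: 10/10/5 class composition, 250–290 bp products, ≥ 100 bp
primer-free flanks, central AsiSI motif, planted homopolymer runs at
cut-distant offsets so slippage always has a target, and a primer set with
pairwise Hamming distance ≥ 5 over the full 20-mers.

## Numerical and design choices

* **Translocation denominator.** Matrix rates divide each cell by total
  classified (cis + trans) pairs, and unordered pair rates sum `(i,j)` and
  `(j,i)`. The published figures do not state their denominator; this one
  is self-normalising, monotone in the underlying propensity, and is
  applied consistently everywhere, so within-package comparisons are
  well-defined.
* **"Per DSB" totals** are sums of per-position percent rates over the
  ±100 bp window (means available via `per_position = "mean"`). Summation
  is the reading that makes a per-DSB total commensurate with event-level
  probabilities: the sum of per-position event rates is the expected
  per-read event count.
* **Metagene averaging** is unweighted across loci, the usual metagene
  convention; depth weighting would couple group means to library
  composition.
* **`min_depth`** (default 100) gates rate emission: a rate estimated from
  a handful of reads is noise, and missing stays missing through deltas
  rather than silently becoming zero.
* **Primer matching** uses the full primer length with `max_mismatch = 1`,
  tolerating one sequencing error; pool validation guarantees uniqueness
  at that radius, and pairs matching two same-side primers are counted
  unmatched because they are indistinguishable from primer artefacts.
* **GA hyperparameters** (population 24, 30 generations, tournament 3,
  crossover 0.7, per-gene mutation 0.1, 2 elites, mandatory seed) are
  small, fast and standard; elitism makes best-so-far fitness provably
  monotone, and every run is bitwise reproducible from its seed. Real
  genes mutate by a Gaussian of σ = 10% of the range clipped to the
  domain, so genomes are in-domain at all times. The external-aligner
  fitness (concordant-pair rate parsed from the aligner summary) is a
  documented subprocess contract; the package's own guarantees are stated
  and tested with synthetic fitness functions.
* **Degenerate inputs.** Zero-depth pileup columns carry empty base
  strings and decode to zero counts; empty FASTQ inputs yield zero
  matrices and empty splits; an empty parameter space renders an empty
  argument string; `n_pairs = 0` produces empty, valid FASTQ files.

## Problem sizes used by the test suite

The suite states its guarantees at desk scale, chosen so the full run
completes in a few minutes: sensitivity-floor recovery pools 50 replicates
of one 5,000,000-deep pileup column (2.5×10⁸ reads, ~1,250 expected
events, so the pooled estimate has ~3% relative error against a 10%
tolerance); parameter recovery runs ten seeded ±DSB pairs at depth 10⁵
per position over a 3-locus panel and checks 99% binomial intervals;
translocation recovery classifies 2×10⁵ simulated pairs; oracle suites are
exact (brute-force classifier on 200 pairs, hand-parsed pileup records,
exhaustive microhomology on 1,000 random instances); the GA criterion uses
an exhaustively enumerable 81-genome space across 10 seeds. Uncut-control
deltas are required to stay inside a simultaneous (Bonferroni-corrected)
99.9% binomial envelope.

## Known limitations

Translocation detection is primer-resolution: it identifies *which* loci
joined, not the junction breakpoint within the read, and inversions or
same-locus rearrangements are out of scope. The caller trusts its input
alignment — realignment around indels and base-quality recalibration
belong to the upstream engines. Deletion class totals count a multi-bp
deletion once at its anchor; per-position deletion coverage counts it at
every deleted base; both are reported, and which one a downstream analysis
should use depends on whether events or affected nucleotides are the
quantity of interest. Finally, rate recovery guarantees are binomial:
at depth `d` a mutation class at true rate `p` carries relative error
`~1/sqrt(d·p)`, so rare classes need deep data — the motivation for the
assay's very deep amplicon coverage in the first place.
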