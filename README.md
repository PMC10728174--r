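# imutseq

Quantifying DNA double-strand-break (DSB) induced mutations from
multiplexed amplicon deep sequencing — for researchers studying DSB repair
who need per-nucleotide mutation rates, deletion mechanism annotation and
translocation maps at endonuclease-cut loci.

## What it computes

A single multiplex PCR amplifies 25 loci (10 HR-prone, 10 NHEJ-prone, 5
uncut controls) as ~250–290 bp products centred on the cut, so every read
pair starts with the primers that amplified it. The package:

* **classifies read pairs by primer identity** — one forward plus one
  reverse primer of the same locus is a correctly repaired (*cis*) pair;
  primers from two different loci evidence a **translocation** (*trans*).
  The locus×locus count matrix has cis on the diagonal and rates
  `counts / total classified pairs`; translocated reads are split out
  before mutation calling.
* **calls per-nucleotide mutation profiles** from samtools-dialect pileup
  text: for each position, the 12 directional substitution rates, the
  insertion rate, the deletion coverage rate (each as % of reads covering
  the position, `rate = 100·k/depth`), plus deletion events by size class
  (1 bp / 2–5 bp / >5 bp). Deletions are annotated with break adjacency
  and junction microhomology — the largest
  `k ≤ min(del length, right flank)` with
  `ref[start..start+k) == ref[end..end+k)` — flagging MMEJ (large class,
  homology ≥ 2 bp; observed junctions carry 2–7 bp) and polymerase
  slippage (≤ 2 bp inside a homopolymer run ≥ 3).
* **removes background per nucleotide**: Δ = rate⁺DSB − rate⁻DSB at every
  position and mutation type, and the chained treatment delta
  `(treat⁺ − treat⁻) − (ctrl⁺ − ctrl⁻)`. Metagene profiles average rates
  across loci on the cut-relative axis (−100..+100 bp); per-locus "per
  DSB" summaries sum the per-position percent rates over that window.
* **simulates the whole assay**: paired 2×150 FASTQ reads or pileup
  columns under a parameterised mutation spectrum (exponential ~20 bp
  substitution peak with a C>T-led signature, break-adjacent deletions by
  class, distant homopolymer slippage, 6–70 bp MMEJ deletions with 2–7 bp
  junction homology, insertions, translocation chimeras, uniform
  sequencing error), with a machine-readable truth table and byte-exact
  seeding.
* **tunes aligner parameters** with a seeded genetic algorithm against a
  pluggable alignment-efficiency fitness; the packaged default genome
  renders the production Bowtie2 string
  `--fr --maxins 400 ... --score-min L,-1.0,-0.5` verbatim.

## Worked example

```r
library(imutseq)
pool <- default_pool()                      # packaged synthetic 25-locus panel
sub  <- primer_pool(as.data.frame(pool)[pool$locus_id %in%
                                        c("HR01", "NHEJ01", "CTRL01"), ])

sp    <- mutation_spectrum()                # defaults = published per-DSB rates
plus  <- pileup_to_profile(simulate_pileup(sub, sp, depth = 2e5,
                                           seed = 2)$pileup, sub)
minus <- pileup_to_profile(simulate_pileup(sub, null_spectrum(),
                                           depth = 2e5, seed = 3)$pileup, sub)
d  <- delta_profiles(plus, minus)           # background-subtracted rates
mg <- metagene_profile(d, sub, "HR")
print(mg)
#> metagene: sub_total over group HR ( 1 loci, 201 positions )
#>   extreme mean rate 0.049% at +0 bp

s <- locus_summary(d, sub, annotations = deletion_annotations(plus))
s[, c("locus_id", "repair_class", "sub_total", "mmej_rate")]
#>   locus_id repair_class sub_total mmej_rate
#> 1     HR01           HR     0.958    0.0790
#> 2   NHEJ01         NHEJ     1.086    0.0725
#> 3   CTRL01        UNCUT    -0.380    0.0000
```

The substitution delta peaks exactly at the cut (+0 bp); summed over the
±100 bp window the cut loci show ~1% substitutions per DSB and MMEJ event
rates near the injected 0.068%, while the uncut control fluctuates around
zero — the per-nucleotide subtraction has removed the 0.1%/base sequencing
error entirely.

For translocations:

```r
sim  <- simulate_sample(pool, mutation_spectrum(transloc_rate = 1e-4),
                        50000, seed = 1)
scan <- scan_fastq(sim$r1, sim$r2, pool)
print(scan$matrix)
#> transloc_matrix: 25 loci, 49980 classified pairs ( 49978 cis / 2 trans )
#>   aggregate translocation rate: 4.002e-05
translocation_summary(scan$matrix, pool)$class_summary
```

A command-line entry point (`exec/imutseq`) wraps the same functions as
`simulate`, `transloc`, `call`, `tune` and `run` subcommands; `run`
orchestrates a full sample sheet (`--config run.yaml`) through
translocation filtering, calling and the delta analysis.

## Layout

* `R/` — primer-pool catalogue, simulators, read classifier, pileup
  caller, delta/metagene/summary analysis, GA tuner, pipeline orchestration
* `src/` — Rcpp pileup base-string decoder and batch primer matcher
* `inst/extdata/synthetic_pool_25loci.tsv` — synthetic 25-locus panel
* `vignettes/imutseq-methods.Rmd` — model, parameter and design notes
* `tests/testthat/` — unit, property and acceptance suites
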