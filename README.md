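# ngsam

Simulation of mutagenesis-aided sequencing (NG-SAM) of repetitive
genomic regions.

## The problem

Repeat units longer than a sequencing read make short-read assembly
ambiguous: no read captures a unit together with unique flanking
context, so the order and orientation of the units cannot be recovered.
Mutagenesis-aided sequencing breaks the symmetry chemically. The region
is amplified with an error-prone PCR so every copy accumulates random
substitutions; sufficiently mutated copies are no longer repetitive and
assemble unambiguously, and the original sequence is recovered by
aligning the reconstructed mutant copies and calling a majority-vote
consensus. The cloning-free variant simulated here isolates individual
mutant molecules purely by PCR and dilution:

1. mutagenic PCR (`n1 = 20` cycles from `S0 = 5000` molecules),
2. dilution by `d1 = 70,000`,
3. mutation-free cleanup PCR (`n2 = 20` cycles),
4. dilution by `d2 = 16×10⁶` — down to ~20 molecules ("mutant types"),
5. final PCR (`n3 = 30` cycles) and paired-end short-read sequencing of
   the pooled mutants (4,000x total coverage),
6. assembly into per-mutant contigs, orientation against the longest
   contig, multiple alignment, majority-vote consensus.

`ngsam` is a simulation pipeline for this protocol, aimed at protocol
design: which repeat structures and which dilution factors make the
experiment likely to succeed.

## What is inside

* **PCR** — branching-process molecule counts
  (`N_i = N_{i−1} + Binom(N_{i−1}, λ)`, `λ = 0.75`) and a backward
  coalescent sampler of the genealogy of the few sampled molecules,
  conditional on the counts, with branch lengths in replication events
  (`simulate_counts()`, `sample_genealogy()`).
* **Mutagenesis** — a general non-reversible (UNREST) substitution model
  built from a 12-weight mutation spectrum, with a branch-length scaling
  factor calibrated by bisection so that 10 mutagenic cycles yield a 5%
  mean mutated-site fraction (`build_unrest()`, `calibrate_scaling()`,
  `mutate_pool()`).
* **Protocol** — the PCR/dilution chain with Poisson dilution sampling,
  identity-by-descent tracking through the cleanup PCR, and final-PCR
  descendant weights (`run_protocol()`, `simulate_stage_counts()`).
* **Sequencing** — log-normal fragmentation (mean 400 bp, CV 0.055 →
  mean insert 198 bp with 101-bp reads), coverage allocation
  proportional to final-PCR descendants, a position-ramped substitution
  error model, paired FASTQ output (`fragment_and_sequence()`,
  `write_fastq()`).
* **Assembly & consensus** — a builtin de Bruijn assembler (k = 90,
  coverage cutoff, tip clipping, bubble merging only below 10%
  divergence so mutant types stay separate), contig orientation by local
  affine alignment, center-star multiple alignment, majority-vote
  consensus (`assemble()`, `orient_contigs()`, `msa()`,
  `majority_consensus()`).
* **Evaluation** — percent identity of the aligned portion, percent of
  target length recovered, their product (percent correctly
  reconstructed bases), failure-stage bookkeeping, and the two
  experiment-grid drivers (`evaluate()`, `run_experiment()`,
  `run_setting1()`, `run_setting2()`).

## Worked example

```r
library(ngsam)
set.seed(7)

model <- calibrate_scaling(build_unrest())   # beta for 5% load @ 10 cycles
model$beta
#> [1] 0.01209412

expected_stage_counts(protocol_params())[["S4"]]
#> [1] 23.51115            # expected mutant types at the operating point

target <- generate_random_target(unit_length = 500, unit_count = 4)
res <- run_experiment(target, protocol_params(), model, seed = 101)
res[, c("success", "failure_stage", "pct_identity", "pct_length",
        "pct_correct", "n_mutant_types", "n_contigs")]
#>   success failure_stage pct_identity pct_length pct_correct n_mutant_types n_contigs
#> 1    TRUE          none     99.94901      98.05          98             23        25
```

Reading: the protocol sampled 23 mutant molecules after the second
dilution; the assembler reconstructed 25 contigs from their pooled
reads; the majority-vote consensus aligned to the 2,000-bp target over
98.05% of its length with 99.95% identity in the aligned portion, so
98.0% of target bases were reconstructed correctly. (The missing bases
are the target's ends, where fragment coverage ramps down.)

A thin command-line front end is installed at `inst/cli/ngsam.R`
(`calibrate`, `run-one`, `grid-units`, `grid-dilution`).

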