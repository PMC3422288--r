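---
title: "Simulating mutagenesis-aided sequencing of repetitive regions"
author: "ngsam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mutagenesis-aided sequencing of repetitive regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Regions built from repeat units longer than a sequencing read cannot be
assembled from short reads: no read spans a unit together with unique
flanking context, so the assembly graph has multiple equally good
resolutions. Mutagenesis-aided sequencing side-steps this by amplifying
the region with an error-prone PCR so that every copy accumulates random
substitutions. Sufficiently mutated copies are no longer repetitive — each
unit of each copy is individually recognizable — so they assemble
unambiguously, and the original sequence is recovered afterwards by
aligning the reconstructed mutant copies and voting per column. The
cloning-free variant simulated here isolates individual mutant molecules
by serial dilution instead of molecular cloning: a mutagenic PCR, a
dilution, a mutation-free "cleanup" PCR, a second, much harsher dilution
down to tens of molecules, and a final PCR that turns those few molecules
into enough material for one short-read library.

`ngsam` simulates this entire experiment — molecules, mutations, reads,
assembly, consensus — and scores how well the reconstruction matches the
known target. Its purpose is protocol design: mapping which repeat
structures and which dilution factors give a high success probability
before any wet-lab work.

## Model components and their assumptions

### PCR as a branching process, genealogy by backward simulation

Each PCR cycle duplicates every molecule independently with probability
$\lambda$ (the per-cycle efficiency), so counts follow
$N_i = N_{i-1} + \mathrm{Binomial}(N_{i-1}, \lambda)$ and the expected
final count is $N_0(1+\lambda)^n$. We use $\lambda = 0.75$ for all three
PCRs, a typical empirical estimate; `pcr_params()` accepts a per-cycle
vector should cycle-dependent efficiencies ever be needed. Plateau-phase
kinetics, primer exhaustion and chimera formation are not modelled.

Simulating every molecule forward is infeasible ($5000 \cdot 1.75^{20}
\approx 3.6\times10^8$ molecules after the mutagenic PCR alone), and
unnecessary: only the molecules sampled by dilution — and their ancestry —
matter. `sample_genealogy()` therefore simulates backwards, conditional
on the count trajectory. Walking cycles in reverse, each tracked lineage
is one of the cycle's products with hypergeometric probability
$(N_i - N_{i-1})/N_i$; a product accrues one replication event on its
branch and jumps to a template drawn uniformly (without replacement
within a cycle, since a molecule duplicates at most once per cycle) from
the previous cycle's pool. Template collisions with other tracked
lineages are coalescences. Branch lengths count replication events — the
clock on which PCR mutations arise. The sampler is validated in the test
suite against a brute-force forward simulation that tracks every
parent-child link on tiny instances, comparing founder counts, lineage
depths and total replication events in distribution.

Counts beyond $2^{31}$ occur at realistic settings; above the exact
range of R's samplers the binomial, hypergeometric and Poisson draws
switch to their asymptotic (normal / with-replacement) equivalents,
whose error at those magnitudes is far below Monte-Carlo noise.

### Mutagenesis: a calibrated UNREST model

Base-analogue mutagenesis has a strongly asymmetric spectrum, so the
substitution process is the fully general non-reversible (UNREST) 4x4
rate matrix: off-diagonal rates proportional to the twelve ordered
substitution weights, diagonals closing the rows to zero, no detailed
balance imposed. The shipped `default_spectrum()` is a transition-biased
synthetic approximation (dPTP-type A->G/T->C transitions dominant,
8-oxo-dG-type G->T/C->A transversions present); the exact published
spectrum is not reproduced in text form anywhere we could transcribe it
from, so the spectrum is a configurable input and the default is labelled
an approximation.

The matrix is normalized to one expected substitution per site per unit
time at uniform composition, and a scaling factor $\beta$ converts
replication events to time: a branch of $r$ replications evolves each
site by $\exp(r\beta Q)$. Sites are independent; insertions and
deletions are not modelled. `calibrate_scaling()` fixes $\beta$ against
the reported mutation load of the protocol — on average 5% of sites
mutated after 10 mutagenic cycles. Genealogy shape does not depend on
$\beta$, so the calibration separates cleanly: root-to-leaf replication
depths are sampled once by Monte Carlo (20 genealogies x 100 sampled
molecules from a 10-cycle PCR at $\lambda=0.75$, $S_0=5000$), and the
expected mutated-site fraction
$f(\beta) = \mathbb{E}_d[1 - \sum_b w_b (e^{d\beta Q})_{bb}]$ is then a
deterministic increasing function solved by bisection to $10^{-5}$.
Calibration assumes the cleanup PCR introduces no mutations, and the
calibration template's base composition is configurable (uniform by
default) because the sequence on which the load was historically measured
is not available. The same $\beta$ extrapolated to the protocol's 20
mutagenic cycles yields a ~10% load — slightly less than double, since
doubly mutated sites are counted once.

### The protocol chain

`run_protocol()` composes the stages: mutagenic PCR counts ($S_1$),
Poisson dilution ($S_2 \sim \mathrm{Pois}(S_1/d_1)$), cleanup PCR counts
($S_3$), second dilution ($S_4$). A dilution factor of exactly 1 carries
the whole volume over deterministically (no aliquot is taken, so there
is nothing Poisson about it); any factor above 1 is Poisson sampling. A
zero after either dilution is an `empty_sample` failure — a real and intended failure mode at extreme
dilution. The $S_4$ molecules are traced backward through the cleanup PCR
(mutation-free, so only founder assignment matters) to their distinct
first-dilution ancestors; only those ancestors' mutagenic genealogy is
sampled and mutated. Two post-dilution molecules sharing an ancestor are
identical by descent and form one mutant type with multiplicity two — the
backward sampler on the cleanup PCR, rather than a uniform founder
shortcut, is what makes that relatedness correct. The genealogy sample
size is guarded by `genealogy_sample_cap` (default 200, comfortably above
the observed $S_4$ around 20-30); exceeding it is a loud configuration
error, never a silent truncation. Each molecule finally runs an
independent 30-cycle branching process whose descendant count becomes its
sequencing-coverage weight.

At the default operating point the expected chain gives
$S_4 = 5000 \cdot 1.75^{40}/(70000 \cdot 16\times10^6) \approx 23.5$
mutant types; the realized distribution (mean in the low twenties, SD
near 5) is one of the quantities the acceptance script recomputes.

### Sequencing

Fragments are drawn per mutant with log-normal lengths. The published
parameters are an arithmetic mean of 400 bp and a coefficient of
variation of 0.055; we read the CV on the natural scale (the scale on
which a fragment-size distribution is normally quoted) and derive the
log-scale parameters as $\sigma^2 = \ln(1+\mathrm{cv}^2)$,
$\mu = \ln(\mathrm{mean}) - \sigma^2/2$, so the realized mean and CV
match exactly. With 101-bp paired reads the implied mean insert is
$400 - 2\cdot101 = 198$ bp. Fragments shorter than a read (or longer
than the molecule) are redrawn; adapter read-through is not simulated.
Starts are uniform, strands symmetric; read 2 is the reverse complement
of the fragment's 3' end.

Total coverage is 4000x of the target, split across mutant types
proportionally to their final-PCR descendant counts (so amplification
jitter propagates into coverage imbalance), which gives roughly 200x per
type at the operating point. A trained platform intensity model is
deliberately out of scope; the error model is a configurable per-base
substitution rate, by default ramping linearly from 0.1% at the first
position to 1% at the last, with FASTQ qualities encoding the true
position-wise error probability. This preserves the error load that
stresses assembly without pretending platform realism.

### Assembly and consensus

The builtin assembler is a compact de Bruijn implementation chosen so
that whole experiments run hermetically with no external binaries:
(k+1)-mer counting on both strands, a coverage cutoff at 10% of the
count-weighted median k-mer multiplicity (at least 1) to remove error
k-mers, unitig condensation, clipping of dead-end tips shorter than 2k,
and bubble merging restricted to parallel paths diverged at most
`max_divergence` (default 0.1). That restriction is the scientifically
load-bearing parameter: mutant types differ by about twice the 10%
mutation load and must not be collapsed, while error-induced bubbles
within a type are. The k-mer length default is 90 — long k-mers buy the
specificity needed to keep ~20 mutated copies of the same template apart,
at the cost of coverage — and contigs shorter than 400 bp are dropped. A
Velvet adapter (same role, the historical tool's flags) is provided for
systems where the binary exists; the builtin backend is the default and
the one all tests exercise, and its coverage estimate is its own, not a
re-implementation of any particular assembler's.

Contigs are oriented against the longest contig by local affine
alignment (match +5, mismatch -4, gap open 10, extend 4) in both
orientations. The acceptance threshold is the score of a 50-bp perfect
match (250): no published threshold exists, only the failure mode, and
random 600-bp sequence scores far below this while any genuine mutant
copy scores far above. A contig failing both orientations fails the
whole experiment (`strandedness` stage) rather than being dropped — an
unorientable contig means the reconstruction cannot be trusted.

The multiple alignment is a center-star progressive alignment seeded on
the longest contig with free-end-gap pairwise alignments, merged under
"once a gap, always a gap"; for rows that are all ~10%-mutated copies of
one template this is effectively as good as a full MSA and has no
external dependency (a MAFFT adapter exists for cross-checks). The
consensus is a per-column majority vote over {A, C, G, T, gap}; columns
won by the gap are removed, and ties break deterministically in the
fixed order A < C < G < T < gap, with tied columns reported for logging.
More sophisticated probabilistic consensus callers are intentionally out
of scope.

### Evaluation

`evaluate()` aligns the consensus locally to the target in both
orientations with the same scoring. The reconstruction is unambiguous
when the best score reaches the acceptance threshold and beats the
opposite orientation by a ratio of at least 1.1 (no published margin
exists; the value is configurable and logged). Reported metrics:
percent identity of the aligned portion, percent of target length
covered, and their product — the percentage of correctly reconstructed
bases. Tracking mutations in tandem targets are not used by assembly or
consensus; they exist so unit order and orientation can be audited.

## Experiment grids and seeds

`run_setting1()` maps reconstruction success over unit length x unit
count (defaults: lengths 4, 9, ..., 3999; counts 4, 8, ..., 100; cells
kept when the total is at most 30 kb; five replicates per cell, each
replicate re-randomizing the target and all downstream stages).
`run_setting2()` fixes a tandem target — by default three copies of a
random 3,813-bp unit, the size of a well-known tandem gene duplication,
with one tracking mutation per copy — and varies the two dilution
factors. Every experiment derives all stage seeds from one master seed
via a documented splitting scheme (seed the generator, draw the stage
seeds, reseed per stage), so any row of a result table is reproducible
in isolation. Failures are recorded per row and never abort a grid.

## Problem sizes used in tests and the acceptance script

The published grids span hundreds of cells with targets up to 30 kb;
mapping them is a cluster-scale exercise, not something a package check
should attempt. The shipped checks therefore run the same code at
reduced sizes chosen to keep the whole suite in the minutes range while
leaving Monte-Carlo error well inside the tolerances tested: 500
counts-only protocol runs for the mutant-type distribution; 25
genealogies x 5 molecules on 1-kb templates for the mutation load at 10
and 20 cycles; and five full end-to-end replicates on a 4 x 500 bp
target at the full 4000x coverage for the reconstruction-identity check.
The end-to-end target (2 kb) sits inside the published "safe" region
(four units of 1,000-4,000 bp), so the expected behaviour is success
with aligned identity above 99%.

What passing these checks does not show: performance on real genomic
repeats (non-random base composition, near-identical rather than
identical units, context-dependent mutagenesis), platform-realistic
error structure, or the exact behaviour of the historical Velvet /
exonerate / muscle toolchain, all of which are outside the simulation's
scope.

## Known limitations

* Substitution-only mutagenesis; indels from error-prone PCR are ignored.
* The default spectrum is a labelled approximation, not a measured one.
* The builtin assembler treats pairs as single-end reads; mate-aware
  repeat resolution is deliberately absent (the consensus procedure
  operates on contigs).
* Dilution is ideal Poisson sampling; pipetting biases and carry-over
  chemistry are not modelled.
* `evaluate()` compares against alternative orientations, not against
  alternative alignment locations within the target.
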