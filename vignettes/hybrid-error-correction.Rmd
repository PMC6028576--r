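---
title: "Hybrid error correction of noisy long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid error correction of noisy long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridEC)
```

## The problem

Single-molecule long reads (PacBio, Nanopore) span multiple kilobases but
carry 10--35% sequencing error, dominated by insertions and deletions.
Short Illumina reads are far more accurate (per-base error well below 1%)
and come with informative per-base PHRED qualities, but are too short to
resolve repeats on their own. Hybrid error correction uses alignments of
the accurate short reads to polish the long reads before downstream steps
such as *de novo* assembly. All reads are assumed to come from the same or
highly similar individuals.

hybridEC corrects each long read in place, using the long read itself as
the coordinate frame. The algorithm has three layers: a consensus *quick
correction*, an *optimization-based correction* for the remaining sites,
and an optional *iterative learning* loop around both.

## Questionable sites and the evidence pileup

Short-read alignments (from any SAM-producing aligner, or the built-in
one) are walked base by base. A long-read position where at least one
primary alignment disagrees — a mismatch, an extra short-read base
(proposing an insertion into the long read), or a missing short-read base
(proposing a deletion) — is marked *questionable*. Agreeing reads at such
positions are recorded too, so every consensus fraction is relative to the
full covering depth, not just to the disputants.

Edit semantics generalise base replacement to the three kinds of
disagreement the pileup can see: `SUB` (replace the base), `DEL` (drop
it), `INS` (insert bases at an inter-base locus). A deletion has no base
of its own, so its vote quality is the floored mean PHRED of the two
flanking short-read bases; an insertion vote takes the floored mean of the
inserted bases. `N` never matches anything and never votes. Secondary
(0x100) and supplementary (0x800) alignments are excluded so each short
read votes at most once per site, and soft-clipped bases contribute no
evidence. Coordinates are 0-based half-open everywhere inside the package;
conversion happens only at the SAM/FASTQ boundary.

Sites covered by fewer than `min_coverage` reads (default 2) are left
untouched: a single read trivially agrees with itself, and guarding
against single-read edits costs little at realistic coverage.

## Quick correction

If at least a fraction $\eta$ (default 0.9) of the reads covering a
questionable site support the *same* edit, that edit is applied outright.
Demanding 90% rather than a simple majority prevents spurious corrections
driven by high-frequency, low-quality reads. Symmetrically, when at least
$\eta$ of the covering reads agree with the long read as it stands, the
site is resolved as "keep" and skips the optimization step entirely —
this is what makes the quick step shrink the optimization search space:
at 50x coverage with 1% short-read error, roughly a quarter of covered
positions acquire at least one disagreeing read, and almost all of them
are resolved here without an edit.

## Optimization-based correction

For each remaining questionable site with $N$ aligned short reads, every
read $k$ gets two weights: a quality weight
$\hat{\omega}_q^k = \omega_q^k / \max_{1 \le k \le N} \omega_q^k$, where
$\omega_q^k$ is the PHRED quality of the read's base at the site (the
per-base value, the finest signal the FASTQ offers), and a similarity
weight $\hat{\omega}_s^k$, the read's alignment identity: exact matches
divided by the short-read length. The cost of read $k$ is the equal-weight
convex combination

$$J_k = \tfrac{1}{2}\left(\hat{\omega}_q^k + \hat{\omega}_s^k\right),$$

and the winner is $k^* = \arg\max_k J_k$. Quality and identity are not
contending objectives — a high-quality read is not systematically less
similar — which is why a convex combination is used rather than a
multi-objective search. Ties on $J$ go to the read with the highest raw
quality; residual ties go to the lexicographically smallest read
identifier, so every run is fully deterministic.

The candidate set is *all* $N$ aligned reads, agreeing ones included. An
agreeing winner resolves the site without an edit. This detail carries
the method's robustness: at a site where one low-quality (error-typical,
around Q15) read disputes several high-quality (around Q35) agreeing
reads, the agreeing reads win the argmax and the long read is kept as-is.
Restricting candidates to disagreeing reads would instead let the lone
disputant rewrite a correct base at every such site; in our simulations
at the default conditions that variant *lowers* mean truth identity from
86% to 78% in a single pass, while the all-reads rule raises it to above
99%. Note that if all covering reads propose the same edit (perfect
consensus), quick correction and the argmax provably pick the same edit,
and with $\eta$ close to 1 the two steps agree with high probability;
this is tested property-style.

If every quality at a site is zero, all quality weights are defined as 0
and the cost decides on identity alone, keeping $J$ well defined.

## Iterative learning

One pass of the core algorithm applies every decision. The iterative mode
is more conservative: per iteration $\ell$, let $\mu^{(\ell)}$ be the
$\alpha$-percentile (default $\alpha = 95$, nearest-rank convention: the
value at rank $\lceil \alpha N / 100 \rceil$ of the ascending sort) of
the iteration's optimal costs $J_{k^*}$. Only quick corrections and
optimized corrections with $J_{k^*} \ge \mu^{(\ell)}$ are applied; the
rest are deferred. Applied sites are *locked*: they are never re-decided
and never reverted, which is the designed fix for the reversion behaviour
of greedy iterate-and-revert correctors. Quick corrections carry no
optimal cost and are always applied and locked — 90% consensus is itself
high confidence.

The short reads are then realigned against the updated long reads (fresh
alignments, prior ones discarded, because corrected context can change
which reads align where), and the loop repeats. Locked coordinates are
carried through the coordinate shifts that applied insertions and
deletions cause, via a per-read offset map rebuilt after each application
pass; each lock also remembers the base content it protects, which lets
the test suite verify no-reversion directly.

Termination uses the unique-k-mer count of the corrected long reads
(distinct length-$k$ substrings, default $k = 21$; errors inflate this
count, so fewer is better). The loop stops after iteration $\ell$ when
the relative improvement
$(\mathrm{uk}^{(\ell-1)} - \mathrm{uk}^{(\ell)}) / \mathrm{uk}^{(\ell-1)}$
falls strictly below $\varepsilon$ (default 0.02), or when the iteration
cap $n$ (default 5) is reached. An improvement of exactly $\varepsilon$
continues. If the count ever *rises*, the loop stops with a warning and
emits the previous iteration's reads — improvement is expected but not
guaranteed, so the guard is conservative.

High confidence is taken as $J^* \ge \mu$ (inclusive); with the
nearest-rank percentile this applies slightly more than $(100-\alpha)\%$
of optimized decisions, e.g. 5.1% at $\alpha = 95$ on 1000 costs.

## The built-in aligner

Realignment needs an aligner on every iteration. An external command
template (e.g. a bwa-mem pipeline writing SAM) can be plugged in and is
preferable at genome scale; for self-contained operation the package
ships a seed-and-extend aligner: exact 13-mer seeds sampled every 6 bp
from the short read (both strands) vote for a (long read, strand,
diagonal) candidate; seeds occurring more than 20 times across the long
reads are treated as repetitive and ignored; the best candidate's window
is then aligned end-to-end with a banded dynamic program (band 32 around
the seeded diagonal; match +1, mismatch −2, gap −2, free overhangs on the
window side). Alignments under 60% identity are discarded. It emits one
primary alignment per short read. The band covers the indel drift a 100
bp read accumulates against a 15%-error target with margin; reads whose
true diagonal drifts beyond it lose identity and are dropped rather than
mis-placed.

## The synthetic-data generator

`simulate_hybrid_data()` emulates the data regime the method targets: a
uniform-random reference (default 50 kb), long reads sampled from it
(default ~20 reads of 5--10 kb) with errors injected independently per
base at 15% — within the error range reported for PacBio chemistry — and
split evenly between substitutions, insertions and deletions; and short
reads (default 100 bp at 50x) with 1% substitution error. Qualities are
informative by construction: correct bases draw from a clamped normal
around Q35 (sd 3), erroneous bases around Q15 (sd 4), clamped to [2, 41],
mirroring the premise that base quality separates signal from error.
Truth alignments of the short reads against the *erroneous* long reads
are produced by lifting reference coordinates through each long read's
recorded edit script — no aligner involved — so tests of the correction
core are decoupled from aligner behaviour. Every injected error is
recorded with its position on the erroneous read, which is what makes
reversion rates measurable.

What the simulator does *not* model: context-dependent error profiles
(e.g. homopolymer-length errors typical of real PacBio/Nanopore data),
short-read indel errors, paired-end structure, coverage biases (GC,
mappability), repeats beyond what a uniform random sequence contains, and
heterozygosity. Passing tests therefore demonstrate the machinery is
correct under clean uniform-error conditions, not that real-data accuracy
will match these numbers; on repetitive or heterozygous genomes the
consensus and locking behaviour can differ materially.

Default problem sizes are chosen so the full suite runs in minutes on a
single CPU: the reference fixture is 50 kb with ~150 kb of long-read
bases and ~25,000 short reads; unit tests use an 8 kb variant.

## Numerical and degenerate-case choices

* Percentile convention: nearest-rank on the ascending sort — integer
  exact and trivially oracle-testable.
* All-zero qualities at a site: quality weights defined as 0.
* Empty optimal-cost pool in an iteration (everything quick-corrected):
  $\mu$ is undefined/NA and only quick corrections are applied.
* A zero unique-k-mer baseline stops the loop rather than dividing by
  zero.
* Overlapping edits cannot collide: each locus yields at most one
  decision, and edits are applied in an order (base edits before
  insertions at the same locus, positions processed independently) that
  keeps every original coordinate valid.
* PHRED encoding is fixed to Phred+33; no autodetection.
* k-mers are counted without reverse-complement canonicalization by
  default, since long and short reads are compared in the orientation
  given; a `canonical` flag folds strands when wanted.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_hybrid_data(sim_config(reference_length = 8000,
                                       n_long = 6,
                                       long_length = c(1500, 2500),
                                       coverage = 30, seed = 7))
truth_metrics(sim$long_reads, sim$truth_map, sim$reference)$mean_pi
#> [1] 86.30761

run <- correct_long_reads(sim$long_reads, sim$short_reads,
                          alignments = sim$alignments, iterative = TRUE)
summary(run)
truth_metrics(run$reads, sim$truth_map, sim$reference)$mean_pi
#> [1] 99.94676
```

## Known limitations

* The built-in aligner reports a single best location per short read; in
  regions where several long reads overlap the same reference interval,
  realignment spreads evidence across them and per-read depth drops
  accordingly (initial truth alignments place each read on every
  containing long read).
* Indel normalisation (left-alignment) is not performed, so equivalent
  indel placements in homopolymers may split votes between adjacent loci.
* Counting k-mers with plain string sets is exact but memory-bound;
  genome-scale counting would need a disk-backed or probabilistic
  counter, which is out of scope.
* Short reads are assumed pre-trimmed; untrimmed adapters depress
  alignment identity and with it the similarity weight.
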