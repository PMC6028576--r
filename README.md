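# hybridEC

Hybrid error correction of noisy long sequencing reads in R.

Single-molecule long reads (PacBio/Nanopore) carry 10–35% sequencing
error; short Illumina reads are highly accurate and carry per-base PHRED
qualities. hybridEC polishes long reads using alignments of short reads to
them, for workflows (assembly polishing, isoform analysis, small-genome
work) where reads and a short-read library from the same or highly similar
individuals are available.

## Method

Positions on a long read where at least one aligned short read disagrees
(mismatch, insertion or deletion) are *questionable*. They are resolved in
two steps:

1. **Quick correction.** If a fraction ≥ η (default 0.9) of the covering
   reads support the same edit, apply it outright; if ≥ η agree with the
   long read as-is, keep it and skip the next step.
2. **Optimization-based correction.** For the N short reads aligned to the
   site, compute a normalised quality weight
   ω̂\_q^k = ω\_q^k / max\_k ω\_q^k (per-base PHRED) and a similarity
   weight ω̂\_s^k (alignment identity: exact matches / short-read length),
   score each read with the convex combination

       J_k = (ω̂_q^k + ω̂_s^k) / 2,

   and apply the edit of the argmax read k\* (ties: highest raw quality,
   then smallest read id). An agreeing winner keeps the base unchanged.

An optional **iterative learning** loop applies, per iteration, only quick
corrections plus optimized corrections whose optimal cost J\* reaches the
α-percentile (default 95) of the iteration's costs, *locks* them so they
are never re-decided or reverted, realigns the short reads against the
updated long reads, and repeats until the relative improvement in unique
k-mers (k = 21) drops below ε (default 0.02) or n = 5 iterations are
reached.

The package also ships a self-contained simulator (reference, noisy long
reads with a recorded truth edit script, short reads with informative
qualities, truth alignments in SAM), k-mer and truth-based evaluation
metrics, a built-in seed-and-extend banded aligner for realignment, and a
small CLI (`exec/hybridec`) with `correct`, `simulate` and `evaluate`
subcommands. External aligners are pluggable as command templates.

## Worked example

```r
library(hybridEC)

sim <- simulate_hybrid_data(sim_config(reference_length = 8000, n_long = 6,
                                       long_length = c(1500, 2500),
                                       coverage = 30, seed = 7))
truth_metrics(sim$long_reads, sim$truth_map, sim$reference)$mean_pi
#> [1] 86.30761

run <- correct_long_reads(sim$long_reads, sim$short_reads,
                          alignments = sim$alignments, iterative = TRUE,
                          verbose = TRUE)
#> iteration 1: mu=0.7183 quick=1751 optimized=131 deferred=2434 uk=6288 CONTINUE
#> iteration 2: mu=0.985 quick=0 optimized=72 deferred=1325 uk=6288 STOP_EPSILON

truth_metrics(run$reads, sim$truth_map, sim$reference)$mean_pi
#> [1] 99.94676
```

The six simulated long reads start at 86.3% mean identity against their
true source intervals (15% injected error). Iteration 1 applies 1751
strong-consensus corrections and the 131 highest-cost optimized
corrections and locks them; iteration 2 finds the remaining improvement in
unique 21-mers below 2% and stops. The corrected reads reach 99.9% mean
truth identity. `summary(run)` prints the per-iteration table;
`run$locked` lists the locked coordinates.

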