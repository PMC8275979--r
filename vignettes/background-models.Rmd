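---
title: "Background models, matching criteria and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background models, matching criteria and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nullseqgen)
```

# The problem

Motif enrichment analysis asks whether a transcription-factor motif occurs
in a foreground sequence set more often than expected under a null model.
The null model is embodied by background sequences, and because genomes
carry strong local composition biases — GC content above all — a background
whose composition differs from the foreground's yields spurious enrichment
of GC- or AT-rich motifs. This package constructs backgrounds that match
the foreground's composition, either synthetically (by rearranging the
foreground itself) or genomically (by selecting real sequences from a
pool).

# The four models

## Global k-let shuffle (model `k`)

`kletShuffle()` rearranges a sequence while conserving the exact multiset
of its k-lets (length-k substrings). For k = 1 this is a uniform
permutation. For k ≥ 2 it is an Eulerian walk on the de Bruijn multigraph:
vertices are the (k−1)-lets, each k-let of the input is an edge, and any
Eulerian path from the first (k−1)-let to the last spells a valid
rearrangement. A walk that consumes edges in random order dead-ends, so
the construction first samples a random arborescence oriented toward the
terminal vertex — with Wilson's loop-erased-random-walk algorithm, which
draws the arborescence uniformly when walk successors are drawn uniformly
over the out-edge multiset — and places each vertex's tree edge last in
its exit order. The walk is then guaranteed to finish having used every
edge.

Consequences worth knowing:

* all j-let counts for j ≤ k are conserved *exactly*, not in expectation;
* the first and last (k−1)-lets of the output equal the input's (they are
  the path endpoints) — for highly constrained inputs the only valid
  rearrangement may be the input itself (`AAAA` at k = 2 stays `AAAA`);
* uniformity over the valid rearrangement set is an empirical quality
  goal verified by sampling tests against brute-force enumeration, not a
  hard contract of the implementation;
* a k no smaller than the sequence length returns the sequence unchanged.

IUPAC ambiguity codes are ordinary symbols here: an `N` is conserved as an
`N` in exactly the k-contexts it occupies. Nothing is expanded or resolved.

## Windowed k-let shuffle (model `w`)

`windowShuffle()` conserves *local* composition: windows of width W
(default 100 bp) starting every S bp (default 50 bp, i.e. 50% overlap) are
k-let-shuffled in place, left to right, each later window seeing the
partially shuffled sequence. The defaults follow the convention of
sliding-window composition analysis: 100 bp is near nucleosomal scale and
short enough to track isochore-like GC variation, and the half-window step
smooths window-boundary artifacts.

With overlapping windows, two readings of "shuffle within a sliding
window" exist: shuffle disjoint copies and concatenate, or re-shuffle
overlaps in place. The in-place reading was chosen as the simplest
composition consistent with an overlapping default; it means exact k-let
conservation holds per window only for the last window touching a region.
Global mononucleotide counts are conserved exactly for every k, W, S
(each window operation is a rearrangement of its window). Residues after
the last full window are shuffled as a shrunken tail window so no residue
escapes; a tail shorter than k stays as-is (no k-let of order k fits).

## Genomic GC-bin matching (model `g`)

`buildGCIndex()` assigns each pool sequence to the integer bin
`floor(100 · gc)`, with gc = 1 in bin 100 — 101 bins in steps of 1% GC.
`matchGCBin()` draws a uniformly random member of the foreground's bin.
Two policies are deliberate:

* **Empty-bin fallback.** When the exact bin is empty, the search expands
  ring-wise (distance 1, 2, ...), pooling the bins at −d and +d before
  sampling so neither side is favored, and the result records the
  distance used. Failing would make the tool brittle on small pools; the
  reported `bin_distance` keeps the relaxation auditable.
* **Replacement.** Sampling is with replacement by default: precomputed
  pools at one bin size can be smaller than a foreground set.
  `withReplacement = FALSE` removes each chosen record; exhaustion then
  surfaces as fallback distances or as `accepted = FALSE`.

## Windowed genomic matching (model `c`)

`matchWindowed()` computes the foreground's sliding-window %GC profile
(same W and S defaults) and accepts a pool candidate when **every** window
of the candidate's profile lies within the foreground band
mean ± m·sd, with m = 2.6 by default. The band criterion admits several
readings (candidate mean in band; band overlap; full containment). Full
containment was chosen because it is parameter-free beyond m, is monotone
in m (useful for testing and for users widening the band), and reduces
sensibly in the degenerate limit: a foreground with homogeneous %GC
(sd = 0) accepts exactly the candidates whose every window equals its
mean. The model does not additionally require global GC-bin equality —
window containment already constrains the candidate's mean.

The multiplier m is in units of foreground-profile standard deviations.
The sd is the *population* (divide-by-n) standard deviation: the window
values are the complete profile of the sequence, not a sample from a
larger population, and the acceptance band depends directly on this
choice, so it is fixed and documented rather than configurable.

# Composition conventions

* **%GC policy.** G, C and the IUPAC strong code S count toward GC; the
  denominator is the full length. Other ambiguity codes (R, Y, K, M, N,
  ...) contribute zero — a conservative, unambiguous rule that reduces to
  the standard definition on ACGT-only sequences. On heavily masked
  genomes this biases %GC of N-rich records downward; the partitioner's
  N-fraction filter is the guard.
* **GC bin arithmetic.** Bins are computed as `(100 · gcCount) %/% length`
  in integer arithmetic, so the floor rule has no floating-point edge
  cases (e.g. a true 51% never lands in bin 50 via a 50.999... double).
* **K-mer counting.** Counts are literal over the extended alphabet; the
  total is L − k + 1 (0 when k > L). Sub-k-mer marginals follow up to the
  one edge term at the sequence end.
* **Window layout.** 0-based half-open windows at offsets 0, S, 2S, ...
  with offset + W ≤ L; trailing partial windows are not emitted, keeping
  per-window %GC values on a common denominator. A sequence shorter than W
  is profiled as a single whole-sequence window.

# The genome partitioner

`partitionGenome()` tiles each contig into non-overlapping `binSize`-bp
bins (step = bin size — a background pool should not contain
near-duplicates), discards bins whose N fraction exceeds 0.1 by default
(assembly gaps would otherwise flood the low-GC bins), and by default
drops each contig's short remainder. Identifiers are `contig:start-end`
in 0-based half-open coordinates, matching the optional BED3 sidecar.
Only the forward strand is emitted: %GC is strand-symmetric, so reverse
complements add no matching power. With the filters disabled
(`maxNFraction = 1`, `dropRemainder = FALSE`) the bins of a contig
concatenate back to the contig exactly — the reconstruction property the
tests assert.

# Quality control

Four comparisons are computed: per-sequence %GC density over the 101 1%
bins (one observation per sequence, so short and long sequences weigh
equally — the pooled-residue alternative would let long sequences
dominate), pooled overlapping dinucleotide content over the IUPAC and the
ACGT alphabets (never counting across record boundaries; in ACGT mode
ambiguity-containing dinucleotides are excluded before normalization), and
a sequence-length histogram with half-open 10-bp bins (10 bp resolves the
100/250/500/750/1000 pool sizes without fragmenting typical peak-length
distributions).

Each comparison is scored with the mean absolute error on the normalized
frequencies and with three goodness-of-fit statistics on counts, the
background rescaled to the foreground total (the divergences require
matched totals): Pearson's χ², the G statistic 2·ΣO·ln(O/E) (0·ln 0 taken
as 0), and the Cressie–Read power divergence at λ = 2/3, the exponent
recommended in the Cressie–Read framework as a compromise between the χ²
(λ = 1) and G (λ → 0) ends of the family; λ is exposed as a parameter.
Statistics are reported raw, without p-values: after sparse-cell pooling
the degrees of freedom are ill-defined, and these are QC metrics, not
hypothesis tests.

Cells where both counts are zero are dropped. A cell with expected 0 but
observed > 0 makes the divergences undefined; by default the report sets
the statistics to NA and flags the offending labels rather than silently
pooling, and `poolSparse = TRUE` (CLI `--pool-sparse`) merges cells with
expected count below 5 into one pooled cell first. The MAE is always
defined. Plot data are emitted as one TSV per comparison so the metrics
are testable headlessly; rendering is left to the user.

# Numerical and degenerate-input choices

* The windowed acceptance band is evaluated with a 1e-9 absolute epsilon
  on both edges, so the sd = 0 band still accepts candidates whose window
  values equal the mean through an identical float computation.
* Ring-search ties (bins −d and +d both occupied) are pooled before
  sampling, weighting each candidate record equally rather than each bin.
* `matchGCBin` failure is a value (`accepted = FALSE`), not an error; the
  batch driver reports unmatched identifiers separately.
* Every random operation accepts a seed; batch drivers derive a per-record
  sub-seed from it (a fixed linear-congruential mix of seed and record
  position, kept below 2^31), so each record's output does not depend on
  how many replicates its predecessors produced. RNG state is
  saved and restored around seeded calls, so library calls never perturb
  user-level randomness. When the CLI receives no seed, one is drawn from
  entropy and logged, keeping every run reproducible after the fact.

# The synthetic data generators

`simulateForeground()` draws i.i.d. residues with a controllable GC
probability: constant (`gcTarget`, default 0.41, a typical mammalian
genome-wide level), per-sequence uniform (`gcRange`, spreading a set
across GC bins), or linearly ramped along each sequence (`gcGradient`,
creating the within-sequence heterogeneity the windowed models are for).
`simulateGenome()` concatenates 1-kb blocks of block-constant GC
(isochore-like patterning) and overwrites random stretches with N
(assembly gaps) to exercise the partitioner's filter.

These generators emulate composition structure only. Real regulatory
sequences additionally carry repeats, CpG depletion, motif clustering and
phylogenetic correlation, none of which i.i.d. sampling reproduces — so
the passing test suite demonstrates that the models' *composition
contracts* hold (exact k-mer conservation, exact bin agreement, band
containment, partition arithmetic), not that any particular biological
enrichment analysis is well calibrated. The exact-conservation guarantees,
however, are input-independent: they hold for any sequence by
construction, which is why property tests on synthetic data are
informative here.

# Problem sizes used by the test suite

The suite verifies shuffle conservation on 1,000 random sequences
(lengths 10–500, alphabets of 2–15 IUPAC letters) for k = 1..5; shuffle
support against brute-force enumeration on sequences of length ≤ 9 plus
5,000 draws from a fixed reference sequence; windowed shuffling on a
200-case random (k, W, S) grid; GC-bin matching on 5,000 foregrounds
against a ~10,000-record pool saturating all 101 bins; band monotonicity
on 100 foreground/pool pairs; the Cressie–Read identities on 1,000 random
count vectors; partition arithmetic on 100 contig/bin-size combinations
including the five published pool sizes; and byte-identical same-seed
reruns of every CLI subcommand.

# Known limitations

* Uniformity of the k = 1 and k ≥ 2 shuffles is exact in construction but
  only sampling-verified in tests; no formal proof accompanies the
  implementation.
* The windowed matcher scans the whole pool per foreground (no GC
  pre-index); for very large pools model `g` is the fast path.
* Genomic matching is mononucleotide-only by design: selecting genomic
  sequences matched on dinucleotides would drastically shrink candidate
  sets and is out of scope.
* The %GC policy ignores partial GC information in R/Y/K/M/N codes; on
  heavily masked pools consider tightening the partitioner's
  `maxNFraction` instead.
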