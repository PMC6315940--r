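---
title: "Finding boundaries of structured RNA domains: methods and design"
author: "rnabound authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding boundaries of structured RNA domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnabound)
```

## The problem

De novo gene finders for structured non-coding RNAs, and window-based
screens of RNA--protein binding data, report *windows* that contain a
structured element — not the element's boundaries. Downstream work
(covariance-model building, structure clustering, motif comparison) needs
those boundaries precisely. This package takes the base-pairing
probability matrix of a window — from a McCaskill-style partition function
on a single sequence, or from consensus folding of a multiple sequence
alignment, where covariation sharpens the signal — and locates the
*self-contained* structured segment inside it: the segment whose internal
base pairs have no partners outside it, and which no pairs span within a
margin of `f` nucleotides.

## The segment fitness

For a window of length $n$ with pairing probabilities $p_{mn}$, every
candidate segment $[k, l]$ with $1 + f \le k < l \le n - f$ is scored by
the product of three geometric means:

$$F_{kl} = I_{bp} \times O_{\neg bp} \times S_{\neg bp}
  = \left[\prod_{m=k}^{l} \sum_{n=k}^{l} p_{mn}\right]^{\frac{1}{l-k+1}}
    \times \left[\prod_{m=k}^{l} \Big(1 - \sum_{n \notin [k,l]} p_{mn}\Big)\right]^{\frac{1}{l-k+1}}
    \times \left[\prod_{m=k-f}^{k-1} \Big(1 - \sum_{n=l+1}^{l+f} p_{mn}\Big)\right]^{\frac{1}{f}}$$

$I_{bp}$ rewards pairing mass *inside* the segment, $O_{\neg bp}$ rewards
the absence of pairs *crossing* its boundaries, and $S_{\neg bp}$ rewards
the absence of pairs *spanning* it between the two flanking margins.
Geometric means are used for length normalisation because pair
probabilities are exponentially distributed: an arithmetic mean would be
dominated by a few near-certain pairs. The predicted boundary is the
exhaustive argmax $[u, v] = \arg\max_{k,l} F_{kl}$.

Before scoring, probabilities are replaced by log-odds **base-pair
scores** against a null model of random pairing:

$$s(p) = \max\!\left(0,\; \frac{\log(p / p_0)}{\log(1 / p_0)}\right)$$

so that $s(p_0) = 0$, $s(1) = 1$ and $s(\sqrt{p_0}) = 1/2$. Pairs at or
below the null probability contribute nothing; the transform also
compresses the influence of individual high-probability pairs.

### Numerical realisation

All three components are computed in log space
(`rnaboundFitness()`), summing logarithms instead of multiplying
probabilities, with an explicit $-\infty$ sentinel and **no epsilon
smoothing** — smoothing would silently reorder segments near the
boundary of admissibility. A segment is disqualified ($-\infty$) when
any in-segment position has zero in-segment mass, or when crossing or
spanning score mass reaches 1 at any position.

Two choices here were genuinely open:

* **Scope of the score transform.** The fitness is defined on
  probabilities, and the crossing/spanning terms are written as
  $1 - \sum p$; after substituting scores, a row's score sum may exceed 1
  (scores are not probabilities). We substitute scores in *all three*
  terms for internal consistency, clamping $(1 - \sum s)$ at zero — a
  segment with overwhelming boundary-crossing score mass is simply
  disqualified. Because the alternative reading (transform inside only,
  raw probabilities in the $1 - \sum$ terms) is also defensible, it is
  exposed as `transform = "inside-only"` in `findBoundaries()` — one
  switch, so both variants stay testable.
* **Capping the inside term.** For the same reason, the per-position
  in-segment sum $\sum_{n\in[k,l]} s_{mn}$ is capped at 1 inside
  $I_{bp}$. This keeps each component in $[0, 1]$ and the log-fitness
  bounded above by 0, with equality exactly for a perfectly
  self-contained segment — the bound the test suite asserts. Without the
  cap a crowded row could push the "geometric mean of probabilities"
  above 1, which has no probabilistic reading.

Ties in the argmax are broken deterministically to the smallest start,
then the smallest end; the choice is arbitrary but fixed and documented.

The production scanner maintains per-row cumulative sums, so the full
scan is $O(n^3)$ worst case (in practice far less, because segments
containing a mass-free position short-circuit). The naive evaluator that
walks the defining index sets is kept alive as the oracle in the test
suite, which requires exact agreement of $(u, v, \text{score})$ between
the two routes on random windows.

## The comparator fitness

For method comparison the package also implements the weighted
inside-minus-crossing fitness of Dotu and colleagues:

$$f_{ij} = \frac{\sum_{i \le x < y \le j} w_1\, p_{xy}
  - \sum_{x \in [i,j]} \sum_{y \notin [i,j]} w_2\, p_{xy}}{j - i + 1}$$

with the recommended weights $w_1 = 2$, $w_2 = 1$ (tuned on microRNA-like
single hairpins). Two deliberate readings: the comparator consumes **raw
probabilities**, not transformed scores — it is a distinct fitness, not a
re-weighting of the same kernel — and the denominator is taken as the
segment length $j - i + 1$ (the printed form of the formula in
circulation contains an obvious index typo). Its scan uses 2-D prefix
sums, $O(n^2)$ overall.

The comparator has a known failure mode on H/ACA-box snoRNAs, which are
two adjacent hairpins: covering both hairpins roughly doubles both the
pair mass and the length, so a single hairpin can win on density. The
three-component fitness has no such length trade-off — its crossing term
actively penalises cutting between the hairpins — and the test suite
asserts (on synthetic double-hairpin cases only, and only for the
log-space fitness) that the prediction covers both planted stems.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p0` | 0.0005 | null-model pairing probability; pairs at or below it score 0 |
| `f`  | 10 nt  | flanking margin checked for spanning pairs |
| `w1` | 2      | comparator weight on in-segment pair mass |
| `w2` | 1      | comparator weight on crossing pair mass |
| `min_gap` | 1 nt | minimum separation between sub-optimal segments (strict non-overlap) |

`p0 = 0.0005` and `f = 10` are the benchmark settings of the method's
original evaluation; no single $(p_0, f)$ combination is best for every
structure class (high $p_0$ favours clean single hairpins, low $p_0$
keeps the weak pairs that hold branched structures together), which is
why both are exposed rather than hard-coded. Raising `p0` can only
remove entries from the score table — a monotonicity the tests assert.

## Sub-optimal segments

Windows can contain clusters of structures (tRNA arrays, miRNA
clusters). `suboptimalSegments()` extracts non-overlapping segments
greedily: highest score first, then repeatedly the best segment that
does not conflict with any already selected, stopping at $-\infty$
(log fitness) or at non-positive scores (comparator). `min_gap = 1`
means strict non-overlap with adjacency allowed; the greedy rule is the
natural reading of "filter non-overlapping regions with highest
fitness", and no claim of global optimality is made.

## Alignment handling

`filterAlignment()` applies the standard quality gate for consensus
folding: rows with more than 75% gaps are dropped (never the reference
row — a failing reference rejects the window), at least 3 rows must
survive, and the mean pairwise identity must lie in $[60\%, 95\%)$ —
below that alignments are unreliable, above it covariation carries no
signal beyond the single sequence.

Identity conventions are stated rather than assumed, since the common
formulas differ: gap-vs-gap positions leave the denominator, gap-vs-base
counts as mismatch (a switch `exclude_gap_base` gives the other
convention), `N` matches nothing. The per-column profile ignores columns
where the reference is gapped and columns with more than 25% gaps, the
convention used for identity profiles of windows whose alignments exceed
the nominal window length through reference gaps. For the same reason
predictions on alignment matrices live in *alignment-column*
coordinates; `columnsToReference()` maps them to ungapped reference
positions (snapping inward at reference gaps), and coordinate frames are
carried as tags that `boundaryDifference()` refuses to mix.

## Evaluation framework

Predictions are scored against annotated boundaries by **signed**
left/right differences,

$$\text{left} = \text{actual start} - u, \qquad
  \text{right} = v - \text{actual end},$$

positive = predicted boundary outside the annotation (excess), negative
= inside (short). Left and right are never summed or absolute-valued:
aggregation would erase which side failed and in which direction.
Summaries report per-group medians and IQRs, flagging groups of five or
fewer. Two prediction sets are compared with the two-sided Wilcoxon
rank-sum test: the exact null distribution of $U$ when both samples are
at most 20 without ties, otherwise the normal approximation with tie and
continuity corrections. The test suite checks the exact path against
full combinatorial enumeration for all sample sizes up to 8, and the
approximate path against a 2000-replicate null calibration at $n = 50$.

## The synthetic-data generator

`plantStructure()` builds windows with a planted self-contained
structure and known truth: `hairpin` (one stem-loop, miRNA-like),
`cloverleaf` (closing stem plus three arms, tRNA-like) and
`double_hairpin` (two stems and a hinge, H/ACA-like). Stem pairs carry
`stem_prob` (default 0.95, a strongly conserved stem). One generator
feature deserves its own paragraph: real Boltzmann ensembles leave **no
position with exactly zero pairing mass** — loops and hinges breathe,
pairing transiently with nearby stem positions. A stem-only matrix would
therefore be unrealistic *and* degenerate for any fitness whose inside
term takes a geometric mean: one mass-free loop position sends every
containing segment to $-\infty$. The generator consequently plants, as
part of its declared pair set, one weak "breathing" pair (at most
`breathing_prob = 0.08`, load-capped so no row approaches mass 1,
partners at least 4 nt away to respect the minimum hairpin loop) for
every in-domain position the stems leave unpaired. Background noise
pairs are sprinkled with per-cell probability `noise_density = 0.02` at
values below `noise_prob`; at `noise_prob` $\le p_0$ the noise is
provably invisible to the score transform, which the tests assert by
exact equality of score matrices.

What the generator does **not** emulate: alternative foldings competing
with the planted structure, fuzzy stem registers (slipped helices),
pseudoknots, correlated noise from alignment errors, or the coordinate
inflation real alignment matrices show through reference gaps. Passing
the planted-recovery suite therefore demonstrates correctness of the
search under clean, well-separated signal — not benchmark performance on
genomic windows, which requires the external multi-species alignments
and is out of scope here.

`toyFold()` provides exact ensembles from sequence alone: every nested
structure over canonical pairs (minimum hairpin loop 3) gets Boltzmann
weight $w^{\#\text{pairs}}$, $w = e^{-E/kT}$, and pair probabilities
come from an inside–outside computation. It is a single-per-pair-energy
(Nussinov-style) model — correctly normalised ensembles for tests, not
RNAfold numerics (no stacking, no loop penalties). The tests hold it to
exact agreement with brute-force structure enumeration up to length 14,
and to row mass at most 1. `mutateAlignment()` turns a reference into a
toy alignment with independent substitutions at unpaired positions and
*joint* compensatory substitutions at planted pairs — the covariation
signal consensus folders exploit. Its defaults (`sub_rate = 0.1`,
`compensatory_rate = 0`) make the no-mutation contract exact at
`sub_rate = 0`.

All generators are bit-reproducible under a fixed seed and restore the
caller's RNG state.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` use: 50 seeded cases per
layout with windows of 100–200 nt for planted recovery; 20 random sparse
windows of 26–40 nt for scanner/oracle equivalence (the naive evaluator
is quartic, so small windows are where exhaustive cross-checking is
informative); 100 random sequences up to 14 nt for folder/enumeration
equality (structure counts grow quickly beyond that); 2000 null
replicates at $n = 50$ for Wilcoxon calibration. These sizes give stable
pass/fail behaviour at desk scale while exercising every code path.

## Known limitations

* The exhaustive scan is cubic; windows beyond a few thousand positions
  would need a banded or windowed search (deliberately not implemented —
  the intended inputs are gene-finder windows of 100–200 nt).
* Greedy sub-optimal extraction is not a globally optimal tiling.
* The toy folder is not a thermodynamic folder; adapters to external
  folding executables are intentionally out of the package's contract,
  which starts at the probability matrix.
* Genome-scale benchmark figures (multi-species alignment medians per
  RNA family) cannot be reproduced from this package alone; the
  synthetic benchmark in the acceptance script exercises the identical
  pipeline at desk scale instead.
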