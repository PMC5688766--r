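---
title: "Reconstructing cancer karyotypes from copy-number and bridge data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cancer karyotypes from copy-number and bridge data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction problem

Short-read tumor sequencing yields two local summaries of a rearranged
genome: a per-segment copy-number (CN) profile, estimated from mean
read coverage, and a list of *bridges* — pairs of segment extremities
that are adjacent in the tumor but not in the reference — each
supported by some number of discordant read pairs. Neither source says
how the segments chain into whole chromosomes. `karyograph` poses that
chaining as a combinatorial optimization on a *bridge graph*:
vertices are interval extremities; interval edges (weighted by
observed CN), reference edges (unweighted) and bridge edges (weighted
by support) each stand for a pair of antiparallel directed edges. A
rearranged chromosome is an alternating interval/non-interval walk
between telomeric vertices, and a whole karyotype is an integer
assignment of traversal counts `f(e)` obeying, at every non-telomeric
vertex, the two balance equalities (interval edges out = non-interval
edges in, and symmetrically). Telomeric vertices are deliberately
unconstrained: they are where chromosomes begin and end.

The objective is the discordance score

$$d_G(f) = \sum_{e \in E_I}\frac{l_e}{L}\,\lvert f(e) - w(e)\rvert
  \;+\; \alpha \sum_{e \in E_V}\frac{w(e)}{\mu}\bigl(1 - \min(1, f(e))\bigr),$$

whose two terms are each normalized to `[0, 1]` (the first exactly
when all per-interval deviations are at most 1). Length-weighting
encodes that CN estimates of long intervals, being averages over more
reads, are more trustworthy and should cost more to contradict.

### Assumptions

* Chromosomes of the tumor run telomere-to-telomere over reference
  intervals; circular chromosomes are not modeled (but see
  *Degenerate structures* below).
* Every junction used by the tumor was observed as a bridge; the
  method never invents an unobserved junction. Data with false
  positives is therefore preferable to data with false negatives.
* CN is total (not allele-specific) and the sample is a single clone
  (an optional normal-contamination fraction is supported).

## The ILP

For each connection two integer variables `x(e→), x(e←)` count
directed traversals (fold-back bridges, which pair an extremity with
itself, collapse to a single variable counted once on each side of the
balance equalities — one traversal consumes one incoming and one
outgoing interval visit). The absolute deviations enter through slack
variables `t_e ≥ |f(e) − w(e)|`; bridge use through binaries
`y_e ≤ f(e)` rewarded by `α w(e)/μ`. Since the reward is the only
incentive on `y`, `y ∈ {0,1}` linearizes `min(1, f)` exactly.

Numerical choices:

* **Variable bounds.** MIP solvers need finite boxes; each directed
  count is bounded by `⌈max interval weight⌉ + (number of bridges) + 2`,
  which cannot cut off an optimum at realistic noise levels (an
  optimal `f` never exceeds the largest CN by more than the extra
  traversals the bridges can force).
* **Optimality.** The relative MIP gap is set to 0; the reported
  objective is recomputed in R from the rounded integer solution, so
  scores are exact rational arithmetic up to double precision.
* **Backend.** The MILP is solved by HiGHS via `scipy.optimize.milp`
  through a bundled Python helper; problems are batched so one
  interpreter launch serves a whole simulation study. The solver is
  deterministic for a fixed input, so reconstruction is reproducible;
  among multiple optima the solver's choice is accepted, and the
  evaluation measures are defined up to orientation and chromosome
  order so this tie-breaking does not affect them.
* **Tolerances.** Score comparisons (the equal-or-better-score
  measure) use an absolute tolerance of `1e-9`.

### Path decomposition and degenerate structures

The optimal multiplicities are decomposed by a greedy
Hierholzer-style sweep: start at a telomere with unused outgoing
interval capacity, alternate interval and non-interval edges until no
continuation remains, repeat; bridge continuations are preferred over
reference ones so that junction capacity lands inside paths. Balance
guarantees a walk can only stall at a telomere. The flow constraints
are local, so three degenerate structures can survive in an optimum
and are surfaced rather than hidden: telomere-detached balanced
**cycles** (reported in `cycles` with a warning), bridges joining two
telomeric vertices that terminate a walk without a final interval
(**bridge-terminated paths**), and **dangling** junction capacity
between unconstrained telomeric vertices. All evaluation measures are
computed from `f` directly, so these reporting choices never affect
scores.

### A boundary of the model

A rearrangement that clips a chromosome end (e.g. a deletion removing
the last segments) leaves a tumor chromosome ending at an interior
breakpoint. Such a karyotype is *outside* the valid-path space — no
telomere-to-telomere path system reproduces its CN profile — and even
noiseless data then has a strictly positive optimum (the flow couples
the flanking intervals). `is_telomere_bounded()` tests a karyotype for
this; in the default simulation scenario roughly 3–4% of draws are
affected. This is a property of the model, not of the solver: exact
zero-noise recovery holds for every telomere-bounded truth, and the
test suite asserts precisely that, alongside the explicit
counterexample.

## The simulator

`simulate_tumor()` starts from `ploidy` copies of `C` chromosomes,
each a sequence of 300 unit-length *atomic segments* (the smallest
unit at which a breakpoint can occur; using 300 per chromosome rather
than base pairs merely sets the resolution), and applies `N`
operations whose types and positions are uniform: deletions,
inversions and tandem duplications pick a chromosome copy, a uniform
start and a span uniform in `[1, min(30, room)]`; translocations pick
two distinct chromosome copies and interior cut points and swap
suffixes. The span cap avoids erasing whole chromosomes within a few
operations. Whole-chromosome gains and losses exist behind
`op_weights` but are disabled by default, matching the four-operation
protocol. Truth (segmentation, integer CN, bridge set) is derived by
comparing tumor and reference, so the simulator and the derivation
code check each other.

Parameters, defaults and units:

| parameter | default | meaning |
|---|---|---|
| `C` | 5 | reference chromosomes |
| `N` | 5 | operations applied |
| `eps` | 0.28 | CN noise scale (CN units per atomic segment) |
| `p` | 0.05 | probability a bridge goes unobserved |
| `lambda` | 0.1866 | exponential rate of bridge support (mean ≈ 5.4 read pairs) |
| `segments_per_chromosome` | 300 | atomic segments per chromosome |
| `max_span` | 30 | span cap for intra-chromosomal operations (atomic segments) |
| `ploidy` | 2 | copies of each chromosome |
| `normal_fraction` | 0 | normal-cell contamination of the CN signal |
| `alpha` (reconstruction) | 0.1 simulation / 0.5 real data | bridge-term weight |

### The noise model

Observed CN is modeled as a coverage average: every atomic unit of an
interval carries an independent `N(0, eps)` measurement error, so an
interval of length `l` sees Gaussian noise with standard deviation
`eps/√l` (`cn_noise = "scaled"`, the default). This is the reading
consistent with how CN estimates arise (means over reads) and with the
length-weighting rationale of the score itself. The alternative
`cn_noise = "flat"` adds `N(0, eps)` to every interval regardless of
length; under it, any interval-level decoder — however clever — errs
with probability `2Φ(−0.5/0.28) ≈ 7.4%` per isolated interval, which
with ~15 intervals per karyotype caps exact-CN recovery near 55% and
makes high success rates unattainable in principle. We treat the
flat model as a stress test, not as the default measurement model.
Noise is *not* clipped at zero for empty intervals: the score uses
absolute deviations and clipping would bias it. Bridge support is
drawn from `Exp(lambda)` and kept real-valued (an option rounds it);
dropped bridges (probability `p` each) disappear from the observation
but keep their breakpoints in the segmentation, since breakpoints are
detected from the tumor/reference comparison.

What the simulator does **not** emulate: clustered or recurrent
breakpoints, chromothripsis-style shattering, mixtures of distinct
tumor clones (only normal contamination via `normal_fraction`),
read-level artifacts (mappability, GC, insert-size variance), and
allele phasing. Passing simulation benchmarks therefore speaks to the
solver and score under the stated noise model, not to robustness
against those real-data effects.

## Evaluation measures

Against the simulated truth `T` (and the observed, noisy `T*`):

1. **correct** — same integer CN profile and same set of bridges
   used; orientation and chromosome order are ignored.
2. **ECN** — same integer CN profile.
3. **EBS** — reconstruction's score ≤ truth's score on the observed
   graph. When a true bridge was dropped, the truth is scored by its
   edge usage restricted to observed connections (it need not be a
   feasible path system there).
4. **EOB** — every observed bridge is used and the CN matches the
   truth on all intervals except those owning an extremity of a
   dropped bridge.
5. **CN score** — length-weighted fraction of intervals with the
   correct CN, in `[0, 1]`.

These satisfy correct ⇒ ECN ⇒ CN score = 1, and correct plus
no-dropped-bridges ⇒ EOB; the suite asserts the chain on every
evaluation.

## Study sizes

The batch drivers default to desk-scale sizes chosen to keep a full
reproduction in the minutes range on one CPU: 300 karyotypes in 3
batches of 100 for base-scenario medians, 100 karyotypes per value for
parameter sweeps (`run_scenario()` takes arbitrary sizes for larger
studies). With batched solving, a base-scenario karyotype costs a few
tens of milliseconds end to end.

```{r example}
library(karyograph)
s <- run_scenario(scenario_params(), n_karyotypes = 300, batch_size = 100,
                  alpha = 0.1, seed = 1)
print(s)
```

## Known limitations

* No junction prediction: unobserved bridges cannot be recovered, so
  sensitivity of the upstream SV caller bounds what reconstruction
  can achieve.
* Chromosomes clipped at their ends by rearrangements lie outside the
  path model (see above).
* Multiple optimal karyotypes can exist for one data set; the solver
  returns one, and only CN- and bridge-usage-level agreement is
  scored.
* Real-data ingestion expects pre-segmented CN and breakpoint-matched
  bridges; calling those from reads is out of scope.
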