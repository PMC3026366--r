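---
title: "Time-lagged information-theoretic inference of gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-lagged information-theoretic inference of gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlgrn)
```

## The model

`tlgrn` infers a directed gene regulatory network (GRN) from a time series
of expression measurements taken at equally spaced time points.  The data
model is the Boolean formalism: after quantization every gene is ON (1) or
OFF (0) at each time point, and an edge $i \to j$ asserts that gene $i$'s
state helps determine gene $j$'s state some number of time points later.
All information quantities are plug-in empirical entropies on the binary
alphabet, in bits:

$$H(A) = -p_0\log_2 p_0 - p_1\log_2 p_1, \qquad
  \mathrm{MI}(A;B) = H(A) + H(B) - H(A,B),$$
$$\mathrm{CMI}(A;B\mid C) = H(A,C) + H(B,C) - H(C) - H(A,B,C),$$

with the convention $0\log 0 = 0$ and no pseudocounts (smoothing is
reserved for the code-length estimators below, where it has an operational
meaning).

Plain MI is symmetric and ignores timing.  The package's central device is
a **non-negative regulatory lag** for every ordered pair: $\tau(A\to B)$ is
the time from $A$'s initial up-regulation (its first switch to ON; taken as
$t=1$ for a gene already ON at the start) to $B$'s first subsequent
expression change.  Differencing both genes' initial-change times — the
older convention — makes one direction of every asynchronous pair negative;
anchoring on the regulator's ON event instead encodes the biological
premise that a regulator acts while it is up-regulated, and yields
$\tau \ge 1$ by construction.  **TLMI** is then MI computed after deleting
the last $\tau$ symbols of the regulator sequence and the first $\tau$
symbols of the target sequence (so each regulator state is paired with the
target state $\tau$ steps later); **TLCMI** does the same for CMI, with the
conditioning gene trimmed on the regulator side.  At $\tau = 0$ both reduce
exactly to MI/CMI, and unlike MI, TLMI is directional.

## Why lag-trimmed metrics: MI saturation

With growing numbers of time points the empirical entropies of binarized
profiles drift upward while pairwise MI — dominated at small sample sizes
by positive estimation bias — decays toward its (small) true value.  Past a
data size that depends on the network, MI therefore stops discriminating
regulatory pairs from background, and the accuracy of MI-thresholding
algorithms saturates.  Restricting each pair's comparison to its
lag-aligned window is the package's answer: the regulator's state is
correlated with the target's *delayed* response, which the simultaneous MI
dilutes.  `miCurveStudy()` computes the entropy / conditional-entropy / MI
curves over data prefixes, and `saturationSweep()` re-runs a full inference
on growing prefixes (by default from 15 points in steps of 5, the standard
13-run design for a 75-point course) to locate the saturation point of the
recall/precision ratio.

## Network selection by MDL and PMDL

Both inference algorithms score every ordered pair with TLMI (or MI at the
conventional unit lag), then try **every observed score** as an edge
threshold $\theta$ — edge kept iff score $\ge \theta$ — plus a $+\infty$
sentinel for the empty model.  This realizes every distinct candidate
network the score matrix can induce (at most $n^2$ of them, nested as
$\theta$ falls).  Candidates are compared by description length:

* **Network MDL** charges each gene $k_j\log_2 n$ bits to name its $k_j$
  parents plus $2^{k_j}\cdot$`cptEntryBits` bits of conditional-probability-
  table memory (model length), and codes each gene's time course with
  Laplace($+\tfrac12$)-smoothed conditional frequencies given its parents'
  lag-shifted states (data length).  The selected network minimizes
  $\lambda\cdot\text{model} + \text{data}$.  The exact constants of the
  historical formulation are not published, so these formulas are this
  package's concrete instantiation; absolute bit counts are
  implementation-specific and only the induced ranking of candidates
  matters.  `cptEntryBits` defaults to 8 (one byte per stored table entry).
* **PMDL** drops the model-length term: each gene is coded by the
  Krichevsky–Trofimov sequential estimator, one Bernoulli context per joint
  parent state, charging $-\log_2\frac{c_t + 1/2}{n_t + 1}$ for the $t$-th
  symbol given the counts accumulated so far in its context.  Because a
  predictive code never sees the future, no separate model cost is needed
  and the arbitrariness of the $\lambda$ knob disappears.  After threshold
  selection, **CMI pruning** removes edges $i \to j$ whose TLCMI given some
  other current regulator $k$ of $j$ falls below `cmiThreshold`: high MI
  can reflect an indirect route, and a co-regulator that explains the
  dependence away marks the edge as a shortcut.  All marked edges are
  removed simultaneously after the scan, so the result is independent of
  scan order.  A `conditionAll` switch conditions on every third gene
  instead of co-regulators only, for sensitivity analysis.

With multiple parents in lagged mode, each parent contributes its own
pairwise lag and the target is coded over the common overlap window
$[\max_i \tau_i + 1,\, m]$, keeping a single well-defined CPT per gene.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lambda` | 0.2 | – | weight on model length in network MDL; 0.2 is the published synthetic-data setting, 0.1 the biological-data setting ("retain most of the connections") |
| `cmiThreshold` | 0.1 | bits | PMDL pruning threshold (published value) |
| `defaultTau` | 1 | time points | lag substituted when the event-based lag is undefined; 1 recovers the legacy unit-delay algorithms |
| `minOverlap` | 4 | time points | smallest lag-trimmed window any metric accepts; with fewer binary samples MI is essentially noise, so oversized lags fall back to `defaultTau` (flagged) |
| `cptEntryBits` | 8 | bits | model-length charge per CPT entry |
| `maxParents` | unset | – | optional in-degree cap; CPTs grow as $2^k$, and a guard warns past $2^{16}$ entries |

## Preprocessing

Continuous profiles are prepared as the historical pipeline prescribes.
Missing time points are imputed by neighbour means — interior gaps take the
mean of the two temporal neighbours, leading/trailing gaps copy the nearest
observed value; runs of gaps fill left-to-right against the next observed
value, which degenerates to the two-neighbour mean for single gaps.
Quantization is per gene and rank-based: sort the $m$ values, discard
exactly one minimum and one maximum cell as outliers (even under ties),
threshold at the median of the rest, and map values strictly above the
threshold to ON.  Ties at the threshold go to OFF, which makes constant
genes deterministically all-OFF (with a warning) rather than arbitrary.
Because the rule is rank-based it is invariant under any strictly monotone
rescaling of a gene's profile.  A consequence worth noting: every gene's
binarized profile is close to half ON over the full course — this balance
assumption is carried into the simulator below.

## The synthetic generator

`randomBooleanNetwork()` + `simulateSeries()` produce ground-truth-known
time courses: each gene draws an in-degree from
Binomial(`maxInDegree`, `edgeDensity`), uniform parents, a truth table and
per-parent integer delays (default 1; larger values create genuinely
multi-step lags for exercising TLMI's advantage over unit-lag MI).
Dynamics are synchronous with i.i.d. per-step flip noise.  Two deliberate
design choices depart from the most naive random Boolean network:

* **Balanced truth tables** (default): each table is a random permutation
  of half 0s and half 1s.  Median quantization forces real binarized
  profiles to ~50% ON occupancy; uniformly drawn tables instead pin many
  genes to one state, which no median-quantized dataset exhibits.
* **Slow exogenous inputs**: parentless genes follow a two-state Markov
  chain switching with probability `inputSwitch` (default 0.15, dwell ≈ 7
  samples) rather than sitting at a constant ($2^0$-entry table) value.
  Kinetic in-silico generators produce strongly autocorrelated
  trajectories, and constant roots would freeze an entire noiseless
  network onto a fixed point, leaving nothing to infer.

What the generator does **not** emulate: continuous kinetics (ODE/SDE),
module extraction from a curated interactome, uneven sampling, or
measurement models beyond symmetric symbol flips.  Consequently the exact
published saturation points of specific in-silico networks are not
reproducible here; the package's tests assert the *directional* saturation
behaviour instead.  One honest caveat, computed by the test suite and the
acceptance script themselves: averaged over simulated networks, mean gene
entropy at 100 points exceeds that at 15 points and mean pairwise MI at
100 points falls below that at 15 points, but the per-network conjunction
of both inequalities holds in only roughly 60% of random 5-gene networks
(flip noise 0.05).  A Boolean network with genuine unit-lag couplings
retains true simultaneous pairwise MI at large $m$, unlike median-quantized
kinetic data whose simultaneous MI is near zero — so the per-seed
conjunction, as opposed to the seed-averaged direction, is not a property
this generator can guarantee.

## Numerical and design choices

* Logarithms are base 2 throughout; every score and code length is in bits.
* Floating-point MI/CMI values in $[-10^{-12}, 0)$ are clamped to 0; more
  negative values raise an internal-consistency error rather than being
  silently absorbed.
* Threshold comparison is $\ge$, so the densest candidate is realizable;
  description-length ties (within $10^{-9}$ bits) break toward the larger
  threshold, i.e. the sparser network — the MDL-natural and deterministic
  choice.
* Degenerate evaluation cases follow explicit conventions: precision is 1
  when nothing was inferred, recall is 1 when the reference network is
  empty, and the recall/precision ratio is reported only when precision is
  positive.  Evaluation is direction-sensitive by default (an `undirected`
  switch relaxes matching).
* Genes already ON at $t=1$ count as up-regulated at $t=1$; a regulator
  that never switches ON, or a target that never changes afterwards, has
  an undefined lag and falls back to `defaultTau` with a flag, so
  downstream computations stay total.
* Laplace smoothing means the data length is not exactly monotone along
  the threshold sweep (splitting a context adds a little smoothing slack);
  the sweep therefore evaluates every candidate rather than relying on
  monotonicity, and the brute-force oracle tests confirm the attained
  minimum.
* Self-loops are rejected everywhere: a gene's MI with itself is its
  entropy and would trivially pass any threshold.

## Scale of the shipped experiments

The test suite and the acceptance script run entirely on simulated data at
sizes a laptop handles in seconds: identity checks on 1000 random sequence
pairs/triples (lengths 4–50), exhaustive-sweep oracle comparisons on 50
instances with $n \le 4$, $m \le 12$, chain-pruning over 50 replicates at
$m = 40$, the saturation study on 20 five-gene networks at 100 points, a
13-prefix sweep of a 10-gene, 75-point course, and parameter recovery on a
noiseless 10-gene, 60-point course.  These sizes were chosen to keep the
exhaustive oracles exact and the stochastic rates stable, and they match
the experimental designs described above.

## Known limitations

* Binary quantization discards amplitude information; multi-level
  quantization is not implemented.
* The lag estimator keys on single events (first up-regulation, first
  subsequent change) and is therefore sensitive to noise at those specific
  time points; undefined lags fall back to the unit delay.
* Absolute description lengths are not comparable across packages or to
  historical implementations — only within-sweep rankings are meaningful.
* On noiseless data a network can reach a fixed point early; frozen
  profiles carry no information and no inference method can recover their
  edges.  This is a property of the dynamics, not of the estimator.
* Time points must be equally spaced; a single lag per pair is not
  meaningful otherwise, and the package makes no attempt to handle uneven
  sampling.
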