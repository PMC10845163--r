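---
title: "Reflection symmetry, suppressed motifs and long cycles in threshold Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reflection symmetry, suppressed motifs and long cycles in threshold Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolsym)
```

## The model and its assumptions

`boolsym` studies synchronous signed threshold Boolean networks. A network
is an `n × n` trit matrix `W`; gene `j` switches on at the next step
exactly when its signed input sum `Σ_i W[i, j] x_i` is strictly positive.
Three modeling commitments are fixed throughout and deliberately not
configurable:

* **Ties map to 0.** A zero input sum means "off". This makes the all-zero
  state a fixed point of every signed network and anchors the whole
  analysis (every functional graph has at least one cycle, so the maximum
  cycle length is always at least 1, with fixed points counted as
  length-1 cycles).
* **Synchronous update.** All genes update at once. Asynchronous schemes
  change the attractor structure and are out of scope.
* **LSB-first state encoding.** State `(x0, x1, …)` is the integer
  `Σ x_i 2^i`. All integer states in JSON output are accompanied by the
  decoded bit tuple so no consumer has to know this.

General Boolean networks (one truth table per gene, class `bfn`) are
supported wherever the definitions only use the update map `f` — the
symmetry metrics, attractors and trajectories — because reflection
symmetry is a property of the dynamics, not of the threshold
parameterization.

## State space, attractors, and the cap

`transition_map()` materializes τ over all `2^n` states;
`find_attractors()` extracts every cycle and exact basin size by iterative
pointer chasing (linear in the number of states, no recursion, so deep
transients cannot overflow a stack). Maps are refused above a cap of
`n = 22` (`options(boolsym.state_cap = …)` to change): beyond that the
successor table alone is tens of megabytes and exhaustive analysis stops
being the right tool. Above the cap only the Monte-Carlo symmetry
estimates are offered — curated biological models reach a few hundred
genes, where `2^n` is out of reach for any exact method.

## Reflection symmetry: two metrics, always both

A state `x` transitions *fully symmetrically* when `τ(¬x) = ¬τ(x)`. The
fully-symmetric count is a blunt instrument on large networks (it demands
all `n` bits cooperate at once), so the per-bit relaxation — the partial
symmetry ratio `p_sr`, the fraction of (state, bit) pairs with
`f(x)_i ≠ f(¬x)_i` — is reported alongside it everywhere. The two
coincide at the extremes (`p_sr = 1` iff every transition is fully
symmetric) and `p_sr` always dominates the fully-symmetric fraction,
since a fully symmetric state contributes all of its `n` bits. Reporting
both avoids committing to either reading of "symmetry ratio" when
screening model repositories, where published percentages have been
phrased both ways.

The Monte-Carlo estimator (`sampled_symmetry()`) draws `m` states
uniformly with replacement and evaluates both indicators on the sample;
the estimates are unbiased, and the default `m = 10^4` puts the binomial
95% half-width at about one percentage point — adequate for separating
the ~50% random baseline from enriched models. No tie handling is needed
anywhere: a Boolean state is never its own complement.

## The 3-motif universe and the 3284-class convention

A 3-motif is the induced 3 × 3 trit submatrix on a node triple,
considered up to simultaneous row/column permutation. The canonical form
is the lexicographically smallest row-major flattening over the 6
relabelings with trit order −1 < 0 < 1, stored as a base-3 integer (any
total, deterministic convention would do; this one is cheap and makes the
id itself decodable back to a matrix). Exhaustive enumeration of the
19 683 labeled matrices yields 3411 classes — independently confirmed by
Burnside's lemma, (3^9 + 3·3^5 + 2·3^3)/6 — of which 127 contain a node
with no inter-node edge in either direction (self-loops ignored).
Excluding those leaves the 3284 *connected* classes. This connectivity
convention is the unique natural one under which the class count matches
the published size of the motif universe, and network scans
(`motif_census()`) therefore scan all C(n,3) triples but count only
connected triads.

## Suppressed motifs and gluing

`motif_enrichment()` compares per-triple motif rates between a target and
a baseline population; motifs with baseline support of at least
`min_support = 50` whose rate ratio falls below `delta = 0.05` are flagged
suppressed. Both thresholds are exposed; the defaults operationalize
"almost completely absent" while requiring enough baseline mass for the
ratio to be meaningful. Under the package's study conditions (twenty
200-generation GA runs against 10^4 density-matched random networks) the
regenerated suppressed set has on the order of a hundred classes; the set
is regenerated from scratch rather than shipped, since it is a property
of the evolved populations, not a constant.

`glue_network()` tests the causal claim: starting from the empty matrix,
a uniform node triple and a uniform motif from the set are drawn and the
motif's 9 entries stamped on (overwriting), until the nonzero fraction
reaches the target density or a stamp budget of `50 n²` runs out (the
budget exists because sparse motif sets — in the extreme, the all-zero
motif — can never reach a high density; that outcome is reported, not
raised). Stamping with overwriting is the simplest procedure that yields
a density-controlled network whose triads are dominated by the chosen
set; networks glued from the suppressed set show a large cycle-length
deficit against density-matched uniform networks, while networks glued
from random motif subsets of the same size do not, so the deficit is
attributable to the motifs rather than to the gluing process.

## The Pareto genetic algorithm

The GA (`evolve_pareto()`) maximizes maximum cycle length while
minimizing edge count on genomes of `n²` trits. The multi-objective
machinery is deliberately standard: non-dominated sorting with crowding
distance, binary tournaments, uniform crossover at rate 0.7, per-locus
mutation to a uniformly chosen *different* trit at rate `1/n²` (one
expected mutation per genome), and elitist μ+λ survivor truncation. All
rates are arguments. Density is scored as the raw nonzero count —
integer-valued, monotone in density, and free of any `n²` normalization
ambiguity. Front hypervolume is tracked per generation against the
reference point (cycle 0, edges `n²+1`). Elitism guarantees the best
cycle length is non-decreasing across generations, which the tests assert.
Runs are reproducible from the `seed` argument alone.

## Random ensembles and surveys

"Random network" defaults to i.i.d. uniform trits per entry (expected
density 2/3). The fixed-density generator (`random_density_network()`)
places an exact number of edges and covers density-conditioned baselines;
drawing its edge count from Binomial(`n²`, 2/3) recovers the uniform
ensemble distributionally, which the tests check. Kauffman NK networks
(`kauffman_network()`) give the general-Boolean null: K distinct uniform
inputs per node and fair-coin truth tables, whose expected partial
symmetry ratio is 1/2 (for any state, the input patterns of `x` and `¬x`
differ, so the two table lookups are independent fair coins).

`cycle_length_survey()` aggregates maximum cycle length by edge count,
excitatory/inhibitory mix, mean simple-circuit length, or self-loop
counts. Circuit enumeration is an exact DFS over simple directed cycles
(each counted once, rooted at its minimal vertex; self-loops are length-1
circuits, a circuit's sign is the product of its edge signs) and is
guarded to small `n`, where the surveys operate. Surveys default to 10^4
samples — the trends of interest (denser networks cycle longer;
self-inhibition correlates positively and self-excitation negatively with
cycle length) are already unambiguous there, and the sample size is an
argument for anyone who wants survey-scale precision. When probing the
density trend specifically, sweep densities with the fixed-density
generator: the uniform ensemble concentrates near density 2/3 and leaves
most of the density axis unsampled.

Single-edge perturbation (`edge_perturbation_decrement()`) supports two
modes, because "altering a random edge" is ambiguous: any of the `n²`
matrix positions (including creating an edge where none existed), or only
currently nonzero positions. The default is the broad reading; a flag
restricts to existing edges.

## What the synthetic conditions do and do not show

Every experiment in the package is self-generating: random ensembles,
evolved populations, glued networks and generated `.bnet` fixtures. These
reproduce the *mechanistic* claims — rarity of long cycles, the
suppressed-motif effect, symmetry enrichment under selection for cycles —
under controlled conditions. They do not emulate real gene regulatory
models: curated models have heavy-tailed in-degrees, highly non-random
truth tables (canalyzing, monotone), and node counts far above the exact
cap, and the package's screen of such models (`symmetry_screen()` over
user-supplied `.bnet` exports) is exactly that — a screen, whose sampled
estimates carry the reported confidence half-widths. Passing tests on
generated fixtures show the pipeline is correct, not that any particular
biological repository is symmetry-enriched.

Test and acceptance runs use desk-scale problem sizes chosen once: 7-node
networks (128 states) for the population experiments, 10^6 uniform draws
for the rare-cycle check, 10^3 networks per arm for the gluing contrast,
and twenty GA replicates. These sizes make every contrast of interest
decisive (the gluing deficit, for instance, is significant far beyond
p < 10^-4) while keeping a full run in minutes.

## A caution from exhaustive enumeration at n = 2

Exhaustive analysis of all 81 two-node networks is a useful reminder that
"maximal-cycle networks are reflection symmetric" must be stated
carefully. The global maximum cycle length at `n = 2` is 2, attained by
eight networks. Only one of them — mutual excitation,
`W = [[0,1],[1,0]]`, which is also the unique minimal-edge winner, i.e.
the Pareto corner the evolutionary search targets — has a fully
reflection-symmetric transition diagram; one winner has *no* fully
symmetric transitions at all. At `n = 3` the situation is clean: both
networks attaining the global maximum (cycle length 6 out of 8 states)
are fully symmetric. So full symmetry of every attaining network is a
property that emerges at `n = 3` but fails at `n = 2`, where the tiny
state space leaves room for asymmetric period-2 solutions; the
enrichment of symmetry among *optimized* (long-cycle, low-density)
networks is the robust phenomenon. The acceptance suite states the strict
all-winners claim at both sizes and records its failure at `n = 2` as an
expected, documented outcome rather than weakening the check.

## Numerical and degenerate-input choices

* Integer state arithmetic is used up to the cap (`2^22 < 2^31`), so all
  state indices are exact; nothing relies on floating-point encodings.
* `trajectory` allocation is bounded by `min(t_max, 2^n) + 1` — a repeat
  is forced within `2^n` steps.
* Zero-variance samples in `compare_populations()` return an explicit
  degenerate result (p = 1 for equal means, 0 otherwise) instead of NaN.
* Empty motif baselines, unreachable glue densities, out-of-range states,
  and oversized per-node in-degrees in `.bnet` compilation all fail (or
  report) with specific messages; parse errors name the offending line.
* `.bnet` operator precedence is NOT over AND over OR, matching the
  BoolNet dialect; expressions are compiled to truth tables by exhaustive
  evaluation (per-node in-degree capped at 16), and `threshold_to_bnet()`
  emits a disjunctive normal form whose compiled dynamics equal the
  threshold rule exactly — the tests verify the round trip state by
  state.

## Known limitations

* Exact attractor analysis stops at the state-space cap; there is no
  SAT-based or sampling-based attractor finder for large `n`.
* Motif analysis is limited to 3-node motifs, and population comparisons
  are against sampled baselines, not degree-preserving rewiring nulls.
* Only the synchronous deterministic update is implemented; probabilistic
  and multi-level models are out of scope.
* Multi-level model import (e.g. GINsim XML) is not supported; models
  must be exported to the `.bnet` text dialect first.
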