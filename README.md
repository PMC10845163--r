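# boolsym

Long dynamical cycles — circadian clocks, the cell cycle, oscillatory
signalling — are a hallmark of gene regulatory networks, yet most random
interaction topologies produce only short limit cycles. `boolsym` is a
toolkit for asking *which local interaction structures support or destroy
long cycles* in the simplest expressive model of regulation: the
synchronous signed threshold Boolean network.

## The model

A network of `n` binary genes is specified by a trit matrix
`W ∈ {−1, 0, +1}^{n×n}`, where `W[i, j]` is the sign of the directed edge
from gene `i` to gene `j` (+1 excitatory, −1 inhibitory, 0 absent). All
genes update at once:

    x_j(t+1) = 1   if  Σ_i W[i, j] · x_i(t) > 0
             = 0   otherwise (ties go to 0)

This defines a map τ on the `2^n` states; every trajectory falls onto a
directed cycle of τ (a fixed point is a cycle of length 1). The package
revolves around three quantities of that functional graph:

* **maximum cycle length** — the length of the longest attractor cycle;
* **dynamical reflection symmetry** — a state `x` transitions *fully
  symmetrically* when `τ(¬x) = ¬τ(x)`, with `¬` the bitwise NOT; the
  **partial symmetry ratio**

      p_sr = 1/(2^n · n) Σ_x Σ_i θ(|f(x)_i − f(¬x)_i|),  θ(u) = 1 iff u > 0

  is the fraction of per-state bits that land on complementary values from
  complementary starts (`p_sr = 1` exactly when every transition is fully
  symmetric);
* **3-motif content** — the census of induced 3-node signed subgraphs up
  to node relabeling (3284 connected classes), including detection of
  *suppressed motifs*: classes that all but vanish from populations evolved
  for long cycles, and that actively destroy cycles when networks are glued
  together from them.

On top sit a non-dominated-sorting Pareto genetic algorithm (maximize
cycle length, minimize edge count), random ensembles (uniform trit,
fixed-density, Kauffman NK) with sampling surveys, exact and Monte-Carlo
symmetry metrics, and readers/writers for TSV/JSON matrices and BoolNet
`.bnet` model files, so curated Boolean models of biological systems can
be screened for symmetry directly.

## Worked example

```r
library(boolsym)

# two mutually excitatory genes, each self-inhibiting
net <- read_network(system.file("extdata", "toggle.tsv", package = "boolsym"))
net
#> signed_network with 2 nodes, 4 edges

att <- find_attractors(net)
att
#> attractor_set: 2 attractor(s); cycle lengths 1 2
att$basin_size
#> [1] 2 2

symmetry_report(net)
#> symmetry_report (n = 2, exact): full_sym = 0.5000, p_sr = 0.5000
```

The network has a fixed point (both genes off) and a period-2 oscillation,
each draining half of the four states. Half of the states transition fully
symmetrically — the two oscillating states are each other's complement —
and half of all bit transitions are symmetric (`p_sr = 0.5`).

Evolving 7-gene networks for long cycles at low density:

```r
front <- evolve_pareto(7L, pop_size = 100L, generations = 200L, seed = 1L)
front
#> pareto_front (n = 7 ): 9 members; best cycle 21
data.frame(cycle_len = front$members$cycle_len, edges = front$members$edges)
#>   cycle_len edges
#> 1         1     0
#> 2        21    13
#> 3        18    10
#> 4        12     8
#> ...
```

A 21-step limit cycle from only 13 signed edges — uniform random sampling
needs on the order of a million draws to find a 7-node network with a cycle
of length 19 (`batch_max_cycle(random_genomes(7, 1e6), 7)` reproduces the
rarity). Evolved front members carry far more fully symmetric transitions
than density-matched random networks, and a motif census of the front
(`motif_census`, `motif_enrichment`) exposes the suppressed-motif set;
`glue_network` builds networks from any motif set to test their causal
effect on cycle length.

There is also a command line:

```sh
boolsym motifs census --connected-only     # prints 3284
boolsym symmetry --net inst/extdata/toggle.tsv
boolsym evolve --n 7 --pop 100 --generations 200 --seed 1 --out run1
```

(`inst/bin/boolsym` when running from a source checkout.)

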