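# brnest

Logical-parameter estimation for qualitative biological regulatory networks.

## The problem

In the Thomas formalism, a gene network is a signed, thresholded directed
graph: each entity holds a discrete expression level in `0..max_level`, and
each interaction activates (`+`) or inhibits (`-`) its target once the
source reaches its threshold. The dynamics are fixed by the *logical
parameters* `K_v(W)` — for every entity `v` and every subset `W` of its
regulators, the level toward which `v` drifts (one unit per asynchronous
transition) when its current *resources* (present activators plus absent
inhibitors) are exactly `W`. A state with every entity at its target is a
stable steady state; a cycle in the state graph is sustained oscillation
(homeostasis).

The `K` values are rarely measurable. brnest infers them: it enumerates
every parametrization of the network (`prod((l_v+1)^(2^|G-(v)|))`
candidates, optionally narrowed by declared parameter ranges), builds each
candidate's asynchronous state graph, verifies wet-lab observations written
in Computation Tree Logic with a built-in explicit-state fixpoint model
checker, and returns the parametrizations accepted in every state. The
candidate space is split into contiguous index blocks evaluated by
independent parallel workers; results are invariant to the worker count.

The package is for systems biologists and method developers working with
qualitative models: it reads and writes an SMBioNet-style four-section
model format (VAR/REG/PARA/CTL), exports state graphs as DOT or GraphML,
and ships the textbook *Pseudomonas aeruginosa* mucus-production network
plus seeded random-network generators.

## Worked example

The two-gene *Pseudomonas aeruginosa* network: `x` (sigma factor AlgU,
levels 0–2) activates itself at threshold 2 and its inhibitor `y` at
threshold 1; `y` represses `x`. Two observations: from rest the system must
not over-express `x` (normal mucoid homeostasis), and the over-expressed
state `(2,1)` must be stable (the pathogenic phenotype).

```r
library(brnest)
fx <- pseudomonas_model()
fit <- brn_estimate(fx$network, fx$formulas, workers = 2)
fit
#> Logical-parameter estimation
#>   network: pseudomonas (2 entities)
#>   observations:
#>     (x=0 & y=0) -> (AG (!x=2))
#>     (x=2 & y=1) -> (AG x=2)
#>   parametrizations evaluated: 324
#>   accepted: 37
#>   model indices: 73 75 77 79 80 81 82 83 85 87 89 91 92 93 94 95 181 183 185 187 ...
```

Of the 324 candidate parametrizations (3^4 for `x`'s four resource subsets,
2^2 for `y`'s two), 37 satisfy both observations in every state. The
hand-checkable homeostasis model is among them; its state graph shows the
two published behaviors — the four-state oscillation and the pathogenic
stable state:

```r
K <- as_parametrization(fx$network, list(x = c(0, 2, 1, 2), y = c(0, 1)))
g <- build_state_graph(fx$network, K)
g
#> Asynchronous state graph: 6 states, 5 transitions, 1 deadlock(s)
#>   stable: (2,1)
sat_set(g, "AG(x=2)")
#> Sat(AG x=2): 2 of 6 states
```

`coef(fit)` returns the accepted models as a K-value matrix (one row per
model, one column per parameter slot), `write_results(fit)` serializes them
to the results format, and `plot(fit, which = 1)` draws an accepted model's
state graph.

A shell front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "brnest.R", package = "brnest"))')
Rscript "$CLI" count --input inst/extdata/pseudomonas.smb
# states: 6
# parametrizations: 324
Rscript "$CLI" estimate --input inst/extdata/pseudomonas.smb --workers 4 --output results.txt
```

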