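---
title: "Estimating logical parameters of qualitative regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating logical parameters of qualitative regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brnest)
```

## The modeling framework

brnest works in the qualitative (René Thomas) formalism for gene regulation.
A *biological regulatory network* (BRN) is a directed graph whose vertices
are entities (genes, proteins) and whose edges are interactions labeled with
a threshold $\tau$ and a sign ($+$ activation, $-$ inhibition). Each entity
$v$ has a discrete expression range $\{0,\dots,\ell_v\}$; a *qualitative
state* is one level per entity, so the state space is the cartesian product
of the ranges, of size $\prod_v (\ell_v + 1)$.

In a state $s$, the *resources* of $v$ are the regulators currently helping
it: activators at or above their threshold and inhibitors strictly below
theirs — an absent inhibitor helps. The dynamics are driven by the *logical
parameters* $K_v(W)$, one per entity and resource subset $W$: they give the
target level toward which $v$ evolves when its resources are exactly $W$.
Evolution is in unit steps,

$$
s_v \vartriangle K =
\begin{cases}
s_v + 1 & s_v < K\\
s_v - 1 & s_v > K\\
s_v & s_v = K,
\end{cases}
$$

and updating is *asynchronous*: a transition of the state graph changes
exactly one entity by exactly one unit. A state where every entity sits at
its target has no outgoing transition — a deadlock, biologically a stable
steady state. Cycles in the state graph are the qualitative signature of
sustained oscillation (homeostasis).

The parameters $K_v(W)$ are rarely measurable. The estimation problem is:
given the network structure and wet-lab observations encoded as CTL
(Computation Tree Logic) formulas, find every complete assignment of
$K$ values — every *parametrization* — whose state graph satisfies the
observations. The number of candidates is
$\prod_v (\ell_v + 1)^{2^{|G^-(v)|}}$ with $G^-(v)$ the regulators of $v$,
so even the two-gene example below has $3^4 \times 2^2 = 324$ candidates and
realistic networks have millions; the package therefore treats estimation as
an embarrassingly parallel sweep over an indexed candidate space.

## The model checker

Each candidate's state graph is a Kripke structure, and each observation a
CTL formula over atoms `entity = level`. brnest decides them with a built-in
explicit-state labeling algorithm: `EX` is a pre-image, `E[p U q]` a least
fixpoint, `EG p` a greatest fixpoint, and the universal operators reduce by
the standard dualities. Two semantic choices matter and are deliberate:

* **Totalization.** CTL path semantics needs a total transition relation,
  so deadlocks receive a self-loop before checking (never stored in the
  graph itself). This makes `AG` hold at a stable state for any property the
  state satisfies, which is exactly the biological reading — a deadlocked
  system stays where it is.
* **Acceptance in all states.** A candidate is accepted when the conjunction
  of the observations holds in *every* state. Published observations are
  guard-style implications (`(x=0 & y=0) -> AG(...)`), vacuously true
  outside their guard, so all-states acceptance is equivalent to checking
  from unconstrained initial states. Checking from a designated initial
  state instead would require information the input format does not carry.

The grammar accepts `,` as conjunction alongside `&` (published observations
print `AG(OGT=1,OGA=0,...)`), reads a bare `X` as `AX`, and restricts atoms
to equalities; a level set such as $\{v \ge 1\}$ is written as a disjunction
of equalities. Counter-example traces are out of scope; `violating_states()`
lists the states where a formula fails, which for guarded observations is
the more direct diagnostic.

## Enumeration and parallel decomposition

Parameter *slots* — one per (entity, resource subset) — are ordered by
entity declaration order, then by resource-subset bitmask over
declaration-ordered regulators, empty set first. A parametrization is a
tuple of slot values and the space enumerates in mixed radix with the last
slot varying fastest. These conventions are arbitrary but fixed, so a model
index identifies the same parametrization in every run and for every worker
count. An optional PARA section restricts individual slots to value ranges,
shrinking the product.

`brn_estimate()` splits `[0, total)` into `workers` contiguous blocks of
near-equal size (larger blocks first — the deterministic remainder rule) and
evaluates each block in an independent forked process; workers share no
mutable state, and the reduction step merges accepted index lists in global
order, linearly in the number of accepted models. Because block boundaries
never influence per-candidate evaluation, results are invariant to the
worker count — the test suite asserts byte-identical result files for 1, 2,
4 and 8 workers. The same partition/reduce contract would carry over
unchanged to a distributed backend; transport is deliberately not part of
the package's contract.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `workers` | 1 | number of index blocks / forked processes |
| `max_states` | $10^6$ | capacity cap on explicit state-graph construction |
| `para` | none | PARA-style per-slot value restrictions |
| `diagnostics` | off | per-formula first-failure counts for rejected models |
| `edge_density` (generator) | 0.3 | probability of each ordered interaction |

The state cap exists because explicit-state construction is the package's
chosen representation: a 23-gene Boolean model already has $8{,}388{,}608$
states, and building such graphs one candidate at a time is not a desk-scale
computation. The cap fails fast with an explicit message and can be raised
knowingly. Parametrization counts are tracked as doubles and index
arithmetic refuses spaces beyond $2^{53}$, where exactness would be lost;
spaces that large are not enumerable anyway.

## Validator behavior worth knowing

Thomas' convention ties $\ell_v$ to the out-degree of $v$. Declared VAR
ranges are authoritative in this package: the validator only warns on a
mismatch, because published models do not always satisfy the equality.
Duplicate ordered interaction pairs are rejected (the interaction set is a
subset of $V \times V$). No observability or monotonicity constraints are
imposed on $K$ values — PARA ranges are the only restriction mechanism.

## The fixtures and the random generator

`pseudomonas_model()` is the two-gene mucus-production network: `x` (the
sigma factor AlgU, levels 0–2) activates itself at threshold 2 and its
inhibitor `y` at threshold 1; `y` represses `x` at threshold 1. The two
observations encode normal homeostasis (from rest, `x` never reaches 2) and
the pathogenic response (the over-expressed state `(2,1)` is stable). The
thresholds and formula texts reconstruct published artwork rather than
printed tables, and the fixture's `notes` field says so; downstream checks
therefore assert structural facts (a non-empty accepted set containing a
model with the `(2,1)` deadlock and a homeostatic cycle) rather than exact
K values.

`hbp_like_model()` is a nine-entity Boolean stand-in for the hexosamine
biosynthetic pathway intersection with PI3K/Myc and P53–MDM2 signalling.
Entity order fixes the state-tuple coordinates. It contains the attested
motifs — the P53–MDM2 negative feedback loop, CMyc activating OGT, OGA
inhibiting OGT, the OGT–CMyc positive loop — and invented wiring for the
rest, chosen so every entity's out-degree matches its Boolean range. It is
used for structural checks (512 states, Boolean K slots, deadlock
reporting), never for reproducing published accepted-model counts, which
depend on the exact supplementary topology.

`random_brn(n, max_level, edge_density, seed)` draws each ordered pair
(self-loops included) with the given density, signs uniformly, thresholds
uniformly on the valid range, deterministically per seed and without
touching the caller's RNG stream. It emulates the combinatorial variety of
small BRNs — dense feedback, self-regulation, multi-level thresholds — and
is the substrate for the property tests. It does not emulate biological
degree distributions, coherent sign patterns or modular pathway structure,
so passing tests demonstrate correctness of the algorithms on arbitrary
topologies, not biological plausibility of any particular random model.

## Verification strategy and problem sizes

The model checker is verified against an independent oracle implemented in
the test suite from the path-based definitions: reachability closure for
`EF`/`AG`, SCC-or-self-loop detection inside the satisfying region for `EG`,
direct successor inspection for `EX`/`AX` (via igraph, no fixpoint
iteration). One hundred seeded random graphs of up to 64 states are checked
against the oracle for every operator form, alongside the duality and
least-fixpoint-soundness identities. The estimator is verified against a
single-loop brute-force sweep (expand.grid over slot values) on the full
324-candidate Pseudomonas space. These sizes keep the default suite under a
minute while exercising every code path; the algorithms themselves have no
small-size assumptions.

## Worked example

```{r example}
fx <- pseudomonas_model()
fit <- brn_estimate(fx$network, fx$formulas, workers = 2)
fit
```

The 37 accepted parametrizations include the hand-checkable homeostasis
model ($K_x(\{\}) = 0$, $K_x(\{x\}) = 2$, $K_x(\{y\}) = 1$,
$K_x(\{x,y\}) = 2$, $K_y(\{\}) = 0$, $K_y(\{x\}) = 1$), whose state graph
has the four-state cycle
$(0,0) \to (1,0) \to (1,1) \to (0,1) \to (0,0)$ and the pathogenic stable
state $(2,1)$:

```{r graph}
K <- as_parametrization(fx$network, list(x = c(0, 2, 1, 2), y = c(0, 1)))
g <- build_state_graph(fx$network, K)
g
sat_set(g, "AG(x=2)")
```

## Known limitations

* Explicit-state only: no BDD/symbolic representation, no on-the-fly
  construction; full-space estimation of large published models is out of
  scope by design, while their state-space sizes are still computed exactly.
* Asynchronous updating only; synchronous state graphs are not built.
* Acceptance semantics is all-states; designated-initial-state checking is
  not offered because the input format cannot express initial states.
* Process-level parallelism on one machine; no cluster transport, no
  dynamic load balancing, no fault tolerance beyond failing the run with
  the offending index range.
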