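---
title: "Modular decomposition of synchronous Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular decomposition of synchronous Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolmod)
```

## The model

A synchronous Boolean network on variables $x_1,\dots,x_n$ is a map
$F:\{0,1\}^n \to \{0,1\}^n$, $F(x) = (f_1(x),\dots,f_n(x))$, where every
coordinate is updated simultaneously. `boolmod` stores each rule $f_i$ as a
truth table over its regulators, compiled from logic expressions in a plain
`name, expression` file dialect (`&`, `|`, `!`, parentheses, constants, and
`+` for addition over GF(2)). States are bit vectors printed with the first
declared variable leftmost, so `"010"` means $x_1=0, x_2=1, x_3=0$; since
this textual order coincides with numeric order of the underlying integer
codes, the lexicographically smallest state of a cycle is a canonical
anchor, which gives attractors stable set semantics.

Because state space is finite and the map deterministic, every forward
orbit ends in an *attractor*: a steady state or limit cycle, the model's
analogue of a cell phenotype. `enumerate_attractors()` computes all of them
(plus the full basin map) by treating the $2^n$-state successor table as a
functional graph and extracting its cycles with pointer doubling; the sweep
is guarded at $n \le 24$ by default because memory grows as $2^n$.
`iterate_to_attractor()` and `sample_attractors()` cover larger networks,
the latter giving a lower bound on the attractor count whose coverage is
quantified exactly by `attractor_detection_probability()`:
an attractor holding a fraction $p$ of state space is missed by $s$ uniform
restarts with probability $(1-p)^s$. Restarts are drawn with replacement;
for the state-space sizes where sampling is the only option the distinction
is negligible.

## Structural decomposition

The wiring diagram has an edge $u \to v$ when $f_v$ depends *essentially*
on $u$ — published models sometimes list regulators that never change a
rule's output, so every structural computation first calls
`reduce_to_essential_regulators()`, which is idempotent and preserves the
dynamics state-by-state. The strongly connected components of the wiring
diagram are the *modules*; contracting them yields an acyclic module DAG
$Q$. Restriction `F|_S` keeps the rules of $S$ and turns outside regulators
into declared *external parameters*; the converse operation is the
semi-direct product $F \rtimes_P G$, which substitutes upstream variables
for the external parameters of $G$ according to a coupling scheme $P$.

`structural_decompose()` returns the modules in a deterministic topological
order of $Q$ (ties broken by smallest contained variable index, so indices
are stable across runs) together with the coupling schemes needed to fold
them back. Two design choices make the round trip trivially auditable:
external parameters manufactured by restriction are *named after the
upstream variable they came from*, so every scheme is an identity map on
names; and `recompose()` restores the original declaration order, so
`recompose(structural_decompose(net))` reproduces the input bit-exactly
(after essential reduction). Bracketing of the fold is associative, which
the test suite checks by building three-module products both ways.

## Dynamic decomposition

If the upstream part sits on an attractor $C_1 = (\alpha_1,\dots,\alpha_r)$,
the downstream part sees the periodic input $g(t)$, the projection of
$\alpha_{t \bmod r}$ onto the coupled variables, and becomes a
*non-autonomous* network $y(t+1) = F_2(g(t), y(t))$. Its attractors are
computed as the cycles of the finite deterministic *product automaton* on
pairs $(t \bmod r,\, y)$. This construction settles the phase bookkeeping
unambiguously: trajectories of a length-$r$ cycle come in $r$ phases, every
product-automaton cycle visits phase 0, and anchoring each cycle at phase 0
(smallest driven state) makes the composition
$C_1 \oplus C_2$ — pairing $\alpha_{t \bmod r}$ with the driven state at
matching phase — well defined. Composed attractors have length
$\mathrm{lcm}(|C_1|,|C_2|)$ exactly; the combined cycle lists all
$\mathrm{lcm}$ pairs.

`dynamic_decompose()` peels one upstream module at a time (the left-most in
topological order), enumerates its attractors, and handles each in one of
two ways: a steady upstream attractor pins the downstream parameters to
constants, making the remainder autonomous so the decomposition can recurse
fully; a cyclic one drives the remainder through the product automaton.
With an empty coupling the construction degenerates to the cross product,
where the attractor set is the Cartesian product of the factors and the
number of attractors obeys the phase-counting law
$|A(F_1 \times F_2)| = \sum_{C_1, C_2} \gcd(|C_1|,|C_2|)$ — both are used
as independent checks in the tests, alongside exhaustive enumeration, which
the decomposition must (and does) reproduce exactly.

```{r}
net <- parse_rules(c("x1, x2", "x2, x1", "x3, x2 & x4", "x4, x3"))
as_tibble(dynamic_decompose(net))
```

## Robustness, complexity and their trade-off

Phenotypical robustness $r(F)$ labels each vertex of the Boolean hypercube
with the attractor it flows to and reports the fraction of hypercube edges
joining equally labelled vertices. The ordered (per-state, per-flip) and
unordered (per-edge) formulations coincide because the comparison is
symmetric; the implementation uses the unordered form with normalizer
$n2^{n-1}$ — half the work, same value. $r(F)=1$ exactly when there is a
single attractor, since any two basins meet along some cube edge.
`sampled_robustness()` estimates $r$ from single-bit perturbations of
random states (estimates are multiples of $1/\text{samples}$, and the same
draws serve the attractor-count estimate when both are requested);
`derrida_value()` provides the classical one-step measure for comparison.

## The random modular ensemble

`generate_modular_network()` emulates ensembles of random gene-network
models with a prescribed modular structure. Its conventions:

- $N$ nodes in $m$ modules of equal size $N/m$; each module's internal
  wiring is drawn with exactly `in_degree` distinct regulators per node, no
  self-loops, and redrawn until strongly connected. At the reference
  condition (60 nodes, in-degree 3) this rejection sampling needs about 22
  draws on average, a number the acceptance script recomputes.
- The module DAG is a uniformly drawn weakly connected lower-triangular
  binary matrix with unit diagonal, obtained by rejection from unbiased
  off-diagonal coin flips.
- Every off-diagonal 1-entry contributes **exactly one** cross-module edge,
  and that edge **replaces** one intra-module regulator of the target node
  (redrawn if the removal would break the donor module's internal strong
  connectivity). Replacement is the only reading that keeps the global
  in-degree fixed while coupling the modules, and the in-degree constraint
  is what makes robustness comparable across $m$; the alternative (raising
  the in-degree of coupled nodes) would confound the comparison.
- All rules are nested canalizing functions (NCFs) on their final regulator
  sets, the rule class that dominates published expert-curated models. The
  sampler draws a uniform input order, uniform canalizing input values and
  uniform canalized outputs, with the default output of the last layer
  complemented so that every input is essential; an independent recursive
  checker (`is_nested_canalizing()`) validates every emitted table in the
  tests. Essentiality of every regulator guarantees the generated wiring
  diagram is exactly the drawn one, hence the SCC count is exactly $m$.
- No self-loops are generated: a singleton's self-loop would not make its
  SCC non-trivial, and self-loops would artificially inflate intra-module
  connectivity.
- One seed fixes the whole construction; the same seed yields a
  bit-identical network.

What the ensemble does **not** emulate: heterogeneous in-degrees, scale-free
wiring, unequal module sizes, biased truth tables, or the particular logic
of any real regulatory system. Passing tests on this ensemble therefore
support the decomposition and control theory on *all* networks (those
results are exact) but support the robustness–modularity findings only as
tendencies of this stylised ensemble.

## The simulation pipeline

`run_experiment()` generates networks per module count, follows a common
set of random initial states to attractors (complexity lower bound), reuses
those states with one random bit flip each for the robustness estimate, and
returns one tidy record per network. Desk-scale defaults are $N = 12$,
$m \in \{1,2,3\}$, in-degree 3, a few hundred networks per condition and
500 restarts per network; with module size required to exceed the
in-degree, $m \le 3$ is the usable range at $N = 12$. These sizes keep a
full run in seconds while the qualitative orderings — complexity increasing
in $m$, robustness at fixed complexity increasing in $m$ — emerge as
statistical tendencies, not per-seed guarantees; the reference study behind
this design ran at 60 nodes with tens of thousands of networks per
condition, far beyond a desk-scale test budget, and its fitted curves are
figure-only, so no numerical reproduction of them is attempted.

The trade-off between robustness and complexity is summarised by fitting
$y = \alpha + (1-\alpha)e^{-k(x-1)}$ to mean robustness per attractor
count: $\alpha$ is the robustness floor retained at high complexity, $k$
the decay rate, and the curve passes through $(1,1)$ by construction
because single-attractor networks have $r = 1$ exactly. The fit uses
Levenberg–Marquardt least squares with $\alpha$ box-constrained to $[0,1]$,
started at the empirical minimum of $y$; bins holding fewer than 5 networks
are excluded because sparse means destabilise the fit. Exact recovery of
planted $(\alpha, k)$ on noise-free curve data is part of the test suite.

```{r, fig.width = 5, fig.height = 3.2}
rec <- run_experiment(N = 12, module_counts = 1:3, in_degree = 3,
                      networks_per_condition = 50, n_samples = 200,
                      seed = 1)
summarize_experiment(rec)$by_m
plot_complexity_ecdf(rec)
```

## Control by module composition

Controls pin a node to a constant, delete it (pinned to 0 and substituted
out of every rule), or fix/sever one edge (the source read as a constant
inside the target rule only — the constant-substitution convention; both
deletion constants are stated explicitly in the documentation and used
consistently). A control set *stabilizes* a network at $C$ when the
controlled network has $C$ as its only attractor; controlled variables stay
in the network with constant rules so states remain comparable.

The composition theorem makes control modular: controls stabilizing $F_1$
at $C_1$ and the driven $F_2^{C_1}$ at $C_2$ jointly stabilize
$F_1 \rtimes_P F_2$ at $C_1 \oplus C_2$, *provided $C_1$ or $C_2$ is a
steady state*. `compose_module_controls()` walks the modules in topological
order, verifies each module control against the already-stabilized upstream
trajectory, refuses compositions where both sides are cyclic (the theorem's
hypothesis; no attempt is made to go beyond it), and re-verifies the union
on the full network. `search_minimal_controls()` provides the brute-force
baseline on small networks; the module-by-module strategy can occasionally
return more controls than a global search, which is why the tests compare
both on a worked example.

## Numerical choices and limitations

- State codes are integers (hence the $n \le 24$ sweep guard and an
  $n \le 30$ code limit); trajectory-level functions fall back to per-state
  stepping with hashed cycle detection for any $n$.
- Truth tables are flat 0/1 vectors indexed by regulator values read as a
  binary number, first regulator most significant; serialization emits
  disjunctive normal form, so `parse -> serialize -> parse` is the identity
  on reduced networks.
- Attractor equality is canonical-rotation equality; sampled attractor
  comparisons therefore identify limit cycles up to rotation.
- All stochastic entry points take a single seed and draw everything from
  it; re-running with the same seed reproduces results bit-exactly.
- Exhaustive verification (and hence `verify_stabilization()`'s default
  oracle cross-check in the tests) is limited to desk-scale networks;
  beyond the guard only sampling-based statements are available.
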