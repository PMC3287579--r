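---
title: "Censusing the state space of hybrid Boolean network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censusing the state space of hybrid Boolean network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnss)
```

## The model and its assumptions

A Boolean network model of a signaling pathway assigns each of N
components a binary state σᵢ and a logical update rule over its
regulators.  The operator conventions are the standard ones for logical
models: regulators that can each activate a target on their own are
joined with OR; regulators that are jointly required are joined with
AND; inhibition is NOT.  `bnss` adds two departures from the purely
deterministic picture, both motivated by how signaling models are
actually built:

* **Free nodes.**  Components with no characterised regulation (a
  receptor whose upstream input is unknown, say) are not given an
  arbitrary rule; they are declared `RANDOM` and redrawn independently
  as Bernoulli(1/2) at every update.  The interactions stay
  deterministic, but the network as a whole evolves stochastically — a
  hybrid dynamics whose trajectories are samples from a finite Markov
  chain, not orbits of a map.
* **Clamps.**  A sustained stimulus (hormone present) or a genetic
  perturbation (knockout) is modelled by holding a node at a fixed value
  at *every* update, including t = 0.  A clamp overrides both the
  node's rule and its FREE status.  This is deliberately not the same
  as changing the initial condition: a clamped knockout can never be
  re-activated by upstream logic.

Two update schemes are provided because the field uses both and they
genuinely differ.  Under **synchronous** update every rule reads the
state at time t; under **sequential** update nodes are swept in
declaration order, each rule reading the partially updated state, with
free draws made at the node's position in the sweep.  Synchronous is
the default: it is the scheme whose transition semantics ("the rules
acting at t determine the state at t+1") is unambiguous, and it makes
the engine-versus-oracle comparison exact.  The sequential order is the
declaration order of the rule file — no random permutation — because a
fixed order maximises reproducibility; users who care about update-order
artefacts should compare the two modes rather than rely on either.

## What the analyses compute

Write Σₜ for the state vector at update t.  A run of t_m updates from
one initial condition records the trajectory {Σ₀, …, Σ_{t_m}} (the
initial state is recorded by default; `record_initial = FALSE` drops
it, and the census then counts t_m states — the convention is exposed
because published counts rarely say which was used).

* **Census.**  Recorded states are grouped by exact identity over *all*
  nodes — free and clamped included — i.e. Hamming distance 0.  The
  census stores visit times and counts; the number of distinct states is
  the sampled cardinality of the space of states, bounded by Ω = 2^N.
  Cardinality statistics over an ensemble report the per-run
  cardinalities, their mean and sample standard deviation (n − 1
  denominator, the reporting norm).
* **Frozen/variable partition.**  A node is frozen iff it shows one
  constant value at every recorded update ≥ burn-in in *every* run.
  The definition is ensemble-wide on purpose: a node that is constant
  within each run but takes different values across initial conditions
  (a bistable switch) is variable, because one partition is meant to
  characterise the network, not a single run.  Adding runs can only
  shrink the frozen set.  A clamped node is always frozen at its clamp
  value.
* **Synchrony.**  Variable nodes whose recorded value sequences
  (concatenated across runs, post burn-in) are *exactly* equal form a
  synchrony group; with `include_complementary = TRUE` an exactly
  negated sequence joins with a flag.  Exactness is deliberate — the
  interesting biological statement is "these nodes are always in the
  same state", and a tolerance would dilute it to a correlation claim.
  The pairwise `joint_census` is the occupancy version: a 2×2 table
  over recorded states, with the verdict `synchronized_equal` when the
  off-diagonal cells are empty, `synchronized_opposite` when the
  diagonal is, `unsynchronized` otherwise.
* **Efficiency.**  For a designated output node, the fraction of runs
  in which it is True at each update — the population-level phenotype
  curve on which wild-type and knockouts are compared.
* **Mutant comparison.**  `compare_networks` runs the base network and
  each single-node False-clamp mutant under one configuration and
  reports cardinality, partition, top states and (optionally)
  efficiency per network, plus the intersection of the variable sets —
  the nodes that stay variable under every perturbation.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `updates` (t_m) | 20 (CLI) | update sweeps | typical signaling transients resolve within ~20 sweeps; census studies use 100–300 |
| `n_runs` | 30 (CLI) | replicate runs | 30 random initial conditions is the usual scale for cardinality mean ± SD; 300 for efficiency curves |
| `burn_in` | 0 | update index | censuses default to counting everything; for transient-sensitive analyses (partition, synchrony, joint census) a burn-in of 4 is recommended — hybrid signaling models settle after roughly 3–4 updates |
| `mode` | synchronous | — | see above |
| `seed` | required | — | every random draw derives from (seed, run index) via a fixed integer hash, so ensembles are order-independent and bit-reproducible |
| `record_initial` | TRUE | — | whether Σ₀ is counted; affects all census totals by one state per run |

## The exact oracle

For networks of up to 12 nodes (16 for deterministic maps)
`enumerate_dynamics` builds the full transition structure: a sparse
row-stochastic matrix over all 2^N states, with each state branching
uniformly over its 2^F free-draw outcomes (at the node's sweep position
in sequential mode, so oracle and engine semantics coincide exactly).
Recurrent classes are the strongly connected components of the
transition graph with no outgoing edges — computed by condensation via
igraph — and a stationary distribution is solved exactly on each class
by a dense linear solve (classes here are tiny; π = πP holds to 1e−12,
checked in the tests).  For a deterministic cycle this reduces to the
uniform time-average.  The oracle is the package's ground truth: the
acceptance tests require sampled state frequencies to match stationary
distributions within total variation 0.05 at 20,000 updates, and frozen
sets and synchronization verdicts to match exactly.

A subtlety worth recording: the oracle's frozen set is defined from the
recurrent classes *reachable from clamp-consistent starting states*,
because the empirical classifier sees trajectories started from random
valid initial conditions and (after burn-in) confined to those classes.
Comparing against all recurrent classes would be wrong whenever
unreachable attractors exist.

## What the synthetic data does and does not establish

The bundled fixtures (`toy_fixtures()`) and the random-network generator
are the package's test world.  The toys are chosen so every claimed
behaviour has a hand-checkable counterpart: a pure 4-cycle (T1), a
bistable network whose partition differs per-run versus ensemble-wide
(T2), a free node driving two followers into perfect synchrony
(T3prime), a constant network, and a 6-node mix of clamp, free node and
logic (mix6).  The generator produces NK-style random networks —
fixed in-degree k, random AND/OR combinations with per-leaf negation,
a designated free fraction — which exercise the parser, engine and
analyses over hundreds of structures.

What a green suite establishes: the engine's sampling statistics agree
with exact Markov-chain quantities on small networks; the analyses
satisfy their conservation laws and invariants on arbitrary generated
networks; the whole pipeline is bit-reproducible.  What it does not
establish: anything about a specific published biological model.  The
43-node stomatal-closure network that motivates the method ships only
as a user-transcription template (its rule table belongs to its source
publication); until a user transcribes it, the wild-type/mutant numbers
associated with that model are outside what this package can verify.
Real rule tables are also sparser and more heterogeneous than the
generator's fixed-k expressions, and real models often use priority or
asynchronous-random update classes, which are out of scope here.

## Numerical and design choices

* State identity uses all nodes, including free and clamped ones; two
  visits to the same logic state with different free-node draws are
  different states.  This matches the Hamming-distance definition over
  the full state vector.
* `top_states` breaks count ties by earliest first visit, then by
  lexicographic bit string — reports are deterministic.
* Per-run RNG streams come from a multiplicative hash of
  (seed, run index) folded into [1, 2³¹ − 2]; run 3 of a 30-run
  ensemble equals run 3 simulated alone.
* The stationary solver uses the recurrent-class decomposition plus a
  least-squares solve of the augmented system (πᵀ(P − I) = 0, Σπ = 1);
  negative round-off below 1e−12 is clipped and the vector renormalised.
* Degenerate inputs: an empty rule file, a duplicate node, an undefined
  regulator, a malformed expression and a clamp on an undeclared node
  are all rejected with typed conditions (`bn_parse_error`,
  `bn_validation_error`, `bn_unknown_node`) carrying line numbers where
  applicable; `burn_in` that leaves no recorded states is an error, not
  an empty census.
* The CLI accepts a JSON configuration file as an alternative to flags
  (flags win).  YAML was considered and dropped: no YAML parser is a
  package dependency, and JSON covers the manifest-driven
  reproducibility workflow.

## Known limitations

* The exact oracle is brute force by design; beyond ~12 nodes use
  sampling only.  No BDD/symbolic attractor detection.
* Sequential mode fixes the declaration order; ranked/priority and
  random-order asynchronous schemes are not implemented.
* Efficiency curves are descriptive; no statistical comparison between
  curves is provided.
* The engine is pure R and comfortable at the scale the analyses target
  (hundreds of runs × hundreds of updates × tens of nodes); it is not a
  tool for 10⁶-update chains on large networks.
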