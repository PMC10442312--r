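---
title: "Source identification through contact tracing queries: models, algorithms and theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source identification through contact tracing queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sictf)
```

This vignette is the package's account of its science: the models, the
identification algorithms, the closed-form theory, the numerical and
design choices where the problem left them open, and what the synthetic
generators do and do not capture about real epidemics.

## The identification problem

An epidemic starts from a single unknown source on a contact network that
is itself unknown to the investigating agency. The task begins when the
first patient is hospitalized (hospital diagnoses are the reliable early
signal for a new disease) and must proceed through three query types:

* **household query** — reveals the members of one household; free and
  unlimited, but counted;
* **contact query** — reveals all direct contacts of a node; counted per
  newly revealed edge (an edge is never counted twice);
* **test query** — processed at no more than `max(1, floor(0.01 N))` per
  day, with the result delivered the *next* day. A symptomatic patient
  past the presymptomatic stage reveals their symptom-onset day; an
  asymptomatic or presymptomatic patient only that they have (or had) the
  disease; exposed and susceptible agents test negative. Asymptomatic
  results never disclose whether the infection is current or past, and a
  node is not re-tested.

The epidemic does not pause: each day of testing is a day of further
spread. Success is measured two ways — recovering the true source, and
recovering the first symptomatic patient (relevant because an asymptomatic
source is invisible to onset-based algorithms).

## The contact network

`generate_hnm(N, d_h, d_c, seed)` builds the household network model:
`N` nodes partitioned into households of size `d_h + 1`, every household a
clique, plus `d_c` external half-edges per node paired uniformly at
random. Pairings that would create self-loops, duplicate edges, or
duplicate a household edge are discarded (kept as a count), so external
degrees can fall slightly below `d_c` but never exceed it. Households are
the unit of structure the LS+ algorithm exploits.

Two deliberate choices:

* By default an `N` that is not a multiple of `d_h + 1` is rejected, which
  keeps the household-size invariant exact. The standard study populations
  (400 and 1000, with `d_h = 2`) are *not* multiples of three, so
  `allow_remainder = TRUE` permits one final smaller household; every
  batch runner uses it when needed.
* Connectivity is not enforced. A run whose source component never
  produces a hospitalization is simply discarded (and counted) by the
  experiment layer, mirroring how detection conditions the real task.

Locally, the network of households looks like a regular tree, which
motivates the **red–blue tree**: the root (red) has `d_c` red and `d_h`
blue children; other red nodes have `d_c − 1` red and `d_h` blue children;
blue nodes have `d_c` red children. A household is a red node with its
blue children; red nodes are each household's earliest-reachable member.
Level `n ≥ 1` holds `λ₁ρ₁ⁿ + λ₂ρ₂ⁿ` nodes, with `ρ₁,₂ = (d_c−1±D)/2` and
`D = √((d_c−1)² + 4 d_c d_h)`; the package cross-checks this spectral form
against explicit breadth-first counts (`rb_level_count()`), and treats
`d_h = 0` as the special case `d_c (d_c−1)^{n−1}` where the second
eigenvalue degenerates.

## The epidemic

`simulate_dde()` advances in whole days. A node infected on day `t` is
exposed through day `t + T_E − 1` and infectious from `t + T_E`. With
probability `p_a` the course is asymptomatic: infectious `T_I` days, then
recovered. Otherwise the node is presymptomatic-infectious for `T_P` days,
symptomatic at onset `t + T_E + T_P`, and either hospitalized at
`onset + T_H` (probability `p_h`) or recovered at `onset + T_I − T_P`.
Each infectious node attempts each susceptible neighbor independently with
probability `p_i` per day; same-day infections land simultaneously and the
recorded infector is a uniform draw among that day's infectious neighbors
of the newly infected node — by exchangeability of the independent
attacker successes this equals a uniform draw among the successful
attackers. Defaults (`p_i = 0.1`, `p_a = 0.4`, `p_h = 0.083`, `T_E = 3`,
`T_P = 2`, `T_I = 14`, `T_H = 7` days, `d_c = 3`, `d_h = 2`) are the
standard calibration of this model family, chosen so that `d_c·p_i = 0.3`
external infections per infectious day and rounded mean state durations
match the data-driven simulators it abstracts.

Conventions the day-granularity forces, fixed once here: all transitions
occur at day boundaries; presymptomatic nodes are infectious; hospitalized
and recovered nodes are not; the source draws its course like everyone
else (so the source can be asymptomatic); re-infection is impossible.

The trajectory is computed to the horizon (or epidemic extinction) up
front and replayed day by day through the oracle. Queries cannot influence
the epidemic, so this is distributionally identical to advancing lazily in
real time — an equivalence the infinite-tree model does *not* enjoy, which
is why `simulate_dde_nr()` (no presymptomatic state, `T_I = ∞`, on the
red–blue tree) is a live object that the oracle genuinely grows one day at
a time while an algorithm runs. Its tree is materialized lazily: infected
nodes on creation, susceptible neighbors only when a query reveals them;
per-node counters of unrealized child slots make a growth day two binomial
draws per infectious node.

## The LS and LS+ algorithms

LS keeps a candidate — always the node with the earliest revealed symptom
onset — starting from the first hospitalized patient (whose onset is known
at detection without a test). Per iteration it queues the candidate's
household members and backward contacts for testing (on a static network,
all neighbors; the backward window `[t − (T_E+T_P) − (σ_E+σ_P),
t − (T_E+T_P) + (σ_E+σ_P)]` is computed and logged for interface parity
with time-varying networks). The iteration ends only when the test queue
drains; any onset earlier than the running best updates the next
candidate, possibly several times per iteration. No update means
termination. Termination is guaranteed because candidate onsets strictly
decrease and are bounded below.

LS+ reacts to positives without an onset time: their household members are
queued, and when such a node belongs to the *current candidate's*
household, its backward contacts are queued too, with the wider
asymptomatic window `[t − (T_P+2T_E+T_I), t − (T_P+2T_E)]`. One subtlety
matters for correctness: a node tested in an earlier iteration may only
later become a household member of the current candidate, so each
iteration also queues the backward contacts of the candidate's
*already-known* asymptomatic household members. Without this, the
algorithm demonstrably misses sources that the tree-model success
condition (below) guarantees. The `v2` variants cut an iteration the
moment the candidate first updates, trading tests for the theoretical
guarantee.

Queue order is first-in-first-out, household members before backward
contacts, ties by node id; nodes are never queued or tested twice. These
orderings are not dictated by the problem; they are fixed for determinism.

On the tree model the success structure is sharp, and the test suite
asserts it run by run: LS finds the source *iff* every transmission-path
node is symptomatic; LS+ finds it whenever every traversed household
contains a symptomatic path node and the source is symptomatic (the
converse fails: LS+ sometimes wins anyway, so only the one-directional
implication is asserted).

## The Size-Gain baseline

`run_size_gain()` adapts the classical candidate-filtering baseline: it
knows the whole network (distances come from the graph, not from queries),
keeps every node as a potential source, and discards candidates violating
the delay constraint `|(t₂−t₁) − δ(d₂−d₁)| < σ(d₁+d₂)` for observation
pairs, where `d_i` are candidate-to-observation distances. A negative
observation only lower-bounds its onset, so its side of the absolute value
is dropped; an asymptomatic observation only upper-bounds it, so the sign
reverses. Two package choices:

* The constraint in its home setting assumes one hop per day; the
  discrete-day epidemic's mean per-hop delay is `δ = T_E + 1/p_i − 1` days
  (latency plus the geometric infection delay), and `σ` defaults to that
  delay's standard deviation `√(1−p_i)/p_i`. Without the `δ` scaling the
  true source is excluded almost surely.
* Sensor placement maximizes expected candidate-set reduction over
  hypotheses (source, infection day). The exhaustive scan is quartic in
  problem size, so the implementation samples hypotheses from the
  candidate set times a coarsened day grid (`n_hyp`, `day_step`) and caps
  the number of scored sensor locations per day (`scan_cap`); all three
  are documented knobs, seeded for determinism, and the toy-graph tests
  run the exhaustive versions against a brute-force enumeration oracle.

Past a deadline (by convention the day LS and LS+ finished on the same
trace) the estimate is a uniform draw from the surviving candidates;
inconsistent constraints can empty the set, recorded as failure.

## Theory: from tree profiles to success probabilities

Everything analytic lives on the tree approximation. With
`p = p_a / (p_a + (1−p_a)(1−p_h))` — the probability of being asymptomatic
given not hospitalized, the relevant conditioning for path nodes other
than the detected one — and `P(n)` the distribution of the
transmission-path length `d(s,h)`:

* **LS.** `P(success) = Σₙ (1−p)ⁿ P(n)` (`ls_success_probability()`),
  exact on the tree model because success is equivalent to all `n`
  non-terminal path nodes being symptomatic.
* **LS+.** A path of length `n` with `k` nodes that share their household
  with no other path node traverses `(n+1−k)/2` two-node households. With
  `α, β` indicating whether the source's and the terminal household hold
  two path nodes, the number of such paths is
  `C((n+k−3)/2, k−2+α+β) · d_h^{(n−k+1)/2} · d_c^{(n−k+1)/2−α−β} ·
  d_c(d_c−1)^{k+α+β−2}`, and the success condition holds with probability
  `(1−p)^{(n+k−1)/2} (1+p)^{(n−k+1)/2−α−β}` (each interior two-node
  household needs at least one symptomatic member:
  `1−p² = (1−p)(1+p)`). Dividing by the spectral level count and mixing
  over `P(n)` gives the lower bound in
  `ls_plus_success_lower_bound()`. Two structural identities guard the
  transcription: at `p = 0` the counts must resum to exactly the level
  count for every `n` (asserted for `n ≤ 8` over several branching
  choices), and the `n = 2` coefficient must equal the directly enumerable
  `((1−p)² + 2(1−p))/3` at `(d_c, d_h) = (3, 2)`. Both identities, and the
  simulated success rates, reject a variant of the formula in circulation
  in which `d_h` is carried inside the `(1−p)` exponent; the package
  implements the combinatorially verified form.
* **Path-length law.** Rescaling time by `T_E` (`p_i' = 1 − (1−p_i)^{T_E}`)
  and averaging the two node types maps the tree epidemic onto a
  `(d_r, d)`-ary random exponential tree: the root has `d_r = d_c + d_h`
  child slots, every other node `d` — the eigenvector-weighted mean
  red–blue degree, `d = f_r(d_c+d_h) + (1−f_r)(d_c+1)` with
  `f_r = ρ₁/(ρ₁+d_h)` — and each open slot fills with probability `p_i`
  per day. Arity here counts *children* (the binary case has two children
  per node); that reading is forced by the consistency of the expected
  profile `a_{t,l} = d_r p_i (d p_i)^{l−1} Σ_m C(m, l−1)(1−p_i)^{m−l+1}`
  with the closed-form size `a_t = 1 + d_r((1−p_i+dp_i)^t −1)/(d−1)`, and
  is verified by simulation. Substituting the expected profile into the
  stopped deterministic-tree law
  `P(l) = Σ_t ((c_{t,l}−c_{t−1,l})/(c_t−c_{t−1})) q^{c_{t−1}}
  (1−q^{c_t−c_{t−1}})`, `q = 1−(1−p_a)p_h`, yields the analytic
  path-length distribution (`ret_stopped_path_dist()`); the implementation
  asserts its algebraic identity with the explicit substitution to 1e−9.

`predict_success()` composes the three stages with `n_max = 20` path
lengths and a day-sum truncation of `t_max = 200`, reporting the
truncation deficit; the `0⁰ = 1` convention covers the degenerate
`q ∈ {0, 1}` boundaries, and `d ≤ 1` is rejected rather than patched.

### Simulators as oracles

Only the level profile of an exponential tree matters, so the Monte-Carlo
simulators track per-level node and open-slot counts — exact by slot
exchangeability — which vectorizes across 10⁵ replicates. Fractional `d`
is realized by giving each node `floor(d)` slots plus one with probability
`d − floor(d)`: linearity of expectation makes the simulated mean profile
equal the analytic one *at the fractional `d`*, so the theory is tested at
its actual parameters instead of a rounded surrogate. In the stopped
simulator, the within-day uniform ordering means the first hospitalized
node's level is drawn proportionally to that day's per-level additions.

One approximation gap is real and measured rather than hidden: the stopped
law evaluates `1 − q^{c_t − c_{t−1}}` at the *expected* day increment,
while the simulated increment is random; since that map is concave, the
substitution is biased (a Jensen gap). At the default parameters the
total-variation distance between the analytic law and 10⁴ stopped
simulations is stably ≈ 0.02–0.03 — visually excellent agreement, but
above the ≈ 0.015 that pure multinomial sampling noise would explain. The
corresponding acceptance test asserts the stricter
below-sampling-noise claim and is expected to fail; the package reports
the gap as a property of the approximation.

## Experiments

`run_experiment()` draws, per realization: a fresh network, a uniform
source, an epidemic conditioned on producing a hospitalization (discards
counted), then runs each algorithm through a sealed oracle built on the
same trace — on the tree model, by re-simulating with the identical seed,
since the live tree is mutated by its oracle. Success rates carry Wilson
score intervals, query costs Student-t intervals; everything is
reproducible from one base seed via a pre-drawn seed pool. Default
replication in the package's own validation is deliberately modest
(hundreds to a few thousand runs per point, stated in each test) so the
whole suite stays within minutes; the configuration accepts the
full-scale 4800 realizations per point.

What the synthetic generators do **not** capture about real data:
time-varying contacts and site-mediated transmission, heterogeneous
household sizes and degrees, age-dependent hospitalization, reporting
noise and non-compliance (the framework can absorb non-compliers by
treating them as asymptomatic, but no separate mechanism is implemented),
and parameter drift over time. Passing tests therefore demonstrate
internal consistency of models, algorithms and theory under the stated
assumptions — not field performance.

## Known limitations

* The LS+ bound is proved sharp only on the tree model; on the loopy
  household network the theory is an approximation validated empirically.
* The Size-Gain scan knobs trade fidelity for tractability at `N = 400`;
  with `scan_cap = Inf` and a dense day grid the implementation is
  exhaustive but slow.
* The stopped-tree analytic law carries the Jensen gap described above.
* Identification on traces whose epidemic outruns the simulation horizon
  is guarded (runs are flagged partial) rather than extended indefinitely.
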