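---
title: "Simulating cumulative culture on combinatorial technology trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cumulative culture on combinatorial technology trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`totemsim` simulates a crafting game that has become a standard paradigm
for studying cumulative cultural evolution. Players (here: automated
random-search agents, "bots") start with six freely available base
resources and a four-slot workshop. A workshop attempt is an unordered
multiset of one to four items — repetition allowed, order never
meaningful — and succeeds exactly when it matches the input multiset of
one of the hidden crafting recipes, producing that recipe's output. The
recipe set forms a *technology tree*: 27 intermediate items (tools,
parts) and 115 *logs*, the high-value items that can be placed, one to
three at a time, into a totem panel. Because multisets with repetition
grow combinatorially, undirected search gets harder as the pool grows:
6 items offer `sum(choose(6 + k - 1, k))` = 209 distinct attempts,
10 items already offer 1,000, and the 115 log types admit 266,915
distinct totems.

An agent's final score is the score of its best totem (zero if none)
plus 15 points per distinct item it produced itself. A totem of logs
with values $v_1, \dots, v_k$ ($k \le 3$) scores

$$ S = \Big(\sum_i v_i\Big)\,(1 + \beta\,\alpha), \qquad
   \alpha = \#\{\text{distinct logs}\} - 1 \in \{0, 1, 2\}, $$

with $\beta = 0.5$ by default, so a fully diverse totem doubles its
value sum. Only the $\alpha$ rule and the monotone dependence on value
and diversity are fixed by the paradigm; the multiplicative form is this
package's choice — the simplest formula with those properties — and it
is pluggable (`score_params(totem_formula = ...)`) so alternative forms
(e.g. an additive diversity bonus) can be swapped in without touching
anything else.

## The tree generator

The original game's recipe list is not public, so the generator is a
structural surrogate: any tree satisfying the game's stated invariants
is acceptable, and experiments average over tree realizations by
default. The invariants enforced (and re-checked by `validate_tree()`)
are: one recipe per non-base item with a globally unique input multiset
of size 1–4; acyclicity and reachability of every item from the base
resources; *usefulness* — every intermediate lies in at least one log's
innovation closure; and a minimum depth for "basic" logs, which must
embody at least eight innovations (`min_basic_log_closure = 8`).

Generation is layered, which makes acyclicity and reachability true by
construction. Intermediates draw recipe inputs from the items already
placed, weighted by `1 + complexity` so that deep chains form; the first
seven intermediates form a spine of strictly increasing depth, which
guarantees — for every seed, not just typically — that an intermediate
of complexity ≥ 7 exists to anchor the basic log. Non-basic logs are
*refinements*: each combines one existing log with intermediate items,
mirroring the game's log-refinement with tools; while any intermediate
is still in no log's closure, the next log recipe is forced to include
one, which makes usefulness deterministic as well. Infeasible parameter
combinations (e.g. a depth requirement exceeding the intermediate
count) are rejected with the violated constraint named.

An item's *complexity* is the size of its innovation closure — the set
of recipes that must be executed to reach it from the base resources.
`innovation_closure()` is checked in the test suite against an
independent forward-production oracle.

## Log values

Each log gets a unique integer point value drawn from its complexity
tier's interval. Tier intervals are consecutive, disjoint and increasing
with closure size, so *more complex is always strictly more valuable*,
while equal-complexity logs differ in value within a tier. The lowest
tier is forced to contain the floor, 50 points, so the cheapest
single-log totem scores exactly 50 (the game's printed minimum). The
default ceiling parameter is 1235 points: with the default formula the
best conceivable totem (three distinct top-value logs) then scores
$2 \times 3 \times 1235 = 7410$, matching the printed maximum of the
original game. That ceiling depends on the unpublished value assignment
and is therefore a calibration, not an asserted result.

## Agents

Bots perform undirected random search: slot count $N$ uniform on
1–4, then $N$ independent uniform draws *with replacement* from the
currently visible pool, canonicalized to a multiset. The induced
distribution over multisets is deliberately non-uniform (ordered draws
pool their probability onto their sorted form); this follows directly
from the stated two-step draw. Each agent has a budget of 188 *unique*
attempts — the empirical mean number of unique combinations humans
produced in a session — and collisions with its own attempt history cost
nothing. Collisions are resolved by redrawing; if 1,000 consecutive
collisions occur on a small pool, the simulator switches to exact
enumeration of the untried multisets and draws one from the exact
conditional distribution of the two-step process, so the fallback does
not distort the search. A fully exhausted design space (possible only on
toy trees, since 188 < 209) ends the run early and is recorded.

Successes are immediately usable: a produced item joins the pool before
the next attempt. An agent's innovation record counts items *it
produced itself*, even when a groupmate found them first — mirroring how
human scores counted own production. By default a bot's totem is scored
over its own produced logs; the `totem_from_visible` flag switches to
scoring over all logs visible to it, the other reading of an ambiguous
antecedent in the source paradigm.

## Population structures

Three variants: `isolated` (no social information), `complete_group`
(default six agents, everyone permanently sees everyone's innovations,
instantly usable), and `metapopulation` (default 3 × 2: six agents
re-partitioned into three reciprocal pairs every epoch). A 45-minute
session with ties re-drawn every 3 minutes gives the default of 15
epochs; each agent's budget is split evenly across epochs (the remainder
goes to the earliest epochs) and agents advance round-robin, so attempt
counts never differ by more than one at any time.

Epoch matchings are sampled by shuffling the agents and chunking — every
perfect matching is the image of the same number of permutations, so
this is *exactly* uniform over the 15 matchings on six agents, with no
rejection loop; the test suite checks uniformity jointly (all 15
matchings, chi-square) and marginally (partner uniform among five). Under
uniform matching a given pair connects in an epoch with probability 1/5,
hence within 15 epochs with probability $1 - (4/5)^{15} \approx 0.965$ —
the design's "almost every pair meets" property, verified by Monte
Carlo.

When ties rotate, the default is *no retention*: another agent's item is
usable only while its producer is a current neighbor (own production is
always permanent). The original paradigm is silent here — human players
made borrowed knowledge permanent by reproducing it, which random bots
rarely do — so the alternative is exposed as `retention = TRUE` rather
than hard-coded. Bots under partial connectivity are a simulator
generalization; the original bot runs used only isolated agents and
complete groups of six.

## Experiments, seeding, and reproducibility

`run_experiment()` runs `n_replicates` independent replicates of a
treatment; replicate $i$ uses the derived seed
`derive_seed(master_seed, i)`, a fixed affine hash, so any replicate can
be reproduced in isolation. By default every replicate generates a fresh
tree and fresh log values, so summaries average over realizations of the
innovation landscape; `fresh_tree = FALSE` (or passing a fixed
`techtree`) reuses a single landscape, which is what the original
bot simulations did with their fixed game tree — both modes are
supported because the original tree is unrecoverable. Summaries report
the per-agent mean and standard deviation of final scores, the fraction
of agents building a totem, and a percentile bootstrap CI of the mean
(1,000 resamples).

Every stochastic entry point takes a `seed`; identical seeds give
bit-identical event logs. Internally the hot loop encodes a combination
as a base-$M$ integer over the ranks of its sorted items ($M$ = item
count + 1), which is a bijective image of the canonical multiset key;
this is an implementation detail verified to leave trajectories
unchanged relative to the direct string-key implementation.

## What the simulations do and do not show

The test suite replicates the *qualitative* bot results at 1,000
replicates on default-sized trees: fully connected groups of six
out-innovate isolated agents on average (one-sided resampling check),
and essentially no isolated bot ever builds a totem — reaching a log
requires at least eight nested successes within 188 random attempts
against a combinatorially exploding space. The original study's exact
bot summary numbers (mean scores of 51 and 99, the 0.004% totem rate
among social bots) depend on the unpublished recipe tree and are *not*
reproduction targets; on surrogate trees only directions and orders of
magnitude are meaningful. Human results (guided variation, partial
information) are entirely out of scope: the agents here search at
random, and extending them with heuristic or memory-limited policies is
an extension point, not a feature.

Problem sizes used by the checks — chosen as the package's own test
design — are: exhaustive enumeration oracles up to pool size 8 (slots
≤ 4) and six log types; 100 generation seeds for invariant validation;
10,000 schedules for matching uniformity; 1,000 replicates for the
social-versus-isolated contrast.

## Numerical and degenerate-input choices

Counting uses `choose()` in double precision (exact far beyond the
sizes involved). Log-value tiers require interval widths at least the
tier's log count, else an explicit "too narrow" error. `best_totem()`
breaks score ties deterministically towards the canonically smallest
totem, and searches exhaustively (cost grows as the multiset
coefficient of the available log count — intended for the handful of
logs an agent actually produces). Trees with no logs are valid
landscapes (agents then score innovations only); a tree with no recipes
at all yields 188 recorded failures and score zero.
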