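---
title: "Kinship-driven social networks across the demographic transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship-driven social networks across the demographic transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinnet)
```

## The model

`kinnet` implements an agent-based model of how the demographic
transition — falling fertility together with growing population size —
reshapes the structure of human social networks, and through it the
efficiency of reputation-based norm enforcement.

**Pedigree.** A population grows in strictly non-overlapping
generations. Each agent is a record `(id, gender, ancestry)`, where the
ancestry set holds the ids of the known mother, father and up to four
grandparents. Within a generation, opposite-gender agents whose ancestry
sets are disjoint form life-long monogamous pairs; each pair draws an
independent Poisson(κ) number of children, with independent uniform
genders. κ is the total fertility rate: with `n` agents and close to
`n/2` pairs, about `κ·n/2` children are born, so the population grows by
a factor of roughly κ/2 per generation. The simulation stops at the
first generation whose size reaches the target `n_target` (500 or 2000
by default) and randomly removes agents down to exactly that size.

**Kin graph.** Two agents of the final generation are recognised kin
when their ancestry sets intersect — siblings and first cousins. Kin
recognition deliberately stops at first cousins; extending it one degree
further changes the scale of kin counts but not the qualitative
behaviour. Under constant fertility `k` the closed form
`expected_kin_count(k)` gives `k − 1` siblings and `2k(k − 1)` cousins:
44 same-generation relatives at `k = 5`, collapsing to 5 at `k = 2`.

**Social network.** Every agent maintains exactly ν social contacts
(default ν = 60, a little above the kin supply at the high-fertility
end). Agents with more than ν relatives drop a random subset of kin ties
down to ν; everyone's remaining gap is filled with "friend" edges drawn
uniformly at random between non-kin, until the network is exactly
ν-regular. The mean kin degree d(g) — the average number of relatives an
agent actually has — is the model's fertility proxy: a network is
classified *low-fertility* when `d(g) ≤ ν/3` and *high-fertility* above
that (the boundary counts as low; only a deterministic convention is
needed, boundary cases are measure-zero in simulation).

**Structure metrics.** The local clustering coefficient χᵢ is the
standard closed-triangle fraction: the share of an agent's contact pairs
that are themselves connected. χ is its unweighted mean, δ the mean
shortest-path length over ordered pairs, and the step-count profile
gives the mean number of agents at exact hop distance 0, 1, 2, … from an
ego. On a ν-regular network the distance-1 entry is ν by construction.

**Reputation dynamics.** One randomly chosen focal agent is observed
defecting by one randomly chosen contact. In every later round, each
still-uninformed contact `i` of the focal adopts the bad belief with
probability `1 − (1 − α)^βᵢ`, where βᵢ counts i's informed contacts who
also know the focal — gossip happens between contacts about a shared
acquaintance, and each informed mutual acquaintance is an independent
chance α of transmission. Updates are synchronous: all βᵢ are computed
from the beliefs at the start of the round. Without forgiving, beliefs
only ever switch from neutral to bad, so the informed set grows
monotonically; with forgiving, every bad belief independently reverts
with probability π at the end of each round, and the process can die
out.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| κ (`kappa`) | mean children per couple | swept over 2.5–5.0 | children |
| `n_target` | final population size | 500 / 2000 | agents |
| ν (`nu`) | social capacity | 60 | contacts |
| `n_founders` | founder population | 100 (range 50–100) | agents |
| α (`alpha`) | gossip probability per informed mutual acquaintance | 0.1 | probability/round |
| π (`pi`) | forgiving probability | 0.5 (or none) | probability/round |
| `replicates` | networks per condition | 400 full scale; 50 at test scale | — |
| `max_rounds` | reputation round budget | 100 | rounds |

The κ range covers the classic start and end points of the demographic
transition (hunter-gatherer fertility near 5, post-transition fertility
near replacement); 2.5 rather than 2.0 keeps simulated populations from
collapsing. ν = 60 sits just above the undiluted kin supply at κ = 5, so
that high-fertility agents can fill almost their whole network with kin
while low-fertility agents must recruit mostly friends.

## Design choices

A few points were genuinely open and were resolved as follows.

* **Pair formation** is a greedy random matching: shuffle both genders,
  match each female to the first unmatched male she is unrelated to.
  This is maximal in practice, and surplus agents of the more numerous
  gender simply stay unmatched, which is the intended demographic
  behaviour. A maximum-cardinality matching would differ only in rare
  highly-inbred corner cases.
* **Founders** have empty ancestry rather than sentinel ancestor ids, so
  founders are never recognised kin and are always pairable; the kin
  test degrades gracefully across the first two generations.
* **Mean kin degree** is reported as the per-agent average number of
  relatives (twice the edge count over n), matching the interpretation
  "how many relatives does an average individual have" and the ν-capped
  axis it is compared against.
* **Truncation order.** Over-capacity agents are visited in random
  order, each dropping uniformly chosen kin ties until at ν. Removals
  are symmetric, so a partner may end below ν and later receive friend
  edges. At ν = 60 and κ ≤ 5 truncation is rare, so order effects are
  negligible.
* **Friend completion** is stub matching with restarts: one stub per
  missing contact, random pairing, keep legal pairs (non-kin — including
  kin whose tie was truncated — no duplicates, no self-loops). Small
  residual deficits are finished by enumerating the legal pairs among
  the remaining under-capacity nodes and sampling with stub-multiplicity
  weights; a provably dead-ended residual triggers a fresh restart of
  the friend phase (bounded by `max_restarts`). This samples near-uniform
  fixed-degree completions, which is all the analyses need.
* **Gossip eligibility.** The default `shared_acquaintance` variant lets
  the focal agent's contacts update, with informed mutual contacts as
  transmitters — the reading consistent with gossip "about shared
  acquaintances" and the only one under which news can cover the focal's
  neighbourhood. Two alternatives are selectable for sensitivity
  analysis: `noncontact`, under which only non-contacts of the focal
  update (while transmitters are still the focal's contacts, confining
  the news to the observer's surroundings), and `broadcast`, under which
  any informed neighbour transmits to anyone. All headline analyses use
  the default.
* **Extent denominators.** Spread is recorded both as a fraction of all
  agents and as a fraction of the focal's ν contacts; summaries use the
  contact denominator, since under the default variant the focal's
  contacts are the reachable set.
* **Degenerate inputs.** Agents with fewer than two contacts (possible
  only in imported networks) get clustering 0 rather than NaN;
  disconnected imported networks are summarised over reachable pairs
  with an explicit `connected = FALSE` flag and a warning. Simulated
  ν = 60 networks are, in practice, always connected.

## Reproducibility

All randomness flows through R's global RNG. Top-level drivers take a
`seed` argument; replicate r of a sweep runs under
`derive_seed(master, counter)`, a counter-based derivation, so any
single replicate can be reproduced in isolation. With a fixed seed,
`simulate_pedigree()` is bit-reproducible (same ids, genders and
ancestry sets), and sweep tables are identical across runs.

## What the generator does and does not emulate

The generator reproduces the mechanics that drive the phenomenon of
interest: kin supply scaling with fertility, a fixed personal network
size, and random (non-assortative) friend recruitment. It deliberately
omits mortality schedules, age structure, overlapping generations,
remarriage, affinal (in-law) kinship, and homophilous friend choice.
Real friendship formation is assortative and partly mediated by
geography, which pulls friends closer in the network than a uniform
draw; passing tests therefore demonstrate the structural mechanism, not
a calibrated fit to any empirical society.

One consequence of the stopping rule deserves emphasis. Stopping at the
first generation whose size reaches the target overshoots the target by
up to a factor of κ/2, and the subsequent random thinning removes each
agent's cousins proportionally: thinning a cohort to a fraction ρ keeps
only ρ of everyone's cousins. At κ = 5 the undiluted mean kin degree of
a full cohort is about `2κ² + κ ≈ 55`, but the thinned, analysed
generation typically carries d(g) ≈ 30–45 (and the dilution varies with
where the target happens to fall in the geometric growth ladder). All
fertility-class comparisons therefore classify each replicate by its
realised d(g), not by its nominal κ. The dilution compresses
high-fertility clustering and step-count contrasts relative to an
undiluted cohort; the directional effects are unaffected, but ratio
comparisons between fertility extremes are sensitive to it (see the
package tests for which quantities are asserted as directions versus
ratios).

## Problem sizes used in the tests

The test suite exercises the full study grid — κ ∈ {2.5, 5.0} ×
n ∈ {500, 2000}, ν = 60 — at 50 replicates per cell with two reputation
trajectories per network, alongside brute-force oracle comparisons on
random graphs of up to 50 nodes and closed-form checks on deterministic
pedigrees. Full-scale runs (400 replicates per cell) are a configuration
choice away (`sim_config(replicates = 400)`).

## A worked example

```{r example, eval = FALSE}
set.seed(1)
gen <- simulate_pedigree(kappa = 5, n_target = 500, n_founders = 100)
kin <- build_kin_adjacency(gen)
mean_kin_degree(kin)
net <- add_random_friends(truncate_kin_degree(kin, 60), 60)
network_summary(net)
run_reputation(net, alpha = 0.1, pi = NULL)
```

## Known limitations

* Kin recognition stops at first cousins; societies tracking second
  cousins would show the same mechanism at a larger kin scale.
* Friend edges are uniform random; homophily would moderate (not
  reverse) the clustering decline.
* The reputation model follows a single defection; repeated or multiple
  simultaneous defections, payoffs, and strategy evolution are out of
  scope.
* Trajectory summaries censor the time-to-half-contacts statistic at
  `max_rounds` when spread stalls below half, which is the typical
  low-fertility outcome; censored means are reported as such.
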