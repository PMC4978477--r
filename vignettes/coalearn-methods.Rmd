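---
title: "Corecursive associative learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corecursive associative learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalearn)
```

## The model

Associative learning is treated here as a *corecursive* process. A coalgebra
is a state space together with a step map: a halting predicate, an emission
function producing one observation per step, and a successor function. The
unfold (anamorphism) of a coalgebra from an initial state is the stream of
its emissions. For learning, the state is the pair
(remaining training list, current association network); the halting
predicate tests for an exhausted list; the emission merges the first pair
into the network; and the successor pairs "tail of the list" with that same
merge, `pair_fn(tau, mu)`. Unfolding from `(pairs, g0)` emits the network
snapshots `[g1, ..., gn]`, one per training event.

Two formulations are provided and proven equivalent by the test suite:

* `learn_ext(model, pairs, g0)` — the network is an explicit input
  (external memory);
* `learn_int(model, pairs)` — the exponential transpose (currying) of the
  external model: a function from initial networks to streams. The package
  implements the transpose operationally: `transpose(f)(a)(b) == f(a, b)`,
  with `untranspose` as its pointwise inverse, and `learn_int` is literally
  `transpose` applied to the two-argument external model.

The classical recursive (`rlearn_fold`) and iterative (`ilearn_loop`)
rote-learning productions compute the same final network on every finite
list; they serve as independent oracles for the corecursive model rather
than as alternative implementations of it.

Why a stream and not just a final network? The k-th snapshot depends only on
the first k events (productivity), which justifies reading the stream as the
time course of one evolving network. The prefix property is tested directly:
truncating the list to k events reproduces the first k snapshots.

## Association networks and merge rules

An association network is a directed graph whose edges carry a real-valued
strength and a co-occurrence count. Networks are value-semantic: merges
return new networks, so snapshot histories are cheap for the small graphs
this package targets.

Two merge-rule families are built in.

**Halfway rule.** The first co-occurrence of a (cue, target) pair creates
the edge at strength $\sigma_0$; each further co-occurrence updates
$\sigma \leftarrow (1+\sigma)/2$. Strength increases strictly monotonically
towards the fixed point 1 and halves its distance to 1 on every update, so
it is within $10^{-6}$ of the asymptote after at most 30 updates from any
starting point in (0, 1). The default $\sigma_0 = 0.5$ is a package choice
(the worked examples leave it open): with it, the n-th update of a single
edge sits exactly at $\sigma_n = 1 - 2^{-n}$ — the same trajectory the
update recurrence itself generates — so "first occurrence" needs no special
case in the analysis.

**Rescorla–Wagner rule.** One conditioning trial with present cues $X$,
outcome $O$ and asymptote $\lambda$ updates every present cue's edge to $O$
by $\Delta V_X = \alpha_X \beta (\lambda - \sum V)$, the prediction summed
over all present cues before any strength changes. Parameters: per-cue
salience $\alpha_X \in [0,1]$ (with a configurable default for unlisted
cues, 0.3), learning rate $\beta \in [0,1]$ (default 1), asymptote
$\lambda$ (default 1, overridable per trial). Strengths are deliberately
not clipped to $[0,1]$, so conditioned inhibition is representable. The
closed form for repeated single-cue trials,
$V_n = \lambda(1-(1-\alpha\beta)^n)$, and the blocking effect (a cue
pre-trained to asymptote prevents a co-present novel cue from gaining
strength) are both verified to tight numerical tolerance.

**Decay.** Both rules accept a multiplicative retention factor
`decay` in (0, 1]: every existing strength is multiplied by it before each
merge; 1 (the default) disables it. Normalization variants are out of
scope.

## Typed networks: wide versus narrow learning

A `network_type` partitions the vertex vocabulary into named classes and
lists the allowed (source class, target class) edge signatures, plus a flag
for whether conjunction vertices are representable. Narrow, species-specific
learning profiles are expressed as small signature sets: the rat type
allows odour→food but not colour→food or tone→food; the quail type allows
colour→illness; the pigeon type allows colour→food and tone→shock-avoidance
but not the converse pairings. `validate_pair` classifies vertices by
declared vocabulary or by a `"class:value"` id prefix for open vocabularies,
and `learn_ext` refuses a type-violating list *before any learning* — an
unrepresentable pair means there is no merge function over such networks,
and partial learning would misstate that. `apply_type_map` renames vertices
along a vocabulary map as a graph homomorphism; when the map collapses
vertices, coinciding edges keep the maximum strength (counts are summed, a
package choice: it preserves tally semantics).

## Elemental versus configural encoding

`encode_trial` fixes how a compound stimulus becomes training events. The
elemental schema makes each attribute an independently predictive cue (one
event per attribute). The configural schema builds a single conjunction
vertex from the attribute tuple; the id joins the attribute values in
sorted order with "∧", so it is invariant to the order the attributes are
listed in — "canonical attribute order" is realized as lexicographic order
of values, the simplest convention satisfying order-invariance. The
colour×shape discrimination (an XOR-structured mapping) separates the two:
elementally, every cue co-occurs equally often with both responses, all
recalls tie, and the criterion is never reached; configurally there are
four distinct conjunction cues and one block suffices.

## Rote learning to criterion

`train_to_criterion` repeats blocks of one presentation per event (the
within-block order shuffled by a seeded generator; one presentation per
pair per block is the package's convention) and then tests recall of every
cue. A recall tie counts as *incorrect* — deliberately conservative, so
chance behaviour cannot pass criterion. Recall itself exposes the full
tie-set; the deterministic prediction breaks ties lexicographically on the
target id, a documented convention callers can ignore in favour of the
tie-set.

## The ablation test

`ablate_common_component` flags the model's shared merge machinery as
removed: every `learn_*` call then fails for every list — all learning
capacities stand and fall together — while recall on previously built
networks keeps working, since representability does not factor through the
merge component. This is the operational form of the three-part empirical
schema for a shared (universal) component.

## Synthetic data

`generate_pairlist` produces the two training lists of a two-list design.
In the AB,CD condition the second list uses fresh cues and fresh targets
(no repetition within or between lists); in the AB,ABr condition the second
list re-pairs the first list's cues and targets under a uniform random
derangement, so the vertex sets coincide but no (cue, target) pair recurs.
Output is deterministic given the seed. The generator emulates the
*structure* of list-learning conditions only: no quantitative
trials-to-criterion data accompany the designs it mirrors, so passing tests
establish structural properties (disjointness, derangement, seeded
determinism and the learnability contrasts above), not fits to human or
animal learning curves. Real experimental data would add item-level
salience differences, forgetting between sessions and response noise, none
of which the generator models.

## Numerical and design choices

* **Step budget.** Streams are conceptually infinite; `unfold` therefore
  takes a mandatory budget (default 10,000) and flags whether the halting
  predicate or the budget stopped evaluation. All worked examples are
  finite and far below the default.
* **Emission order.** Outputs are collected head-first (temporal order);
  the halting branch emits nothing.
* **Right-associated fold.** `fold` is right-associated: it agrees with
  left association for associative operations and is the safe general
  choice for non-associative ones (head-first reduction is only valid for
  associative combines).
* **Serialization.** Strengths are written with 12 significant digits and
  JSON keys in sorted order, so identical runs give byte-identical files.
* **Problem sizes.** The property-style tests run on the scale the worked
  examples inhabit — lists of up to ~a dozen events over vocabularies of a
  handful of items, 200 randomized equivalence cases, 100-trial
  conditioning curves — which exercises every code path in well under a
  minute; the dynamics at stake (fixed points, prefix properties,
  equivalences) do not change with scale.

## Known limitations

* Only the operational currying contract of the external/internal
  correspondence is implemented; no general adjoint-fold machinery.
* Normalization terms for the merge rules are not implemented (only
  multiplicative decay).
* No backpropagation-based merge rule; the merge interface accepts one,
  but none is shipped.
* Latent inhibition, temporal contiguity and propositional-inference
  accounts of learning are outside the model family.
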