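# coalearn

Corecursive (coalgebraic) models of associative learning for R.

Associative learning — acquiring a map from cues to targets by experiencing
co-occurrences — can be modelled as a *corecursive* process: a machine that,
at each time step, consumes the next training pair, merges it into a growing
association network, and emits the updated network. `coalearn` implements
this picture operationally:

* **Recursion-scheme combinators.** `unfold()` runs a `coalgebra()` (halting
  predicate, emission, successor) to produce a finite stream; `fold()` is the
  dual right-associated reduction; `pair_fn()` builds product successors
  ⟨f, g⟩ : x ↦ (f(x), g(x)); `transpose()`/`untranspose()` implement the
  currying bijection between two-argument and curried functions.
* **Association networks.** Directed graphs whose edges carry an associative
  strength σ and a co-occurrence count, with two update (merge) rules:
  the *halfway* rule σ ← (1 + σ)/2 (first occurrence creates the edge at
  σ₀), and the *Rescorla–Wagner* rule ΔV_X = α_X·β·(λ − ΣV), which
  reproduces acquisition curves and blocking.
* **Typed learning constraints.** A `network_type()` declares vertex classes
  and the allowed (source class → target class) edge signatures, expressing
  species-specific learning selectivity (e.g. odour→food learnable by rats,
  colour→food not): lists that violate the type are refused before any
  learning, because no merge function is defined over such networks.
* **Learning models.** `learn_ext(model, pairs, g0)` unfolds the coalgebra
  over (remaining pairs, current network) and emits the snapshot stream
  [g₁, …, gₙ]; `learn_int(model, pairs)` is its exponential transpose, a
  function from initial networks to streams. `rlearn_fold()` and
  `ilearn_loop()` are the classical recursive and iterative productions used
  as equivalence oracles. `train_to_criterion()` runs rote-learning blocks;
  `encode_trial()` switches between elemental and configural (conjunctive
  cue) encodings; `ablate_common_component()` implements the shared-component
  ablation test.
* **Fixtures and generators.** `fixture()` ships the worked examples
  (bread/butter list, the two word→shape mappings, the colour×shape
  discrimination, species-typed problems); `generate_pairlist()` produces
  seeded two-list conditions (AB,CD and AB,ABr).
* **I/O and CLI.** TSV pair lists, JSON networks, JSON-lines snapshot
  streams, DOT export, and a thin command-line wrapper
  (`inst/cli/coalearn`) with `learn`, `recall`, `simulate`, `fixture` and
  `demo rw` subcommands.

## Worked example

```r
library(coalearn)

pairs <- fixture("bread_butter")$pairs   # (bread,butter), (knife,fork), (knife,butter)
s <- learn_ext(learning_model(), pairs)  # halfway rule, sigma0 = 0.5
length(s)
#> [1] 3
final_network(s)
#> <association_network: 4 vertices, 3 edges>
#>   bread -> butter  (strength 0.5, count 1)
#>   knife -> butter  (strength 0.5, count 1)
#>   knife -> fork  (strength 0.5, count 1)
recall(final_network(s), "knife")$ties
#> [1] "butter" "fork"
```

Three training pairs yield three network snapshots g₁, g₂, g₃. Each pair was
seen once, so every edge sits at the initial strength σ₀ = 0.5; the cue
*knife* was paired with both *fork* and *butter* equally often, so its recall
is a tie, which the package exposes rather than hiding behind a tie-break.

The internal-memory model gives the same stream by currying:

```r
f <- learn_int(learning_model(), pairs)  # network -> stream
length(f(association_network()))
#> [1] 3
```

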