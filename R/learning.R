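#' Construct a training pair list
#'
#' An ordered, finite list of training events. Each event has a non-empty
#' cue specification (a single id or a set of simultaneously present cues),
#' a target id, and an optional per-trial asymptote `lambda` (used by the
#' Rescorla-Wagner rule).
#'
#' @param events List of events; each event is `c(cue, target)` or
#'   `list(cues =, target =, lambda =)`.
#' @param schema `"elemental"` or `"configural"`; records how the events
#'   were encoded.
#' @return An object of class `pair_list`.
#' @examples
#' p <- pair_list(list(c("bread", "butter"), c("knife", "fork"),
#'                     c("knife", "butter")))
#' length(p)
#' @export
pair_list <- function(events, schema = c("elemental", "configural")) {
  schema <- match.arg(schema)
  stopifnot(is.list(events))
  events <- lapply(events, normalize_event)
  structure(list(events = events, schema = schema), class = "pair_list")
}

#' @export
length.pair_list <- function(x) length(x$events)

#' @export
print.pair_list <- function(x, ...) {
  cat(sprintf("<pair_list: %d %s event%s>\n", length(x$events), x$schema,
              if (length(x$events) == 1L) "" else "s"))
  for (ev in x$events)
    cat(sprintf("  (%s) -> %s%s\n", paste(ev$cues, collapse = ", "),
                ev$target,
                if (is.na(ev$lambda)) "" else sprintf("  [lambda %g]", ev$lambda)))
  invisible(x)
}

#' Build a pair list from a cue-to-target mapping
#'
#' @param cues,targets Parallel character vectors.
#' @param schema Passed to [pair_list()].
#' @return A [pair_list()] in the given order.
#' @export
pair_list_from_map <- function(cues, targets, schema = "elemental") {
  stopifnot(length(cues) == length(targets))
  pair_list(Map(function(a, b) c(a, b), cues, targets), schema = schema)
}

#' Take the first `k` events of a pair list
#'
#' @param pairs A [pair_list()].
#' @param k Number of events to keep (0..length).
#' @return A [pair_list()].
#' @export
head_pairs <- function(pairs, k) {
  pair_list(pairs$events[seq_len(k)], schema = pairs$schema)
}

#' Construct a learning model
#'
#' Bundles the merge rule, the network type constraining which associations
#' are representable, the step budget of the underlying unfold, and the
#' ablation flag used by the empirical-test utilities.
#'
#' @param rule A [merge_rule()].
#' @param ntype A [network_type()]; defaults to the fully permissive type.
#' @param budget Step budget; must be at least the longest list trained.
#' @param ablated If `TRUE` the model's common learning component has been
#'   removed: every `learn_*` call fails, while recall on previously built
#'   networks keeps working. See [ablate_common_component()].
#' @return An object of class `learning_model`.
#' @export
learning_model <- function(rule = merge_rule("halfway"),
                           ntype = permissive_type(),
                           budget = 10000L, ablated = FALSE) {
  stopifnot(inherits(rule, "merge_rule"), inherits(ntype, "network_type"),
            budget >= 0)
  structure(list(rule = rule, ntype = ntype, budget = as.integer(budget),
                 ablated = isTRUE(ablated)),
            class = "learning_model")
}

#' @export
print.learning_model <- function(x, ...) {
  cat(sprintf("<learning_model: %s rule, budget %d%s>\n",
              x$rule$name, x$budget, if (x$ablated) ", ABLATED" else ""))
  invisible(x)
}

check_learnable <- function(model, pairs) {
  if (model$ablated)
    stop("common component unavailable: the model has been ablated, ",
         "no learning capacity remains", call. = FALSE)
  for (i in seq_along(pairs$events)) {
    v <- validate_pair(model$ntype, pairs$events[[i]])
    if (!v$ok)
      stop(sprintf("no merge function defined over such networks (event %d): %s",
                   i, paste(v$violations, collapse = "; ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Associative learning with the network as external input
#'
#' The external-memory learning model: an unfold of the coalgebra whose
#' state is the pair (remaining training list, current network), whose
#' halting predicate tests for an exhausted list, whose emission merges the
#' first pair into the current network, and whose successor pairs
#' "tail of the list" with that same merge. Unfolding from `(pairs, g0)`
#' emits one network snapshot per event: the stream `[g1, ..., gn]`
#' (`g0` is excluded; it is the caller's input). Snapshot k depends only on
#' the first k events.
#'
#' Events that are unrepresentable under the model's network type are
#' refused up front — there is no merge function defined over such
#' networks, so no partial learning occurs.
#'
#' @param model A [learning_model()].
#' @param pairs A [pair_list()].
#' @param g0 Initial [association_network()] (default empty).
#' @return A [stream()] of association networks.
#' @examples
#' p <- pair_list(list(c("bread", "butter"), c("knife", "fork"),
#'                     c("knife", "butter")))
#' s <- learn_ext(learning_model(), p)
#' length(s)                      # 3 snapshots
#' final_network(s)
#' @export
learn_ext <- function(model, pairs, g0 = association_network()) {
  stopifnot(inherits(model, "learning_model"), inherits(pairs, "pair_list"),
            inherits(g0, "association_network"))
  check_learnable(model, pairs)
  tau <- function(s) s[[1L]][-1L]                       # tail of the pair list
  mu <- function(s) merge_event(s[[1L]][[1L]], s[[2L]], model$rule)
  co <- coalgebra(
    halt = function(s) length(s[[1L]]) == 0L,
    emit = mu,
    next_state = pair_fn(tau, mu)
  )
  unfold(co, list(pairs$events, g0), max_steps = model$budget)
}

#' Associative learning with the network as internal memory
#'
#' The internal-memory model is the exponential transpose of the external
#' one: instead of taking the pair list and the network together, it takes
#' the pair list and returns a function from initial networks to snapshot
#' streams. `learn_int(model, pairs)(g0)` equals
#' `learn_ext(model, pairs, g0)` elementwise for every `g0`.
#'
#' @inheritParams learn_ext
#' @return A function `association_network -> stream`.
#' @export
learn_int <- function(model, pairs) {
  stopifnot(inherits(model, "learning_model"), inherits(pairs, "pair_list"))
  check_learnable(model, pairs)
  transpose(function(p, g) learn_ext(model, p, g))(pairs)
}

#' Final network of a snapshot stream
#'
#' @param s A [stream()] of association networks, as produced by
#'   [learn_ext()].
#' @param g0 Network returned when the stream is empty.
#' @return An [association_network()].
#' @export
final_network <- function(s, g0 = association_network()) {
  if (length(s$elements) == 0L) g0 else s$elements[[length(s$elements)]]
}

#' Encode a stimulus/outcome observation as training events
#'
#' Under the elemental schema each attribute of the stimulus becomes an
#' independently predictive cue: a multi-attribute stimulus contributes one
#' event per attribute. Under the configural schema the attribute tuple is
#' collapsed into a single conjunction vertex (attribute values sorted
#' lexicographically and joined with the conjunction sign, so the id is
#' invariant to attribute order), which requires conjunction vertices to be
#' representable under the network type.
#'
#' @param schema `"elemental"` or `"configural"`.
#' @param stimulus Character vector: one id, or the attribute tuple of a
#'   compound stimulus.
#' @param outcome Target id.
#' @param ntype Optional [network_type()]; configural encoding against a
#'   type with `configural = FALSE` is an error.
#' @return List of events (length >= 1), each `list(cues, target, lambda)`.
#' @examples
#' encode_trial("elemental", "bell", "sq")
#' encode_trial("configural", c("black", "square"), "+")
#' @export
encode_trial <- function(schema = c("elemental", "configural"),
                         stimulus, outcome, ntype = NULL) {
  schema <- match.arg(schema)
  stimulus <- as.character(stimulus)
  stopifnot(length(stimulus) >= 1L, length(outcome) == 1L)
  if (schema == "configural") {
    if (!is.null(ntype) && !ntype$configural)
      stop("unrepresentable conjunction: the network type has no ",
           "conjunction vertices (configural = FALSE)", call. = FALSE)
    return(list(normalize_event(c(conjunction_id(stimulus),
                                  as.character(outcome)))))
  }
  lapply(stimulus, function(a) normalize_event(c(a, as.character(outcome))))
}

#' Canonical conjunction vertex id
#'
#' @param attributes Character vector of attribute values.
#' @return A single id, e.g. `"black\u2227square"`.
#' @export
conjunction_id <- function(attributes) {
  paste(sort(as.character(attributes), method = "radix"), collapse = "\u2227")
}

#' Rote learning to a criterion
#'
#' Repeats presentation blocks until recall meets a criterion. Each block
#' presents every training event once, in an order shuffled by the seeded
#' generator, continuing learning from the current network. After each
#' block every event's cue is tested with [recall()]: a prediction is
#' correct only if it uniquely matches the event's target — a tie counts as
#' incorrect, so chance behaviour cannot pass criterion.
#'
#' @param model A [learning_model()].
#' @param pairs A [pair_list()]: the mapping to be learned (for configural
#'   or multi-attribute material, encode first with [encode_trial()]).
#' @param criterion Required fraction of correct cue tests in [0, 1].
#' @param max_blocks Maximum number of blocks before giving up.
#' @param seed Integer seed for the presentation shuffles.
#' @param g0 Initial network.
#' @return List with `network` (final state), `blocks` (blocks used;
#'   `NA_integer_` on failure), `success`, and `accuracy` (fraction correct
#'   after the last block).
#' @examples
#' ws1 <- fixture("ws1")
#' train_to_criterion(learning_model(), ws1$pairs, criterion = 1)$blocks  # 1
#' @export
train_to_criterion <- function(model, pairs, criterion = 1,
                               max_blocks = 10L, seed = 1L,
                               g0 = association_network()) {
  stopifnot(criterion >= 0, criterion <= 1, max_blocks >= 1)
  check_learnable(model, pairs)
  net <- g0
  acc <- NA_real_
  local_rng(seed, {
    for (block in seq_len(max_blocks)) {
      order_ <- sample.int(length(pairs$events))
      shuffled <- pair_list(pairs$events[order_], schema = pairs$schema)
      net <- final_network(learn_ext(model, shuffled, net), g0 = net)
      acc <- test_block_accuracy(net, pairs)
      if (acc >= criterion)
        return(list(network = net, blocks = block, success = TRUE,
                    accuracy = acc))
    }
    list(network = net, blocks = NA_integer_, success = FALSE, accuracy = acc)
  })
}

# Fraction of events whose cue uniquely recalls its target (ties incorrect).
test_block_accuracy <- function(net, pairs) {
  correct <- vapply(pairs$events, function(ev) {
    all(vapply(ev$cues, function(cue) {
      r <- recall(net, cue)
      length(r$ties) == 1L && identical(r$prediction, ev$target)
    }, logical(1)))
  }, logical(1))
  mean(correct)
}

#' Recursive rote learning (classical production)
#'
#' The classical recursive formulation: an empty list returns the network
#' unchanged; otherwise recurse on the tail after merging the first pair.
#' On every finite input the result equals the last snapshot of
#' [learn_ext()]; it serves as an independent equivalence oracle for the
#' corecursive model.
#'
#' @param pairs A [pair_list()].
#' @param network Initial [association_network()].
#' @param rule A [merge_rule()].
#' @return The final [association_network()].
#' @export
rlearn_fold <- function(pairs, network = association_network(),
                        rule = merge_rule("halfway")) {
  go <- function(events, net) {
    if (length(events) == 0L) return(net)
    go(events[-1L], merge_event(events[[1L]], net, rule))
  }
  go(pairs$events, network)
}

#' Iterative rote learning (while-loop production)
#'
#' The non-recursive counterpart of [rlearn_fold()]: an explicit while-loop
#' over head and tail. Agrees with [rlearn_fold()] on every finite input.
#'
#' @inheritParams rlearn_fold
#' @return The final [association_network()].
#' @export
ilearn_loop <- function(pairs, network = association_network(),
                        rule = merge_rule("halfway")) {
  events <- pairs$events
  while (length(events) > 0L) {
    network <- merge_event(events[[1L]], network, rule)
    events <- events[-1L]
  }
  network
}

#' Ablate the model's common learning component
#'
#' Removes the shared merge machinery that every learning capacity of the
#' model factors through. On the returned model every `learn_*` call fails
#' for every pair list — all learning capacities are lost together — while
#' [recall()] on previously built networks still works, because
#' representability is untouched. This is the operational form of the
#' three-part empirical test for a shared (universal) component: capacities
#' that factor through a common process must stand and fall together.
#'
#' @param model A [learning_model()].
#' @return The same model with `ablated = TRUE`.
#' @export
ablate_common_component <- function(model) {
  stopifnot(inherits(model, "learning_model"))
  model$ablated <- TRUE
  model
}

# Evaluate `code` under a temporary, seeded RNG state, restoring the
# caller's stream afterwards.
local_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
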