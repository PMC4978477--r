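#' Construct a coalgebra
#'
#' A coalgebra packages the three ingredients of a corecursive process: a
#' halting predicate over states, an emission function producing one output
#' per step, and a successor function advancing the state. [unfold()] runs a
#' coalgebra from an initial state, producing the stream of emitted outputs.
#'
#' For any state exactly one of two things happens: if `halt(state)` is
#' `TRUE` the process stops and emits nothing (the terminal branch), else the
#' process emits `emit(state)` and continues from `next_state(state)`. Both
#' `emit` and `next_state` are expected to be pure: equal states must give
#' equal results.
#'
#' @param halt Predicate `state -> logical(1)`; `TRUE` stops the unfold.
#' @param emit Function `state -> output`, called only on non-halting states.
#' @param next_state Function `state -> state`, called only on non-halting
#'   states. Often built with [pair_fn()] from per-component successors.
#' @return An object of class `coalgebra`.
#' @seealso [unfold()], [repeat_coalgebra()], [count_coalgebra()]
#' @examples
#' co <- coalgebra(halt = function(n) n == 0,
#'                 emit = function(n) 1,
#'                 next_state = function(n) n - 1)
#' unfold(co, 3)$elements
#' @export
coalgebra <- function(halt, emit, next_state) {
  stopifnot(is.function(halt), is.function(emit), is.function(next_state))
  structure(list(halt = halt, emit = emit, next_state = next_state),
            class = "coalgebra")
}

#' @export
print.coalgebra <- function(x, ...) {
  cat("<coalgebra: halt/emit/next_state>\n")
  invisible(x)
}

#' Run a coalgebra: the unfold (anamorphism)
#'
#' Repeatedly tests the halting predicate; while it is false, appends one
#' emitted output and advances the state. The outputs are collected
#' head-first, i.e. in temporal order of emission. Evaluation always
#' terminates: a step budget is mandatory (default 10000), so a
#' conceptually infinite stream is cut short and flagged via `terminated`.
#'
#' The k-th element of the result depends only on the first k steps
#' (productivity): unfolding with a larger budget extends, never rewrites,
#' the prefix produced with a smaller one.
#'
#' @param coalg A [coalgebra()].
#' @param state Initial state.
#' @param max_steps Non-negative integer step budget.
#' @return An object of class `stream`: a list with `elements` (outputs in
#'   emission order) and `terminated` (`TRUE` if the halting predicate fired,
#'   `FALSE` if the budget cut evaluation short).
#' @examples
#' unfold(repeat_coalgebra(), 3)            # three 1's
#' unfold(count_coalgebra(), count_state(0, list("a", "b", "c")))
#' @export
unfold <- function(coalg, state, max_steps = 10000L) {
  stopifnot(inherits(coalg, "coalgebra"),
            is.numeric(max_steps), length(max_steps) == 1L, max_steps >= 0)
  max_steps <- as.integer(max_steps)
  elements <- vector("list", max_steps)
  n <- 0L
  terminated <- FALSE
  repeat {
    if (isTRUE(coalg$halt(state))) {
      terminated <- TRUE
      break
    }
    if (n >= max_steps) break
    n <- n + 1L
    elements[[n]] <- with_step_index(n, coalg$emit(state))
    state <- with_step_index(n, coalg$next_state(state))
  }
  stream(elements[seq_len(n)], terminated)
}

# Re-signal errors from emit/next_state with the 1-based step index attached.
with_step_index <- function(step, expr) {
  withCallingHandlers(expr, error = function(e) {
    stop(sprintf("unfold step %d: %s", step, conditionMessage(e)), call. = FALSE)
  })
}

#' Construct a stream (finite list of emitted outputs)
#'
#' @param elements List of outputs in emission order.
#' @param terminated `TRUE` when the coalgebra's halting predicate was
#'   reached, `FALSE` when a step budget stopped evaluation first.
#' @return An object of class `stream`.
#' @export
stream <- function(elements = list(), terminated = TRUE) {
  stopifnot(is.list(elements), is.logical(terminated), length(terminated) == 1L)
  structure(list(elements = elements, terminated = terminated),
            class = "stream")
}

#' @export
print.stream <- function(x, ...) {
  cat(sprintf("<stream of %d element%s; %s>\n",
              length(x$elements), if (length(x$elements) == 1L) "" else "s",
              if (x$terminated) "terminated" else "budget-exhausted"))
  invisible(x)
}

#' @export
length.stream <- function(x) length(x$elements)

#' Product pairing of two functions
#'
#' `pair_fn(f, g)` is the function `x -> list(f(x), g(x))`: both components
#' applied to the same input. This is how successor functions over product
#' states are assembled, e.g. the next-state map of the learning model pairs
#' "tail of the pair list" with "merge of the first pair".
#'
#' @param f,g Functions accepting the same input.
#' @return A function returning the two results as an unnamed list of length 2.
#' @examples
#' pair_fn(function(n) 1, function(n) n - 1)(3)  # list(1, 2)
#' @export
pair_fn <- function(f, g) {
  stopifnot(is.function(f), is.function(g))
  function(x) list(f(x), g(x))
}

#' Fold (catamorphism) over a finite list
#'
#' Right-associated reduction: `fold(f, list(x1, x2, x3), init)` computes
#' `f(x1, f(x2, f(x3, init)))`. With `init` absent the reduction runs over
#' the list alone, so `fold(f, list(x1, x2, x3))` is `f(x1, f(x2, x3))`;
#' the list must then be non-empty. Right association is the safe general
#' choice: it agrees with left association for associative `combine` and is
#' well defined for non-associative ones.
#'
#' @param combine Binary function.
#' @param items Finite list (or atomic vector) of items.
#' @param init Optional initial value, combined at the right end.
#' @return The reduced value.
#' @examples
#' fold(`+`, c(1, 2, 3), 0)     # 6
#' fold(function(a, b) if (a < b) a else b, c(4, 2, 6))  # 2
#' @export
fold <- function(combine, items, init) {
  stopifnot(is.function(combine))
  items <- as.list(items)
  if (missing(init)) {
    if (length(items) == 0L)
      stop("fold over an empty list requires an initial value", call. = FALSE)
    return(Reduce(combine, items, right = TRUE))
  }
  Reduce(combine, items, init, right = TRUE)
}

#' Exponential transpose (currying) and its inverse
#'
#' `transpose(f)` converts a two-argument function into its curried form:
#' `transpose(f)(a)(b) == f(a, b)` for all inputs. `untranspose` inverts it,
#' so `untranspose(transpose(f))` is pointwise equal to `f`. This is the
#' operational content of the product-exponential adjunction that relates
#' the external-memory learning model to the internal-memory one: the
#' internal model is the transpose of the external model.
#'
#' @param f A function of two arguments.
#' @param g A curried function `a -> (b -> c)`.
#' @return For `transpose`, a function `a -> (b -> c)`; for `untranspose`,
#'   a function of two arguments.
#' @examples
#' transpose(`+`)(2)(3)            # 5
#' untranspose(transpose(`+`))(2, 3)  # 5
#' @export
transpose <- function(f) {
  stopifnot(is.function(f))
  function(a) function(b) f(a, b)
}

#' @rdname transpose
#' @export
untranspose <- function(g) {
  stopifnot(is.function(g))
  function(a, b) g(a)(b)
}

#' Example coalgebras: repeat and count
#'
#' `repeat_coalgebra()` emits the constant 1 while decrementing a counter:
#' unfolding from n yields a list of n ones (halt tests for zero, the
#' successor is the pairing of "constant 1" with "decrement"). Negative
#' starting states never halt and are cut off by the budget.
#'
#' `count_coalgebra()` threads a counter alongside a list of items: from
#' state `(n, items)` it emits `n + 1` and advances to `(n + 1, tail)`,
#' halting when the item list is empty. Unfolding from `(0, [a, b, c])`
#' yields the progressive counts `[1, 2, 3]`. Use [count_state()] to build
#' the paired state.
#'
#' @return A [coalgebra()].
#' @examples
#' unfold(repeat_coalgebra(), 3)$elements    # 1, 1, 1
#' s <- unfold(count_coalgebra(), count_state(0, list("a", "b", "c")))
#' unlist(s$elements)                        # 1 2 3
#' @export
repeat_coalgebra <- function() {
  coalgebra(
    halt = function(n) n == 0,
    emit = function(n) 1,
    next_state = function(n) n - 1
  )
}

#' @rdname repeat_coalgebra
#' @export
count_coalgebra <- function() {
  coalgebra(
    halt = function(s) length(s$items) == 0L,
    emit = incl,
    next_state = tailr
  )
}

#' @param n Count so far (non-negative number).
#' @param items List of items remaining to be counted.
#' @rdname repeat_coalgebra
#' @export
count_state <- function(n, items) {
  stopifnot(is.numeric(n), length(n) == 1L, is.list(items))
  list(n = n, items = items)
}

#' Counting successor components
#'
#' `incl` increments the counter of a [count_state()] and ignores the item
#' list; `tailr` increments the counter and drops the first item. Together
#' (via [pair_fn()] semantics, here fused into emit/next) they drive
#' [count_coalgebra()].
#'
#' @param s A [count_state()].
#' @return `incl`: the incremented count. `tailr`: the successor state.
#' @export
incl <- function(s) s$n + 1

#' @rdname incl
#' @export
tailr <- function(s) count_state(s$n + 1, s$items[-1L])
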