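#' Construct an association network
#'
#' A directed graph whose edges carry a real-valued associative strength and
#' a co-occurrence count. Networks are value-semantic: every update returns
#' a new network, so snapshot histories are cheap copies of small graphs.
#'
#' @param vertices Character vector of vertex identifiers (case-sensitive,
#'   Unicode allowed). Endpoints of edges are added automatically.
#' @param edges Data frame with columns `source`, `target`, `strength`,
#'   `count`; at most one row per ordered (source, target) pair.
#' @return An object of class `association_network`.
#' @examples
#' g <- association_network()
#' g <- merge_halfway(c("bread", "butter"), g, merge_rule("halfway"))
#' recall(g, "bread")
#' @export
association_network <- function(vertices = character(), edges = empty_edges()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "strength", "count") %in% names(edges)))
  edges <- edges[, c("source", "target", "strength", "count")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$strength <- as.numeric(edges$strength)
  edges$count <- as.integer(edges$count)
  rownames(edges) <- NULL
  net <- structure(
    list(vertices = unique(c(as.character(vertices), edges$source, edges$target)),
         edges = edges),
    class = "association_network")
  validate_network(net)
}

empty_edges <- function() {
  data.frame(source = character(), target = character(),
             strength = numeric(), count = integer(),
             stringsAsFactors = FALSE)
}

validate_network <- function(net) {
  e <- net$edges
  if (anyDuplicated(paste0(e$source, "\r", e$target)))
    stop("duplicate edge for an ordered (source, target) pair", call. = FALSE)
  if (length(e$strength) && any(!is.finite(e$strength)))
    stop("edge strengths must be finite", call. = FALSE)
  if (length(e$count) && any(e$count < 0L))
    stop("occurrence counts must be non-negative", call. = FALSE)
  if (!all(c(e$source, e$target) %in% net$vertices))
    stop("every edge endpoint must be a vertex", call. = FALSE)
  net
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("<association_network: %d vertices, %d edges>\n",
              length(x$vertices), nrow(x$edges)))
  if (nrow(x$edges)) {
    e <- x$edges[order(x$edges$source, x$edges$target), ]
    apply(e, 1L, function(r)
      cat(sprintf("  %s -> %s  (strength %.4g, count %s)\n",
                  r[["source"]], r[["target"]],
                  as.numeric(r[["strength"]]), r[["count"]])))
  }
  invisible(x)
}

#' @export
`==.association_network` <- function(e1, e2) {
  network_equal(e1, e2)
}

#' Compare two association networks for equality
#'
#' Equal iff they have the same vertex set and the same edge set with equal
#' strengths (within `tol`) and counts; edge order is irrelevant.
#'
#' @param a,b Association networks.
#' @param tol Absolute tolerance on strengths.
#' @return Logical scalar.
#' @export
network_equal <- function(a, b, tol = 1e-12) {
  if (!setequal(a$vertices, b$vertices)) return(FALSE)
  ea <- a$edges[order(a$edges$source, a$edges$target), , drop = FALSE]
  eb <- b$edges[order(b$edges$source, b$edges$target), , drop = FALSE]
  if (nrow(ea) != nrow(eb)) return(FALSE)
  if (nrow(ea) == 0L) return(TRUE)
  all(ea$source == eb$source) && all(ea$target == eb$target) &&
    all(abs(ea$strength - eb$strength) <= tol) && all(ea$count == eb$count)
}

#' Number of edges / vertices of a network
#'
#' @param net An association network.
#' @return Integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_vertices <- function(net) length(net$vertices)

#' Out-degree of a vertex
#'
#' @param net An association network.
#' @param vertex Vertex id.
#' @return Number of outgoing edges (0 for unknown vertices).
#' @export
out_degree <- function(net, vertex) sum(net$edges$source == vertex)

#' Strength of a single edge
#'
#' @param net An association network.
#' @param source,target Endpoint ids.
#' @param default Value returned when the edge is absent.
#' @return Numeric strength.
#' @export
edge_strength <- function(net, source, target, default = NA_real_) {
  i <- which(net$edges$source == source & net$edges$target == target)
  if (length(i)) net$edges$strength[i] else default
}

#' Construct a merge rule
#'
#' A merge rule is the parameterized update applied to the network for each
#' training event. Two families are provided:
#'
#' * `halfway`: on the first co-occurrence of a pair an edge is created at
#'   strength `sigma0`; each further co-occurrence updates the strength to
#'   `(1 + strength) / 2`, which increases monotonically towards 1.
#' * `rescorla_wagner`: trial-level prediction-error learning. For every cue
#'   X present on a trial with outcome O and asymptote lambda, the strength
#'   V of the edge X -> O changes by `alpha_X * beta * (lambda - sum V)`,
#'   the sum running over all present cues' edges to O. Strengths may leave
#'   [0, 1] (conditioned inhibition) but remain finite.
#'
#' Both rules may be wrapped with multiplicative decay: with `decay < 1`
#' every existing edge strength is multiplied by `decay` before each merge
#' (1 means no decay).
#'
#' @param name `"halfway"` or `"rescorla_wagner"`.
#' @param sigma0 Initial strength on first occurrence, in (0, 1). The
#'   default 0.5 makes repeated co-occurrence trace out
#'   `sigma_n = 1 - 2^-n`, the same trajectory as the update's fixed-point
#'   recurrence.
#' @param alpha Named numeric vector of per-cue saliences in [0, 1]
#'   (Rescorla-Wagner only); cues not named fall back to `alpha_default`.
#' @param alpha_default Salience used for cues absent from `alpha`.
#' @param beta Learning rate in [0, 1] (Rescorla-Wagner only).
#' @param lambda Default asymptote for trials that do not carry their own.
#' @param decay Multiplicative retention factor in (0, 1]; 1 = no decay.
#' @return An object of class `merge_rule`.
#' @export
merge_rule <- function(name = c("halfway", "rescorla_wagner"),
                       sigma0 = 0.5, alpha = numeric(), alpha_default = 0.3,
                       beta = 1, lambda = 1, decay = 1) {
  name <- match.arg(name)
  stopifnot(sigma0 > 0, sigma0 < 1,
            all(alpha >= 0), all(alpha <= 1),
            alpha_default >= 0, alpha_default <= 1,
            beta >= 0, beta <= 1,
            is.finite(lambda),
            decay > 0, decay <= 1)
  structure(list(name = name, sigma0 = sigma0, alpha = alpha,
                 alpha_default = alpha_default, beta = beta,
                 lambda = lambda, decay = decay),
            class = "merge_rule")
}

#' @export
print.merge_rule <- function(x, ...) {
  cat(sprintf("<merge_rule %s: sigma0=%g beta=%g lambda=%g decay=%g>\n",
              x$name, x$sigma0, x$beta, x$lambda, x$decay))
  invisible(x)
}

apply_decay <- function(net, rule) {
  if (rule$decay < 1 && nrow(net$edges))
    net$edges$strength <- rule$decay * net$edges$strength
  net
}

#' Halfway merge: co-occurrence update towards 1
#'
#' Merges one (cue, target) co-occurrence into the network. An absent edge
#' is created with strength `sigma0` and count 1 (endpoints are added to the
#' vertex set if missing); a present edge is updated to
#' `(1 + strength) / 2` and its count incremented. The input network is
#' unchanged; a new network is returned.
#'
#' @param event Character vector `c(cue, target)` or list with elements
#'   cue/target.
#' @param network An [association_network()].
#' @param rule A [merge_rule()] with name `"halfway"`.
#' @return The updated network.
#' @examples
#' g1 <- merge_halfway(c("bread", "butter"), association_network(),
#'                     merge_rule("halfway"))
#' edge_strength(g1, "bread", "butter")   # 0.5
#' @export
merge_halfway <- function(event, network, rule = merge_rule("halfway")) {
  stopifnot(inherits(rule, "merge_rule"), rule$name == "halfway")
  ev <- as_cue_target(event)
  network <- apply_decay(network, rule)
  i <- which(network$edges$source == ev$cue & network$edges$target == ev$target)
  if (length(i)) {
    network$edges$strength[i] <- (1 + network$edges$strength[i]) / 2
    network$edges$count[i] <- network$edges$count[i] + 1L
  } else {
    network$edges <- rbind(network$edges,
                           data.frame(source = ev$cue, target = ev$target,
                                      strength = rule$sigma0, count = 1L,
                                      stringsAsFactors = FALSE))
    network$vertices <- unique(c(network$vertices, ev$cue, ev$target))
  }
  rownames(network$edges) <- NULL
  network
}

as_cue_target <- function(event) {
  if (is.list(event) && !is.null(event$cue))
    return(list(cue = as.character(event$cue), target = as.character(event$target)))
  event <- as.character(unlist(event, use.names = FALSE))
  stopifnot(length(event) == 2L)
  list(cue = event[[1L]], target = event[[2L]])
}

#' Rescorla-Wagner merge: prediction-error update
#'
#' Applies one conditioning trial. Every present cue's edge to the outcome
#' has its strength V incremented by `alpha_X * beta * (lambda - sum V)`,
#' where the summed prediction runs over all present cues (absent edges
#' predict 0 and are created by the update). The shared prediction error is
#' computed once before any strength changes, so the update reproduces
#' acquisition curves, blocking and conditioned inhibition.
#'
#' @param trial List with `cues` (non-empty character vector of present
#'   cues), `outcome` (id), and optionally `lambda` (asymptote for this
#'   trial; defaults to the rule's lambda).
#' @param network An [association_network()].
#' @param rule A [merge_rule()] with name `"rescorla_wagner"`.
#' @return The updated network.
#' @examples
#' r <- merge_rule("rescorla_wagner", alpha_default = 0.3, beta = 1, lambda = 1)
#' g <- merge_rescorla_wagner(list(cues = "light", outcome = "food"),
#'                            association_network(), r)
#' edge_strength(g, "light", "food")   # 0.3
#' @export
merge_rescorla_wagner <- function(trial, network,
                                  rule = merge_rule("rescorla_wagner")) {
  stopifnot(inherits(rule, "merge_rule"), rule$name == "rescorla_wagner")
  cues <- unique(as.character(trial$cues))
  if (length(cues) == 0L) stop("a trial needs at least one present cue", call. = FALSE)
  outcome <- as.character(trial$outcome)
  lambda <- if (!is.null(trial$lambda) && !is.na(trial$lambda))
    as.numeric(trial$lambda) else rule$lambda
  network <- apply_decay(network, rule)
  v <- vapply(cues, function(x) edge_strength(network, x, outcome, default = 0),
              numeric(1))
  error <- lambda - sum(v)
  for (x in cues) {
    a <- if (x %in% names(rule$alpha)) rule$alpha[[x]] else rule$alpha_default
    dv <- a * rule$beta * error
    i <- which(network$edges$source == x & network$edges$target == outcome)
    if (length(i)) {
      network$edges$strength[i] <- network$edges$strength[i] + dv
      network$edges$count[i] <- network$edges$count[i] + 1L
    } else {
      network$edges <- rbind(network$edges,
                             data.frame(source = x, target = outcome,
                                        strength = dv, count = 1L,
                                        stringsAsFactors = FALSE))
      network$vertices <- unique(c(network$vertices, x, outcome))
    }
  }
  rownames(network$edges) <- NULL
  validate_network(network)
}

#' Apply one training event under a merge rule
#'
#' Dispatches on the rule's name: halfway rules treat the event as a single
#' (cue, target) pair (cue sets are split into one halfway update per cue),
#' Rescorla-Wagner rules treat it as a trial with a set of present cues.
#'
#' @param event A training event: `c(cue, target)` or
#'   `list(cues =, target =, lambda =)`.
#' @param network An [association_network()].
#' @param rule A [merge_rule()].
#' @return The updated network.
#' @export
merge_event <- function(event, network, rule) {
  if (rule$name == "rescorla_wagner") {
    trial <- normalize_event(event)
    merge_rescorla_wagner(list(cues = trial$cues, outcome = trial$target,
                               lambda = trial$lambda), network, rule)
  } else {
    trial <- normalize_event(event)
    for (cue in trial$cues)
      network <- merge_halfway(c(cue, trial$target), network, rule)
    network
  }
}

normalize_event <- function(event) {
  if (is.list(event) && (!is.null(event$cues) || !is.null(event$cue))) {
    cues <- as.character(if (!is.null(event$cues)) event$cues else event$cue)
    target <- as.character(event$target)
    lambda <- if (!is.null(event$lambda)) event$lambda else NA_real_
  } else {
    ev <- as_cue_target(event)
    cues <- ev$cue
    target <- ev$target
    lambda <- NA_real_
  }
  stopifnot(length(cues) >= 1L, length(target) == 1L)
  list(cues = cues, target = target, lambda = as.numeric(lambda))
}

#' Recall: the strongest associate of a cue
#'
#' Among the cue's outgoing edges, returns the target(s) of maximal
#' strength. The full tie-set is exposed so callers can treat ties as chance
#' behaviour; the deterministic prediction breaks ties lexicographically on
#' the target id. A cue with no outgoing edges predicts nothing.
#'
#' @param network An [association_network()].
#' @param cue Vertex id.
#' @return List with `prediction` (target id or `NA_character_`), `ties`
#'   (character vector of all maximizers, sorted), and `strength` (winning
#'   strength, `NA` if none).
#' @export
recall <- function(network, cue) {
  out <- network$edges[network$edges$source == as.character(cue), , drop = FALSE]
  if (nrow(out) == 0L)
    return(list(prediction = NA_character_, ties = character(), strength = NA_real_))
  top <- out$strength == max(out$strength)
  ties <- sort(out$target[top], method = "radix")
  list(prediction = ties[[1L]], ties = ties, strength = max(out$strength))
}

#' Construct a network type
#'
#' A network type delimits which associations are representable: a
#' partition of the vertex vocabulary into named classes, the set of
#' allowed (source class -> target class) edge signatures, and whether
#' conjunction (configural) vertices are representable. Species-specific
#' learning constraints (e.g. rats acquire odour-to-food but not
#' colour-to-food associations) are expressed as narrow signature sets.
#'
#' Vertices are classified either by membership of a declared vocabulary or
#' by a `"class:value"` id prefix for open-ended vocabularies (a class with
#' a `NULL`/empty vocabulary is open).
#'
#' @param classes Named list: class name -> character vector of vertex ids
#'   (possibly empty for an open vocabulary). Vocabularies must be pairwise
#'   disjoint.
#' @param signatures Two-column data frame (or matrix) of allowed
#'   (from-class, to-class) pairs; both must be declared classes.
#' @param configural Whether conjunction vertices are representable.
#' @return An object of class `network_type`.
#' @examples
#' rat <- network_type(
#'   classes = list(odour = character(), colour = character(),
#'                  tone = character(), food = character()),
#'   signatures = data.frame(from = "odour", to = "food"))
#' validate_pair(rat, c("odour:almond", "food:pellet"))$ok   # TRUE
#' validate_pair(rat, c("colour:red", "food:pellet"))$ok     # FALSE
#' @export
network_type <- function(classes, signatures, configural = FALSE) {
  stopifnot(is.list(classes), length(names(classes)) == length(classes),
            all(nzchar(names(classes))))
  vocab <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(vocab))
    stop("class vocabularies must be pairwise disjoint", call. = FALSE)
  signatures <- as.data.frame(signatures, stringsAsFactors = FALSE)
  names(signatures)[1:2] <- c("from", "to")
  signatures$from <- as.character(signatures$from)
  signatures$to <- as.character(signatures$to)
  bad <- setdiff(c(signatures$from, signatures$to), names(classes))
  if (length(bad))
    stop("signatures reference undeclared classes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(classes = classes, signatures = signatures,
                 configural = isTRUE(configural)),
            class = "network_type")
}

#' @export
print.network_type <- function(x, ...) {
  cat(sprintf("<network_type: %d classes, %d signatures%s>\n",
              length(x$classes), nrow(x$signatures),
              if (x$configural) ", configural" else ""))
  invisible(x)
}

#' A fully permissive network type
#'
#' Single open class `"item"` with the item-to-item signature allowed;
#' every vertex is classifiable, so every pair validates. Used as the
#' default when no typing constraint is wanted.
#'
#' @param configural Whether conjunction vertices are representable.
#' @return A [network_type()].
#' @export
permissive_type <- function(configural = TRUE) {
  network_type(classes = list(item = character()),
               signatures = data.frame(from = "item", to = "item"),
               configural = configural)
}

#' Class of a vertex under a network type
#'
#' @param ntype A [network_type()].
#' @param vertex Vertex id.
#' @return Class name, or `NA_character_` if the vertex is unclassifiable.
#' @export
vertex_class <- function(ntype, vertex) {
  vertex <- as.character(vertex)
  for (cl in names(ntype$classes))
    if (vertex %in% ntype$classes[[cl]]) return(cl)
  # "class:value" prefix convention for open vocabularies
  if (grepl(":", vertex, fixed = TRUE)) {
    cl <- sub(":.*$", "", vertex)
    if (cl %in% names(ntype$classes)) return(cl)
  }
  open <- names(ntype$classes)[vapply(ntype$classes, length, 0L) == 0L]
  if (length(open) == 1L) return(open)
  NA_character_
}

#' Validate a training pair against a network type
#'
#' A pair is representable iff both endpoints are assignable to declared
#' classes and the (cue class, target class) signature is allowed. An
#' unrepresentable pair means there is no merge function defined over
#' networks of this type, so the pair cannot be learned at all.
#'
#' @param ntype A [network_type()].
#' @param event `c(cue, target)` or a list with cue(s)/target.
#' @return List with `ok` (logical) and `violations` (character vector of
#'   human-readable reports, empty when ok).
#' @export
validate_pair <- function(ntype, event) {
  ev <- normalize_event(event)
  violations <- character()
  tcl <- vertex_class(ntype, ev$target)
  if (is.na(tcl))
    violations <- c(violations,
                    sprintf("unrepresentable vertex: '%s'", ev$target))
  for (cue in ev$cues) {
    ccl <- vertex_class(ntype, cue)
    if (is.na(ccl)) {
      violations <- c(violations, sprintf("unrepresentable vertex: '%s'", cue))
    } else if (!is.na(tcl) &&
               !any(ntype$signatures$from == ccl & ntype$signatures$to == tcl)) {
      violations <- c(violations,
                      sprintf("signature %s -> %s not allowed (pair '%s' -> '%s')",
                              ccl, tcl, cue, ev$target))
    }
  }
  list(ok = length(violations) == 0L, violations = violations)
}

#' Rename vertices along a type/vocabulary map
#'
#' Applies a vertex map (a graph homomorphism on vertices) to the network:
#' every vertex is renamed, edges follow their endpoints. When the map
#' collapses two vertices, parallel edges that become identical are merged
#' keeping the maximum strength and the summed co-occurrence count.
#'
#' @param vmap Named character vector `old id -> new id`; must be defined
#'   (named) for every vertex present in the network.
#' @param network An [association_network()].
#' @return The transformed network.
#' @export
apply_type_map <- function(vmap, network) {
  stopifnot(is.character(vmap), !is.null(names(vmap)))
  missing_v <- setdiff(network$vertices, names(vmap))
  if (length(missing_v))
    stop("vertex map undefined on: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  e <- network$edges
  if (nrow(e)) {
    e$source <- unname(vmap[e$source])
    e$target <- unname(vmap[e$target])
    key <- paste0(e$source, "\r", e$target)
    if (anyDuplicated(key)) {
      e <- do.call(rbind, lapply(split(e, key), function(grp) {
        data.frame(source = grp$source[[1L]], target = grp$target[[1L]],
                   strength = max(grp$strength), count = sum(grp$count),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  association_network(vertices = unname(vmap[network$vertices]), edges = e)
}
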