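# Strengths are serialized with 12 significant digits and JSON keys are
# emitted in sorted order, so identical runs give byte-identical files.

#' Read a training pair list from TSV
#'
#' Expects a tab-separated file with a header and columns `cue`, `target`,
#' and optionally `lambda` (numeric asymptote) and `context`. A cue cell
#' may hold several attributes separated by `|`; such rows are routed
#' through [encode_trial()] under the requested schema (one event per
#' attribute for elemental, a single conjunction vertex for configural).
#' A non-empty `context` cell is treated as one more stimulus attribute.
#'
#' @param path File path.
#' @param schema `"elemental"` or `"configural"`.
#' @return A [pair_list()] preserving row order.
#' @export
read_pairlist <- function(path, schema = c("elemental", "configural")) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8", check.names = TRUE)
  if (!all(c("cue", "target") %in% names(df)))
    stop("pair-list TSV needs 'cue' and 'target' columns; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  events <- list()
  for (i in seq_len(nrow(df))) {
    cue <- df$cue[[i]]
    if (is.na(cue) || !nzchar(cue))
      stop(sprintf("row %d: empty cue", i), call. = FALSE)
    attrs <- strsplit(cue, "|", fixed = TRUE)[[1L]]
    if ("context" %in% names(df) && !is.na(df$context[[i]]) &&
        nzchar(df$context[[i]]))
      attrs <- c(df$context[[i]], attrs)
    lambda <- NA_real_
    if ("lambda" %in% names(df) && !is.na(df$lambda[[i]]) &&
        nzchar(df$lambda[[i]])) {
      lambda <- suppressWarnings(as.numeric(df$lambda[[i]]))
      if (is.na(lambda))
        stop(sprintf("row %d: non-numeric lambda '%s'", i, df$lambda[[i]]),
             call. = FALSE)
    }
    evs <- encode_trial(schema, attrs, df$target[[i]])
    evs <- lapply(evs, function(ev) { ev$lambda <- lambda; ev })
    events <- c(events, evs)
  }
  pair_list(events, schema = schema)
}

#' Write a pair list to TSV
#'
#' Multi-cue events are written with `|`-joined cue attributes, so a
#' round-trip through [read_pairlist()] under the elemental schema
#' restores the same events.
#'
#' @param pairs A [pair_list()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pairlist <- function(pairs, path) {
  lines <- c("cue\ttarget\tlambda",
             vapply(pairs$events, function(ev) {
               sprintf("%s\t%s\t%s", paste(ev$cues, collapse = "|"),
                       ev$target,
                       if (is.na(ev$lambda)) "" else format_strength(ev$lambda))
             }, character(1)))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

format_strength <- function(x) {
  vapply(x, function(v) format(signif(v, 12), scientific = FALSE, trim = TRUE),
         character(1))
}

network_to_json <- function(network, network_type_name = "untyped") {
  e <- network$edges[order(network$edges$source, network$edges$target),
                     , drop = FALSE]
  edges <- lapply(seq_len(nrow(e)), function(i)
    list(count = e$count[[i]], source = e$source[[i]],
         strength = as.numeric(format_strength(e$strength[[i]])),
         target = e$target[[i]]))
  jsonlite::toJSON(
    list(edges = edges,
         network_type = network_type_name,
         vertices = sort(network$vertices, method = "radix")),
    auto_unbox = TRUE, digits = NA)
}

#' Write / read an association network as JSON
#'
#' The schema is `{"edges": [{"count", "source", "strength", "target"}],
#' "network_type": name, "vertices": [...]}` with sorted keys and sorted
#' vertex/edge order; `read_network(write_network(x))` reproduces `x`.
#'
#' @param network An [association_network()].
#' @param path File path.
#' @param network_type_name Label stored in the file.
#' @return `write_network`: `path`, invisibly. `read_network`: the network.
#' @export
write_network <- function(network, path, network_type_name = "untyped") {
  writeLines(network_to_json(network, network_type_name), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$vertices) && is.null(obj$edges))
    stop("not a network JSON file: ", path, call. = FALSE)
  edges <- if (length(obj$edges)) {
    as.data.frame(obj$edges, stringsAsFactors = FALSE)
  } else empty_edges()
  association_network(vertices = unlist(obj$vertices), edges = edges)
}

#' Write / read a snapshot stream as JSON lines
#'
#' One network JSON object per line, in temporal order (`g1` first).
#'
#' @param s A [stream()] of association networks.
#' @param path File path.
#' @return `write_snapshots`: `path`, invisibly. `read_snapshots`: a list
#'   of networks.
#' @export
write_snapshots <- function(s, path) {
  writeLines(vapply(s$elements, network_to_json, character(1)), path)
  invisible(path)
}

#' @rdname write_snapshots
#' @export
read_snapshots <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    edges <- if (length(obj$edges))
      as.data.frame(obj$edges, stringsAsFactors = FALSE) else empty_edges()
    association_network(vertices = unlist(obj$vertices), edges = edges)
  })
}

#' Export a network in Graphviz DOT format
#'
#' One edge statement per association, labelled with the strength rounded
#' to 3 decimals.
#'
#' @param network An [association_network()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
export_dot <- function(network, path) {
  e <- network$edges[order(network$edges$source, network$edges$target),
                     , drop = FALSE]
  isolated <- setdiff(network$vertices, c(e$source, e$target))
  lines <- c(
    "digraph association_network {",
    sprintf('  "%s";', sort(isolated, method = "radix")),
    sprintf('  "%s" -> "%s" [label=%.3f];', e$source, e$target, e$strength),
    "}")
  writeLines(lines, path)
  invisible(path)
}
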