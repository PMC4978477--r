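# Independent brute-force oracle for unfold: a plain repeat-loop that
# accumulates emissions, sharing no code with coalearn::unfold().
oracle_unfold <- function(coalg, state, budget) {
  out <- list()
  terminated <- FALSE
  steps <- 0L
  repeat {
    if (isTRUE(coalg$halt(state))) { terminated <- TRUE; break }
    if (steps >= budget) break
    out <- c(out, list(coalg$emit(state)))
    state <- coalg$next_state(state)
    steps <- steps + 1L
  }
  list(elements = out, terminated = terminated)
}

# Random pair list over small vocabularies; caller controls the RNG seed.
random_pair_list <- function(n, n_cues = 6L, n_targets = 6L) {
  pair_list_from_map(sample(paste0("c", seq_len(n_cues)), n, replace = TRUE),
                     sample(paste0("t", seq_len(n_targets)), n, replace = TRUE))
}

# Random halfway-rule network built by replaying a random history, so it is
# always a reachable network state.
random_network <- function(n_events = 5L) {
  rlearn_fold(random_pair_list(n_events), association_network(),
              merge_rule("halfway"))
}

# Tally oracle: expected co-occurrence counts from an event history.
tally_counts <- function(pairs) {
  keys <- vapply(pairs$events,
                 function(ev) paste0(ev$cues[[1L]], "\r", ev$target),
                 character(1))
  table(keys)
}

expect_network_equal <- function(a, b, tol = 1e-12) {
  expect_true(network_equal(a, b, tol = tol))
}

# Scratch-file helpers for the IO tests.
tmp_path <- function(name) file.path(tempdir(), name)

tmp_json <- function(text) {
  p <- tempfile(fileext = ".json")
  writeLines(text, p)
  p
}
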