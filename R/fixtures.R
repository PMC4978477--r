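# Shape/suit glyphs used as vertex ids (Unicode ids are first-class);
# ASCII aliases travel with each fixture for display-poor terminals.
glyph <- c(
  white_square   = "\u25a1", # white square
  white_triangle = "\u25b3", # white triangle
  heart          = "\u2661", # heart
  diamond        = "\u25c7", # diamond
  black_triangle = "\u25b4", # black triangle
  black_square   = "\u25fe", # black square
  club           = "\u2663", # club
  spade          = "\u2660"  # spade
)

#' Built-in worked-example fixtures
#'
#' Returns one of the small, fully specified training problems used
#' throughout the package's examples and tests:
#'
#' * `bread_butter`: the three-pair list
#'   (bread, butter), (knife, fork), (knife, butter) — the canonical trace
#'   of the external-memory learning model.
#' * `ws1`: four word-to-shape associations, bell/kite/tent/yacht to
#'   white square / white triangle / heart / diamond, trained in mapping
#'   order.
#' * `ws2`: four word-to-symbol associations, goat/lion/mule/toad to
#'   black triangle / black square / club / spade; training order starts
#'   (toad, spade), (lion, black square), then follows the mapping order
#'   for the remaining pairs (the full order is a documented convention).
#' * `configural_ca`: the colour-by-shape discrimination
#'   (black, square) -> "+", (black, triangle) -> "-",
#'   (white, square) -> "-", (white, triangle) -> "+"; solvable only with
#'   conjunction cues. Comes with both the configural type `G_C`
#'   (conjunctions representable) and its elemental counterpart `G_E`
#'   in `$ntype_elemental`.
#' * `rat_odour_food`: a species-typed problem — rats acquire
#'   odour-to-food but not colour-to-food or tone-to-food associations;
#'   the network type allows only the odour-to-food signature.
#' * `quail_colour_water`: quails avoid coloured water later paired with
#'   illness; colour-to-illness is the only allowed signature (odour is
#'   representable but not connectable).
#' * `pigeon_selectivity`: pigeons associate colour with food and tone
#'   with shock avoidance, but not the converse pairings.
#'
#' The `expected` element documents derivable facts (edge counts, recall
#' targets, snapshot counts); the test suite recomputes them from the pair
#' list rather than trusting the record.
#'
#' @param name One of `"bread_butter"`, `"ws1"`, `"ws2"`,
#'   `"configural_ca"`, `"rat_odour_food"`, `"quail_colour_water"`,
#'   `"pigeon_selectivity"`.
#' @return A list with `name`, `pairs` (a [pair_list()]), `ntype`
#'   (a [network_type()]), `aliases` (ASCII names for any glyph ids),
#'   and `expected`.
#' @examples
#' fx <- fixture("ws1")
#' fx$pairs
#' @export
fixture <- function(name) {
  known <- c("bread_butter", "ws1", "ws2", "configural_ca",
             "rat_odour_food", "quail_colour_water", "pigeon_selectivity")
  if (length(name) != 1L || !name %in% known)
    stop("unknown fixture; available: ", paste(known, collapse = ", "),
         call. = FALSE)
  switch(name,
    bread_butter = list(
      name = name,
      pairs = pair_list(list(c("bread", "butter"), c("knife", "fork"),
                             c("knife", "butter"))),
      ntype = permissive_type(),
      aliases = character(),
      expected = list(n_snapshots = 3L, n_edges = 3L,
                      recall = c(bread = "butter"),
                      knife_out_degree = 2L)
    ),
    ws1 = list(
      name = name,
      pairs = pair_list_from_map(
        c("bell", "kite", "tent", "yacht"),
        unname(glyph[c("white_square", "white_triangle", "heart", "diamond")])),
      ntype = network_type(
        classes = list(word = c("bell", "kite", "tent", "yacht"),
                       shape = unname(glyph[c("white_square", "white_triangle",
                                              "heart", "diamond")])),
        signatures = data.frame(from = "word", to = "shape")),
      aliases = stats::setNames(c("white_square", "white_triangle", "heart", "diamond"),
                      unname(glyph[c("white_square", "white_triangle",
                                     "heart", "diamond")])),
      expected = list(n_edges = 4L,
                      recall = stats::setNames(
                        unname(glyph[c("white_square", "white_triangle",
                                       "heart", "diamond")]),
                        c("bell", "kite", "tent", "yacht")))
    ),
    ws2 = list(
      name = name,
      # Mapping order: goat, lion, mule, toad. Printed training prefix is
      # (toad, spade), (lion, black square); the rest follows mapping order.
      pairs = pair_list_from_map(
        c("toad", "lion", "goat", "mule"),
        unname(glyph[c("spade", "black_square", "black_triangle", "club")])),
      ntype = network_type(
        classes = list(word = c("goat", "lion", "mule", "toad"),
                       shape = unname(glyph[c("black_triangle", "black_square",
                                              "club", "spade")])),
        signatures = data.frame(from = "word", to = "shape")),
      aliases = stats::setNames(c("black_triangle", "black_square", "club", "spade"),
                      unname(glyph[c("black_triangle", "black_square",
                                     "club", "spade")])),
      expected = list(n_edges = 4L,
                      recall = stats::setNames(
                        unname(glyph[c("black_triangle", "black_square",
                                       "club", "spade")]),
                        c("goat", "lion", "mule", "toad")))
    ),
    configural_ca = local({
      stimuli <- list(c("black", "square"), c("black", "triangle"),
                      c("white", "square"), c("white", "triangle"))
      outcomes <- c("+", "-", "-", "+")
      conj <- vapply(stimuli, conjunction_id, character(1))
      list(
        name = name,
        pairs = pair_list(Map(function(s, o) c(conjunction_id(s), o),
                              stimuli, outcomes),
                          schema = "configural"),
        stimuli = stimuli, outcomes = outcomes,
        ntype = network_type(
          classes = list(conjunction = conj, response = c("+", "-")),
          signatures = data.frame(from = "conjunction", to = "response"),
          configural = TRUE),
        ntype_elemental = network_type(
          classes = list(colour = c("black", "white"),
                         shape = c("square", "triangle"),
                         response = c("+", "-")),
          signatures = data.frame(from = c("colour", "shape"),
                                  to = c("response", "response")),
          configural = FALSE),
        aliases = character(),
        expected = list(n_edges = 4L,
                        recall = stats::setNames(outcomes, conj))
      )
    }),
    rat_odour_food = list(
      name = name,
      pairs = pair_list(list(c("odour:almond", "food:pellet"),
                             c("odour:vanilla", "food:mash"))),
      ntype = network_type(
        classes = list(odour = character(), colour = character(),
                       tone = character(), food = character()),
        signatures = data.frame(from = "odour", to = "food")),
      aliases = character(),
      expected = list(n_edges = 2L,
                      forbidden = list(c("colour:red", "food:pellet"),
                                       c("tone:buzz", "food:pellet")))
    ),
    quail_colour_water = list(
      name = name,
      pairs = pair_list(list(c("colour:blue", "illness:nausea"))),
      ntype = network_type(
        classes = list(colour = character(), odour = character(),
                       illness = character()),
        signatures = data.frame(from = "colour", to = "illness")),
      aliases = character(),
      expected = list(n_edges = 1L,
                      forbidden = list(c("odour:sour", "illness:nausea")))
    ),
    pigeon_selectivity = list(
      name = name,
      pairs = pair_list(list(c("colour:green", "food:grain"),
                             c("tone:whistle", "avoid:shock"))),
      ntype = network_type(
        classes = list(colour = character(), tone = character(),
                       food = character(), avoid = character()),
        signatures = data.frame(from = c("colour", "tone"),
                                to = c("food", "avoid"))),
      aliases = character(),
      expected = list(n_edges = 2L,
                      forbidden = list(c("tone:whistle", "food:grain"),
                                       c("colour:green", "avoid:shock")))
    )
  )
}

#' List the available fixture names
#'
#' @return Character vector of names accepted by [fixture()].
#' @export
fixture_names <- function() {
  c("bread_butter", "ws1", "ws2", "configural_ca",
    "rat_odour_food", "quail_colour_water", "pigeon_selectivity")
}

#' Generate a seeded two-list learning condition
#'
#' Produces the two training lists of a list-learning design:
#'
#' * `AB_CD`: the second list uses fresh cues and fresh targets — no
#'   cue or target is repeated within or between lists (elemental
#'   transfer condition).
#' * `AB_ABr`: the second list re-pairs the first list's cues and targets
#'   under a derangement, so both lists share their vertex sets but no
#'   (cue, target) pair occurs in both (configural interference
#'   condition: only list context plus cue predicts the outcome).
#'
#' Output is deterministic for a given seed.
#'
#' @param cues,targets Character vocabularies to draw from. `AB_CD` needs
#'   at least `2 * n_pairs` of each; `AB_ABr` at least `n_pairs` (and
#'   `n_pairs >= 2` so a derangement exists).
#' @param n_pairs Number of pairs per list.
#' @param condition `"AB_CD"` or `"AB_ABr"`.
#' @param seed Integer seed.
#' @return List with `list1` and `list2`, both [pair_list()]s, and
#'   `condition`.
#' @examples
#' gl <- generate_pairlist(paste0("c", 1:8), paste0("t", 1:8),
#'                         n_pairs = 4, condition = "AB_CD", seed = 7)
#' gl$list1
#' @export
generate_pairlist <- function(cues, targets, n_pairs,
                              condition = c("AB_CD", "AB_ABr"), seed = 1L) {
  condition <- match.arg(condition)
  cues <- unique(as.character(cues))
  targets <- unique(as.character(targets))
  stopifnot(n_pairs >= 1)
  need <- if (condition == "AB_CD") 2L * n_pairs else n_pairs
  if (length(cues) < need || length(targets) < need)
    stop(sprintf("condition %s with %d pairs needs at least %d cues and %d targets",
                 condition, n_pairs, need, need), call. = FALSE)
  if (condition == "AB_ABr" && n_pairs < 2L)
    stop("AB_ABr needs at least 2 pairs for a derangement to exist",
         call. = FALSE)
  local_rng(seed, {
    if (condition == "AB_CD") {
      cu <- sample(cues, 2L * n_pairs)
      ta <- sample(targets, 2L * n_pairs)
      list(list1 = pair_list_from_map(cu[seq_len(n_pairs)],
                                      ta[seq_len(n_pairs)]),
           list2 = pair_list_from_map(cu[n_pairs + seq_len(n_pairs)],
                                      ta[n_pairs + seq_len(n_pairs)]),
           condition = condition)
    } else {
      cu <- sample(cues, n_pairs)
      ta <- sample(targets, n_pairs)
      list(list1 = pair_list_from_map(cu, ta),
           list2 = pair_list_from_map(cu, ta[derangement(n_pairs)]),
           condition = condition)
    }
  })
}

# Uniform random derangement by rejection; n is small in every design here.
derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}
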