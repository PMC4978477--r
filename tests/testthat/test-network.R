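test_that("halfway merge creates a first edge at sigma0 and strengthens on repeats", {
  rule <- merge_rule("halfway", sigma0 = 0.5)
  g1 <- merge_halfway(c("bread", "butter"), association_network(), rule)
  expect_equal(n_edges(g1), 1L)
  expect_equal(edge_strength(g1, "bread", "butter"), 0.5)
  expect_setequal(g1$vertices, c("bread", "butter"))

  g2 <- merge_halfway(c("bread", "butter"), g1, rule)
  expect_equal(edge_strength(g2, "bread", "butter"), 0.75)
  expect_equal(g2$edges$count, 2L)
  # input unchanged (value semantics)
  expect_equal(edge_strength(g1, "bread", "butter"), 0.5)
})

test_that("repeated halfway updates approach 1 within 1e-6 in at most 30 steps", {
  rule0 <- merge_rule("halfway")
  for (sigma0 in c(0.01, 0.25, 0.5, 0.9, 0.999)) {
    rule <- merge_rule("halfway", sigma0 = sigma0)
    g <- association_network()
    sigma_prev <- 0
    for (i in 1:30) {
      g <- merge_halfway(c("a", "b"), g, rule)
      sigma <- edge_strength(g, "a", "b")
      expect_gt(sigma, sigma_prev)   # strictly monotone
      expect_lte(sigma, 1)
      sigma_prev <- sigma
    }
    expect_lt(abs(1 - edge_strength(g, "a", "b")), 1e-6)
  }
})

test_that("default sigma0 traces sigma_n = 1 - 2^-n", {
  rule <- merge_rule("halfway")
  g <- association_network()
  for (n in 1:12) {
    g <- merge_halfway(c("x", "y"), g, rule)
    expect_equal(edge_strength(g, "x", "y"), 1 - 2^-n)
  }
})

test_that("halfway updates on all-distinct pairs commute under permutation", {
  rule <- merge_rule("halfway")
  base <- pair_list_from_map(paste0("c", 1:6), paste0("t", 1:6))
  ref <- rlearn_fold(base, association_network(), rule)
  set.seed(11)
  for (i in 1:10) {
    perm <- pair_list(base$events[sample.int(6)])
    expect_network_equal(rlearn_fold(perm, association_network(), rule), ref)
  }
})

test_that("occurrence counts match a tally oracle over random histories", {
  rule <- merge_rule("halfway")
  set.seed(5)
  for (i in 1:10) {
    pairs <- random_pair_list(30, n_cues = 4, n_targets = 3)
    g <- rlearn_fold(pairs, association_network(), rule)
    want <- tally_counts(pairs)
    got <- stats::setNames(g$edges$count,
                           paste0(g$edges$source, "\r", g$edges$target))
    expect_setequal(names(got), names(want))
    expect_equal(got[names(want)], stats::setNames(as.integer(want), names(want)))
  }
})

test_that("Rescorla-Wagner single-cue acquisition matches the closed form", {
  # closed form for repeated single-cue trials: V_n = lambda (1 - (1 - ab)^n)
  for (params in list(c(a = 0.3, b = 1, l = 1), c(a = 0.1, b = 0.5, l = 2),
                      c(a = 0.9, b = 0.2, l = 0.5))) {
    rule <- merge_rule("rescorla_wagner", alpha_default = params[["a"]],
                       beta = params[["b"]], lambda = params[["l"]])
    g <- association_network()
    ab <- params[["a"]] * params[["b"]]
    for (n in 1:100) {
      g <- merge_rescorla_wagner(list(cues = "cs", outcome = "us"), g, rule)
      expect_equal(edge_strength(g, "cs", "us"),
                   params[["l"]] * (1 - (1 - ab)^n), tolerance = 1e-9)
    }
  }
})

test_that("a cue pre-trained to asymptote blocks a novel compound cue", {
  rule <- merge_rule("rescorla_wagner", alpha_default = 0.3, beta = 1, lambda = 1)
  g <- association_network()
  while (abs(1 - edge_strength(g, "A", "us", default = 0)) >= 1e-6)
    g <- merge_rescorla_wagner(list(cues = "A", outcome = "us"), g, rule)
  for (i in 1:10)
    g <- merge_rescorla_wagner(list(cues = c("A", "B"), outcome = "us"), g, rule)
  expect_lt(abs(edge_strength(g, "B", "us")), 1e-5)
})

test_that("Rescorla-Wagner supports per-cue salience, per-trial lambda and inhibition", {
  rule <- merge_rule("rescorla_wagner", alpha = c(A = 0.5), alpha_default = 0.1,
                     beta = 1, lambda = 1)
  g <- merge_rescorla_wagner(list(cues = c("A", "B"), outcome = "us"),
                             association_network(), rule)
  expect_equal(edge_strength(g, "A", "us"), 0.5)   # named salience
  expect_equal(edge_strength(g, "B", "us"), 0.1)   # default fallback

  # extinction below zero is representable (conditioned inhibition)
  g2 <- merge_rescorla_wagner(list(cues = c("A", "B"), outcome = "us",
                                   lambda = 0), g, rule)
  expect_lt(edge_strength(g2, "A", "us"), edge_strength(g, "A", "us"))
  expect_true(all(is.finite(g2$edges$strength)))
})

test_that("multiplicative decay shrinks existing strengths before each merge", {
  rule <- merge_rule("halfway", sigma0 = 0.5, decay = 0.9)
  g <- merge_halfway(c("a", "b"), association_network(), rule)
  g <- merge_halfway(c("c", "d"), g, rule)
  expect_equal(edge_strength(g, "a", "b"), 0.45)    # decayed once, not merged
  expect_equal(edge_strength(g, "c", "d"), 0.5)     # fresh edge, no decay yet
  g <- merge_halfway(c("a", "b"), g, rule)
  expect_equal(edge_strength(g, "a", "b"), (1 + 0.9 * 0.45) / 2)
})

test_that("recall returns the strongest associate, exposing ties deterministically", {
  rule <- merge_rule("halfway")
  g <- rlearn_fold(fixture("bread_butter")$pairs, association_network(), rule)
  r <- recall(g, "bread")
  expect_equal(r$prediction, "butter")
  expect_equal(r$ties, "butter")

  rk <- recall(g, "knife")
  expect_setequal(rk$ties, c("butter", "fork"))
  expect_equal(rk$prediction, "butter")  # lexicographic tie-break
  expect_equal(rk$strength, 0.5)

  r0 <- recall(g, "fork")   # no outgoing edges
  expect_true(is.na(r0$prediction))
  expect_length(r0$ties, 0)
})

test_that("validate_pair enforces species-typed signatures", {
  rat <- fixture("rat_odour_food")$ntype
  expect_true(validate_pair(rat, c("odour:almond", "food:pellet"))$ok)

  v <- validate_pair(rat, c("colour:red", "food:pellet"))
  expect_false(v$ok)
  expect_match(v$violations, "colour -> food", all = FALSE)

  v2 <- validate_pair(rat, c("unclassifiable", "food:pellet"))
  expect_false(v2$ok)
  expect_match(v2$violations, "unrepresentable vertex", all = FALSE)

  perm <- permissive_type()
  expect_true(validate_pair(perm, c("anything", "goes"))$ok)
})

test_that("apply_type_map renames, preserves structure, and merges collisions by max", {
  rule <- merge_rule("halfway")
  g <- rlearn_fold(fixture("ws1")$pairs, association_network(), rule)

  idm <- stats::setNames(g$vertices, g$vertices)
  expect_network_equal(apply_type_map(idm, g), g)

  # bijective rename: isomorphic network, same strength multiset
  bij <- stats::setNames(paste0(g$vertices, "'"), g$vertices)
  h <- apply_type_map(bij, g)
  expect_equal(n_edges(h), n_edges(g))
  expect_equal(sort(h$edges$strength), sort(g$edges$strength))
  # homomorphism: mapped endpoints are maps of the original endpoints
  orig <- g$edges[order(g$edges$source, g$edges$target), ]
  mapped <- h$edges[order(h$edges$source, h$edges$target), ]
  expect_setequal(paste(unname(bij[orig$source]), unname(bij[orig$target])),
                  paste(mapped$source, mapped$target))

  # collapsing two cues with edges to one target keeps the max strength
  toy <- association_network(edges = data.frame(
    source = c("a", "b", "c"), target = c("z", "z", "z"),
    strength = c(0.5, 0.75, 0.2), count = c(1L, 2L, 1L)))
  vm <- c(a = "ab", b = "ab", c = "c", z = "z")
  collapsed <- apply_type_map(vm, toy)
  expect_equal(n_edges(collapsed), 2L)
  expect_equal(edge_strength(collapsed, "ab", "z"), 0.75)

  expect_error(apply_type_map(c(a = "x"), toy), "undefined on")
})

test_that("network invariants are enforced at construction", {
  expect_error(association_network(edges = data.frame(
    source = c("a", "a"), target = c("b", "b"),
    strength = c(0.5, 0.6), count = c(1L, 1L))), "duplicate edge")
  expect_error(association_network(edges = data.frame(
    source = "a", target = "b", strength = Inf, count = 1L)), "finite")
})
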