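test_that("interaction match scoring follows the class-compatibility rules", {
  p <- interaction_params()
  expect_equal(interaction_match_score(tp(1, 5, "cWW"), tp(2, 6, "cWW"), p),
               p$pair_full)
  # symmetric endpoint flip is a full match
  expect_equal(interaction_match_score(tp(1, 5, "tHS"), tp(2, 6, "tSH"), p),
               p$pair_full)
  expect_equal(interaction_match_score(tp(1, 5, "cWW"), tp(2, 6, "tHS"), p), 0)
  # orientation-only and single-edge agreements are partial
  expect_equal(interaction_match_score(tp(1, 5, "cWW"), tp(2, 6, "cHS"), p),
               p$pair_partial)
  expect_equal(interaction_match_score(tp(1, 5, "tWS"), tp(2, 6, "cWH"), p),
               p$pair_partial)
  # kind mismatch scores zero; stacks match at the stack score
  expect_equal(interaction_match_score(tp(1, 5, "cWW"), ts(2, 3), p), 0)
  expect_equal(interaction_match_score(ts(1, 2), ts(5, 6), p), p$stack)
})

test_that("compatibility graphs enforce one-to-one order-consistent matching", {
  A <- toy_graph(c("A", "A", "A"))
  g <- build_compatibility_graph(A, A)
  # identical bases everywhere positive: no pruning, |A| x |B| vertices
  expect_equal(nrow(g$vertices), 9L)
  vid <- function(u, v) which(g$vertices$u == u & g$vertices$v == v)
  # the identity triple is mutually compatible
  expect_true(g$adj[vid(1, 1), vid(2, 2)])
  expect_true(g$adj[vid(2, 2), vid(3, 3)])
  # crossing matches within a segment are not
  expect_false(g$adj[vid(1, 2), vid(2, 1)])
  # reusing a nucleotide on either side is not
  expect_false(g$adj[vid(1, 1), vid(1, 2)])
  expect_false(g$adj[vid(1, 1), vid(2, 1)])
})

test_that("self-alignment recovers the identity matching with all interactions", {
  g <- toy_graph(c("A", "G", "C", "U", "G", "C"),
                 segments = rep(1:2, each = 3L),
                 pairs = dplyr::bind_rows(tp(1, 6, "tHS"), tp(2, 5, "cWW")),
                 stacks = dplyr::bind_rows(ts(1, 2), ts(2, 3)))
  al <- align_interactions(g, g)
  expect_equal(al$aligned_length, 6L)
  expect_equal(al$matches$u, al$matches$v)
  expect_equal(al$matched_pairs, 2L)
  expect_equal(al$matched_stacks, 2L)
})

test_that("a single shared pair with no sequence identity aligns exactly that pair", {
  p <- interaction_params()
  A <- toy_graph(c("A", "A", "G", "G"), pairs = tp(1, 3, "tHS"))
  B <- toy_graph(c("C", "C", "U", "U"), pairs = tp(2, 4, "tHS"))
  al <- align_interactions(A, B, p)
  expect_equal(al$aligned_length, 2L)
  expect_equal(al$matches, tibble::tibble(u = c(1L, 3L), v = c(2L, 4L)))
  expect_equal(al$score, p$pair_full + 2 * p$seq_mismatch)
  # matches the exhaustive enumeration oracle
  expect_equal(al$score, brute_force_align_score(A, B, p))
})

test_that("clique search equals exhaustive enumeration on random small graphs", {
  p <- interaction_params()
  set.seed(301)
  for (k in 1:12) {
    A <- random_graph(sample(3:6, 1), n_pairs = sample(0:2, 1),
                      n_segments = sample(1:2, 1))
    B <- random_graph(sample(3:6, 1), n_pairs = sample(0:2, 1),
                      n_segments = sample(1:2, 1))
    expect_equal(align_interactions(A, B, p)$score,
                 brute_force_align_score(A, B, p),
                 tolerance = 1e-9,
                 info = sprintf("case %d", k))
  }
})

test_that("alignment score is symmetric and bounded by self-alignment", {
  p <- interaction_params()
  set.seed(302)
  for (k in 1:10) {
    A <- random_graph(sample(4:7, 1), n_pairs = 2)
    B <- random_graph(sample(4:7, 1), n_pairs = 2)
    sab <- align_interactions(A, B, p)$score
    sba <- align_interactions(B, A, p)$score
    expect_equal(sab, sba, tolerance = 1e-9)
    expect_gte(align_interactions(A, A, p)$score, sab)
    expect_lte(align_interactions(A, B, p)$aligned_length,
               min(nrow(A$nucleotides), nrow(B$nucleotides)))
  }
})

test_that("adding a shared interaction never decreases the optimal score", {
  p <- interaction_params()
  set.seed(303)
  for (k in 1:8) {
    A <- random_graph(6, n_pairs = 1)
    B <- random_graph(6, n_pairs = 1)
    s0 <- align_interactions(A, B, p)$score
    A2 <- A; B2 <- B
    A2$pairs <- dplyr::bind_rows(A2$pairs, tp(2, 5, "tWH"))
    B2$pairs <- dplyr::bind_rows(B2$pairs, tp(2, 5, "tWH"))
    s1 <- align_interactions(A2, B2, p)$score
    expect_gte(s1, s0 - 1e-9)
  }
})

test_that("greedy mode returns a valid (possibly suboptimal) alignment", {
  set.seed(304)
  A <- random_graph(8, n_pairs = 3)
  B <- random_graph(8, n_pairs = 3)
  exact <- align_interactions(A, B, interaction_params())
  greedy <- align_interactions(A, B, interaction_params(greedy = TRUE))
  expect_lte(greedy$score, exact$score + 1e-9)
  expect_equal(anyDuplicated(greedy$matches$u), 0L)
  expect_equal(anyDuplicated(greedy$matches$v), 0L)
})

test_that("empty graphs yield an empty alignment", {
  A <- toy_graph(character(0))
  B <- toy_graph(c("A", "G"))
  al <- align_interactions(A, B)
  expect_equal(al$aligned_length, 0L)
  expect_equal(al$score, 0)
})
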