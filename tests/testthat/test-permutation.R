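sparse_F <- function() {
  vaf_matrix(rbind(c(0.5, 0, 0), c(0.9, 0.3, 0.2)),
             c("A", "B", "C"), c("t1", "t2"))
}

test_that("mutation groups partition variants by first observation", {
  g <- mutation_groups(sparse_F())
  expect_equal(length(g$groups), 2L)
  expect_equal(g$groups[[1]], 1L)
  expect_equal(g$groups[[2]], c(2L, 3L))
  expect_equal(g$times, c(1L, 2L))
})

test_that("indistinguishable co-appearing trajectories are merged", {
  F <- vaf_matrix(cbind(c(0, 0.30, 0.52), c(0, 0.31, 0.50)), c("x", "y"))
  m <- group_mutations(F, similarity_tol = 0.05)
  expect_equal(length(m$vaf$variant_ids), 1L)
  expect_equal(m$vaf$variant_ids, "x+y")
  expect_equal(unname(m$vaf$values[, 1]), c(0, 0.305, 0.51))
  expect_equal(m$members[["x+y"]], c("x", "y"))
  # trajectories differing beyond the tolerance stay separate
  F2 <- vaf_matrix(cbind(c(0, 0.3, 0.5), c(0, 0.3, 0.1)))
  m2 <- group_mutations(F2, similarity_tol = 0.05)
  expect_equal(length(m2$vaf$variant_ids), 2L)
  # distinct first-observation times: nothing merged even at a huge tol
  F3 <- vaf_matrix(rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3)))
  m3 <- group_mutations(F3, similarity_tol = 0.5)
  expect_equal(m3$vaf$values, F3$values)
})

test_that("matrix extension inserts virtual rows under the given order", {
  F <- sparse_F()
  e1 <- extend_vaf(F, orders = list("A", c("B", "C")))
  expect_equal(unname(e1$square$values),
               rbind(c(0.5, 0, 0), c(0.9, 0.3, 0), c(0.9, 0.3, 0.2)))
  expect_equal(e1$square$variant_ids, c("A", "B", "C"))
  expect_equal(e1$row_map, c(1L, NA_integer_, 2L))
  # alternate order: columns reordered to birth order A, C, B
  e2 <- extend_vaf(F, orders = list("A", c("C", "B")))
  expect_equal(e2$square$variant_ids, c("A", "C", "B"))
  expect_equal(unname(e2$square$values),
               rbind(c(0.5, 0, 0), c(0.9, 0.2, 0), c(0.9, 0.2, 0.3)))
  # already-square input is unchanged
  Fsq <- vaf_matrix(rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3)))
  e3 <- extend_vaf(Fsq)
  expect_equal(e3$square$values, Fsq$values)
  expect_error(extend_vaf(F, orders = list("A", c("B", "B"))), "bijection")
})

test_that("observed rows survive the extension unchanged", {
  for (s in 1:10) {
    truth <- simulate_population(8, seed = 700 + s)
    F <- observe_vaf(truth, 4, seed = s)
    ext <- suppressWarnings(extend_vaf(F))
    obs <- which(!is.na(ext$row_map))
    expect_equal(unname(ext$square$values[obs, order(ext$order)]),
                 unname(F$values[ext$row_map[obs], ]))
    expect_true(is_square_vaf(ext$square))
  }
})

test_that("exhaustive permutation search counts and scores all extensions", {
  F <- sparse_F()
  ep <- exhaustive_permutation_search(F, "et")
  expect_equal(ep$n_candidates, 2L)  # 1! * 2!
  # brute force over both extensions
  s1 <- exhaustive_tree_search(extend_vaf(F, list("A", c("B", "C")))$square)
  s2 <- exhaustive_tree_search(extend_vaf(F, list("A", c("C", "B")))$square)
  expect_equal(ep$result$score$value, max(s1$score$value, s2$score$value))
  # singleton groups degenerate to a single tree search
  Fsq <- vaf_matrix(rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3)))
  ep2 <- exhaustive_permutation_search(Fsq, "et")
  expect_equal(ep2$n_candidates, 1L)
  expect_equal(ep2$result$tree$parent, exhaustive_tree_search(Fsq)$tree$parent)
})

test_that("candidate count equals the product of group-size factorials", {
  for (s in 1:8) {
    truth <- simulate_population(7, seed = 900 + s)
    F <- observe_vaf(truth, 3, seed = s)
    g <- mutation_groups(F)
    ep <- exhaustive_permutation_search(F, "gt")
    expect_equal(ep$n_candidates, prod(factorial(g$sizes)))
  }
})

test_that("greedy permutation search matches EP-GT on simple instances", {
  Fsq <- vaf_matrix(rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3)))
  gp <- greedy_permutation_search(Fsq)
  expect_equal(gp$result$tree$parent, greedy_tree_search(Fsq)$tree$parent)
  # one group of size 2: GP commits the higher-scoring permutation
  F <- sparse_F()
  gp2 <- greedy_permutation_search(F)
  ep2 <- exhaustive_permutation_search(F, "gt")
  expect_equal(gp2$result$score$value, ep2$result$score$value)
})

test_that("EP-GT dominates GP-GT on randomized sparse instances", {
  for (s in 1:12) {
    truth <- simulate_population(7, seed = 1100 + s)
    F <- observe_vaf(truth, sample(2:4, 1), seed = s)
    gp <- greedy_permutation_search(F)
    ep <- exhaustive_permutation_search(F, "gt")
    expect_equal(gp$result$status, ep$result$status)
    if (gp$result$status == "found")
      expect_lte(gp$result$score$log_value,
                 ep$result$score$log_value + 1e-9)
  }
})

test_that("GP backtracks to the second-best permutation on dead ends", {
  # group {A, B} at t1, {C} at t2; the higher-scoring order (A, B) admits
  # no valid placement for C, the order (B, A) does
  F <- vaf_matrix(rbind(c(0.25, 0.6, 0), c(0.1, 0.35, 0.6)),
                  c("A", "B", "C"), c("t1", "t2"))
  gp <- greedy_permutation_search(F)
  expect_equal(gp$result$status, "found")
  expect_equal(gp$permutation[[1]], c("B", "A"))
  expect_equal(gp$result$tree$variant_ids, c("B", "A", "C"))
  # verify against the exhaustive permutation search
  ep <- exhaustive_permutation_search(F, "gt")
  expect_equal(gp$result$score$value, ep$result$score$value)
  # and that the committed-first order indeed fails outright
  e_ab <- extend_vaf(F, list(c("A", "B"), "C"))
  expect_equal(greedy_tree_search(e_ab$square)$status, "no_valid_solution")
})

test_that("random permutations are uniform per group and reproducible", {
  F <- sparse_F()
  expect_identical(random_permutation(F, seed = 3),
                   random_permutation(F, seed = 3))
  F3 <- vaf_matrix(rbind(c(0.3, 0.2, 0.1)), c("a", "b", "c"))
  seen <- unique(vapply(1:120, function(s)
    paste(random_permutation(F3, seed = s)[[1]], collapse = ""), character(1)))
  expect_equal(sort(seen), sort(c("abc", "acb", "bac", "bca", "cab", "cba")))
  # singleton groups give the identity
  expect_equal(random_permutation(vaf_matrix(matrix(0.5)), seed = 1)[[1]], "v1")
})
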