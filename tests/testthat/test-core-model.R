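worked3 <- function() {
  vaf_matrix(rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3)))
}

test_that("clone_frequency subtracts child VAFs from the parent's VAF", {
  F <- worked3()
  tr <- clonal_tree(c(0, 1, 1))
  expect_equal(clone_frequency(F, tr, i = 2, k = 1), 1.0 - 0.4)
  # founder fully displaced by its only child
  expect_equal(clone_frequency(F, tr, i = 1, k = 0), 0.0)
  # complement of a single variant
  F1 <- vaf_matrix(matrix(0.6))
  expect_equal(clone_frequency(F1, clonal_tree(0L), i = 1, k = 0), 0.4)
  expect_error(clone_frequency(F, tr, i = 4, k = 0), "out of range")
  expect_error(clone_frequency(F, tr, i = 1, k = 2), "not born")
})

test_that("tree likelihood is the product of parent-clone frequencies", {
  F <- worked3()
  s1 <- tree_likelihood(F, clonal_tree(c(0, 1, 1)))
  expect_equal(s1$value, 0.6)
  expect_equal(s1$factors, c(1.0, 0.6))
  s2 <- tree_likelihood(F, clonal_tree(c(0, 1, 2)))
  expect_equal(s2$value, 0.4)
  # empty product for a single variant
  s3 <- tree_likelihood(vaf_matrix(matrix(1.0)), clonal_tree(0L))
  expect_equal(s3$value, 1.0)
  expect_equal(s3$log_value, 0.0)
  # nonpositive factor makes the log -Inf
  F2 <- vaf_matrix(rbind(c(1, 0), c(0.6, 0.4)))
  s4 <- tree_likelihood(F2, clonal_tree(c(0, 0)))
  expect_true(s4$factors[1] <= 0)
  expect_identical(s4$log_value, -Inf)
})

test_that("validity flags child frequencies exceeding the parent's", {
  F <- vaf_matrix(rbind(c(0.8, 0), c(0.3, 0.6)))
  bad <- is_valid_tree(F, clonal_tree(c(0, 1)))
  expect_false(bad)
  expect_equal(attr(bad, "violation"), c(time = 2, parent = 1))
  expect_true(is_valid_tree(F, clonal_tree(c(0, 0))))
  expect_true(is_valid_tree(vaf_matrix(matrix(1.0)), clonal_tree(0L)))
  # relaxation tolerates the excess
  expect_true(is_valid_tree(F, clonal_tree(c(0, 1)), neg_tol = 0.4))
})

test_that("clonal frequency matrix inverts the VAF matrix for a tree", {
  F <- worked3()
  C <- compute_cfm(F, clonal_tree(c(0, 1, 1)))
  expect_equal(unname(C$values[3, ]), c(0.1, 0.1, 0.5, 0.3))
  expect_equal(unname(rowSums(C$values)), rep(1, 3))
  C1 <- compute_cfm(vaf_matrix(matrix(0.6)), clonal_tree(0L))
  expect_equal(unname(C1$values[1, ]), c(0.4, 0.6))
})

test_that("negative clone frequencies are clamped under neg_tol, else infeasible", {
  F <- vaf_matrix(rbind(c(0.8, 0), c(0.3, 0.6)))
  tr <- clonal_tree(c(0, 1))
  # c_{2,1} = 0.3 - 0.6 = -0.3: infeasible at neg_tol 0 ...
  expect_error(compute_cfm(F, tr, neg_tol = 0),
               class = "clonetrace_infeasible")
  # ... accepted, clamped and renormalized at neg_tol 0.4
  C <- compute_cfm(F, tr, neg_tol = 0.4)
  expect_equal(C$raw[2, "v1"][[1]], -0.3)
  expect_equal(C$values[2, "v1"][[1]], 0)
  expect_equal(unname(rowSums(C$values)), rep(1, 2))
})

test_that("forward model sums clone frequencies over subtrees", {
  chain <- clonal_tree(0L)
  V <- vaf_from_truth(chain, matrix(c(0.4, 0.6), 1))
  expect_equal(unname(V$values[1, 1]), 0.6)
  tr <- clonal_tree(c(0, 1))
  V2 <- vaf_from_truth(tr, matrix(c(0.1, 0.5, 0.4), 1))
  expect_equal(unname(V2$values[1, ]), c(0.9, 0.4))
})

test_that("round trip truth -> VAF -> CFM reproduces the clone frequencies", {
  for (s in 1:25) {
    truth <- simulate_population(sample(2:10, 1), seed = 400 + s)
    V <- vaf_from_truth(truth$tree, truth$trajectories)
    C <- compute_cfm(V, truth$tree, neg_tol = 0)
    expect_equal(unname(C$values), unname(truth$trajectories),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(C$values)), rep(1, nrow(C$values)),
                 tolerance = 1e-9)
  }
})

test_that("trees flagged invalid produce a negative clone frequency", {
  set.seed(77)
  n_invalid <- 0
  for (s in 1:40) {
    inst <- random_square_instance(9200 + s, n_min = 3, n_max = 5)
    N <- ncol(inst$F$values)
    pr <- vapply(seq_len(N), function(i) sample(0:(i - 1), 1), integer(1))
    tr <- clonal_tree(pr, inst$F$variant_ids)
    if (!isTRUE(is_valid_tree(inst$F, tr))) {
      n_invalid <- n_invalid + 1
      expect_error(compute_cfm(inst$F, tr, neg_tol = 0),
                   class = "clonetrace_infeasible")
    }
  }
  expect_gt(n_invalid, 0)  # the sample must actually exercise the branch
})

test_that("VAF matrices validate inputs and round-trip through TSV", {
  expect_error(vaf_matrix(matrix(1.2)), "\\[0, 1\\]")
  F <- worked3()
  expect_true(is_square_vaf(F))
  expect_false(is_square_vaf(vaf_matrix(rbind(c(0.5, 0.2), c(0.6, 0.3)))))
  expect_equal(F$first_obs, c(v1 = 1L, v2 = 2L, v3 = 3L))
  tmp <- tempfile(fileext = ".tsv")
  write_vaf(F, tmp)
  expect_equal(read_vaf(tmp)$values, F$values)
  tr <- clonal_tree(c(0, 1, 1), c("a", "b", "c"))
  tmp2 <- tempfile(fileext = ".tsv")
  write_tree(tr, tmp2)
  back <- read_tree(tmp2)
  expect_equal(back$parent, tr$parent)
  expect_equal(back$variant_ids, tr$variant_ids)
})

test_that("clonal trees validate parents and expose haplotypes", {
  expect_error(clonal_tree(c(0, 2)), "earlier-born")
  expect_error(clonal_tree(c(1)), "earlier-born")
  tr <- clonal_tree(c(0, 1, 1, 3))
  expect_equal(tree_haplotypes(tr)[[4]], c(1, 3, 4))
  expect_equal(tree_children(tr)[[2]], c(2L, 3L))  # children of node 1
  haps <- clone_haplotype_ids(tr)
  expect_setequal(haps[["v4"]], c("v1", "v3", "v4"))
})
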