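test_that("parent candidates come from the clones sharing the variant", {
  cl <- sequenced_clones(list(c("v1", "v2", "v4"), c("v1", "v3")))
  expect_setequal(parent_candidates(cl, "v2"), c("v1", "v4"))
  # variant in no clone: unconstrained
  expect_null(parent_candidates(cl, "v9"))
  # sole member of its clone: founder is the only possible parent
  expect_equal(parent_candidates(sequenced_clones(list("v1")), "v1"),
               "founder")
})

test_that("redundant clones are collapsed on construction", {
  cl <- sequenced_clones(list(c("a", "b"), c("b", "a"), "c", character(0)))
  expect_equal(length(cl$clones), 2L)
})

test_that("path consistency demands shared variants precede the branching", {
  cl <- sequenced_clones(list(c("v1", "v2"), c("v1", "v3")))
  good <- clonal_tree(c(0, 1, 1), c("v1", "v2", "v3"))   # v1 -> {v2, v3}
  expect_true(check_path_consistency(good, cl))
  bad <- clonal_tree(c(0, 1, 1), c("v2", "v1", "v3"))    # v2 above v1
  res <- check_path_consistency(bad, cl)
  expect_false(res)
  expect_equal(attr(res, "violation")$ancestor, "v1")
  # an empty clone set never constrains
  expect_true(check_path_consistency(bad, sequenced_clones(list())))
})

test_that("constraints redirect the greedy parent choice", {
  F <- vaf_matrix(rbind(c(1, 0, 0), c(0.9, 0.6, 0), c(0.8, 0.5, 0.3)))
  free <- reconstruct(F, "gt")
  expect_equal(free$tree$parent, c(0L, 1L, 2L))  # greedy hangs v3 on v2
  con <- reconstruct(F, "gt", clones = sequenced_clones(list(c("v1", "v3"))))
  expect_equal(con$tree$parent, c(0L, 1L, 1L))   # constraint forces v3 <- v1
  expect_lte(con$likelihood$value, free$likelihood$value)
  expect_true(check_path_consistency(con$tree,
                                     sequenced_clones(list(c("v1", "v3")))))
})

satisfies_parent_constraint <- function(tree, cl) {
  ids <- tree$variant_ids
  for (i in seq_along(ids)) {
    pc <- parent_candidates(cl, ids[i])
    if (is.null(pc)) next
    earlier <- intersect(pc, ids[seq_len(i - 1)])
    pid <- if (tree$parent[i] == 0) "founder" else ids[tree$parent[i]]
    if (length(earlier)) {
      if (!(pid %in% earlier)) return(FALSE)
    } else if (pid != "founder") {
      return(FALSE)
    }
  }
  TRUE
}

test_that("constraints consistent with the optimum leave it unchanged", {
  for (s in 1:12) {
    inst <- random_square_instance(3300 + s, n_min = 4, n_max = 6)
    free <- exhaustive_tree_search(inst$F)
    # supply two true haplotypes drawn from the generating tree
    haps <- clone_haplotype_ids(inst$truth_tree)
    cl <- sequenced_clones(haps[seq_len(min(2, length(haps)))])
    con <- reconstruct(inst$F, "et", clones = cl)
    expect_true(isTRUE(is_valid_tree(inst$F, con$tree)))
    expect_true(isTRUE(check_path_consistency(con$tree, cl)))
    if (isTRUE(check_path_consistency(free$tree, cl)) &&
        satisfies_parent_constraint(free$tree, cl)) {
      # the unconstrained optimum is feasible, so the scores must agree
      # (the trees themselves may differ only under likelihood ties)
      expect_equal(con$likelihood$log_value, free$score$log_value,
                   tolerance = 1e-9)
    } else {
      expect_lte(con$likelihood$log_value, free$score$log_value + 1e-9)
    }
  }
})

test_that("supplying true haplotypes never hurts the constrained search", {
  # small-scale version of the constrained-benefit experiment
  mis <- sapply(1:15, function(s) {
    truth <- simulate_population(10, seed = 4400 + s)
    F <- observe_vaf(truth, "binomial", seed = s)
    ids <- F$variant_ids
    truth_proj <- project_tree(truth$tree, ids)
    haps <- clone_haplotype_ids(truth$tree)
    set.seed(s)
    ord <- sample.int(10)
    vapply(c(0L, 4L), function(k) {
      cl <- NULL
      if (k > 0) {
        sets <- lapply(haps[ord[seq_len(k)]], intersect, y = ids)
        sets <- sets[lengths(sets) > 0]
        if (length(sets)) cl <- sequenced_clones(sets)
      }
      r <- reconstruct(F, "gp-gt", clones = cl)
      if (r$status != "found") return(NA_real_)
      (1 - clone_recall(r$tree, truth_proj, variants = ids)) * length(ids)
    }, numeric(1))
  })
  ok <- colSums(is.na(mis)) == 0
  expect_gt(sum(ok), 5)
  expect_lte(mean(mis[2, ok]), mean(mis[1, ok]))
})

test_that("clone ids resolve to merged group columns", {
  F <- vaf_matrix(cbind(c(0, 0.30, 0.52), c(0, 0.31, 0.50), c(0.4, 0.5, 0.6)),
                  c("x", "y", "z"))
  m <- group_mutations(F, similarity_tol = 0.05)
  cl <- resolve_clones(sequenced_clones(list(c("x", "z"))), m$vaf)
  expect_equal(cl$clones[[1]], sort(c("x+y", "z")))
  expect_error(resolve_clones(sequenced_clones(list("nope")), m$vaf),
               "not found")
})
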