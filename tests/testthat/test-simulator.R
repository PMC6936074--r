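test_that("simulated frequencies stay on the simplex with correct births", {
  for (s in 1:10) {
    truth <- simulate_population(sample(1:12, 1), seed = 600 + s)
    traj <- truth$trajectories
    N <- truth$params$n_clones
    expect_equal(unname(rowSums(traj)), rep(1, N), tolerance = 1e-9)
    expect_true(all(traj >= 0))
    # clone j does not exist before step j
    for (j in seq_len(N))
      if (j > 1) expect_true(all(traj[seq_len(j - 1), j + 1] == 0))
    expect_true(all(truth$tree$parent < seq_len(N)))
  }
  # a single clone descends from the founder
  t1 <- simulate_population(1, seed = 1)
  expect_equal(t1$tree$parent, 0L)
  expect_identical(simulate_population(6, seed = 9)$tree$parent,
                   simulate_population(6, seed = 9)$tree$parent)
})

test_that("parent sampling is proportional to clone frequencies", {
  set.seed(123)
  draws <- replicate(10000, clonetrace:::sample_parent(c(0.3, 0.7)))
  p_hat <- mean(draws == 1)
  expect_lt(abs(p_hat - 0.7), 0.015)
  tab <- table(factor(draws, levels = 0:1))
  expect_gt(stats::chisq.test(tab, p = c(0.3, 0.7))$p.value, 1e-4)
  # extinct clones are never chosen
  set.seed(5)
  expect_true(all(replicate(200, clonetrace:::sample_parent(c(0.5, 0, 0.5))) != 1))
})

test_that("drift keeps the simplex, zeros and the alpha = Inf limit", {
  set.seed(11)
  f <- c(0.5, 0, 0.3, 0.2)
  g <- clonetrace:::dirichlet_drift(f, 50)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_equal(g[2], 0)
  expect_identical(clonetrace:::dirichlet_drift(f, Inf), f)
})

test_that("observation schedules produce the advertised shapes", {
  truth <- simulate_population(8, seed = 42)
  Fsq <- observe_vaf(truth, 8)
  expect_true(is_square_vaf(Fsq))
  # one new mutation per row
  expect_equal(unname(mutation_groups(Fsq)$sizes), rep(1L, ncol(Fsq$values)))
  F1 <- observe_vaf(truth, 1, seed = 2)
  expect_equal(nrow(F1$values), 1L)
  expect_equal(length(mutation_groups(F1)$groups), 1L)
  # the final step is always observed
  for (s in 1:8) {
    Fk <- observe_vaf(truth, 3, seed = s)
    expect_true(8 %in% attr(Fk, "observed_steps"))
  }
  # binomial draw is reproducible and in range
  Fb1 <- observe_vaf(truth, "binomial", seed = 7)
  Fb2 <- observe_vaf(truth, "binomial", seed = 7)
  expect_identical(Fb1$values, Fb2$values)
  expect_true(nrow(Fb1$values) >= 1 && nrow(Fb1$values) <= 8)
  expect_error(observe_vaf(truth, 20), "1..n_clones")
})

test_that("read-sampling noise behaves like binomial VAF estimates", {
  F <- vaf_matrix(matrix(0.5, 4000, 1), time_labels = paste0("t", 1:4000))
  noisy <- add_sequencing_noise(F, depth = 100, seed = 1)
  s <- stats::sd(noisy$values)
  expect_lt(abs(s - 0.05), 0.01)          # sqrt(0.5 * 0.5 / 100)
  # zeros stay zero, huge depth reproduces the input
  F2 <- vaf_matrix(rbind(c(0.4, 0), c(0.6, 0.2)))
  n0 <- add_sequencing_noise(F2, depth = 50, seed = 2)
  expect_equal(unname(n0$values[, 2][1]), 0)
  nbig <- add_sequencing_noise(F2, depth = 2000000, seed = 3)
  expect_equal(nbig$values, F2$values, tolerance = 2e-3)
})

test_that("greedy recovers the truth when it is the unique ML tree", {
  n_checked <- 0
  for (s in 1:25) {
    inst <- random_square_instance(7700 + s, n_min = 4, n_max = 6,
                                   alpha = Inf)
    o <- oracle_best_tree(inst$F$values)
    truth_pr <- inst$truth_tree$parent
    if (identical(o$pr, truth_pr)) {
      n_checked <- n_checked + 1
      g <- greedy_tree_search(inst$F)
      if (abs(g$score$value - o$L) < 1e-12)  # greedy found an ML-score tree
        expect_equal(g$tree$parent, truth_pr)
      expect_lte(g$score$value, o$L + 1e-12)
    }
  }
  expect_gt(n_checked, 0)
})
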