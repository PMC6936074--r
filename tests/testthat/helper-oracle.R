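# Independent brute-force oracle for the tree searches: enumerates every
# parent assignment with its own likelihood and validity code (plain
# loops, no shared code with the package's search engine).

naive_likelihood <- function(V, pr) {
  N <- ncol(V)
  fval <- function(r, k) if (k == 0) 1 else V[r, k]
  if (N == 1) return(1)
  f <- vapply(2:N, function(i) {
    p <- pr[i]
    ch <- which(pr == p & seq_len(N) < i)
    fval(i - 1, p) - sum(V[i - 1, ch])
  }, numeric(1))
  prod(f)
}

naive_valid <- function(V, pr, tol = 1e-9) {
  N <- ncol(V)
  fval <- function(r, k) if (k == 0) 1 else V[r, k]
  for (i in seq_len(N)) {
    for (p in 0:N) {
      ch <- which(pr == p & seq_len(N) <= i)
      if (length(ch) && sum(V[i, ch]) > fval(i, p) + tol) return(FALSE)
    }
  }
  TRUE
}

# Maximum-likelihood valid tree by full enumeration (likelihoods computed
# for every assignment, validity checked in descending-likelihood order).
oracle_best_tree <- function(V, tol = 1e-9) {
  N <- ncol(V)
  combos <- as.matrix(expand.grid(lapply(seq_len(N), function(i) 0:(i - 1))))
  L <- apply(combos, 1, function(pr) naive_likelihood(V, pr))
  for (r in order(-L)) {
    if (L[r] <= tol) break
    if (naive_valid(V, combos[r, ], tol)) {
      return(list(pr = unname(combos[r, ]), L = L[r]))
    }
  }
  list(pr = NULL, L = -Inf)
}

# Square noise-free instance drawn from the generative model; the true
# tree is valid by construction.  In the rare case where a clone's whole
# subtree drifts to extinction at birth its column is dropped and the
# matrix re-squared over the surviving variants.
random_square_instance <- function(seed, n_min = 4, n_max = 7, alpha = 50) {
  set.seed(seed)
  N <- sample(n_min:n_max, 1)
  truth <- simulate_population(N, seed = seed + 13L, alpha = alpha)
  F <- observe_vaf(truth, N)
  if (ncol(F$values) < N)
    F <- suppressWarnings(extend_vaf(F)$square)
  truth_tree <- align_tree(project_tree(truth$tree, F$variant_ids),
                           F$variant_ids)
  list(truth = truth, truth_tree = truth_tree, F = F)
}

# Shared instance set for the exhaustive-dominance and greedy-soundness
# checks (built once per test run).
acceptance_instances <- local({
  cache <- NULL
  function(n = 200) {
    if (is.null(cache) || length(cache) < n) {
      cache <<- lapply(seq_len(n), function(s) random_square_instance(5000 + s))
    }
    cache[seq_len(n)]
  }
})
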