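# Parent of a new mutation: clone index (0 = founder) drawn with
# probability proportional to the current clone frequencies.
sample_parent <- function(freq) {
  sample.int(length(freq), 1L, prob = freq) - 1L
}

# One step of compositional drift: new ~ Dirichlet(alpha * current).
# Zero components stay zero (extinct clones do not resurrect).
dirichlet_drift <- function(freq, alpha) {
  if (!is.finite(alpha)) return(freq)
  sh <- alpha * freq
  g <- numeric(length(sh))
  pos <- sh > 0
  g[pos] <- stats::rgamma(sum(pos), shape = sh[pos])
  if (sum(g) > 0) g / sum(g) else freq
}

#' Simulate a clonally evolving bacterial population
#'
#' Emulates a long-term evolution experiment: the population starts as a
#' single founder clone, and at each of \code{n_clones} steps one new clone
#' arises.  The parent of the new clone is sampled with probability
#' proportional to the current clone frequencies (spontaneous mutation is
#' more likely to strike an abundant clone); the new clone takes an initial
#' fraction u ~ Uniform(\code{init_fraction_range}) of its parent's
#' frequency.  Between consecutive steps the frequency vector drifts by a
#' Dirichlet perturbation centred on the current vector with concentration
#' \code{alpha} (new ~ Dirichlet(alpha * current); smaller alpha = more
#' volatile; \code{alpha = Inf} disables drift).  Within a step the order
#' is parent sampling, then birth, then drift; the recorded step-i
#' frequencies are therefore exactly the distribution from which the
#' parent of clone i + 1 is drawn -- the quantity the reconstruction
#' likelihood models.
#'
#' @param n_clones number of mutant clones (= variants); the founder is in
#'   addition to these.
#' @param seed optional integer seed (one RNG stream drives topology and
#'   drift; observation and read noise have their own seeds in
#'   [observe_vaf()] / [add_sequencing_noise()]).
#' @param alpha Dirichlet concentration of the between-step drift
#'   (default 50).
#' @param init_fraction_range range of the initial parent fraction taken by
#'   a newborn clone (default \code{c(0.1, 0.5)}).
#' @return An object of class \code{simulation_truth}: list with
#'   \code{tree} (the true \code{clonal_tree}), \code{trajectories}
#'   (step x clone frequency matrix, founder first, rows summing to 1),
#'   \code{variant_ids} and \code{params}.
#' @export
#' @examples
#' truth <- simulate_population(5, seed = 1)
#' rowSums(truth$trajectories)
simulate_population <- function(n_clones, seed = NULL, alpha = 50,
                                init_fraction_range = c(0.1, 0.5)) {
  N <- as.integer(n_clones)
  stopifnot(N >= 1L, alpha > 0, length(init_fraction_range) == 2,
            init_fraction_range[1] > 0, init_fraction_range[2] <= 1,
            init_fraction_range[1] <= init_fraction_range[2])
  if (!is.null(seed)) set.seed(seed)
  parent <- integer(N)
  traj <- matrix(0, N, N + 1L)
  freq <- c(1, rep(0, N))               # founder, clone 1..N
  for (i in seq_len(N)) {
    p <- sample_parent(freq)                          # 0 = founder
    u <- stats::runif(1, init_fraction_range[1], init_fraction_range[2])
    take <- u * freq[p + 1L]
    freq[p + 1L] <- freq[p + 1L] - take
    freq[i + 1L] <- take
    freq <- dirichlet_drift(freq, alpha)
    parent[i] <- p
    traj[i, ] <- freq
  }
  ids <- paste0("m", seq_len(N))
  dimnames(traj) <- list(paste0("t", seq_len(N)), c("founder", ids))
  structure(list(tree = clonal_tree(parent, ids),
                 trajectories = traj,
                 variant_ids = ids,
                 params = list(n_clones = N, seed = seed, alpha = alpha,
                               init_fraction_range = init_fraction_range)),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("Simulated population: founder + %d clones (alpha = %g)\n",
              x$params$n_clones, x$params$alpha))
  print(x$tree)
  invisible(x)
}

#' Observe a simulated population at a subset of time points
#'
#' Selects K observation steps -- always including the final step, so late
#' clones are seen at least once, with the remainder drawn uniformly
#' without replacement -- and returns the VAF matrix at those steps.  When
#' \code{K} equals the number of clones the result is square
#' lower-triangular with one new mutation per row.  Variants whose whole
#' subtree drifted to extinction before every observation (all-zero
#' columns) are dropped; their ids are reported in attribute
#' \code{dropped}.
#'
#' @param truth a [simulate_population()] result.
#' @param timepoints an integer K in \code{1:n_clones}, or
#'   \code{"binomial"} to draw K ~ Binomial(n_clones, 0.6) clamped to that
#'   range (the sparse-observation regime).
#' @param seed optional integer seed.
#' @return A \code{vaf_matrix} with attributes \code{observed_steps} and
#'   \code{dropped}.
#' @export
observe_vaf <- function(truth, timepoints = "binomial", seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- truth$params$n_clones
  K <- if (identical(timepoints, "binomial")) {
    min(max(stats::rbinom(1, n, 0.6), 1L), n)
  } else {
    k <- as.integer(timepoints)
    if (is.na(k) || k < 1L || k > n)
      stop("timepoints must be in 1..n_clones or \"binomial\"")
    k
  }
  steps <- if (K >= n) seq_len(n)
           else sort(c(sample.int(n - 1L, K - 1L), n))
  Vfull <- vaf_from_truth(truth$tree, truth$trajectories)$values
  V <- Vfull[steps, , drop = FALSE]
  dropped <- colnames(V)[colSums(V) == 0]
  V <- V[, colSums(V) > 0, drop = FALSE]
  if (ncol(V) == 0) stop("no variant observed at the selected time points")
  out <- vaf_matrix(V)
  attr(out, "observed_steps") <- steps
  attr(out, "dropped") <- dropped
  out
}

#' Add binomial read-sampling noise to a VAF matrix
#'
#' Replaces each frequency f by Binomial(depth, f) / depth, emulating VAFs
#' estimated from read counts at the given sequencing depth.  Zeros stay
#' zero.
#'
#' @param F a VAF matrix.
#' @param depth read depth (>= 1).
#' @param seed optional integer seed.
#' @return A \code{vaf_matrix}.
#' @export
add_sequencing_noise <- function(F, depth, seed = NULL) {
  F <- as_vaf(F)
  depth <- as.integer(depth)
  stopifnot(depth >= 1L)
  if (!is.null(seed)) set.seed(seed)
  V <- F$values
  V[] <- stats::rbinom(length(V), depth, as.vector(V)) / depth
  vaf_matrix(V, F$variant_ids, F$time_labels)
}
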