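#' Clone frequency implied by a VAF matrix and a clonal tree
#'
#' Under the clonal model a variant's allele frequency is the summed
#' frequency of all clones carrying it, so the frequency of the clone
#' created by variant k at time i is its own VAF minus the VAFs of its
#' children born by time i:
#' \deqn{c_{i,k} = f_{i,k} - \sum_{j \in ch(k),\; j \le i} f_{i,j}.}
#' The founder (k = 0) has allele frequency 1 by convention.
#'
#' @param F a square \code{vaf_matrix} (or matrix) in birth order.
#' @param tree a \code{clonal_tree} over the columns of \code{F}.
#' @param i time-point row index (1..N).
#' @param k clone index (0 = founder, 1..N = variant-born clones); the clone
#'   must be born at or before time i.
#' @return The clone frequency (may be negative when the tree is
#'   inconsistent with the data).
#' @export
#' @examples
#' F <- rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3))
#' tr <- clonal_tree(c(0, 1, 1))
#' clone_frequency(F, tr, i = 2, k = 1)  # 1.0 - 0.4
clone_frequency <- function(F, tree, i, k) {
  F <- as_vaf(F)
  V <- F$values
  N <- length(tree$parent)
  i <- as.integer(i); k <- as.integer(k)
  if (i < 1L || i > nrow(V)) stop("time index i out of range")
  if (k < 0L || k > N) stop("clone index k out of range")
  if (k > i) stop("clone ", k, " is not born at time ", i)
  f_k <- if (k == 0L) 1.0 else V[i, k]
  ch <- which(tree$parent == k & seq_len(N) <= i)
  f_k - sum(V[i, ch])
}

#' Likelihood of a clonal tree (Eq.-style product of parent frequencies)
#'
#' The likelihood of a tree T on a square VAF matrix is the product over
#' variants i = 2..N of the frequency of the chosen parent clone at the
#' preceding time point,
#' \deqn{L(T) = \prod_{i=2}^{N} C_{(i-1),\,pr(i)},}
#' reflecting that a spontaneous mutation arises in a clone with
#' probability proportional to that clone's current population frequency.
#' The empty product (N = 1) is 1.
#'
#' @inheritParams clone_frequency
#' @return An object of class \code{likelihood_score}: list with
#'   \code{value} (the product), \code{log_value} (\code{-Inf} when any
#'   factor is nonpositive) and \code{factors} (per-variant contributions,
#'   for diagnostics).
#' @export
tree_likelihood <- function(F, tree) {
  F <- as_vaf(F)
  N <- length(tree$parent)
  stopifnot(ncol(F$values) == N)
  factors <- if (N >= 2)
    vapply(2:N, function(i) clone_frequency(F, tree, i - 1L, tree$parent[i]),
           numeric(1))
  else numeric(0)
  value <- prod(factors)
  log_value <- if (any(factors <= 0)) -Inf else sum(log(factors))
  if (N == 1L) { value <- 1.0; log_value <- 0.0 }
  structure(list(value = value, log_value = log_value, factors = factors),
            class = "likelihood_score")
}

#' @export
print.likelihood_score <- function(x, ...) {
  cat(sprintf("likelihood %.6g (log %.6g), %d factor(s)\n",
              x$value, x$log_value, length(x$factors)))
  invisible(x)
}

#' Validity of a clonal tree on a VAF matrix
#'
#' A tree is invalid when at some time point the summed allele frequencies
#' of a clone's children exceed the parent's own allele frequency (the
#' children are subpopulations of the parent lineage, so their frequencies
#' cannot add up past it).  For noisy data the comparison can be relaxed by
#' \code{neg_tol} (the same relaxation applied to the clonal frequency
#' matrix).
#'
#' @inheritParams clone_frequency
#' @param neg_tol nonnegative slack allowed on the excess (default 0).
#' @param tol absolute floating-point tolerance.
#' @return Logical scalar; when \code{FALSE}, attribute \code{violation}
#'   holds the first violating \code{c(time, parent)}.
#' @export
is_valid_tree <- function(F, tree, neg_tol = 0, tol = 1e-9) {
  F <- as_vaf(F)
  V <- F$values
  N <- length(tree$parent)
  stopifnot(ncol(V) == N, nrow(V) == N)
  for (i in seq_len(N)) {
    for (p in 0:N) {
      ch <- which(tree$parent == p & seq_len(N) <= i)
      if (!length(ch)) next
      f_p <- if (p == 0L) 1.0 else V[i, p]
      if (sum(V[i, ch]) > f_p + neg_tol + tol) {
        out <- FALSE
        attr(out, "violation") <- c(time = i, parent = p)
        return(out)
      }
    }
  }
  TRUE
}

#' Clonal frequency matrix implied by a VAF matrix and a tree
#'
#' Inverts the clonal model: for every observed time row,
#' \eqn{c_{i,k} = f_{i,k} - \sum_{j \in ch(k),\, t_j \le i} f_{i,j}} (the
#' founder's allele frequency taken as 1).  Entries in
#' \eqn{[-neg\_tol, 0)} are treated as sequencing noise: accepted, clamped
#' to 0, and each row renormalized to sum to 1.  Any entry below
#' \code{-neg_tol} makes the pair (F, T) infeasible and raises an error of
#' class \code{clonetrace_infeasible}.
#'
#' \code{F} need not be square; rows are the observed time points and the
#' per-variant first-observation times decide which children contribute.
#' The tree is matched to the columns of \code{F} by variant id.
#'
#' @inheritParams is_valid_tree
#' @return An object of class \code{cfm}: list with \code{values} (rows =
#'   time points, columns = \code{founder} then the tree's variants in
#'   birth order), \code{raw} (pre-clamp values) and \code{neg_tol}.
#' @export
#' @examples
#' F <- rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3))
#' compute_cfm(F, clonal_tree(c(0, 1, 1)))$values
compute_cfm <- function(F, tree, neg_tol = 0) {
  F <- as_vaf(F)
  V <- F$values
  col <- match(tree$variant_ids, F$variant_ids)
  if (anyNA(col)) stop("tree variants missing from the VAF matrix")
  fo <- F$first_obs[col]
  R <- nrow(V)
  N <- length(tree$parent)
  C <- matrix(0, R, N + 1L,
              dimnames = list(F$time_labels, c("founder", tree$variant_ids)))
  for (k in 0:N) {
    f_k <- if (k == 0L) rep(1.0, R) else V[, col[k]]
    ch <- which(tree$parent == k)
    s <- rep(0, R)
    for (j in ch) {
      born <- seq_len(R) >= fo[j]
      s[born] <- s[born] + V[born, col[j]]
    }
    C[, k + 1L] <- f_k - s
  }
  if (any(C < -neg_tol - 1e-9)) {
    w <- which(C < -neg_tol - 1e-9, arr.ind = TRUE)[1, ]
    stop(structure(class = c("clonetrace_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "no valid solution under tolerance %g (clone frequency %.4g at time row %d)",
                     neg_tol, C[w[1], w[2]], w[1]),
                     call = sys.call())))
  }
  raw <- C
  C[C < 0] <- 0
  rs <- rowSums(C)
  if (any(rs <= 0)) stop("clonal frequency row collapsed to zero")
  C <- C / rs
  structure(list(values = C, raw = raw, neg_tol = neg_tol), class = "cfm")
}

#' @export
print.cfm <- function(x, ...) {
  cat(sprintf("Clonal frequency matrix: %d time points x %d clones (neg_tol = %g)\n",
              nrow(x$values), ncol(x$values), x$neg_tol))
  print(round(x$values, 4))
  invisible(x)
}

#' Forward model: VAF matrix generated by a tree and clone frequencies
#'
#' A variant's allele frequency is the total frequency of the clones in the
#' subtree rooted at its node (every descendant clone carries the variant).
#' This is the forward counterpart of [compute_cfm()]:
#' \code{compute_cfm(vaf_from_truth(T, C), T, 0)} reproduces \code{C}.
#'
#' @param tree a \code{clonal_tree} over N variants.
#' @param C clone frequencies: a \code{cfm} or a matrix with columns
#'   founder, clone 1, ..., clone N (rows summing to 1).
#' @return A \code{vaf_matrix}.
#' @export
vaf_from_truth <- function(tree, C) {
  if (inherits(C, "cfm")) C <- C$values
  C <- as.matrix(C)
  N <- length(tree$parent)
  stopifnot(ncol(C) == N + 1L)
  haps <- tree_haplotypes(tree)
  M <- matrix(0, N + 1L, N)            # M[k+1, j] = 1 iff clone k carries j
  for (k in seq_len(N)) M[k + 1L, haps[[k]]] <- 1
  V <- C %*% M
  vaf_matrix(pmin(pmax(V, 0), 1), variant_ids = tree$variant_ids,
             time_labels = rownames(C))
}
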