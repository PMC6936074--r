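# Thin R layer over the compiled DFS engine shared by the greedy,
# exhaustive and random tree searches.

search_result <- function(F, res) {
  status <- c("found", "no_valid_solution", "budget_exhausted")[res$status + 1L]
  if (status == "found") {
    tree <- clonal_tree(res$pr, F$variant_ids)
    structure(list(tree = tree, score = tree_likelihood(F, tree),
                   status = "found", nodes_explored = res$explored),
              class = "search_result")
  } else {
    structure(list(tree = NULL, score = NULL, status = status,
                   nodes_explored = res$explored),
              class = "search_result")
  }
}

#' @export
print.search_result <- function(x, ...) {
  cat("Tree search:", x$status,
      sprintf("(%.0f placements explored)\n", x$nodes_explored))
  if (x$status == "found") {
    print(x$tree)
    print(x$score)
  }
  invisible(x)
}

run_engine <- function(F, mode, parent_candidates = NULL,
                       required_ancestors = NULL, tol = 1e-9, neg_tol = 0,
                       node_budget = Inf) {
  F <- as_vaf(F)
  if (!is_square_vaf(F))
    stop("tree search needs a square lower-triangular VAF matrix; ",
         "use extend_vaf()/greedy_permutation_search() for sparse time courses")
  N <- ncol(F$values)
  if (is.null(parent_candidates))
    parent_candidates <- lapply(seq_len(N), function(i) 0:(i - 1L))
  if (is.null(required_ancestors))
    required_ancestors <- rep(list(integer(0)), N)
  res <- cpp_tree_search(F$values,
                         lapply(parent_candidates, as.integer),
                         lapply(required_ancestors, as.integer),
                         as.integer(mode), tol, neg_tol,
                         as.double(node_budget))
  search_result(F, res)
}

#' Exhaustive tree search (ET)
#'
#' Enumerates every parent assignment \code{pr(i)} in \code{0:(i-1)} for
#' i = 1..N (founder included as a candidate), discards invalid trees and
#' trees with a nonpositive likelihood factor, and returns the
#' maximum-likelihood valid tree.  Branches whose running factor cannot
#' yield a positive product are pruned; the result is identical to a full
#' enumeration.  The search space grows factorially, so inputs larger than
#' \code{max_variants} are refused (use [greedy_tree_search()] instead).
#'
#' @param F square lower-triangular VAF matrix.
#' @param tol positivity floor for likelihood factors.
#' @param neg_tol validity slack for noisy data (see [is_valid_tree()]).
#' @param max_variants refuse instances larger than this (default 12).
#' @param node_budget cap on explored placements (default unlimited).
#' @return A \code{search_result}: list with \code{tree}, \code{score},
#'   \code{status} (\code{"found"} or \code{"no_valid_solution"}) and
#'   \code{nodes_explored}.
#' @export
#' @examples
#' F <- rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3))
#' exhaustive_tree_search(F)
exhaustive_tree_search <- function(F, tol = 1e-9, neg_tol = 0,
                                   max_variants = 12L, node_budget = Inf) {
  F <- as_vaf(F)
  if (ncol(F$values) > max_variants)
    stop("exhaustive search over ", ncol(F$values), " variants is infeasible ",
         "(factorial space); use greedy_tree_search()")
  run_engine(F, mode = 1L, tol = tol, neg_tol = neg_tol,
             node_budget = node_budget)
}

#' Greedy tree search with backtracking (GT)
#'
#' Grows the tree from the founder: at each step i the parent is the clone
#' with the largest current frequency
#' \eqn{C_{(i-1),k} = f_{(i-1),k} - \sum_{j \in ch(k), j < i} f_{(i-1),j}},
#' provided the choice does not make the partial tree invalid.  Dead ends
#' backtrack to the next-best choice at the previous step (depth-first over
#' per-level candidate lists sorted by descending clone frequency, ties
#' broken by earliest-born candidate).  Worst case O(N!), best case
#' O(N^2) candidate evaluations.
#'
#' @inheritParams exhaustive_tree_search
#' @param parent_candidates optional list (one integer vector per variant)
#'   restricting the allowed parents, e.g. from sequenced-clone constraints;
#'   defaults to \code{0:(i-1)}.
#' @param required_ancestors optional list (one integer vector per variant)
#'   of variants that must lie on the root path, used by the constrained
#'   search.
#' @return A \code{search_result}.
#' @export
greedy_tree_search <- function(F, parent_candidates = NULL,
                               required_ancestors = NULL, tol = 1e-9,
                               neg_tol = 0, node_budget = Inf) {
  run_engine(F, mode = 0L, parent_candidates = parent_candidates,
             required_ancestors = required_ancestors, tol = tol,
             neg_tol = neg_tol, node_budget = node_budget)
}

#' Random tree search (RT baseline)
#'
#' At each step the parent is drawn uniformly at random from the clones
#' born earlier (founder included); invalid picks are retried by
#' backtracking over a shuffled candidate order.  Deterministic given
#' \code{seed}.
#'
#' @inheritParams greedy_tree_search
#' @param seed optional integer seed.
#' @return A \code{search_result}.
#' @export
random_tree_search <- function(F, seed = NULL, tol = 1e-9, neg_tol = 0,
                               node_budget = Inf) {
  if (!is.null(seed)) set.seed(seed)
  run_engine(F, mode = 2L, tol = tol, neg_tol = neg_tol,
             node_budget = node_budget)
}
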