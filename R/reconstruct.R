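#' Reconstruct the clonal tree and clone frequencies from a VAF time course
#'
#' Top-level driver combining the permutation layer (for sparse time
#' courses where several mutations first appear at the same time point)
#' with a tree search:
#' \describe{
#'   \item{\code{gp-gt}}{greedy permutation search + greedy tree search
#'     (the default; on a square input it degenerates to plain GT).}
#'   \item{\code{ep-gt}, \code{ep-et}}{exhaustive permutation search with a
#'     greedy or exhaustive tree search.}
#'   \item{\code{gt}, \code{et}, \code{rt}}{tree search on an already
#'     square matrix.}
#'   \item{\code{rp-rt}}{the random baseline: one random permutation per
#'     group plus a random valid tree.}
#' }
#'
#' @param F a \code{vaf_matrix} (or matrix): rows = time points, columns =
#'   variants.
#' @param algorithm search combination, see Details.
#' @param clones optional [sequenced_clones()] constraints (constrained
#'   search).
#' @param neg_tol relaxation for noisy data: clone frequencies down to
#'   \code{-neg_tol} are tolerated during the search and clamped to 0 in
#'   the returned clonal frequency matrix (0.4 is a reasonable setting for
#'   read-count-derived VAFs; 0 for noise-free data).
#' @param similarity_tol if non-\code{NULL}, variants with
#'   indistinguishable trajectories are first merged with
#'   [group_mutations()] at this tolerance.
#' @param seed integer seed for the random algorithms.
#' @param tol positivity floor for likelihood factors.
#' @param node_budget cap on explored tree-search placements; default
#'   unlimited for the square-matrix searches and 1e5 per permutation
#'   evaluation for the permutation layer (see
#'   [greedy_permutation_search()]).
#' @param max_random_restarts for \code{rp-rt}: number of random
#'   permutations tried before giving up.
#' @return An object of class \code{clonal_reconstruction}: list with
#'   \code{status}, \code{tree} (over the resolved birth order),
#'   \code{likelihood}, \code{cfm} (clone frequencies at the observed time
#'   points, founder first), \code{square} (the square matrix actually
#'   scored), \code{order} (birth order of variant ids),
#'   \code{permutation}, \code{n_candidates}, \code{merged} (member map
#'   when \code{similarity_tol} was used) and \code{algorithm}.
#' @export
#' @examples
#' F <- rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3))
#' r <- reconstruct(F, "gt")
#' r$tree
#' r$cfm$values
reconstruct <- function(F,
                        algorithm = c("gp-gt", "ep-gt", "ep-et", "gt", "et",
                                      "rt", "rp-rt"),
                        clones = NULL, neg_tol = 0, similarity_tol = NULL,
                        seed = NULL, tol = 1e-9, node_budget = NULL,
                        max_random_restarts = 100L) {
  algorithm <- match.arg(algorithm)
  nb_square <- node_budget %||% Inf
  nb_perm <- node_budget %||% 1e5
  F <- as_vaf(F)
  merged <- NULL
  if (!is.null(similarity_tol)) {
    gm <- group_mutations(F, similarity_tol)
    F <- gm$vaf
    merged <- gm$members
  }
  if (!is.null(clones)) {
    if (!inherits(clones, "sequenced_clones")) clones <- sequenced_clones(clones)
    clones <- resolve_clones(clones, F)
  }
  if (!is.null(seed)) set.seed(seed)

  out <- switch(algorithm,
    "gt" = , "et" = , "rt" = {
      if (!is_square_vaf(F))
        stop("algorithm '", algorithm, "' needs a square input; ",
             "use gp-gt / ep-gt / ep-et for sparse time courses")
      cs <- constraint_spec(F$variant_ids, clones)
      res <- switch(algorithm,
        "gt" = greedy_tree_search(F, cs$cand, cs$req, tol = tol,
                                  neg_tol = neg_tol, node_budget = nb_square),
        "et" = {
          if (!is.null(clones))
            run_engine(F, mode = 1L, parent_candidates = cs$cand,
                       required_ancestors = cs$req, tol = tol,
                       neg_tol = neg_tol, node_budget = nb_square)
          else exhaustive_tree_search(F, tol = tol, neg_tol = neg_tol,
                                      node_budget = nb_square)
        },
        "rt" = run_engine(F, mode = 2L, parent_candidates = cs$cand,
                          required_ancestors = cs$req, tol = tol,
                          neg_tol = neg_tol, node_budget = nb_square))
      list(result = res,
           extended = list(square = F, order = seq_along(F$variant_ids)),
           permutation = as.list(F$variant_ids), n_candidates = 1L)
    },
    "gp-gt" = greedy_permutation_search(F, clones = clones, tol = tol,
                                        neg_tol = neg_tol,
                                        node_budget = nb_perm),
    "ep-gt" = exhaustive_permutation_search(F, "gt", clones = clones,
                                            tol = tol, neg_tol = neg_tol,
                                            node_budget = nb_square),
    "ep-et" = exhaustive_permutation_search(F, "et", clones = clones,
                                            tol = tol, neg_tol = neg_tol,
                                            node_budget = nb_square),
    "rp-rt" = {
      res <- failed_search(); ext <- NULL; perm <- NULL; tries <- 0L
      for (a in seq_len(max_random_restarts)) {
        orders <- random_permutation(F)
        e <- extend_vaf(F, orders)
        cs <- constraint_spec(e$square$variant_ids, clones)
        r <- run_engine(e$square, mode = 2L, parent_candidates = cs$cand,
                        required_ancestors = cs$req, tol = tol,
                        neg_tol = neg_tol, node_budget = nb_perm)
        tries <- a
        if (r$status == "found") { res <- r; ext <- e; perm <- orders; break }
      }
      list(result = res, extended = ext, permutation = perm,
           n_candidates = tries)
    })

  res <- out$result
  if (res$status != "found") {
    return(structure(list(status = res$status, tree = NULL, likelihood = NULL,
                          cfm = NULL, square = NULL, order = NULL,
                          permutation = NULL, n_candidates = out$n_candidates,
                          merged = merged, algorithm = algorithm,
                          input = F),
                     class = "clonal_reconstruction"))
  }
  tree <- res$tree
  if (!is.null(clones) && !isTRUE(check_path_consistency(tree, clones)))
    stop("internal error: returned tree violates sequenced-clone constraints")
  cfm <- compute_cfm(F, tree, neg_tol = neg_tol)
  structure(list(status = "found", tree = tree, likelihood = res$score,
                 cfm = cfm, square = out$extended$square,
                 order = tree$variant_ids, permutation = out$permutation,
                 n_candidates = out$n_candidates,
                 nodes_explored = res$nodes_explored, merged = merged,
                 algorithm = algorithm, input = F),
            class = "clonal_reconstruction")
}

#' @export
print.clonal_reconstruction <- function(x, ...) {
  cat(sprintf("Clonal reconstruction [%s]: %s\n", x$algorithm, x$status))
  if (x$status == "found") {
    print(x$tree)
    print(x$likelihood)
  }
  invisible(x)
}
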