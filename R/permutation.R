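#' Mutation groups of a sparse time course
#'
#' Variants first observed at the same time point form an unordered group:
#' their within-group birth order is unknown and must be searched over.
#'
#' @param F a VAF matrix.
#' @return An object of class \code{mutation_groups}: list with
#'   \code{groups} (list of integer column-index vectors, ordered by time),
#'   \code{times} (the first-observation row of each group) and
#'   \code{sizes}.
#' @export
mutation_groups <- function(F) {
  F <- as_vaf(F)
  fo <- F$first_obs
  if (anyNA(fo))
    stop("variants never observed (all-zero columns): ",
         paste(F$variant_ids[is.na(fo)], collapse = ", "))
  fo <- unname(fo)
  times <- sort(unique(fo))
  groups <- lapply(times, function(t) which(fo == t))
  structure(list(groups = groups, times = times,
                 sizes = lengths(groups)), class = "mutation_groups")
}

#' @export
print.mutation_groups <- function(x, ...) {
  cat(sprintf("%d mutation group(s), sizes: %s\n", length(x$groups),
              paste(x$sizes, collapse = " ")))
  invisible(x)
}

#' Merge variants with indistinguishable trajectories
#'
#' Variants that first appear at the same time point and whose VAF
#' trajectories differ by less than \code{similarity_tol} at every time
#' point most likely belong to the same clone; they are merged into a
#' single group-column (id = member labels joined by \code{+}, VAF = the
#' per-time mean of the members).
#'
#' @param F a VAF matrix.
#' @param similarity_tol maximum absolute VAF difference for merging
#'   (default 0.05, the usual VAF calling noise floor).
#' @return List with \code{vaf} (the merged \code{vaf_matrix}),
#'   \code{groups} (the [mutation_groups()] of the merged matrix) and
#'   \code{members} (original variant ids behind each merged column).
#' @export
group_mutations <- function(F, similarity_tol = 0.05) {
  F <- as_vaf(F)
  V <- F$values
  fo <- F$first_obs
  if (anyNA(fo)) stop("all-zero columns cannot be grouped")
  clusters <- list()
  for (t in sort(unique(fo))) {
    for (j in which(fo == t)) {
      placed <- FALSE
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (fo[cl[1]] != t) next
        if (all(vapply(cl, function(k) max(abs(V[, k] - V[, j])) < similarity_tol,
                       logical(1)))) {
          clusters[[ci]] <- c(cl, j)
          placed <- TRUE
          break
        }
      }
      if (!placed) clusters[[length(clusters) + 1L]] <- j
    }
  }
  newV <- vapply(clusters, function(cl) rowMeans(V[, cl, drop = FALSE]),
                 numeric(nrow(V)))
  if (is.null(dim(newV))) newV <- matrix(newV, nrow = nrow(V))
  ids <- vapply(clusters, function(cl) paste(F$variant_ids[cl], collapse = "+"),
                character(1))
  G <- vaf_matrix(newV, ids, F$time_labels)
  list(vaf = G, groups = mutation_groups(G),
       members = stats::setNames(lapply(clusters, function(cl) F$variant_ids[cl]),
                                 ids))
}

normalize_orders <- function(F, g, orders) {
  if (is.null(orders)) return(g$groups)
  if (length(orders) != length(g$groups))
    stop("need one ordering per mutation group")
  lapply(seq_along(orders), function(gi) {
    o <- orders[[gi]]
    if (is.character(o)) o <- match(o, F$variant_ids)
    o <- as.integer(o)
    if (anyNA(o) || !setequal(o, g$groups[[gi]]) ||
        length(o) != length(g$groups[[gi]]))
      stop("permutation must be a bijection on its mutation group")
    o
  })
}

#' Extend a sparse VAF matrix to a square lower-triangular matrix
#'
#' When a group of n mutations is first observed at time t, the n clones
#' must have arisen between t-1 and t.  Given a within-group birth order,
#' the matrix is extended by inserting n-1 virtual rows before row t: VAFs
#' are assumed approximately constant over the interval, so every
#' already-introduced variant carries its time-t value in the virtual rows
#' and not-yet-introduced variants carry 0.  Columns are reordered to the
#' resolved birth order; observed rows are preserved exactly.
#'
#' @param F a VAF matrix.
#' @param orders list with one entry per mutation group: the within-group
#'   birth order, as column indices of \code{F} or as variant ids.  Default
#'   is the column order.
#' @return An object of class \code{extended_vaf}: list with \code{square}
#'   (the square \code{vaf_matrix}), \code{order} (column indices of
#'   \code{F} in birth order), \code{row_map} (original row index per
#'   extended row, \code{NA} for virtual rows) and \code{groups}.
#' @export
#' @examples
#' F <- vaf_matrix(rbind(c(0.5, 0, 0), c(0.9, 0.3, 0.2)),
#'                 c("A", "B", "C"), c("t1", "t2"))
#' extend_vaf(F, orders = list("A", c("C", "B")))$square
extend_vaf <- function(F, orders = NULL) {
  F <- as_vaf(F)
  g <- mutation_groups(F)
  V <- F$values
  unused <- setdiff(seq_len(nrow(V)), g$times)
  if (length(unused) && any(V[unused, , drop = FALSE] > 0))
    warning("rows without a newly observed variant are dropped in the extension")
  orders <- normalize_orders(F, g, orders)
  birth <- unlist(orders)
  N <- length(birth)
  rows <- matrix(0, N, N)
  rlabels <- character(N)
  row_map <- integer(N)
  pos <- 0L
  for (gi in seq_along(orders)) {
    t <- g$times[gi]
    n <- length(orders[[gi]])
    base <- V[t, birth]
    intro <- pos
    for (k in seq_len(n)) {
      r <- base
      if (intro + k < N) r[(intro + k + 1L):N] <- 0
      pos <- pos + 1L
      rows[pos, ] <- r
      rlabels[pos] <- if (k == n) F$time_labels[t]
                      else paste0(F$time_labels[t], ".v", k)
      row_map[pos] <- if (k == n) t else NA_integer_
    }
  }
  sq <- vaf_matrix(rows, F$variant_ids[birth], rlabels)
  structure(list(square = sq, order = birth, row_map = row_map, groups = g),
            class = "extended_vaf")
}

# Lexicographic rank (1-based) -> permutation of 1..n, via the factoradic.
unrank_perm <- function(n, rank) {
  r <- rank - 1
  avail <- seq_len(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    f <- factorial(n - i)
    k <- as.integer(r %/% f)
    r <- r - k * f
    out[i] <- avail[k + 1L]
    avail <- avail[-(k + 1L)]
  }
  out
}

all_permutations <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- vector("list", factorial(n))
  pos <- 0L
  for (j in seq_len(n)) {
    for (p in all_permutations(v[-j])) {
      pos <- pos + 1L
      out[[pos]] <- c(v[j], p)
    }
  }
  out
}

failed_search <- function(status = "no_valid_solution") {
  structure(list(tree = NULL, score = NULL, status = status,
                 nodes_explored = 0), class = "search_result")
}

#' Exhaustive permutation search (EP)
#'
#' Evaluates every combination of within-group birth orders (a product of
#' group-size factorials), extends the matrix under each, runs the chosen
#' tree search, and returns the globally best valid result.
#'
#' @param F a VAF matrix.
#' @param tree_search \code{"gt"} (greedy, the EP-GT combination) or
#'   \code{"et"} (exhaustive, EP-ET).
#' @param clones optional [sequenced_clones()] constraints.
#' @inheritParams greedy_tree_search
#' @return List with \code{result} (a \code{search_result} over the best
#'   extension), \code{permutation} (list of variant-id orders per group),
#'   \code{extended} (the best \code{extended_vaf}) and
#'   \code{n_candidates} (number of extensions evaluated, equal to the
#'   product of group-size factorials).
#' @export
exhaustive_permutation_search <- function(F, tree_search = c("gt", "et"),
                                          clones = NULL, tol = 1e-9,
                                          neg_tol = 0, node_budget = Inf) {
  tree_search <- match.arg(tree_search)
  F <- as_vaf(F)
  g <- mutation_groups(F)
  perms_per_group <- lapply(g$groups, all_permutations)
  counts <- lengths(perms_per_group)
  idx <- rep(1L, length(counts))
  best <- NULL
  n_candidates <- 0L
  repeat {
    orders <- lapply(seq_along(idx), function(gi) perms_per_group[[gi]][[idx[gi]]])
    ext <- extend_vaf(F, orders)
    cs <- constraint_spec(ext$square$variant_ids, clones)
    res <- if (tree_search == "gt")
      greedy_tree_search(ext$square, cs$cand, cs$req, tol = tol,
                         neg_tol = neg_tol, node_budget = node_budget)
    else
      run_engine(ext$square, mode = 1L, parent_candidates = cs$cand,
                 required_ancestors = cs$req, tol = tol, neg_tol = neg_tol,
                 node_budget = node_budget)
    n_candidates <- n_candidates + 1L
    if (res$status == "found" &&
        (is.null(best) || res$score$log_value > best$result$score$log_value + 1e-12)) {
      best <- list(result = res, extended = ext,
                   permutation = lapply(orders, function(o) F$variant_ids[o]))
    }
    # advance the mixed-radix counter
    gi <- 1L
    while (gi <= length(idx)) {
      idx[gi] <- idx[gi] + 1L
      if (idx[gi] <= counts[gi]) break
      idx[gi] <- 1L
      gi <- gi + 1L
    }
    if (gi > length(idx)) break
  }
  if (is.null(best))
    best <- list(result = failed_search(), extended = NULL, permutation = NULL)
  best$n_candidates <- n_candidates
  best
}

#' Greedy permutation search (GP)
#'
#' Processes the mutation groups in time order.  For the group first
#' observed at time t, every within-group permutation is scored by
#' extending the matrix up to time t and running the greedy tree search;
#' the maximum-likelihood permutation is committed and the search proceeds
#' to the next group.  When a later group admits no valid tree under the
#' committed prefix, the search backtracks to the previous group's
#' next-best permutation.  Best case evaluates the sum of group-size
#' factorials, worst case their product.
#'
#' @inheritParams exhaustive_permutation_search
#' @param node_budget cap on tree-search placements per permutation
#'   evaluation.  The default (1e5) is far beyond what any completed
#'   greedy search needs and exists to cut off the factorial backtracking
#'   a constrained dead-end ordering can trigger; evaluations that
#'   exhaust it count as having no valid tree.
#' @return As [exhaustive_permutation_search()]; \code{n_candidates} is the
#'   number of (permutation, greedy-search) evaluations performed.
#' @export
greedy_permutation_search <- function(F, clones = NULL, tol = 1e-9,
                                      neg_tol = 0, node_budget = 1e5) {
  F <- as_vaf(F)
  g <- mutation_groups(F)
  m <- length(g$groups)
  V <- F$values
  ids_all <- F$variant_ids
  n_eval <- 0L
  budget <- as.double(node_budget)

  # id-keyed constraint sets, computed once and re-indexed per birth order
  pc_map <- req_map <- NULL
  if (!is.null(clones)) {
    pc_map <- stats::setNames(lapply(ids_all, function(v)
      parent_candidates(clones, v)), ids_all)
    req_map <- stats::setNames(lapply(ids_all, function(v)
      intersect(required_ancestors_of(clones, v), ids_all)), ids_all)
  }

  # square matrix over groups 1..gi for the birth order `ord` (column
  # indices into V); the j-th introduced variant's row copies the group's
  # observed row with not-yet-introduced variants zeroed
  build_square <- function(ord, gi) {
    N <- length(ord)
    S <- matrix(0, N, N)
    pos <- 0L
    for (k in seq_len(gi)) {
      base <- V[g$times[k], ord]
      for (j in seq_len(length(g$groups[[k]]))) {
        pos <- pos + 1L
        r <- base
        if (pos < N) r[(pos + 1L):N] <- 0
        S[pos, ] <- r
      }
    }
    S
  }

  constraint_lists <- function(ord_ids) {
    N <- length(ord_ids)
    cand <- vector("list", N)
    req <- vector("list", N)
    for (i in seq_len(N)) {
      if (is.null(pc_map)) {
        cand[[i]] <- 0:(i - 1L)
        req[[i]] <- integer(0)
        next
      }
      pc <- pc_map[[ord_ids[i]]]
      if (is.null(pc)) {
        cand[[i]] <- 0:(i - 1L)
      } else {
        earlier <- match(intersect(pc, ord_ids[seq_len(i - 1L)]), ord_ids)
        cand[[i]] <- if (length(earlier)) sort(earlier) else 0L
      }
      req[[i]] <- sort(match(intersect(req_map[[ord_ids[i]]], ord_ids),
                             ord_ids))
    }
    list(cand = cand, req = req)
  }

  score_ord <- function(ord, gi) {
    Sq <- build_square(ord, gi)
    cr <- constraint_lists(ids_all[ord])
    res <- cpp_tree_search(Sq, lapply(cr$cand, as.integer),
                           lapply(cr$req, as.integer), 0L, tol, neg_tol,
                           budget)
    list(ll = if (res$status == 0L) res$loglik else -Inf,
         pr = res$pr, ord = ord)
  }

  # Scores for all permutations of group gi come back from one compiled
  # pass (lexicographic order); permutations are unranked lazily as the
  # descending-score walk needs them.
  solve <- function(committed, gi) {
    grp <- g$groups[[gi]]
    n <- length(grp)
    ord_ref <- c(committed, grp)
    Nn <- length(ord_ref)
    Sref <- build_square(ord_ref, gi)
    base <- unname(V[g$times[gi], ord_ref])
    cand_ref <- rep(list(integer(0)), Nn)
    req_ref <- rep(list(integer(0)), Nn)
    restricted <- logical(Nn)
    if (!is.null(pc_map)) {
      ord_ids <- ids_all[ord_ref]
      for (i in seq_len(Nn)) {
        pc <- pc_map[[ord_ids[i]]]
        if (!is.null(pc)) {
          restricted[i] <- TRUE
          cand_ref[[i]] <- as.integer(sort(stats::na.omit(match(pc, ord_ids))))
        }
        req_ref[[i]] <- as.integer(stats::na.omit(match(req_map[[ord_ids[i]]],
                                                        ord_ids)))
      }
    }
    sc <- cpp_gp_score_perms(Sref, base, length(committed), n, cand_ref,
                             req_ref, restricted, tol, neg_tol, budget)
    n_eval <<- n_eval + length(sc)
    for (j in order(-sc)) {
      if (!is.finite(sc[j])) next
      perm_cols <- grp[unrank_perm(n, j)]
      if (gi == m) {
        res <- score_ord(c(committed, perm_cols), gi)
        if (!is.finite(res$ll)) next
        return(res)
      }
      deeper <- solve(c(committed, perm_cols), gi + 1L)
      if (!is.null(deeper)) return(deeper)
    }
    NULL
  }

  out <- solve(integer(0), 1L)
  if (is.null(out))
    return(list(result = failed_search(), extended = NULL,
                permutation = NULL, n_candidates = n_eval))
  orders <- split(out$ord, rep(seq_len(m), g$sizes))
  ext <- extend_vaf(F, orders = unname(orders))
  tree <- clonal_tree(out$pr, ids_all[out$ord])
  list(result = structure(list(tree = tree,
                               score = tree_likelihood(ext$square, tree),
                               status = "found",
                               nodes_explored = NA_real_),
                          class = "search_result"),
       extended = ext,
       permutation = lapply(unname(orders), function(o) ids_all[o]),
       n_candidates = n_eval)
}

#' Random within-group permutations (RP baseline)
#'
#' Draws one uniform permutation per mutation group; deterministic given
#' \code{seed}.  Combined with [random_tree_search()] this is the RP-RT
#' baseline.
#'
#' @param F a VAF matrix.
#' @param seed optional integer seed.
#' @return List of variant-id vectors, one birth order per group.
#' @export
random_permutation <- function(F, seed = NULL) {
  F <- as_vaf(F)
  g <- mutation_groups(F)
  if (!is.null(seed)) set.seed(seed)
  lapply(g$groups, function(grp) F$variant_ids[grp[sample.int(length(grp))]])
}
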