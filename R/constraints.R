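#' Sequenced clone haplotypes
#'
#' Haplotypes of individually sequenced clones (sets of variant ids) used
#' to constrain the tree search.  Redundant clones (identical variant sets)
#' are collapsed and empty sets dropped.
#'
#' @param clones list of character vectors of variant ids (or a single
#'   vector for one clone).
#' @return An object of class \code{sequenced_clones}.
#' @export
#' @examples
#' sequenced_clones(list(c("v1", "v2", "v4"), c("v1", "v3"), c("v1", "v3")))
sequenced_clones <- function(clones) {
  if (is.character(clones)) clones <- list(clones)
  clones <- lapply(clones, function(x) sort(unique(as.character(x))))
  clones <- clones[lengths(clones) > 0]
  key <- vapply(clones, paste, character(1), collapse = "\r")
  clones <- clones[!duplicated(key)]
  structure(list(clones = clones), class = "sequenced_clones")
}

#' @export
print.sequenced_clones <- function(x, ...) {
  cat(sprintf("%d sequenced clone haplotype(s)\n", length(x$clones)))
  for (A in x$clones) cat("  {", paste(A, collapse = ", "), "}\n")
  invisible(x)
}

#' Read sequenced clones from a plain-text file
#'
#' One clone per line, whitespace-separated variant ids.
#'
#' @param file path.
#' @return A \code{sequenced_clones} object.
#' @export
read_clones <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  sequenced_clones(lapply(strsplit(lines, "[[:space:]]+"),
                          function(x) x[nzchar(x)]))
}

#' Allowed parents of a variant under sequenced-clone constraints
#'
#' If variant v appears in at least one sequenced clone, its parent clone's
#' haplotype is contained in every such clone, so the parent variant must
#' be one of the other variants of those clones (or the founder, when none
#' of them was born earlier).  Variants appearing in no sequenced clone are
#' unrestricted.
#'
#' @param clones a \code{sequenced_clones} object.
#' @param v a variant id.
#' @return Character vector of allowed parent variant ids; the literal
#'   \code{"founder"} when the union is empty; \code{NULL} when v is
#'   unconstrained.
#' @export
parent_candidates <- function(clones, v) {
  v <- as.character(v)
  hit <- Filter(function(A) v %in% A, clones$clones)
  if (!length(hit)) return(NULL)
  u <- setdiff(sort(unique(unlist(hit))), v)
  if (!length(u)) return("founder")
  u
}

required_ancestors_of <- function(clones, v) {
  v <- as.character(v)
  cl <- clones$clones
  req <- character(0)
  if (length(cl) >= 2) {
    for (a in seq_len(length(cl) - 1L)) {
      for (b in (a + 1L):length(cl)) {
        sym <- c(setdiff(cl[[a]], cl[[b]]), setdiff(cl[[b]], cl[[a]]))
        if (v %in% sym)
          req <- union(req, intersect(cl[[a]], cl[[b]]))
      }
    }
  }
  setdiff(req, v)
}

#' Ancestral-path consistency of a tree with sequenced clones
#'
#' For each pair of sequenced clones and each variant v in their symmetric
#' difference, every variant u in their intersection must be an ancestor of
#' v (the shared ancestral path forms before the clones branch; otherwise
#' the infinite sites assumption would be violated).  Variants absent from
#' the tree (e.g. in a partially built tree) are skipped, so a partial tree
#' passes if none of its placed variants violates the rule.
#'
#' @param tree a \code{clonal_tree}.
#' @param clones a \code{sequenced_clones} object.
#' @return Logical scalar; when \code{FALSE}, attribute \code{violation}
#'   lists the offending \code{variant}, required \code{ancestor} and the
#'   clone pair.
#' @export
check_path_consistency <- function(tree, clones) {
  haps <- clone_haplotype_ids(tree)
  ids <- tree$variant_ids
  cl <- clones$clones
  if (length(cl) < 2) return(TRUE)
  for (a in seq_len(length(cl) - 1L)) {
    for (b in (a + 1L):length(cl)) {
      inter <- intersect(intersect(cl[[a]], cl[[b]]), ids)
      sym <- intersect(c(setdiff(cl[[a]], cl[[b]]), setdiff(cl[[b]], cl[[a]])), ids)
      for (v in sym) {
        for (u in inter) {
          if (!(u %in% haps[[v]])) {
            out <- FALSE
            attr(out, "violation") <- list(variant = v, ancestor = u,
                                           clone_pair = c(a, b))
            return(out)
          }
        }
      }
    }
  }
  TRUE
}

# Translate sequenced-clone constraints into per-level candidate and
# required-ancestor index sets for a given birth order of variant ids.
# Returns list(cand = NULL-able list, req = list); NULLs mean unrestricted.
constraint_spec <- function(order_ids, clones) {
  if (is.null(clones)) return(list(cand = NULL, req = NULL))
  N <- length(order_ids)
  cand <- vector("list", N)
  req <- vector("list", N)
  for (i in seq_len(N)) {
    v <- order_ids[i]
    pc <- parent_candidates(clones, v)
    if (is.null(pc)) {
      cand[[i]] <- 0:(i - 1L)
    } else {
      earlier <- match(intersect(pc, order_ids[seq_len(i - 1L)]), order_ids)
      cand[[i]] <- if (length(earlier)) sort(earlier) else 0L
    }
    ra <- intersect(required_ancestors_of(clones, v), order_ids)
    req[[i]] <- sort(match(ra, order_ids))
  }
  list(cand = cand, req = req)
}

#' Resolve sequenced-clone variant ids against a VAF matrix
#'
#' Maps each clone variant to the matching column of \code{F}: an exact id
#' match, or a merged group-column (see [group_mutations()]) containing
#' the variant.  Errors when a variant resolves nowhere unless
#' \code{keep_missing} is set, in which case unresolvable variants are
#' dropped from the clone.
#'
#' @param clones a [sequenced_clones()] object.
#' @param F a VAF matrix.
#' @param keep_missing drop unresolvable variants instead of erroring.
#' @return A \code{sequenced_clones} object over column ids of \code{F}.
#' @export
resolve_clones <- function(clones, F, keep_missing = FALSE) {
  F <- as_vaf(F)
  members <- strsplit(F$variant_ids, "+", fixed = TRUE)
  resolve1 <- function(v) {
    hit <- which(vapply(members, function(m) v %in% m, logical(1)))
    if (!length(hit)) {
      if (keep_missing) return(NA_character_)
      stop("sequenced-clone variant '", v, "' not found in the VAF matrix")
    }
    F$variant_ids[hit[1]]
  }
  out <- lapply(clones$clones, function(A) {
    r <- vapply(A, resolve1, character(1))
    unique(r[!is.na(r)])
  })
  sequenced_clones(out)
}

#' Constrained clonal reconstruction with sequenced clones
#'
#' Runs the chosen search with the parent-candidate restriction pruning the
#' greedy argmax domain and the ancestral-path consistency rule pruning
#' partial solutions; the returned tree satisfies both constraints and the
#' usual validity condition.
#'
#' @param F a VAF matrix.
#' @param clones a [sequenced_clones()] object (variant ids resolvable
#'   against the columns of \code{F}; a merged group-column matches if it
#'   contains the variant).
#' @param algorithm one of \code{"gp-gt"}, \code{"ep-gt"}, \code{"ep-et"},
#'   \code{"gt"}, \code{"et"}.
#' @inheritParams reconstruct
#' @return A reconstruction object, as [reconstruct()].
#' @export
constrained_reconstruct <- function(F, clones,
                                    algorithm = c("gp-gt", "ep-gt", "ep-et",
                                                  "gt", "et"),
                                    neg_tol = 0, tol = 1e-9,
                                    node_budget = Inf) {
  algorithm <- match.arg(algorithm)
  reconstruct(F, algorithm = algorithm, clones = clones, neg_tol = neg_tol,
              tol = tol, node_budget = node_budget)
}
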