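#' Construct a clonal tree
#'
#' A clonal tree records, for each variant \eqn{i} (in birth order), the
#' clone in which the mutation occurred: \code{parent[i]} is the index of an
#' earlier-born variant, or 0 for the founder clone.  The haplotype of the
#' clone created by variant \eqn{i} is the set of variants on the path from
#' the root (founder) to node \eqn{i}.
#'
#' @param parent integer vector; \code{parent[i]} in \code{0:(i-1)}.
#' @param variant_ids character labels for the variants, in birth order.
#' @return An object of class \code{clonal_tree}.
#' @export
#' @examples
#' tr <- clonal_tree(c(0, 1, 1), c("a", "b", "c"))
#' tree_haplotypes(tr)
clonal_tree <- function(parent, variant_ids = NULL) {
  parent <- as.integer(parent)
  N <- length(parent)
  if (N < 1L) stop("a clonal tree needs at least one variant")
  if (anyNA(parent) || any(parent < 0L) || any(parent >= seq_len(N)))
    stop("parent[i] must be an earlier-born variant (< i) or the founder (0)")
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(N))
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != N || anyDuplicated(variant_ids))
    stop("variant_ids must be unique and match the parent vector")
  structure(list(parent = parent, variant_ids = variant_ids),
            class = "clonal_tree")
}

#' Children map of a clonal tree
#'
#' @param tree a \code{clonal_tree}.
#' @return A list of length N + 1: element k + 1 holds the integer indices
#'   of the children of node k (node 0 = founder).
#' @export
tree_children <- function(tree) {
  N <- length(tree$parent)
  lapply(0:N, function(k) which(tree$parent == k))
}

#' Haplotypes encoded by a clonal tree
#'
#' @param tree a \code{clonal_tree}.
#' @return \code{tree_haplotypes}: list of integer vectors, element i = the
#'   variant indices on the root path of node i (including i itself).
#'   \code{clone_haplotype_ids}: the same as variant-id character vectors,
#'   named by variant id.
#' @export
tree_haplotypes <- function(tree) {
  N <- length(tree$parent)
  haps <- vector("list", N)
  for (i in seq_len(N)) {
    p <- tree$parent[i]
    haps[[i]] <- if (p == 0L) i else c(haps[[p]], i)
  }
  haps
}

#' @rdname tree_haplotypes
#' @export
clone_haplotype_ids <- function(tree) {
  haps <- lapply(tree_haplotypes(tree), function(h) tree$variant_ids[h])
  names(haps) <- tree$variant_ids
  haps
}

#' Re-index a clonal tree to a new birth order
#'
#' Reorders the variants of a tree to \code{ids} (which must be a
#' permutation of the tree's variant ids) and recomputes parent indices.
#' Fails if the new order places any parent after its child.
#'
#' @param tree a \code{clonal_tree}.
#' @param ids character vector, the new birth order.
#' @return A \code{clonal_tree} over \code{ids}.
#' @export
align_tree <- function(tree, ids) {
  ids <- as.character(ids)
  if (!setequal(ids, tree$variant_ids) || length(ids) != length(tree$variant_ids))
    stop("ids must be a permutation of the tree's variant ids")
  pos <- match(tree$variant_ids, ids)         # old index -> new index
  new_parent <- integer(length(ids))
  for (i in seq_along(tree$parent)) {
    p <- tree$parent[i]
    new_parent[pos[i]] <- if (p == 0L) 0L else pos[p]
  }
  if (any(new_parent >= seq_along(new_parent)))
    stop("requested order places a parent after its child")
  clonal_tree(new_parent, ids)
}

#' Project a clonal tree onto a subset of variants
#'
#' Restricts a tree to the variants in \code{ids}; the parent of a kept
#' variant becomes its nearest kept ancestor (or the founder).  Used to
#' compare a reconstruction against a ground truth when some variants were
#' never observed.
#'
#' @param tree a \code{clonal_tree}.
#' @param ids character vector of variant ids to keep.
#' @return A \code{clonal_tree} over \code{ids} in the original birth order.
#' @export
project_tree <- function(tree, ids) {
  keep <- tree$variant_ids %in% as.character(ids)
  if (!any(keep)) stop("no variant to keep")
  kept_idx <- which(keep)
  new_pos <- integer(length(tree$parent))
  new_pos[kept_idx] <- seq_along(kept_idx)
  new_parent <- integer(length(kept_idx))
  for (j in seq_along(kept_idx)) {
    p <- tree$parent[kept_idx[j]]
    while (p != 0L && !keep[p]) p <- tree$parent[p]
    new_parent[j] <- if (p == 0L) 0L else new_pos[p]
  }
  clonal_tree(new_parent, tree$variant_ids[kept_idx])
}

#' @export
print.clonal_tree <- function(x, ...) {
  N <- length(x$parent)
  cat(sprintf("Clonal tree on %d variants (+ founder)\n", N))
  par_id <- ifelse(x$parent == 0L, "founder", x$variant_ids[pmax(x$parent, 1L)])
  cat(paste0("  ", x$variant_ids, " <- ", par_id, collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write a clonal tree as two-column TSV
#'
#' Columns are \code{child} and \code{parent} variant ids, one row per
#' variant in birth order; the literal token \code{founder} denotes the
#' root.
#'
#' @param file path to a TSV file.
#' @return \code{read_tree} returns a \code{clonal_tree}.
#' @export
read_tree <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  ids <- as.character(d$child)
  parent <- match(as.character(d$parent), ids)
  parent[as.character(d$parent) == "founder"] <- 0L
  if (anyNA(parent)) stop("unknown parent id in ", file)
  clonal_tree(parent, ids)
}

#' @rdname read_tree
#' @param tree a \code{clonal_tree} to write.
#' @export
write_tree <- function(tree, file) {
  par_id <- ifelse(tree$parent == 0L, "founder",
                   tree$variant_ids[pmax(tree$parent, 1L)])
  d <- data.frame(child = tree$variant_ids, parent = par_id,
                  stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
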