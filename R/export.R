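#' Muller plot tables (ggmuller input convention)
#'
#' Converts a reconstruction into the two tables consumed by Muller-plot
#' libraries: an edges table (\code{Parent}, \code{Identity}) with one row
#' per non-root clone, and a population table (\code{Generation},
#' \code{Identity}, \code{Population}) with the clone frequencies at every
#' observed time point.  The founder clone is labelled \code{founder}.
#'
#' @param tree a \code{clonal_tree}.
#' @param cfm a [compute_cfm()] result (clamped and renormalized).
#' @param time_labels optional overrides for the generation labels.
#' @return List of two data frames, \code{edges} and \code{population}.
#' @export
#' @examples
#' F <- rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3))
#' tr <- clonal_tree(c(0, 1, 1))
#' export_muller(tr, compute_cfm(F, tr))
export_muller <- function(tree, cfm, time_labels = NULL) {
  C <- if (inherits(cfm, "cfm")) cfm$values else as.matrix(cfm)
  ids <- tree$variant_ids
  stopifnot(ncol(C) == length(ids) + 1L)
  if (is.null(time_labels)) time_labels <- rownames(C)
  if (is.null(time_labels)) time_labels <- paste0("t", seq_len(nrow(C)))
  par_id <- ifelse(tree$parent == 0L, "founder", ids[pmax(tree$parent, 1L)])
  edges <- data.frame(Parent = par_id, Identity = ids,
                      stringsAsFactors = FALSE)
  population <- data.frame(
    Generation = rep(time_labels, times = ncol(C)),
    Identity = rep(c("founder", ids), each = nrow(C)),
    Population = as.vector(C),
    stringsAsFactors = FALSE)
  list(edges = edges, population = population)
}

#' @rdname export_muller
#' @param tables an [export_muller()] result.
#' @param prefix output path prefix; writes \code{<prefix>_edges.csv} and
#'   \code{<prefix>_population.csv}.
#' @export
write_muller <- function(tables, prefix) {
  ef <- paste0(prefix, "_edges.csv")
  pf <- paste0(prefix, "_population.csv")
  utils::write.csv(tables$edges, ef, row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$population, pf, row.names = FALSE, quote = FALSE)
  invisible(c(ef, pf))
}

#' Binary haplotype table of a clonal tree
#'
#' One row per clone, one 0/1 column per variant: cell = 1 when the
#' variant lies on the clone's root path.  When sequenced clones are
#' supplied, rows whose haplotype matches one of them are flagged in a
#' logical \code{sequenced} column.
#'
#' @param tree a \code{clonal_tree}.
#' @param sequenced optional [sequenced_clones()] object.
#' @return A data frame with \code{clone}, one column per variant, and
#'   \code{sequenced}.
#' @export
export_haplotypes <- function(tree, sequenced = NULL) {
  ids <- tree$variant_ids
  haps <- clone_haplotype_ids(tree)
  M <- t(vapply(haps, function(h) as.integer(ids %in% h),
                integer(length(ids))))
  colnames(M) <- ids
  flag <- rep(FALSE, length(haps))
  if (!is.null(sequenced)) {
    for (A in sequenced$clones)
      flag <- flag | vapply(haps, setequal, logical(1), y = A)
  }
  data.frame(clone = names(haps), M, sequenced = flag,
             check.names = FALSE, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a clonal frequency matrix as TSV
#'
#' Same dialect as [write_vaf()], with the \code{founder} column first.
#'
#' @param cfm a [compute_cfm()] result.
#' @param file output path.
#' @export
write_cfm <- function(cfm, file) {
  C <- if (inherits(cfm, "cfm")) cfm$values else as.matrix(cfm)
  d <- data.frame(time = rownames(C), C, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
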