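#' Construct a VAF matrix
#'
#' A VAF matrix holds the variant allele frequencies \eqn{f_{i,j}} observed
#' in a pooled (metagenome) sequencing time course: rows are time points,
#' columns are variants, and each cell is the fraction of reads supporting
#' the variant allele at that time.  The first-observation time of each
#' variant, \eqn{t_j = \min\{i : f_{i,j} > 0\}}, is computed on
#' construction; it drives the grouping of variants that appear at the same
#' time point.
#'
#' @param values numeric matrix of allele frequencies in \[0, 1\]; rows =
#'   time points, columns = variants.
#' @param variant_ids character vector of variant labels (defaults to the
#'   column names, or \code{v1, v2, ...}).
#' @param time_labels character vector of time-point labels (defaults to the
#'   row names, or \code{t1, t2, ...}).
#' @return An object of class \code{vaf_matrix}: a list with elements
#'   \code{values}, \code{variant_ids}, \code{time_labels} and
#'   \code{first_obs} (integer row index of first observation per variant,
#'   \code{NA} for an all-zero column).
#' @seealso [read_vaf()], [is_square_vaf()], [mutation_groups()]
#' @export
#' @examples
#' F <- vaf_matrix(rbind(c(1, 0, 0), c(1, 0.4, 0), c(0.9, 0.5, 0.3)))
#' F$first_obs
vaf_matrix <- function(values, variant_ids = NULL, time_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a VAF matrix needs at least one time point and one variant")
  if (is.null(variant_ids)) variant_ids <- colnames(values)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(values)))
  if (is.null(time_labels)) time_labels <- rownames(values)
  if (is.null(time_labels)) time_labels <- paste0("t", seq_len(nrow(values)))
  variant_ids <- as.character(variant_ids)
  time_labels <- as.character(time_labels)
  if (length(variant_ids) != ncol(values))
    stop("variant_ids must match the number of columns")
  if (length(time_labels) != nrow(values))
    stop("time_labels must match the number of rows")
  if (anyDuplicated(variant_ids))
    stop("variant ids must be unique")
  if (anyNA(values) || any(values < -1e-9) || any(values > 1 + 1e-9))
    stop("allele frequencies must lie in [0, 1]")
  values[values < 0] <- 0
  values[values > 1] <- 1
  dimnames(values) <- list(time_labels, variant_ids)
  structure(list(values = values,
                 variant_ids = variant_ids,
                 time_labels = time_labels,
                 first_obs = first_observation(values)),
            class = "vaf_matrix")
}

first_observation <- function(values) {
  out <- apply(values, 2, function(x) {
    w <- which(x > 0)
    if (length(w)) w[1L] else NA_integer_
  })
  stats::setNames(as.integer(out), colnames(values))
}

#' Coerce to a VAF matrix
#'
#' @param F a \code{vaf_matrix} or a plain numeric matrix.
#' @return A \code{vaf_matrix}.
#' @export
as_vaf <- function(F) {
  if (inherits(F, "vaf_matrix")) F else vaf_matrix(F)
}

#' Test whether a VAF matrix is square lower-triangular
#'
#' A "square" time course has exactly one new mutation per observed time
#' point: the matrix is N x N with \eqn{f_{i,j} = 0} for \eqn{j > i}.  The
#' tree-search algorithms operate on square matrices; sparse time courses
#' are first extended with [extend_vaf()].
#'
#' @param F a VAF matrix.
#' @param tol absolute tolerance for the zero test.
#' @return Logical scalar.
#' @export
is_square_vaf <- function(F, tol = 1e-9) {
  F <- as_vaf(F)
  V <- F$values
  if (nrow(V) != ncol(V)) return(FALSE)
  all(abs(V[upper.tri(V)]) <= tol)
}

#' @export
print.vaf_matrix <- function(x, ...) {
  cat(sprintf("VAF matrix: %d time points x %d variants%s\n",
              nrow(x$values), ncol(x$values),
              if (is_square_vaf(x)) " (square lower-triangular)" else ""))
  print(round(x$values, 4))
  invisible(x)
}

#' Read / write a VAF matrix as tab-separated text
#'
#' The dialect is: first column = time label, header row = variant ids,
#' cells = decimal allele-frequency fractions.  Square-ness is inferred, not
#' required, on read.
#'
#' @param file path to a TSV file.
#' @return \code{read_vaf} returns a \code{vaf_matrix};
#'   \code{write_vaf} invisibly returns \code{file}.
#' @export
read_vaf <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  vaf_matrix(m, variant_ids = colnames(d)[-1], time_labels = as.character(d[[1]]))
}

#' @rdname read_vaf
#' @param F a VAF matrix to write.
#' @export
write_vaf <- function(F, file) {
  F <- as_vaf(F)
  d <- data.frame(time = F$time_labels, F$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
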