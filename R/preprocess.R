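#' Read a per-time-point variant read-count table
#'
#' Expected TSV columns: \code{time} (sample/time-point label, in
#' chronological file order), \code{site} (variant locus label),
#' \code{ref_reads}, \code{var_fwd}, \code{var_rev} (nonnegative read
#' counts; forward/reverse reads supporting the variant allele).  A column
#' \code{var_reads} is derived as \code{var_fwd + var_rev}.  Converting a
#' VCF into this layout is left to upstream tooling.
#'
#' @param file path to a TSV file.
#' @return A \code{data.frame} of class \code{variant_counts}.
#' @export
read_variant_counts <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  as_variant_counts(d)
}

#' @rdname read_variant_counts
#' @param d a data frame with the columns described above.
#' @export
as_variant_counts <- function(d) {
  need <- c("time", "site", "ref_reads", "var_fwd", "var_rev")
  if (!all(need %in% names(d)))
    stop("count table needs columns: ", paste(need, collapse = ", "))
  d$var_reads <- d$var_fwd + d$var_rev
  if (any(d$ref_reads < 0 | d$var_fwd < 0 | d$var_rev < 0))
    stop("read counts must be nonnegative")
  class(d) <- c("variant_counts", "data.frame")
  d
}

#' Strand-balance filter
#'
#' Variant support with forward/reverse read balance below
#' \code{min_balance} is typically a mapping artifact; such sites have
#' their variant support zeroed at that time point.  Sites with no variant
#' reads are untouched (no balance is defined).
#'
#' @param counts a [read_variant_counts()] table.
#' @param min_balance minimum \code{min(var_fwd, var_rev) / var_reads}
#'   (default 0.25).
#' @return The filtered count table.
#' @export
balance_filter <- function(counts, min_balance = 0.25) {
  stopifnot(min_balance >= 0, min_balance <= 0.5)
  bal <- ifelse(counts$var_reads > 0,
                pmin(counts$var_fwd, counts$var_rev) / counts$var_reads, NA)
  drop <- !is.na(bal) & bal < min_balance
  counts$var_fwd[drop] <- 0L
  counts$var_rev[drop] <- 0L
  counts$var_reads[drop] <- 0L
  counts
}

#' Variant calling thresholds
#'
#' The VAF is the ratio of variant-supporting reads to the total of
#' variant- and reference-supporting reads.  A call is made at a time
#' point only when the VAF is above \code{min_vaf}, the depth (ref + var)
#' above \code{min_depth} and the variant reads above
#' \code{min_var_reads} (all strictly); uncalled entries are 0.
#'
#' @param counts a count table.
#' @param min_vaf,min_depth,min_var_reads strict thresholds (defaults
#'   0.05, 10, 6).
#' @return A numeric matrix of called VAFs, rows = time points in file
#'   order, columns = sites.
#' @export
call_variants <- function(counts, min_vaf = 0.05, min_depth = 10,
                          min_var_reads = 6) {
  depth <- counts$ref_reads + counts$var_reads
  vaf <- ifelse(depth > 0, counts$var_reads / depth, 0)
  called <- vaf > min_vaf & depth > min_depth & counts$var_reads > min_var_reads
  vaf[!called] <- 0
  times <- unique(counts$time)
  sites <- unique(counts$site)
  V <- matrix(0, length(times), length(sites), dimnames = list(times, sites))
  V[cbind(match(counts$time, times), match(counts$site, sites))] <- vaf
  V
}

#' Temporal consistency filter
#'
#' Removes sites whose called VAF becomes zero and then non-zero again at
#' a later time point (a resurrection pattern incompatible with a single
#' mutation birth); extinction after birth (trailing zeros) is allowed.
#'
#' @param V a matrix of called VAFs (rows = ordered time points).
#' @return The matrix restricted to consistent sites.
#' @export
consistency_filter <- function(V) {
  keep <- apply(V, 2, function(x) {
    w <- which(x > 0)
    length(w) > 0 && all(diff(w) == 1)
  })
  V[, keep, drop = FALSE]
}

#' Count table to filtered VAF matrix
#'
#' Applies, in order, the strand-balance filter, the calling thresholds
#' and the temporal consistency filter, then drops sites never called.
#'
#' @inheritParams balance_filter
#' @inheritParams call_variants
#' @return A \code{vaf_matrix}.
#' @export
counts_to_vaf <- function(counts, min_balance = 0.25, min_vaf = 0.05,
                          min_depth = 10, min_var_reads = 6) {
  counts <- balance_filter(counts, min_balance)
  V <- call_variants(counts, min_vaf, min_depth, min_var_reads)
  V <- consistency_filter(V)
  if (ncol(V) == 0) stop("no site survived the variant filters")
  vaf_matrix(V)
}
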