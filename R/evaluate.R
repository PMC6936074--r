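#' Recall of correctly reconstructed clones
#'
#' A clone is correctly reconstructed when the set of variants on its root
#' path (its haplotype) under the predicted tree equals the set under the
#' true tree; recall is the fraction of correct clones.  The founder is
#' not counted (its haplotype is empty under any tree).  When the trees
#' cover different variant sets, pass \code{variants}: haplotypes are then
#' intersected with that set and recall is computed over it, so the
#' comparison is birth-order agnostic.
#'
#' @param predicted,truth \code{clonal_tree} objects.
#' @param variants optional character vector of variant ids to evaluate
#'   over; required when the trees' variant sets differ.
#' @return Recall in \[0, 1\].
#' @export
#' @examples
#' truth <- clonal_tree(c(0, 1, 2))
#' pred <- clonal_tree(c(0, 1, 1))
#' clone_recall(pred, truth)  # clones 1, 2 correct; clone 3 wrong -> 2/3
clone_recall <- function(predicted, truth, variants = NULL) {
  if (is.null(variants)) {
    if (!setequal(predicted$variant_ids, truth$variant_ids))
      stop("trees cover different variant sets; pass `variants`")
    variants <- predicted$variant_ids
  }
  variants <- as.character(variants)
  hp <- clone_haplotype_ids(predicted)
  ht <- clone_haplotype_ids(truth)
  if (!all(variants %in% names(hp)) || !all(variants %in% names(ht)))
    stop("some requested variants are absent from a tree")
  correct <- vapply(variants, function(v)
    setequal(intersect(hp[[v]], variants), intersect(ht[[v]], variants)),
    logical(1))
  mean(correct)
}

#' Log likelihood ratio of a predicted tree over the true tree
#'
#' \code{log(PL/TL)}: the log likelihood of the predicted tree minus that
#' of the true tree.  A positive value means the algorithm found a tree
#' more likely than the truth (possible because the truth is a single
#' random draw from the generative model).  For sparse inputs each tree is
#' scored on its own square extension: pass the truth's extension as
#' \code{F_truth}.
#'
#' @param F square VAF matrix on which the predicted tree is scored.
#' @param predicted,truth \code{clonal_tree} objects.
#' @param F_truth square VAF matrix for the truth (default \code{F}).
#' @return The log ratio; \code{Inf}/\code{-Inf} when exactly one
#'   likelihood is zero, \code{NA} when both are.
#' @export
log_likelihood_ratio <- function(F, predicted, truth, F_truth = F) {
  F <- as_vaf(F)
  F_truth <- as_vaf(F_truth)
  lp <- tree_likelihood(F, align_tree(predicted, F$variant_ids))$log_value
  lt <- tree_likelihood(F_truth, align_tree(truth, F_truth$variant_ids))$log_value
  if (lp == -Inf && lt == -Inf) return(NA_real_)
  lp - lt
}

truth_extension <- function(Fobs, truth_tree) {
  g <- mutation_groups(Fobs)
  orders <- lapply(g$groups, function(grp) {
    ids <- Fobs$variant_ids[grp]
    ids[order(match(ids, truth_tree$variant_ids))]
  })
  extend_vaf(Fobs, orders)
}

#' Simulation experiment driver
#'
#' Generates replicate populations, observes them at the requested
#' temporal resolution, reconstructs each with the requested algorithms,
#' and reports per-replicate recall, log likelihood ratio and
#' misreconstructed-clone counts plus per-condition summaries.  All
#' randomness derives from \code{seed}; the same replicate populations are
#' shared across algorithms, time-point conditions and constraint levels,
#' and re-running with the same arguments reproduces the tables exactly.
#'
#' @param algorithms character vector of [reconstruct()] algorithms.
#' @param n_clones integer vector of population sizes (number of mutant
#'   clones).
#' @param timepoints vector of observation settings: integers,
#'   \code{"all"} (= one time point per clone, square input) or
#'   \code{"binomial"} (K ~ Binomial(n, 0.6)).
#' @param n_reps replicates per condition.
#' @param seed master seed.
#' @param n_known_clones integer vector: numbers of true clone haplotypes
#'   supplied to the constrained search (0 = unconstrained).  For each
#'   replicate a fixed random clone order is drawn once, so the supplied
#'   sets are nested across levels.
#' @param alpha,init_fraction_range simulator parameters, see
#'   [simulate_population()].
#' @param neg_tol passed to [reconstruct()].
#' @return An object of class \code{clone_experiment}: list with
#'   \code{replicates} (one row per replicate x condition x algorithm) and
#'   \code{summary} (per-condition means, s.d. and quartiles of recall,
#'   mean misreconstructed count, mean finite log likelihood ratio, and
#'   failure counts).
#' @export
run_experiment <- function(algorithms = "gp-gt", n_clones = 15,
                           timepoints = "all", n_reps = 100, seed = 1,
                           n_known_clones = 0, alpha = 50,
                           init_fraction_range = c(0.1, 0.5), neg_tol = 0) {
  conds <- expand.grid(n_clones = n_clones,
                       timepoints = as.character(timepoints),
                       n_known = n_known_clones,
                       stringsAsFactors = FALSE)
  truth_cache <- new.env(parent = emptyenv())
  get_truth <- function(nc, rep) {
    key <- paste0(nc, ".", rep)
    if (is.null(truth_cache[[key]]))
      truth_cache[[key]] <- simulate_population(
        nc, seed = derive_seed(seed, nc, rep, 1),
        alpha = alpha, init_fraction_range = init_fraction_range)
    truth_cache[[key]]
  }
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    nc <- conds$n_clones[ci]
    tp <- conds$timepoints[ci]
    nk <- conds$n_known[ci]
    tp_arg <- if (tp %in% c("all", "binomial")) tp else as.integer(tp)
    for (rep in seq_len(n_reps)) {
      truth <- get_truth(nc, rep)
      K <- if (identical(tp_arg, "all")) nc else tp_arg
      Fobs <- observe_vaf(truth, K,
                          seed = derive_seed(seed, nc, rep,
                                             2 + match(tp, unique(conds$timepoints))))
      ids <- Fobs$variant_ids
      truth_proj <- project_tree(truth$tree, ids)
      cl <- NULL
      if (nk > 0) {
        set.seed(derive_seed(seed, nc, rep, 99))
        ord <- sample.int(nc)
        haps <- clone_haplotype_ids(truth$tree)
        sets <- lapply(haps[ord[seq_len(min(nk, nc))]], intersect, y = ids)
        sets <- sets[lengths(sets) > 0]
        if (length(sets)) cl <- sequenced_clones(sets)
      }
      ext_t <- truth_extension(Fobs, truth$tree)
      lt <- tree_likelihood(ext_t$square,
                            align_tree(truth_proj, ext_t$square$variant_ids))$log_value
      for (alg in algorithms) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(
          reconstruct(Fobs, algorithm = alg, clones = cl, neg_tol = neg_tol,
                      seed = derive_seed(seed, nc, rep,
                                         500 + match(alg, algorithms))),
          error = function(e) NULL)
        runtime <- proc.time()[["elapsed"]] - t0
        ok <- !is.null(res) && res$status == "found"
        rec <- llr <- NA_real_
        nmis <- NA_integer_
        if (ok) {
          rec <- clone_recall(res$tree, truth_proj, variants = ids)
          nmis <- as.integer(round((1 - rec) * length(ids)))
          lp <- res$likelihood$log_value
          llr <- if (lp == -Inf && lt == -Inf) NA_real_ else lp - lt
        }
        rows[[length(rows) + 1L]] <- data.frame(
          n_clones = nc, timepoints = tp, n_known = nk, rep = rep,
          algorithm = alg, n_observed = length(ids), status =
            if (ok) "found" else "no_valid_solution",
          recall = rec, n_misreconstructed = nmis,
          log_likelihood_ratio = llr, runtime = runtime,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_replicates <- data.frame(
    n_clones = integer(), timepoints = character(), n_known = integer(),
    rep = integer(), algorithm = character(), n_observed = integer(),
    status = character(), recall = numeric(), n_misreconstructed = integer(),
    log_likelihood_ratio = numeric(), runtime = numeric(),
    stringsAsFactors = FALSE)
  if (!length(rows)) {
    return(structure(list(replicates = empty_replicates,
                          summary = empty_replicates[0, 1:3],
                          params = list(seed = seed, alpha = alpha,
                                        init_fraction_range = init_fraction_range,
                                        n_reps = n_reps)),
                     class = "clone_experiment"))
  }
  replicates <- do.call(rbind, rows)
  key <- interaction(replicates$n_clones, replicates$timepoints,
                     replicates$n_known, replicates$algorithm, drop = TRUE)
  summary <- do.call(rbind, lapply(split(replicates, key), function(d) {
    r <- d$recall[!is.na(d$recall)]
    llr <- d$log_likelihood_ratio
    llr <- llr[!is.na(llr) & is.finite(llr)]
    data.frame(n_clones = d$n_clones[1], timepoints = d$timepoints[1],
               n_known = d$n_known[1], algorithm = d$algorithm[1],
               n = nrow(d), n_failed = sum(d$status != "found"),
               mean_recall = mean(r), sd_recall = stats::sd(r),
               q25_recall = unname(stats::quantile(r, 0.25)),
               median_recall = stats::median(r),
               q75_recall = unname(stats::quantile(r, 0.75)),
               mean_misreconstructed = mean(d$n_misreconstructed, na.rm = TRUE),
               sd_misreconstructed = stats::sd(d$n_misreconstructed, na.rm = TRUE),
               mean_llr = if (length(llr)) mean(llr) else NA_real_,
               mean_runtime = mean(d$runtime), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(replicates = replicates, summary = summary,
                 params = list(seed = seed, alpha = alpha,
                               init_fraction_range = init_fraction_range,
                               n_reps = n_reps)),
            class = "clone_experiment")
}

#' @export
print.clone_experiment <- function(x, ...) {
  cat("Clonal reconstruction experiment\n")
  print(x$summary, digits = 3)
  invisible(x)
}
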