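# Phylogenetic signal in ID dissimilarity: Mantel-style rank correlation
# (Kendall tau-b) between a patristic distance matrix and a behavioural
# dissimilarity matrix, with a nested bootstrap combining tree uncertainty
# (a posterior or pseudo-posterior tree set) and ID estimation uncertainty
# (per-species bootstrap ensembles).

#' Kendall tau-b between two pairwise tables
#'
#' Rank correlation over the unordered-pair (lower-triangle) entries of two
#' symmetric matrices sharing a species set, with the tie-corrected tau-b
#' denominator. Both matrices are vectorized in the same canonical
#' (alphabetical) species order; any shared ordering gives the same value.
#'
#' @param d1,d2 [pairwise_table] objects or symmetric matrices with species
#'   dimnames.
#' @return tau-b in \[-1, 1\]; `NA` (with a warning) if either side is
#'   entirely tied.
#' @export
kendall_tau_b <- function(d1, d2) {
  m1 <- if (inherits(d1, "pairwise_table")) d1$point else as.matrix(d1)
  m2 <- if (inherits(d2, "pairwise_table")) d2$point else as.matrix(d2)
  sp <- sort(rownames(m1))
  if (!setequal(sp, rownames(m2)))
    stop("the two tables cover different species sets")
  m1 <- m1[sp, sp]; m2 <- m2[sp, sp]
  x <- m1[lower.tri(m1)]; y <- m2[lower.tri(m2)]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("tau-b undefined: all pairs tied on one side")
    return(NA_real_)
  }
  cor(x, y, method = "kendall")
}

#' Nested bootstrap for phylogenetic signal in ID dissimilarity
#'
#' Point estimate: tau-b between the patristic distances of `point_tree` and
#' the dissimilarity table computed from the point ID estimates. Uncertainty:
#' each bootstrap replicate draws one tree from `trees` (its distance
#' matrix), one ID matrix per species from that species' bootstrap ensemble,
#' recomputes the behavioural dissimilarity table, and takes tau-b; the CI is
#' the 2.5/97.5 percentile of the replicate taus. Replicates where tau is
#' undefined are excluded and counted.
#'
#' @param ids named list of point ID matrices (or `id_fit` objects), one per
#'   species.
#' @param ensembles named list of bootstrap ensembles matching `ids`.
#' @param point_tree tree used for the point estimate.
#' @param trees a `multiPhylo` set representing tree uncertainty.
#' @param statistic "delta", "theta" or "twoK"; the choice only changes the
#'   dissimilarity computed, never the bootstrap scaffolding.
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param x subspace dimension for "twoK".
#' @param conf confidence level.
#' @param seed optional integer seed.
#' @return object of class `signal_result`: list with `tau`, `boot` (the
#'   replicate taus), `ci`, `n_reps`, `failed`, `statistic`, `seed`.
#' @export
phylo_signal <- function(ids, ensembles, point_tree, trees,
                         statistic = c("delta", "theta", "twoK"),
                         n_reps = 1000, x = 2, conf = 0.95, seed = NULL) {
  statistic <- match.arg(statistic)
  ids <- lapply(ids, function(f) if (inherits(f, "id_fit")) f$ID else f)
  if (is.null(names(ids))) stop("ids must be a named list")
  sp <- names(ids)
  if (!length(trees)) stop("trees must be non-empty")
  draws <- lapply(ensembles[sp], ensemble_draws)
  if (any(!lengths(draws))) stop("empty bootstrap ensemble")
  point_tab <- pairwise_id_table(ids, statistic, x = x)
  tau <- kendall_tau_b(patristic_distances(point_tree, sp), point_tab)
  dist_draws <- lapply(trees, function(tr)
    patristic_distances(tr, sp)$point)
  boot <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      D <- dist_draws[[sample.int(length(dist_draws), 1)]]
      rep_ids <- lapply(draws, function(dd) dd[[sample.int(length(dd), 1)]])
      names(rep_ids) <- sp
      tab <- pairwise_id_table(rep_ids, statistic, x = x)
      suppressWarnings(kendall_tau_b(D, tab))
    }, 0)
  })
  ok <- is.finite(boot)
  ci <- quantile(boot[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 names = FALSE)
  structure(list(tau = tau, boot = boot[ok], ci = ci, n_reps = n_reps,
                 failed = sum(!ok), statistic = statistic, seed = seed),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, digits = 3, ...) {
  cat("Phylogenetic signal in ID dissimilarity (", x$statistic, ")\n",
      sep = "")
  cat("  tau-b =", round(x$tau, digits),
      " 95% CI [", round(x$ci[1], digits), ",", round(x$ci[2], digits),
      "] from", length(x$boot), "bootstrap replicates\n")
  if (x$failed > 0) cat(" ", x$failed, "replicates undefined, excluded\n")
  invisible(x)
}
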