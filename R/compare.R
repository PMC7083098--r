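# Matrix-comparison statistics for among-individual covariance (ID) matrices:
# trace and trace difference (delta), leading-eigenvector angle (theta), and
# Krzanowski subspace similarity (K), with percentile bootstrap CIs taken over
# paired independent draws from per-species bootstrap ensembles.

#' Trace of a covariance matrix
#'
#' Total variance summed over traits: the sum of the diagonal (equivalently of
#' the eigenvalues) of a square matrix.
#'
#' @param m square matrix.
#' @return scalar trace.
#' @export
id_trace <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  sum(diag(m))
}

#' Eigen-decomposition summary of an ID matrix
#'
#' Eigenvalues in descending order with unit-norm eigenvectors and the percent
#' of total variance carried by each axis. Eigenvectors whose eigenvalue is
#' numerically tied with the next one are flagged as directionally unstable
#' (their individual directions are arbitrary within the tied subspace even
#' though subspace statistics remain well defined).
#'
#' @param m symmetric matrix.
#' @param tie_tol gap below which adjacent eigenvalues are treated as tied.
#' @return object of class `eigen_summary`: list with `values`, `vectors`
#'   (unit columns), `percent`, and logical `unstable`.
#' @export
eigen_summary <- function(m, tie_tol = 1e-8) {
  if (max(abs(m - t(m))) > 1e-8) stop("m must be symmetric")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  gaps <- abs(diff(e$values))
  unstable <- c(gaps < tie_tol, FALSE) | c(FALSE, gaps < tie_tol)
  structure(list(values = e$values, vectors = e$vectors,
                 percent = 100 * e$values / sum(e$values),
                 unstable = unstable), class = "eigen_summary")
}

#' Angle between two vectors, folded into the 0 to 90 degree range
#'
#' Arc-cosine of the absolute normalized dot product. The fold to 90 degrees
#' reflects the sign indeterminacy of eigenvectors: v and -v span the same
#' axis, so the angle is invariant to a sign flip (or any rescaling) of either
#' vector.
#'
#' @param v1,v2 nonzero numeric vectors of equal length.
#' @return angle in degrees in \[0, 90\].
#' @export
vector_angle <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction")
  acos(min(1, abs(sum(v1 * v2)) / (n1 * n2))) * 180 / pi
}

#' Orthonormal basis for a subspace of trait space
#'
#' Wraps x eigenvectors (columns) as an orthonormal basis via Gram-Schmidt,
#' preserving the direction of the leading vector. The subspace dimension is
#' restricted to x <= n/2, the validity condition of the Krzanowski
#' comparison.
#'
#' @param vectors n x x matrix whose columns span the subspace.
#' @return object of class `subspace_basis`: list with `n`, `x`, `basis`.
#' @export
subspace_basis <- function(vectors) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors); x <- ncol(vectors)
  if (x > n / 2)
    stop("subspace dimension x = ", x, " exceeds n/2 = ", n / 2)
  B <- matrix(0, n, x)
  for (j in seq_len(x)) {
    v <- vectors[, j]
    if (j > 1) v <- v - B[, 1:(j - 1), drop = FALSE] %*%
        crossprod(B[, 1:(j - 1), drop = FALSE], v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("basis vectors are linearly dependent")
    B[, j] <- v / nv
  }
  structure(list(n = n, x = x, basis = B), class = "subspace_basis")
}

#' Krzanowski subspace similarity K
#'
#' Similarity between two x-dimensional subspaces of n-dimensional trait
#' space: with orthonormal bases A and B, `K = sum of eigenvalues of
#' S = A'BB'A`, which equals the sum of squared cosines of the principal
#' angles between the subspaces. K ranges from 0 (orthogonal subspaces) to x
#' (identical subspaces); `x - K` is the corresponding dissimilarity.
#'
#' @param basis1,basis2 [subspace_basis] objects (or n x x matrices, which are
#'   orthonormalized first) with matching n and x.
#' @return scalar K in \[0, x\].
#' @export
krzanowski_k <- function(basis1, basis2) {
  if (!inherits(basis1, "subspace_basis")) basis1 <- subspace_basis(basis1)
  if (!inherits(basis2, "subspace_basis")) basis2 <- subspace_basis(basis2)
  if (basis1$n != basis2$n || basis1$x != basis2$x)
    stop("bases must share the same n and x")
  A <- basis1$basis; B <- basis2$basis
  S <- t(A) %*% B %*% t(B) %*% A
  sum(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# Leading-x-eigenvector basis of an ID matrix.
id_subspace <- function(m, x) {
  subspace_basis(eigen_summary(m)$vectors[, seq_len(x), drop = FALSE])
}

# One comparison statistic between two ID matrices.
id_statistic <- function(m1, m2, statistic, x = 2) {
  switch(statistic,
    delta = abs(id_trace(m1) - id_trace(m2)),
    theta = vector_angle(eigen_summary(m1)$vectors[, 1],
                         eigen_summary(m2)$vectors[, 1]),
    twoK  = x - krzanowski_k(id_subspace(m1, x), id_subspace(m2, x)),
    stop("unknown statistic: ", statistic))
}

#' Trace difference between two ID matrices with bootstrap CI
#'
#' Point estimate `|tr(id1) - tr(id2)|` with an approximate 95% CI taken as
#' the 2.5/97.5 percentiles of `tr(draw1) - tr(draw2)` over paired draws from
#' the two species' independent bootstrap ensembles (draw i of ensemble 1 is
#' paired with draw i of ensemble 2). Because the CI is on the signed
#' difference, significance is read as the CI excluding zero.
#'
#' @param id1,id2 ID matrix point estimates.
#' @param ens1,ens2 optional [parametric_bootstrap] ensembles; when omitted
#'   only the point estimate is returned.
#' @param conf confidence level for the percentile interval.
#' @return list with `point`, and with ensembles `lo`, `hi`.
#' @export
delta_trace <- function(id1, id2, ens1 = NULL, ens2 = NULL, conf = 0.95) {
  out <- list(point = abs(id_trace(id1) - id_trace(id2)))
  if (!is.null(ens1) || !is.null(ens2)) {
    if (is.null(ens1) || is.null(ens2)) stop("both ensembles are required")
    d1 <- vapply(ensemble_draws(ens1), id_trace, 0)
    d2 <- vapply(ensemble_draws(ens2), id_trace, 0)
    if (!length(d1) || !length(d2)) stop("empty bootstrap ensemble")
    k <- min(length(d1), length(d2))
    q <- quantile(d1[seq_len(k)] - d2[seq_len(k)],
                  c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    out$lo <- q[1]; out$hi <- q[2]
  }
  out
}

#' Symmetric pairwise table of a comparison statistic
#'
#' Container for a species-by-species matrix of one dissimilarity statistic
#' (`delta`, `theta`, `twoK`, or `patristic`) with optional per-cell CI
#' bounds.
#'
#' @param point symmetric numeric matrix with species dimnames.
#' @param statistic statistic tag.
#' @param lo,hi optional matrices of CI bounds.
#' @return object of class `pairwise_table`.
#' @export
pairwise_table <- function(point, statistic, lo = NULL, hi = NULL) {
  if (is.null(dimnames(point)) || is.null(rownames(point)))
    stop("point matrix must carry species dimnames")
  if (max(abs(point - t(point))) > 1e-8) stop("point matrix must be symmetric")
  structure(list(statistic = statistic, labels = rownames(point),
                 point = point, lo = lo, hi = hi),
            class = "pairwise_table")
}

#' @export
print.pairwise_table <- function(x, digits = 3, ...) {
  cat("Pairwise", x$statistic, "table over", length(x$labels), "species\n")
  m <- format(round(x$point, digits))
  if (!is.null(x$lo))
    m[] <- paste0(m, " (", format(round(x$lo, digits)), ", ",
                  format(round(x$hi, digits)), ")")
  m[upper.tri(m, diag = TRUE)] <- ""
  print(m[-1, -ncol(m), drop = FALSE], quote = FALSE)
  invisible(x)
}

#' Tidy long format of a pairwise table
#'
#' @param x a [pairwise_table].
#' @param row.names,optional,... ignored; present for the generic.
#' @return data.frame with one row per unordered species pair: `species_a`,
#'   `species_b`, `stat`, `point`, and `lo`/`hi` when CIs are present.
#' @export
as.data.frame.pairwise_table <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  lab <- x$labels
  idx <- which(lower.tri(x$point), arr.ind = TRUE)
  out <- data.frame(species_a = lab[idx[, 1]], species_b = lab[idx[, 2]],
                    stat = x$statistic, point = x$point[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(x$lo)) { out$lo <- x$lo[idx]; out$hi <- x$hi[idx] }
  out
}

# Look up the (a, b) cell of a long-format pairwise data frame irrespective
# of the order the pair is stored in.
pair_lookup <- function(df, a, b, column = "point") {
  hit <- (df$species_a == a & df$species_b == b) |
         (df$species_a == b & df$species_b == a)
  if (!any(hit)) stop("pair not found: ", a, " / ", b)
  df[[column]][hit][1]
}

#' Pairwise comparison table over a set of species ID matrices
#'
#' Computes one dissimilarity statistic for every unordered species pair:
#' `delta` (absolute trace difference), `theta` (angle between leading
#' eigenvectors, degrees), or `twoK` (`x - K`, the Krzanowski subspace
#' dissimilarity over the leading `x` eigenvectors). When bootstrap ensembles
#' are supplied, approximate CIs are attached from the 2.5/97.5 percentiles of
#' the statistic over paired independent draws; bootstrap draws are matched by
#' eigenvalue rank (the leading vector of each draw is whichever has the
#' largest eigenvalue in that draw).
#'
#' @param ids named list of ID matrices (or `id_fit` objects).
#' @param statistic one of "delta", "theta", "twoK".
#' @param ensembles optional named list of [parametric_bootstrap] ensembles
#'   matching `ids`.
#' @param x subspace dimension for `twoK`.
#' @param conf confidence level.
#' @return a [pairwise_table].
#' @export
pairwise_id_table <- function(ids, statistic = c("delta", "theta", "twoK"),
                              ensembles = NULL, x = 2, conf = 0.95) {
  statistic <- match.arg(statistic)
  ids <- lapply(ids, function(f) if (inherits(f, "id_fit")) f$ID else f)
  if (length(ids) < 2) stop("at least two species are required")
  if (is.null(names(ids))) stop("ids must be a named list")
  lab <- names(ids)
  ns <- length(lab)
  point <- matrix(0, ns, ns, dimnames = list(lab, lab))
  lo <- hi <- if (is.null(ensembles)) NULL else point
  draw_stats <- NULL
  if (!is.null(ensembles)) {
    if (!all(lab %in% names(ensembles)))
      stop("missing ensemble for: ",
           paste(setdiff(lab, names(ensembles)), collapse = ", "))
    ensembles <- ensembles[lab]
  }
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    point[i, j] <- point[j, i] <- id_statistic(ids[[i]], ids[[j]], statistic, x)
    if (!is.null(ensembles)) {
      di <- ensemble_draws(ensembles[[i]])
      dj <- ensemble_draws(ensembles[[j]])
      if (!length(di) || !length(dj))
        stop("empty bootstrap ensemble for pair ", lab[i], " / ", lab[j])
      k <- min(length(di), length(dj))
      s <- if (statistic == "delta") {
        vapply(seq_len(k), function(d) id_trace(di[[d]]) - id_trace(dj[[d]]), 0)
      } else {
        vapply(seq_len(k), function(d)
          id_statistic(di[[d]], dj[[d]], statistic, x), 0)
      }
      q <- quantile(s, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
      lo[i, j] <- lo[j, i] <- q[1]
      hi[i, j] <- hi[j, i] <- q[2]
    }
  }
  pairwise_table(point, statistic, lo = lo, hi = hi)
}

#' Convert a similarity table to the matching dissimilarity
#'
#' Entrywise `x - K`, turning the Krzanowski similarity K into the
#' dissimilarity used alongside delta and theta (all three then increase with
#' dissimilarity, so a positive rank correlation with phylogenetic distance is
#' the uniform prediction under phylogenetic signal). Applying the transform
#' twice returns the original table.
#'
#' @param k_table [pairwise_table] of K (statistic tag "K") or of `x - K`
#'   (tag "twoK").
#' @param x subspace dimension.
#' @return [pairwise_table] with the complementary tag.
#' @export
dissimilarity_from_similarity <- function(k_table, x = 2) {
  if (!inherits(k_table, "pairwise_table")) stop("k_table must be a pairwise_table")
  if (!k_table$statistic %in% c("K", "twoK"))
    stop("statistic tag must be 'K' or 'twoK', got '", k_table$statistic, "'")
  out <- x - k_table$point
  # self-dissimilarity is 0, self-similarity is x
  diag(out) <- if (k_table$statistic == "K") 0 else x
  pairwise_table(out, if (k_table$statistic == "K") "twoK" else "K")
}
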