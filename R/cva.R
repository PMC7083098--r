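# Canonical variate analysis of species mean behaviour: ordination of
# within-individual mean trait vectors that sequentially maximizes
# among-group (species) variance relative to pooled within-group variance.

#' Within-individual mean behaviour
#'
#' Collapses a trial table to one row per individual: the mean of each trait
#' over that individual's trials, with its species label.
#'
#' @param table SDU-scale trial table (output `data` of
#'   [global_standardize()]).
#' @param traits trait columns to average.
#' @return data.frame with columns `species`, `fish_id` and one mean per
#'   trait; one row per distinct `fish_id`.
#' @export
individual_means <- function(table, traits = oft_traits()) {
  stopifnot(all(c("species", "fish_id") %in% names(table)),
            all(traits %in% names(table)))
  sp <- tapply(as.character(table$species), table$fish_id,
               function(x) x[1])
  agg <- stats::aggregate(table[traits], by = list(fish_id = table$fish_id),
                          FUN = mean)
  out <- data.frame(species = unname(sp[agg$fish_id]),
                    fish_id = agg$fish_id, agg[traits],
                    stringsAsFactors = FALSE)
  out[order(out$species, out$fish_id), , drop = FALSE]
}

#' Canonical variate analysis across pre-specified groups
#'
#' Solves the between-group versus pooled-within-group generalized
#' eigenproblem: axis k maximizes among-group variance subject to
#' within-group-metric orthogonality to axes 1..k-1. Group means enter the
#' between-group scatter unweighted by group size. Canonical scores are
#' scaled so the pooled within-group covariance of the scores is the
#' identity (the sphering property); at most `min(traits, groups - 1)` axes
#' are returned.
#'
#' @param means matrix or data.frame of per-individual trait means (rows =
#'   individuals).
#' @param labels group (species) label per row.
#' @return object of class `cva_result`: list with `coefficients` (traits x
#'   axes), `eigenvalues`, `percent` (of among-group variance per axis),
#'   `scores` (data.frame with species labels), and `group_means` (on the
#'   canonical axes).
#' @export
cva_fit <- function(means, labels) {
  X <- as.matrix(means)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("labels must match rows of means")
  groups <- split(seq_len(nrow(X)), labels)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 members")
  p <- ncol(X)
  g <- length(groups)
  # pooled within-group scatter
  Sw <- matrix(0, p, p)
  gm <- matrix(0, g, p, dimnames = list(names(groups), colnames(X)))
  for (k in seq_len(g)) {
    Xi <- X[groups[[k]], , drop = FALSE]
    gm[k, ] <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, gm[k, ]))
  }
  W <- Sw / (nrow(X) - g)
  U <- tryCatch(chol(W), error = function(e)
    stop("pooled within-group covariance is singular; ",
         "consider removing a trait"))
  # unweighted between-group covariance of the group means
  B <- cov(gm)
  # whiten by W and solve the symmetric eigenproblem
  Bw <- t(backsolve(U, t(backsolve(U, B, transpose = TRUE)), transpose = TRUE))
  e <- eigen((Bw + t(Bw)) / 2, symmetric = TRUE)
  k <- min(p, g - 1)
  vals <- pmax(e$values[seq_len(k)], 0)
  A <- backsolve(U, e$vectors[, seq_len(k), drop = FALSE])
  rownames(A) <- colnames(X)
  colnames(A) <- paste0("CV", seq_len(k))
  center <- colMeans(X)
  scores <- sweep(X, 2, center) %*% A
  structure(list(coefficients = A, eigenvalues = vals,
                 percent = 100 * vals / sum(vals),
                 scores = data.frame(species = labels, scores,
                                     stringsAsFactors = FALSE),
                 group_means = sweep(gm, 2, center) %*% A,
                 center = center),
            class = "cva_result")
}

#' @export
print.cva_result <- function(x, digits = 3, ...) {
  cat("Canonical variate analysis:", ncol(x$coefficients), "axes\n")
  cat("Percent of among-group variance:",
      paste0(round(x$percent, 1), "%", collapse = ", "), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Confidence ellipse of a 2-D score cloud
#'
#' Ellipse describing the distribution of points (not the standard error of
#' their mean): the contour of the fitted bivariate Gaussian containing the
#' requested probability mass, with squared radii equal to the covariance
#' eigenvalues scaled by the chi-square(2) quantile.
#'
#' @param scores matrix or data.frame with two numeric columns (>= 3 rows).
#' @param level coverage probability; `level = 0` degenerates to the center
#'   point.
#' @return list with `center`, `radii` (semi-axes, descending), `angle`
#'   (radians, orientation of the major axis), `level`.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  S <- as.matrix(scores)
  if (ncol(S) != 2) stop("scores must have exactly 2 columns")
  if (nrow(S) < 3) stop("need at least 3 points")
  V <- cov(S)
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) <= 0) stop("degenerate score covariance")
  r2 <- qchisq(level, df = 2)
  list(center = colMeans(S),
       radii = sqrt(e$values * r2),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       level = level)
}
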