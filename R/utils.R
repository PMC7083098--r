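`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded calls do not perturb the global random stream.
#' With `seed = NULL` the expression uses (and advances) the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive n reproducible sub-seeds (< 2^31) from one top-level seed. Every
# random stage of the pipeline draws its own sub-seed from this stream, so a
# single integer determines the whole analysis.
make_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Symmetry/definiteness validation used on user-supplied covariance matrices.
check_cov_matrix <- function(M, name, strict = FALSE, dim = NULL, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(name, " must be a square matrix", call. = FALSE)
  if (!is.null(dim) && nrow(M) != dim)
    stop(name, " must be ", dim, "x", dim, call. = FALSE)
  if (max(abs(M - t(M))) > tol)
    stop(name, " must be symmetric", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lim <- if (strict) tol else -tol
  if (min(ev) < lim * max(1, max(abs(ev))))
    stop(name, " must be positive ", if (strict) "definite" else "semi-definite",
         call. = FALSE)
  invisible(TRUE)
}

# Symmetric matrix square root with negative eigenvalues clipped at zero
# (used to draw from possibly singular among-individual covariances).
mat_sqrt_psd <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Observed open-field-trial traits
#'
#' The four behaviours scored in an open field trial, in their fixed analysis
#' order: tracklength (`TL`, body lengths after size scaling), activity
#' (`Act`, percent time moving), area covered (`AC`, percent of arena), and
#' time in the middle zone (`TIM`, square-root seconds).
#'
#' @return character vector of the four trait labels.
#' @export
oft_traits <- function() c("TL", "Act", "AC", "TIM")
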