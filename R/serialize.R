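# Plain-text serialization of fitted objects: fits as JSON (matrices
# row-major with trait-label headers), bootstrap ensembles as a compact
# one-matrix-per-row delimited file, signal results as JSON.

#' Write / read a multivariate fit as JSON
#'
#' Stores the estimated matrices, fixed effects, log-likelihood and fit
#' metadata; the model data needed for bootstrapping is not serialized, so a
#' re-read fit supports comparison but not refitting.
#'
#' @param fit an `id_fit`.
#' @param path file path.
#' @return `read_fit_json` returns a list with the stored elements.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "id_fit"))
  obj <- list(traits = fit$traits,
              ID = unclass(fit$ID), R = unclass(fit$R),
              beta = unclass(fit$beta), cov_names = colnames(fit$beta),
              reml_loglik = fit$reml_loglik, converged = fit$converged,
              n_individuals = fit$n_individuals, n_obs = fit$n_obs,
              constrain_diagonal = fit$constrain_diagonal)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (m in c("ID", "R")) {
    obj[[m]] <- as.matrix(obj[[m]])
    dimnames(obj[[m]]) <- list(obj$traits, obj$traits)
  }
  obj$beta <- matrix(unlist(obj$beta), nrow = length(obj$traits),
                     dimnames = list(obj$traits, obj$cov_names))
  obj
}

#' Write / read a bootstrap ensemble as delimited text
#'
#' One draw per row, the q x q matrix stored row-major.
#'
#' @param ens an `id_ensemble` (or plain list of matrices).
#' @param path file path.
#' @param traits trait labels used when reading back.
#' @return `read_ensemble` returns an `id_ensemble`.
#' @export
write_ensemble <- function(ens, path) {
  draws <- ensemble_draws(ens)
  if (!length(draws)) stop("empty bootstrap ensemble")
  m <- t(vapply(draws, function(d) as.numeric(t(d)),
                numeric(length(draws[[1]]))))
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path, traits = oft_traits()) {
  m <- as.matrix(utils::read.table(path))
  q <- sqrt(ncol(m))
  draws <- lapply(seq_len(nrow(m)), function(i) {
    d <- matrix(m[i, ], q, q, byrow = TRUE,
                dimnames = list(traits, traits))
    (d + t(d)) / 2
  })
  structure(list(draws = draws, n_draws = length(draws), failed = 0L,
                 seed = NULL, method = "file"), class = "id_ensemble")
}

#' Write a phylogenetic-signal result as JSON
#'
#' @param x a `signal_result`.
#' @param path file path.
#' @param include_boot store the full bootstrap tau vector?
#' @return the path, invisibly.
#' @export
write_signal_json <- function(x, path, include_boot = TRUE) {
  stopifnot(inherits(x, "signal_result"))
  obj <- list(statistic = x$statistic, tau = x$tau,
              ci = as.numeric(x$ci), n_reps = x$n_reps, failed = x$failed,
              seed = x$seed)
  if (include_boot) obj$boot <- as.numeric(x$boot)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
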