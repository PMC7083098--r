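# Multi-response random-intercept mixed models by REML.
#
# Model: for individual i, trial j, the q-vector of traits
#   y_ij = X_ij beta + u_i + e_ij,  u_i ~ N(0, ID),  e_ij ~ N(0, R),
# with fixed effects (per trait) of cumulative trial number ("repeat", a
# factor) and within-group testing order (a linear covariate). ID is the
# among-individual covariance matrix -- the target of the analysis -- and R
# the unstructured within-trial residual covariance.
#
# Both covariance matrices are parameterized through Cholesky factors with
# log diagonals, so estimates are symmetric positive (semi-)definite by
# construction and boundary solutions (variances -> 0) are admitted as the
# log-diagonal runs to its lower bound. The restricted likelihood is profiled
# over beta and maximized by L-BFGS-B; individuals sharing a design are
# grouped so each likelihood evaluation factorizes one marginal covariance
# per design class (see src/reml.cpp).

# ---- Cholesky parameterization -------------------------------------------

.lt_idx <- function(q) which(lower.tri(matrix(0, q, q), diag = TRUE))

# position of diagonal elements within the column-major lower-triangle vector
.diag_pos <- function(q) {
  lens <- q:1
  c(0, cumsum(lens)[-q]) + 1
}

.par_to_chol <- function(par, q) {
  L <- matrix(0, q, q)
  L[.lt_idx(q)] <- par
  diag(L) <- exp(diag(L))
  L
}

.par_to_cov <- function(par, q) tcrossprod(.par_to_chol(par, q))

# inverse map, clipping eigenvalues so a boundary or indefinite moment
# estimate still yields a usable starting point
.cov_to_par <- function(M, q, min_eig = 1e-4) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, min_eig * max(1, max(abs(e$values))))
  L <- t(chol(e$vectors %*% (vals * t(e$vectors))))
  par <- L[.lt_idx(q)]
  par[.diag_pos(q)] <- log(diag(L))
  par
}

# ---- model data -----------------------------------------------------------

# Assemble the grouped-design representation of a trial table: individuals
# sharing the same per-trial fixed-effect rows form one class, with their
# stacked observation vectors as columns of a single matrix.
build_model_data <- function(table, traits,
                             fixed_effects = c("repeat", "order")) {
  miss <- setdiff(traits, names(table))
  if (length(miss)) stop("missing trait column(s): ",
                         paste(miss, collapse = ", "))
  if (!"fish_id" %in% names(table)) stop("table must have a fish_id column")
  fixed_effects <- fixed_effects %||% character()
  rep_col <- table[["repeat"]]
  o <- order(table$fish_id, rep_col %||% seq_len(nrow(table)))
  table <- table[o, , drop = FALSE]
  rep_col <- table[["repeat"]]
  Y <- as.matrix(table[traits])
  if (any(!is.finite(Y))) stop("trial table has missing trait cells")
  q <- length(traits)
  n <- nrow(table)
  Xt <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if ("repeat" %in% fixed_effects) {
    if (is.null(rep_col)) stop("no 'repeat' column in table")
    f <- factor(rep_col)
    if (nlevels(f) < 2)
      stop("design error: fewer than 2 repeat levels")
    mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- paste0("repeat", levels(f)[-1])
    Xt <- cbind(Xt, mm)
  }
  if ("order" %in% fixed_effects) {
    if (is.null(table$order_in_group)) stop("no 'order_in_group' column")
    Xt <- cbind(Xt, order = as.numeric(table$order_in_group))
  }
  qrX <- qr(Xt)
  if (qrX$rank < ncol(Xt))
    Xt <- Xt[, sort(qrX$pivot[seq_len(qrX$rank)]), drop = FALSE]
  idx <- split(seq_len(n), factor(table$fish_id, levels = unique(table$fish_id)))
  if (all(lengths(idx) < 2))
    stop("design error: no individual has repeated trials")
  keys <- vapply(idx, function(ii)
    paste(c(length(ii), sprintf("%.8g", Xt[ii, ])), collapse = ","), "")
  classes <- split(seq_along(idx), keys)
  Xs <- vector("list", length(classes))
  Ys <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    members <- classes[[ci]]
    ii0 <- idx[[members[1]]]
    Xs[[ci]] <- kronecker(Xt[ii0, , drop = FALSE], diag(q))
    Ys[[ci]] <- vapply(members, function(mm)
      as.vector(t(Y[idx[[mm]], , drop = FALSE])),
      numeric(length(ii0) * q))
    if (!is.matrix(Ys[[ci]])) Ys[[ci]] <- matrix(Ys[[ci]], ncol = 1)
  }
  list(q = q, traits = traits, cov_names = colnames(Xt),
       Xs = Xs, Ys = Ys,
       n_individuals = length(idx), n_trials = n,
       y_sum = sum(Y), fixed_effects = fixed_effects)
}

# ---- restricted likelihood ------------------------------------------------

.reml_eval <- function(md, G, R) {
  pc <- reml_pieces(md$Xs, md$Ys, G, R)
  ch <- tryCatch(chol(pc$XtVX), error = function(e) NULL)
  if (is.null(ch)) return(list(nll = Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), pc$XtVy))
  yPy <- pc$yty - sum(pc$XtVy * beta)
  nll <- 0.5 * (pc$logdet + 2 * sum(log(diag(ch))) + yPy +
                  (pc$nobs - length(beta)) * log(2 * pi))
  list(nll = nll, beta = beta)
}

# chain rule from the matrix gradient Gamma (d NLL = 0.5 tr(Gamma dG)) to the
# Cholesky parameters: d NLL / d L_ij = (Gamma L)_ij, with the extra L_jj
# factor on the log-diagonal entries
.chol_grad <- function(Gamma, L) {
  M <- Gamma %*% L
  q <- nrow(L)
  g <- M[.lt_idx(q)]
  dp <- .diag_pos(q)
  g[dp] <- diag(M) * diag(L)
  g
}

# objective + analytic gradient closures for one dataset; the last evaluation
# is cached because optim calls fn and gr separately at the same point
.objective_fns <- function(md, diag_id) {
  q <- md$q
  nG <- if (diag_id) q else q * (q + 1) / 2
  nR <- q * (q + 1) / 2
  cache_par <- NULL
  cache <- NULL
  eval_at <- function(par) {
    if (!is.null(cache_par) && identical(par, cache_par)) return(cache)
    if (diag_id) {
      G <- diag(exp(2 * par[seq_len(nG)]), q)
      Lg <- NULL
    } else {
      Lg <- .par_to_chol(par[seq_len(nG)], q)
      G <- tcrossprod(Lg)
    }
    Lr <- .par_to_chol(par[nG + seq_len(nR)], q)
    R <- tcrossprod(Lr)
    r <- tryCatch(reml_nll_grad(md$Xs, md$Ys, G, R),
                  error = function(e) list(ok = FALSE))
    res <- if (!isTRUE(r$ok) || !is.finite(r$nll)) {
      list(value = 1e10, grad = rep(0, length(par)))
    } else {
      gG <- if (diag_id) diag(r$GammaG) * diag(G)
            else .chol_grad(r$GammaG, Lg)
      list(value = r$nll, grad = c(gG, .chol_grad(r$GammaR, Lr)))
    }
    cache_par <<- par
    cache <<- res
    res
  }
  list(fn = function(par) eval_at(par)$value,
       gr = function(par) eval_at(par)$grad)
}

# moment starting values from individual means (between) and within-individual
# deviations
.moment_start <- function(md) {
  q <- md$q
  mu_list <- list()
  Sw <- matrix(0, q, q)
  dfw <- 0
  ks <- numeric(0)
  for (ci in seq_along(md$Ys)) {
    Yc <- md$Ys[[ci]]
    n_i <- nrow(Yc) / q
    for (j in seq_len(ncol(Yc))) {
      Yi <- t(matrix(Yc[, j], q))
      mu_list[[length(mu_list) + 1]] <- colMeans(Yi)
      if (n_i > 1) {
        dev <- sweep(Yi, 2, colMeans(Yi))
        Sw <- Sw + crossprod(dev)
        dfw <- dfw + n_i - 1
      }
      ks <- c(ks, n_i)
    }
  }
  M <- do.call(rbind, mu_list)
  if (nrow(M) < 2) stop("need at least 2 individuals")
  W <- if (dfw > 0) Sw / dfw else diag(q)
  G0 <- cov(M) - W / mean(ks)
  list(G = G0, R = W)
}

# L-BFGS-B occasionally aborts its line search (code 52) at a point whose
# gradient is already at machine precision; a restart is attempted, and the
# terminal point counts as converged when the (projected) gradient max-norm
# is below gtol, mirroring the usual gradient-based convergence criterion.
.optim_restarts <- function(par0, obj, lower, upper, ctl, tries = 3L,
                            gtol = 1e-6) {
  opt <- optim(par0, obj$fn, gr = obj$gr, method = "L-BFGS-B",
               lower = lower, upper = upper, control = ctl)
  while (opt$convergence != 0 && tries > 1L) {
    tries <- tries - 1L
    opt2 <- optim(opt$par, obj$fn, gr = obj$gr, method = "L-BFGS-B",
                  lower = lower, upper = upper, control = ctl)
    if (opt2$value <= opt$value) opt <- opt2 else break
  }
  g <- obj$gr(opt$par)
  # project out components pressing against an active bound
  g[(abs(opt$par - lower) < 1e-10 & g > 0) |
    (abs(opt$par - upper) < 1e-10 & g < 0)] <- 0
  opt$converged <- opt$convergence == 0 || max(abs(g)) < gtol
  opt
}

.fit_reml <- function(md, diag_id = FALSE, start = NULL, control = list()) {
  q <- md$q
  st <- start %||% .moment_start(md)
  parG <- if (diag_id) 0.5 * log(pmax(diag(as.matrix(st$G)), 1e-6))
          else .cov_to_par(st$G, q)
  parR <- .cov_to_par(st$R, q)
  par0 <- c(parG, parR)
  obj <- .objective_fns(md, diag_id)
  nG <- length(parG)
  lower <- rep(-Inf, length(par0))
  upper <- rep(Inf, length(par0))
  gpos <- if (diag_id) seq_len(nG) else .diag_pos(q)
  rpos <- nG + .diag_pos(q)
  lower[gpos] <- -8   # among-individual SD floor ~ exp(-8)
  lower[rpos] <- -7   # residual SD floor (R must stay positive definite)
  upper[c(gpos, rpos)] <- 8
  ctl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)
  opt <- .optim_restarts(par0, obj, lower, upper, ctl)
  G <- if (diag_id) diag(exp(2 * opt$par[seq_len(nG)]), q)
       else .par_to_cov(opt$par[seq_len(nG)], q)
  R <- .par_to_cov(opt$par[nG + seq_len(q * (q + 1) / 2)], q)
  ev <- .reml_eval(md, G, R)
  dimnames(G) <- dimnames(R) <- list(md$traits, md$traits)
  beta <- matrix(ev$beta, nrow = q,
                 dimnames = list(md$traits, md$cov_names))
  list(G = G, R = R, beta = beta, beta_vec = ev$beta,
       loglik = -ev$nll, converged = opt$converged,
       par = opt$par, opt = opt)
}

# ---- user-facing fits -----------------------------------------------------

#' Fit the multivariate among-individual covariance model
#'
#' REML fit of the multi-response random-intercept model, returning the
#' among-individual covariance matrix `ID` and the unstructured residual
#' covariance `R`, both symmetric and positive (semi-)definite by
#' parameterization. With `constrain_diagonal = TRUE` all covariance terms of
#' `ID` are fixed at zero (the reduced model of the 6-df covariance LRT);
#' `R` remains unstructured in both models.
#'
#' @param table trial table on the analysis (SDU) scale with columns
#'   `fish_id`, `repeat`, `order_in_group` and the trait columns.
#' @param traits trait columns to model (default the four OFT traits; a
#'   single trait reduces to the univariate model).
#' @param constrain_diagonal fix all ID covariances at zero?
#' @param fixed_effects any of `"repeat"` (factor of cumulative trial number)
#'   and `"order"` (linear within-group order); `NULL` fits intercepts only.
#' @param start optional list with starting `G` and `R` matrices.
#' @param control passed to [stats::optim()] (`L-BFGS-B`).
#' @return object of class `id_fit` with elements `ID`, `R`, `beta`
#'   (traits x covariates), `reml_loglik`, `converged`, `n_individuals`,
#'   `n_obs`. Non-convergence is warned about, never silent.
#' @export
fit_multivariate <- function(table, traits = oft_traits(),
                             constrain_diagonal = FALSE,
                             fixed_effects = c("repeat", "order"),
                             start = NULL, control = list()) {
  md <- build_model_data(table, traits, fixed_effects)
  fr <- .fit_reml(md, diag_id = constrain_diagonal, start = start,
                  control = control)
  if (!fr$converged)
    warning("REML fit did not converge; best-found estimates returned")
  structure(list(ID = fr$G, R = fr$R, beta = fr$beta,
                 reml_loglik = fr$loglik, converged = fr$converged,
                 n_individuals = md$n_individuals, n_obs = md$n_trials,
                 traits = traits, constrain_diagonal = constrain_diagonal,
                 fixed_effects = md$fixed_effects,
                 model_data = md, opt_par = fr$par, beta_vec = fr$beta_vec),
            class = "id_fit")
}

#' @export
print.id_fit <- function(x, digits = 4, ...) {
  cat("Multivariate random-intercept REML fit (",
      x$n_individuals, " individuals, ", x$n_obs, " trials)\n", sep = "")
  cat("REML log-likelihood:", format(x$reml_loglik, digits = 8),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  cat("Among-individual covariance (ID):\n")
  print(round(x$ID, digits))
  cat("Residual covariance (R):\n")
  print(round(x$R, digits))
  invisible(x)
}

#' Fit a univariate repeatability model
#'
#' REML fit of the Gaussian random-intercept model for one trait, giving the
#' among-individual variance `V_I` and residual variance `V_R`. The
#' log-likelihood of the matching model without the individual random effect
#' is included (`loglik_null`) for the boundary-corrected likelihood ratio
#' test of `V_I` (see [lrt_mixture_p()]).
#'
#' @inheritParams fit_multivariate
#' @param trait the trait column to model.
#' @return object of class `uni_fit`.
#' @export
fit_univariate <- function(table, trait, fixed_effects = c("repeat", "order"),
                           control = list()) {
  stopifnot(length(trait) == 1)
  fit <- fit_multivariate(table, traits = trait,
                          fixed_effects = fixed_effects, control = control)
  structure(list(V_I = fit$ID[1, 1], V_R = fit$R[1, 1], beta = fit$beta,
                 reml_loglik = fit$reml_loglik,
                 loglik_null = .reml_null_loglik(fit$model_data),
                 converged = fit$converged,
                 n_individuals = fit$n_individuals, n_obs = fit$n_obs,
                 trait = trait, fit = fit),
            class = "uni_fit")
}

#' @export
print.uni_fit <- function(x, digits = 4, ...) {
  cat("Univariate repeatability model for", x$trait, "\n")
  cat("  V_I =", round(x$V_I, digits), " V_R =", round(x$V_R, digits),
      " repeatability =", round(repeatability(x), digits), "\n")
  invisible(x)
}

# REML log-likelihood of the fixed-effects-only model (no individual random
# effect, iid residual), in closed form.
.reml_null_loglik <- function(md) {
  p <- ncol(md$Xs[[1]])
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  yty <- 0
  N <- 0
  for (ci in seq_along(md$Xs)) {
    X <- md$Xs[[ci]]; Yc <- md$Ys[[ci]]
    XtX <- XtX + ncol(Yc) * crossprod(X)
    Xty <- Xty + crossprod(X, rowSums(Yc))[, 1]
    yty <- yty + sum(Yc^2)
    N <- N + nrow(X) * ncol(Yc)
  }
  ch <- chol(XtX)
  b <- backsolve(ch, forwardsolve(t(ch), Xty))
  rss <- yty - 2 * sum(b * Xty) + sum(b * (XtX %*% b))
  s2 <- rss / (N - p)
  -0.5 * ((N - p) * (log(2 * pi * s2) + 1) + 2 * sum(log(diag(ch))))
}

#' Repeatability (intraclass correlation)
#'
#' Fraction of phenotypic variance due to consistent among-individual
#' differences, `V_I / (V_I + V_R)`, conditional on the fitted fixed effects.
#'
#' @param fit a [fit_univariate()] result (or anything with `V_I`, `V_R`).
#' @return proportion in \[0, 1\].
#' @export
repeatability <- function(fit) {
  if (fit$V_I + fit$V_R <= 0) stop("total variance must be positive")
  fit$V_I / (fit$V_I + fit$V_R)
}

#' Boundary-corrected likelihood ratio test for a single variance component
#'
#' A variance tested against zero lies on the boundary of its parameter
#' space, so the LRT statistic follows a 50:50 mixture of a point mass at
#' zero and a chi-square with 1 df: `p = 0.5 * P(chisq_1 > statistic)`, with
#' `p = 0.5` at statistic 0.
#'
#' @param loglik_full,loglik_reduced REML log-likelihoods of the models with
#'   and without the random effect.
#' @return list with `statistic` (clipped at 0) and `p`.
#' @export
lrt_mixture_p <- function(loglik_full, loglik_reduced) {
  stat <- 2 * (loglik_full - loglik_reduced)
  if (stat < -0.05)
    stop("reduced model has higher likelihood than the full model; ",
         "check convergence")
  stat <- max(stat, 0)
  list(statistic = stat, p = 0.5 * pchisq(stat, df = 1, lower.tail = FALSE))
}

.check_same_data <- function(a, b) {
  if (!identical(a$traits, b$traits) ||
      a$n_obs != b$n_obs || a$n_individuals != b$n_individuals ||
      abs(a$model_data$y_sum - b$model_data$y_sum) > 1e-6)
    stop("fits are not based on the same data")
  invisible(TRUE)
}

#' LRT for among-trait covariance structure in ID
#'
#' Compares the full model (unstructured ID) to the reduced model with all ID
#' covariances fixed at zero; for q traits the test has q(q-1)/2 degrees of
#' freedom (6 for the four OFT traits).
#'
#' @param full unconstrained [fit_multivariate()] fit.
#' @param diagonal the matching `constrain_diagonal = TRUE` fit on the same
#'   data.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_id_covariances <- function(full, diagonal) {
  if (full$constrain_diagonal || !diagonal$constrain_diagonal)
    stop("expected an unconstrained fit and a diagonal-ID fit")
  .check_same_data(full, diagonal)
  q <- length(full$traits)
  stat <- max(0, 2 * (full$reml_loglik - diagonal$reml_loglik))
  df <- q * (q - 1) / 2
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Cross-species blocked model for a pair of species
#'
#' Fits the eight-trait model in which the two species' four-trait blocks
#' share no individuals, so the cross-species blocks of the joint
#' among-individual matrix are structurally zero and the restricted
#' likelihood separates into the two species' contributions. Unconstrained,
#' the fit therefore equals the two separate species fits; with
#' `constrain_equal = TRUE` the two ID blocks are forced to a single shared
#' matrix (10 shared parameters for 4 traits) while each species keeps its
#' own residual covariance, giving the 10-df equality LRT via
#' [lrt_id_equality()].
#'
#' @param table_s1,table_s2 SDU-scale trial tables for the two species; fish
#'   ids must not overlap.
#' @inheritParams fit_multivariate
#' @param constrain_equal impose ID_s1 = ID_s2?
#' @return object of class `pair_fit` with per-species `ID1`/`ID2` (equal
#'   when constrained), residuals `R1`/`R2`, the blocked 2q x 2q `ID_blocked`
#'   and the joint `reml_loglik`.
#' @export
fit_pair_blocked <- function(table_s1, table_s2, traits = oft_traits(),
                             constrain_equal = FALSE,
                             fixed_effects = c("repeat", "order"),
                             control = list()) {
  shared <- intersect(unique(table_s1$fish_id), unique(table_s2$fish_id))
  if (length(shared))
    stop("individuals appear in both species: ",
         paste(utils::head(shared, 3), collapse = ", "))
  q <- length(traits)
  md1 <- build_model_data(table_s1, traits, fixed_effects)
  md2 <- build_model_data(table_s2, traits, fixed_effects)
  if (!constrain_equal) {
    f1 <- .fit_reml(md1, control = control)
    f2 <- .fit_reml(md2, control = control)
    ID1 <- f1$G; ID2 <- f2$G; R1 <- f1$R; R2 <- f2$R
    ll <- f1$loglik + f2$loglik
    conv <- f1$converged && f2$converged
  } else {
    st1 <- .moment_start(md1); st2 <- .moment_start(md2)
    nC <- q * (q + 1) / 2
    par0 <- c(.cov_to_par((st1$G + st2$G) / 2, q),
              .cov_to_par(st1$R, q), .cov_to_par(st2$R, q))
    obj <- .pair_objective_fns(md1, md2, q)
    lower <- rep(-Inf, 3 * nC); upper <- rep(Inf, 3 * nC)
    dp <- .diag_pos(q)
    lower[dp] <- -8; lower[c(nC + dp, 2 * nC + dp)] <- -7
    upper[c(dp, nC + dp, 2 * nC + dp)] <- 8
    ctl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)
    opt <- .optim_restarts(par0, obj, lower, upper, ctl)
    ID1 <- ID2 <- .par_to_cov(opt$par[seq_len(nC)], q)
    R1 <- .par_to_cov(opt$par[nC + seq_len(nC)], q)
    R2 <- .par_to_cov(opt$par[2 * nC + seq_len(nC)], q)
    dimnames(ID1) <- dimnames(ID2) <- dimnames(R1) <- dimnames(R2) <-
      list(traits, traits)
    ll <- -obj$fn(opt$par)
    conv <- opt$converged
  }
  if (!conv)
    warning("pair model did not converge; best-found estimates returned")
  blocked <- matrix(0, 2 * q, 2 * q)
  blocked[seq_len(q), seq_len(q)] <- ID1
  blocked[q + seq_len(q), q + seq_len(q)] <- ID2
  structure(list(ID1 = ID1, ID2 = ID2, R1 = R1, R2 = R2,
                 ID_blocked = blocked, reml_loglik = ll,
                 constrained = constrain_equal, converged = conv,
                 traits = traits,
                 n_obs = md1$n_trials + md2$n_trials),
            class = "pair_fit")
}

# objective + gradient for the shared-ID pair model: one Cholesky block for
# the common G, one residual block per species; the two species' restricted
# likelihoods (and their matrix gradients) simply add
.pair_objective_fns <- function(md1, md2, q) {
  nC <- q * (q + 1) / 2
  cache_par <- NULL
  cache <- NULL
  eval_at <- function(par) {
    if (!is.null(cache_par) && identical(par, cache_par)) return(cache)
    Lg <- .par_to_chol(par[seq_len(nC)], q)
    Lr1 <- .par_to_chol(par[nC + seq_len(nC)], q)
    Lr2 <- .par_to_chol(par[2 * nC + seq_len(nC)], q)
    G <- tcrossprod(Lg)
    r1 <- tryCatch(reml_nll_grad(md1$Xs, md1$Ys, G, tcrossprod(Lr1)),
                   error = function(e) list(ok = FALSE))
    r2 <- tryCatch(reml_nll_grad(md2$Xs, md2$Ys, G, tcrossprod(Lr2)),
                   error = function(e) list(ok = FALSE))
    res <- if (!isTRUE(r1$ok) || !isTRUE(r2$ok) ||
               !is.finite(r1$nll) || !is.finite(r2$nll)) {
      list(value = 1e10, grad = rep(0, length(par)))
    } else {
      list(value = r1$nll + r2$nll,
           grad = c(.chol_grad(r1$GammaG + r2$GammaG, Lg),
                    .chol_grad(r1$GammaR, Lr1),
                    .chol_grad(r2$GammaR, Lr2)))
    }
    cache_par <<- par
    cache <<- res
    res
  }
  list(fn = function(par) eval_at(par)$value,
       gr = function(par) eval_at(par)$grad)
}

#' LRT for equality of two species' ID matrices
#'
#' Compares the unconstrained blocked pair model to the constrained model
#' with a shared ID; for q traits the constraint removes q(q+1)/2 parameters
#' (10 for the four OFT traits). P values across the 21 species pairs are
#' nominal: no multiplicity correction is applied (the comparisons are
#' non-independent by design).
#'
#' @param unconstrained,constrained [fit_pair_blocked()] fits on the same
#'   pair of tables.
#' @return list with `statistic`, `df`, `p`.
#' @export
lrt_id_equality <- function(unconstrained, constrained) {
  if (unconstrained$constrained || !constrained$constrained)
    stop("expected an unconstrained and a constrained pair fit")
  if (unconstrained$n_obs != constrained$n_obs)
    stop("fits are not based on the same data")
  q <- length(unconstrained$traits)
  stat <- max(0, 2 * (unconstrained$reml_loglik - constrained$reml_loglik))
  df <- q * (q + 1) / 2
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

# ---- parametric bootstrap -------------------------------------------------

# Simulate one replicate of the stacked observation matrices from a fitted
# model on its own design (same individuals, trials and fixed effects).
.simulate_ys <- function(fit) {
  md <- fit$model_data
  q <- md$q
  Lg <- mat_sqrt_psd(fit$ID)
  Lr <- t(chol(fit$R))
  lapply(seq_along(md$Xs), function(ci) {
    X <- md$Xs[[ci]]
    nc <- ncol(md$Ys[[ci]])
    m <- nrow(X)
    n_i <- m / q
    mu <- as.numeric(X %*% fit$beta_vec)
    U <- Lg %*% matrix(rnorm(q * nc), q, nc)
    E <- matrix(rnorm(m * nc), m, nc)
    for (a in seq_len(n_i)) {
      rows <- (a - 1) * q + seq_len(q)
      E[rows, ] <- Lr %*% E[rows, , drop = FALSE]
    }
    mu + U[rep(seq_len(q), n_i), , drop = FALSE] + E
  })
}

#' Parametric bootstrap of an ID matrix estimate
#'
#' Simulates `n_draws` full datasets from the fitted model on the original
#' design and refits each one (warm-started at the point estimates), storing
#' the refitted ID matrices. This is a simulate-then-refit bootstrap, not a
#' normal approximation on the parameters; draws whose refit fails are
#' excluded and counted in `failed`.
#'
#' @param fit a converged [fit_multivariate()] fit.
#' @param n_draws number of bootstrap draws (5000 at publication scale; the
#'   desk-scale default is 200).
#' @param seed optional integer seed; the same seed reproduces the ensemble.
#' @param control optimizer control for the refits.
#' @return object of class `id_ensemble`: list with `draws` (list of
#'   symmetric PSD matrices), `n_draws`, `failed`, `seed`, `method`.
#' @export
parametric_bootstrap <- function(fit, n_draws = 200, seed = NULL,
                                 control = list(maxit = 200L)) {
  if (!inherits(fit, "id_fit")) stop("fit must be an id_fit")
  if (!fit$converged)
    warning("bootstrapping a non-converged fit")
  md <- fit$model_data
  start <- list(G = fit$ID, R = fit$R)
  draws <- vector("list", n_draws)
  failed <- 0L
  with_seed(seed, {
    for (d in seq_len(n_draws)) {
      md2 <- md
      md2$Ys <- .simulate_ys(fit)
      fr <- tryCatch(
        .fit_reml(md2, diag_id = fit$constrain_diagonal, start = start,
                  control = control),
        error = function(e) NULL)
      if (is.null(fr)) failed <- failed + 1L
      else draws[[d]] <- fr$G
    }
  })
  draws <- draws[!vapply(draws, is.null, TRUE)]
  structure(list(draws = draws, n_draws = n_draws, failed = failed,
                 seed = seed, method = "parametric"),
            class = "id_ensemble")
}

#' Extract the matrix draws from a bootstrap ensemble
#'
#' @param ens an `id_ensemble`, or a plain list of matrices (accepted so that
#'   externally constructed draw sets can flow through the comparison
#'   functions).
#' @return list of ID matrix draws.
#' @export
ensemble_draws <- function(ens) {
  if (inherits(ens, "id_ensemble")) return(ens$draws)
  if (is.list(ens)) return(ens)
  stop("not a bootstrap ensemble")
}

#' @export
print.id_ensemble <- function(x, ...) {
  cat("Parametric bootstrap ensemble:", length(x$draws), "draws",
      if (x$failed > 0) paste0("(", x$failed, " failed refits excluded)"),
      "\n")
  invisible(x)
}
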