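test_that("balanced univariate REML matches the one-way ANOVA closed form", {
  sp <- spec4(80, 4, test_id(), test_resid())
  d <- sim_sdu(sp, seed = 41)
  for (tr in c("TL", "TIM")) {
    uf <- fit_univariate(d, tr, fixed_effects = NULL)
    y <- d[[tr]]
    means <- tapply(y, d$fish_id, mean)
    k <- 4
    msa <- k * var(means)
    mse <- sum((y - means[d$fish_id])^2) / (length(y) - length(means))
    expect_equal(uf$V_R, mse, tolerance = 1e-4)
    expect_equal(uf$V_I, max(0, (msa - mse) / k), tolerance = 1e-4)
  }
})

test_that("univariate recovery at moderate size and the boundary cases", {
  ID <- diag(4) * 0.3
  sp <- spec4(500, 5, ID, diag(4) * 0.7)
  d <- sim_sdu(sp, seed = 43)
  uf <- fit_univariate(d, "TL", fixed_effects = NULL)
  r <- repeatability(uf)
  expect_gt(r, 0.25); expect_lt(r, 0.35)

  # all residual variation removed: y is constant within individual
  dd <- d
  for (tr in oft_traits())
    dd[[tr]] <- ave(dd[[tr]], dd$fish_id)
  uf2 <- fit_univariate(dd, "TL", fixed_effects = NULL)
  expect_gt(repeatability(uf2), 0.999)

  # algebraic properties of the repeatability map
  expect_equal(repeatability(list(V_I = 1, V_R = 1)), 0.5)
  expect_equal(repeatability(list(V_I = 0, V_R = 1)), 0)
  rs <- vapply(seq(0, 2, by = 0.25),
               function(v) repeatability(list(V_I = v, V_R = 0.7)), 0)
  expect_true(all(diff(rs) > 0))
  expect_error(repeatability(list(V_I = 0, V_R = 0)), "positive")
})

test_that("boundary-mixture LRT p-values", {
  expect_equal(lrt_mixture_p(10, 10)$p, 0.5)
  expect_equal(lrt_mixture_p(10 + 2.706 / 2, 10)$p, 0.05, tolerance = 1e-3)
  stats_grid <- seq(0, 8, by = 0.5)
  ps <- vapply(stats_grid, function(s) lrt_mixture_p(s / 2, 0)$p, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(lrt_mixture_p(0, 10), "higher likelihood")
})

test_that("single-trait multivariate call equals the univariate fit", {
  sp <- spec4(60, 3, test_id(), test_resid(),
              repeat_effects = outer(0:2, c(-0.1, 0, 0.05, 0.1)),
              order_slope = c(0.02, 0, -0.01, 0))
  d <- sim_sdu(sp, seed = 47)
  mf <- fit_multivariate(d, traits = "Act")
  uf <- fit_univariate(d, "Act")
  expect_equal(mf$ID[1, 1], uf$V_I, tolerance = 1e-6)
  expect_equal(mf$R[1, 1], uf$V_R, tolerance = 1e-6)
  expect_equal(mf$reml_loglik, uf$reml_loglik, tolerance = 1e-6)
})

test_that("estimates are invariant to row order and monotone under nesting", {
  sp <- spec4(80, 4, test_id(), test_resid(),
              order_slope = c(0.02, -0.01, 0, 0.01))
  d <- sim_sdu(sp, seed = 53)
  fit <- fit_multivariate(d)
  set.seed(1)
  perm <- sample(nrow(d))
  fit_p <- fit_multivariate(d[perm, ])
  expect_equal(fit$ID, fit_p$ID, tolerance = 1e-6)
  expect_equal(fit$reml_loglik, fit_p$reml_loglik, tolerance = 1e-6)

  dfit <- fit_multivariate(d, constrain_diagonal = TRUE)
  expect_gte(fit$reml_loglik, dfit$reml_loglik - 1e-8)
  expect_true(all(dfit$ID[lower.tri(dfit$ID)] == 0))

  # PSD by construction, exactly symmetric
  expect_equal(fit$ID, t(fit$ID))
  expect_gte(min(eigen(fit$ID, symmetric = TRUE)$values), -1e-10)
  expect_gt(min(eigen(fit$R, symmetric = TRUE)$values), 0)

  lrt <- lrt_id_covariances(fit, dfit)
  expect_equal(lrt$df, 6)
  expect_gte(lrt$statistic, 0)
  expect_error(lrt_id_covariances(dfit, fit), "unconstrained")
})

test_that("covariance LRT detects strong among-individual correlation", {
  C <- matrix(0.9, 4, 4); diag(C) <- 1
  sp <- spec4(500, 4, 0.3 * C, diag(4) * 0.7)
  d <- sim_sdu(sp, seed = 59)
  fit <- fit_multivariate(d, fixed_effects = NULL)
  dfit <- fit_multivariate(d, constrain_diagonal = TRUE, fixed_effects = NULL)
  expect_lt(lrt_id_covariances(fit, dfit)$p, 0.001)
})

test_that("blocked pair model separates, detects unequal ID, rejects overlap", {
  sp1 <- spec4(300, 4, test_id(), test_resid(), name = "s1")
  # second species with trace larger by 1 SDU^2
  ID2 <- test_id() + diag(4) * 0.25
  sp2 <- spec4(300, 4, ID2, test_resid(), name = "s2")
  d1 <- sim_sdu(sp1, seed = 61)
  d2 <- sim_sdu(sp2, seed = 62)

  unc <- fit_pair_blocked(d1, d2)
  f1 <- fit_multivariate(d1)
  f2 <- fit_multivariate(d2)
  expect_equal(unc$ID1, f1$ID, tolerance = 1e-5)
  expect_equal(unc$ID2, f2$ID, tolerance = 1e-5)
  expect_equal(unc$reml_loglik, f1$reml_loglik + f2$reml_loglik,
               tolerance = 1e-5)
  expect_equal(unc$ID_blocked[1:4, 5:8], matrix(0, 4, 4))

  con <- fit_pair_blocked(d1, d2, constrain_equal = TRUE)
  expect_equal(con$ID1, con$ID2)
  lrt <- lrt_id_equality(unc, con)
  expect_equal(lrt$df, 10)
  expect_lt(lrt$p, 0.01)

  expect_error(fit_pair_blocked(d1, d1), "both species")
})

test_that("parametric bootstrap is reproducible and centred on the estimate", {
  sp <- spec4(200, 4, test_id(), test_resid())
  d <- sim_sdu(sp, seed = 67)
  fit <- fit_multivariate(d)
  e1 <- parametric_bootstrap(fit, n_draws = 100, seed = 5)
  e2 <- parametric_bootstrap(fit, n_draws = 100, seed = 5)
  expect_identical(e1$draws, e2$draws)
  expect_equal(length(e1$draws) + e1$failed, 100)

  arr <- simplify2array(e1$draws)
  mn <- apply(arr, 1:2, mean)
  se <- apply(arr, 1:2, sd) / sqrt(length(e1$draws))
  expect_true(all(abs(mn - fit$ID) <= 3 * se + 1e-8))
  psd <- vapply(e1$draws, function(m)
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gte(min(psd), -1e-10)
})
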