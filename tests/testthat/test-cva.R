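test_that("individual means collapse trials correctly", {
  sp <- spec4(23, 4, test_id(), test_resid(), name = "a")
  d <- sim_sdu(sp, seed = 101)
  im <- individual_means(d)
  expect_equal(nrow(im), 23)
  # mean of means weighted by trial counts reproduces the grand mean
  expect_equal(colMeans(im[oft_traits()]),
               colMeans(d[oft_traits()]), tolerance = 1e-12)
  # an individual with identical trials keeps its trial vector
  dd <- d[d$fish_id == d$fish_id[1], ]
  dd[oft_traits()] <- rep(as.numeric(dd[1, oft_traits()]), each = nrow(dd))
  d2 <- rbind(dd, d[d$fish_id != d$fish_id[1], ])
  im2 <- individual_means(d2)
  expect_equal(as.numeric(im2[im2$fish_id == d$fish_id[1], oft_traits()]),
               as.numeric(dd[1, oft_traits()]))
})

test_that("CVA recovers one-dimensional group separation", {
  set.seed(103)
  n <- 60
  X <- matrix(rnorm(2 * n * 4), 2 * n, 4)
  X[1:n, 1] <- X[1:n, 1] + 4  # groups differ only along trait 1
  colnames(X) <- oft_traits()
  labels <- rep(c("g1", "g2"), each = n)
  cv <- cva_fit(X, labels)
  a1 <- abs(cv$coefficients[, 1])
  expect_gt(a1[1] / sqrt(sum(a1^2)), 0.9)
  expect_gt(cv$percent[1], 90)
})

test_that("CVA solves the generalized eigenproblem with sphered scores", {
  set.seed(107)
  n <- 40
  X <- matrix(rnorm(3 * n * 4), 3 * n, 4) %*% matrix(rnorm(16, 0, 0.4), 4) +
    matrix(rnorm(3 * n * 4, 0, 1), 3 * n, 4)
  colnames(X) <- oft_traits()
  labels <- rep(c("g1", "g2", "g3"), each = n)
  cv <- cva_fit(X, labels)
  # at most min(traits, groups - 1) axes
  expect_equal(ncol(cv$coefficients), 2)

  # oracle: dense eigensolve of W^-1 B
  groups <- split(seq_len(nrow(X)), labels)
  Sw <- matrix(0, 4, 4)
  gm <- t(sapply(groups, function(ii) colMeans(X[ii, ])))
  for (k in seq_along(groups))
    Sw <- Sw + crossprod(sweep(X[groups[[k]], ], 2, gm[k, ]))
  W <- Sw / (nrow(X) - 3)
  B <- cov(gm)
  ev_oracle <- sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)[1:2]
  expect_equal(cv$eigenvalues, ev_oracle, tolerance = 1e-8)

  # sphering: pooled within-group covariance of the scores is the identity
  S <- as.matrix(cv$scores[c("CV1", "CV2")])
  SwS <- matrix(0, 2, 2)
  for (k in seq_along(groups)) {
    Si <- S[groups[[k]], ]
    SwS <- SwS + crossprod(sweep(Si, 2, colMeans(Si)))
  }
  expect_equal(SwS / (nrow(X) - 3), diag(2), tolerance = 1e-6,
               ignore_attr = TRUE)

  # invariance (up to sign) under relabeling of group order
  perm <- c(groups$g3, groups$g1, groups$g2)
  cv2 <- cva_fit(X[perm, ], labels[perm])
  for (j in 1:2)
    expect_equal(abs(cv$coefficients[, j]), abs(cv2$coefficients[, j]),
                 tolerance = 1e-8)

  # independent cross-check against MASS::lda (equal group sizes, where the
  # unweighted between-group scatter coincides with lda's proportional priors)
  skip_if_not_installed("MASS")
  ld <- MASS::lda(X, grouping = labels)
  expect_equal(cv$percent / 100, ld$svd^2 / sum(ld$svd^2), tolerance = 1e-6)
})

test_that("seven groups and four traits give at most four axes", {
  set.seed(109)
  X <- matrix(rnorm(7 * 10 * 4), 70, 4)
  X <- X + matrix(rnorm(7 * 4), 7, 4)[rep(1:7, each = 10), ]
  colnames(X) <- oft_traits()
  cv <- cva_fit(X, rep(paste0("s", 1:7), each = 10))
  expect_equal(ncol(cv$coefficients), 4)
  expect_equal(sum(cv$percent), 100)
  expect_true(all(cv$percent >= 0))
})

test_that("confidence ellipses follow the chi-square geometry", {
  set.seed(113)
  S <- matrix(rnorm(4000), 2000, 2)
  el <- confidence_ellipse(S, level = 0.95)
  r_expect <- sqrt(qchisq(0.95, 2))  # ~2.448 for unit isotropic scores
  expect_equal(el$radii, rep(r_expect, 2), tolerance = 0.1)
  expect_equal(el$center, colMeans(S), tolerance = 1e-12,
               ignore_attr = TRUE)

  el0 <- confidence_ellipse(S, level = 0)
  expect_equal(el0$radii, c(0, 0))

  # rotation equivariance: radii unchanged, orientation rotated
  aniso <- S %*% diag(c(3, 1))
  phi <- 0.7
  Rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  e1 <- confidence_ellipse(aniso)
  e2 <- confidence_ellipse(aniso %*% t(Rot))
  expect_equal(e2$radii, e1$radii, tolerance = 1e-9)
  d_ang <- (e2$angle - e1$angle - phi) %% pi
  expect_lt(min(d_ang, pi - d_ang), 1e-6)

  line <- cbind(1:10, (1:10) * 2)
  expect_error(confidence_ellipse(line), "degenerate")
  expect_error(confidence_ellipse(S[1:2, ]), "3 points")
})
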