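test_that("generator is seed-deterministic and validates its inputs", {
  sp <- spec4(20, 3, test_id(), test_resid())
  a <- simulate_species(sp, seed = 11)
  b <- simulate_species(sp, seed = 11)
  expect_identical(a, b)
  c <- simulate_species(sp, seed = 12)
  expect_false(isTRUE(all.equal(a$tl_cm, c$tl_cm)))

  bad <- test_id(); bad[1, 2] <- bad[2, 1] <- 10  # indefinite
  expect_error(spec4(20, 3, bad, test_resid()), "semi-definite")
  expect_error(spec4(20, 1, test_id(), test_resid()), "trials_per_individual")
  expect_error(species_spec("s", 10, 3, 8, -1, rep(0, 4), test_id(),
                            test_resid()), "mean_sl")
})

test_that("table structure follows the blocked group design with no gaps", {
  sp <- spec4(19, 4, test_id(), test_resid(), group_size = 8)
  tab <- simulate_species(sp, seed = 3)
  expect_equal(nrow(tab), 19 * 4)
  expect_false(anyNA(tab))
  reps <- tapply(tab$`repeat`, tab$fish_id, sort)
  expect_true(all(vapply(reps, identical, TRUE, y = 1:4)))
  per_fish <- unique(tab[c("fish_id", "group", "order_in_group")])
  expect_equal(nrow(per_fish), 19)
  per_fish <- per_fish[order(per_fish$fish_id), ]
  expect_equal(per_fish$group, (seq_len(19) - 1) %/% 8 + 1)
  expect_equal(per_fish$order_in_group, (seq_len(19) - 1) %% 8 + 1)
})

test_that("recorded latent deviations match true_ID at large n", {
  sp <- spec4(2000, 2, test_id(), test_resid())
  tab <- simulate_species(sp, seed = 21)
  u <- attr(tab, "latent_values")
  expect_equal(dim(u), c(2000, 4))
  expect_lt(max(abs(cov(u) - test_id())), 0.05)
})

test_that("zero among-individual variance gives near-zero repeatability", {
  sp <- spec4(200, 5, matrix(0, 4, 4), test_resid())
  d <- sim_sdu(sp, seed = 31)
  # Monte-Carlo SE of the intraclass correlation at rho = 0 for n = 200 x 5;
  # the estimator is truncated at zero and four traits are checked, so a
  # 3 SE band keeps the familywise false-alarm rate below 1%
  band <- 3 * sqrt(2 / (5 * 4 * 200))
  for (tr in oft_traits()) {
    uf <- fit_univariate(d, tr, fixed_effects = NULL)
    expect_lt(repeatability(uf), band)
  }
})

test_that("reference tree patristic distances equal the published matrix", {
  tree <- fish7_tree()
  D <- patristic_distances(tree)$point
  expected <- published_distances()
  expect_equal(D[rownames(expected), colnames(expected)], expected,
               tolerance = 1e-12)
  # against the brute-force path-sum oracle
  B <- patristic_brute(tree)
  expect_equal(D, B[rownames(D), colnames(D)], tolerance = 1e-12)
  # spot values and metric properties
  expect_equal(D["Xiphophorus_hellerii", "Xiphophorus_maculatus"], 0.001)
  expect_true(all(D["Danio_rerio", colnames(D) != "Danio_rerio"] == 0.132))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # four-point condition on every quadruple
  sp <- rownames(D)
  for (q in utils::combn(7, 4, simplify = FALSE)) {
    s <- sp[q]
    sums <- c(D[s[1], s[2]] + D[s[3], s[4]],
              D[s[1], s[3]] + D[s[2], s[4]],
              D[s[1], s[4]] + D[s[2], s[3]])
    two <- sort(sums, decreasing = TRUE)[1:2]
    expect_lt(abs(two[1] - two[2]), 1e-12)
  }
})

test_that("tree jitter preserves topology and per-pair median distances", {
  base <- fish7_tree()
  expect_error(simulate_tree_posterior(base, 5, jitter = -1), "jitter")

  none <- simulate_tree_posterior(base, 5, jitter = 0, seed = 1)
  for (tr in none)
    expect_equal(patristic_distances(tr)$point,
                 patristic_distances(base)$point, tolerance = 1e-12)

  set_a <- simulate_tree_posterior(base, 50, jitter = 0.2, seed = 9)
  set_b <- simulate_tree_posterior(base, 50, jitter = 0.2, seed = 9)
  expect_identical(set_a, set_b)

  draws <- simulate_tree_posterior(base, 1000, jitter = 0.2, seed = 2)
  D0 <- patristic_distances(base)$point
  stack <- vapply(draws, function(tr)
    patristic_distances(tr)$point[lower.tri(D0)], numeric(21))
  med <- apply(stack, 1, stats::median)
  expect_lt(max(abs(med / D0[lower.tri(D0)] - 1)), 0.05)
})
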