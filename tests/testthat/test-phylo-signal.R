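test_that("patristic distances are path-length sums", {
  two <- ape::read.tree(text = "(a:0.3,b:0.2);")
  expect_equal(patristic_distances(two)$point["a", "b"], 0.5)
  expect_error(patristic_distances(two, c("a", "z")), "z")

  set.seed(121)
  for (i in 1:10) {
    tr <- ape::rtree(7)
    D <- patristic_distances(tr)$point
    B <- patristic_brute(tr)
    expect_equal(D, B[rownames(D), colnames(D)], tolerance = 1e-10)
    # metric on a tree with non-negative branch lengths
    labs <- rownames(D)
    for (a in 1:5) for (b in (a + 1):6) for (c in (b + 1):7)
      expect_lte(D[a, b], D[a, c] + D[c, b] + 1e-12)
  }
})

test_that("Kendall tau-b matches brute-force counting and is rank-based", {
  lab <- letters[1:7]
  as_table <- function(v) {
    M <- matrix(0, 7, 7, dimnames = list(lab, lab))
    M[lower.tri(M)] <- v
    M + t(M)
  }
  set.seed(127)
  x <- runif(21)
  expect_equal(kendall_tau_b(as_table(x), as_table(exp(3 * x))), 1)
  expect_equal(kendall_tau_b(as_table(x), as_table(-x)), -1)
  for (i in 1:25) {
    a <- sample(1:6, 21, replace = TRUE)  # heavy ties
    b <- sample(1:6, 21, replace = TRUE)
    expect_equal(kendall_tau_b(as_table(a), as_table(b)), taub_brute(a, b),
                 tolerance = 1e-12)
    # invariance to strictly monotone transforms of either side
    expect_equal(kendall_tau_b(as_table(a), as_table(b)),
                 kendall_tau_b(as_table(qlogis(a / 7)), as_table(b^3)),
                 tolerance = 1e-12)
  }
  expect_warning(t0 <- kendall_tau_b(as_table(rep(1, 21)), as_table(x)),
                 "tied")
  expect_true(is.na(t0))
})

test_that("degenerate uncertainty collapses the signal bootstrap", {
  sp <- fish7_species()$species[1:5]
  set.seed(131)
  mk <- function() { A <- matrix(rnorm(16), 4); crossprod(A) / 4 }
  ids <- stats::setNames(replicate(5, mk(), simplify = FALSE), sp)
  ens <- lapply(ids, function(m) list(m))  # point-mass ensembles
  tree <- ape::rtree(5)
  tree$tip.label <- sp
  trees <- simulate_tree_posterior(tree, 3, jitter = 0, seed = 1)
  res <- phylo_signal(ids, ens, tree, trees, "delta", n_reps = 40, seed = 2)
  expect_equal(length(unique(res$boot)), 1)
  expect_equal(res$ci[1], res$ci[2])
  expect_equal(res$boot[1], res$tau)

  # identical seeds give identical results, across all three statistics
  for (stat in c("delta", "theta", "twoK")) {
    r1 <- phylo_signal(ids, ens, tree, trees, stat, n_reps = 20, seed = 7)
    r2 <- phylo_signal(ids, ens, tree, trees, stat, n_reps = 20, seed = 7)
    expect_identical(r1$boot, r2$boot)
    expect_gte(r1$tau, -1); expect_lte(r1$tau, 1)
    expect_gte(r1$ci[1], -1); expect_lte(r1$ci[2], 1)
  }
})

test_that("nested bootstrap CI covers zero under a no-signal simulation", {
  # Null world: each species' true ID is drawn independently of the (random)
  # tree. Estimates are Wishart perturbations of the truth and each species'
  # ensemble is the matching parametric resample of its estimate, so the
  # bootstrap spread mimics the estimation noise. The 95% CI should then
  # cover tau = 0 in about 95% of replicates.
  set.seed(137)
  sp <- paste0("s", 1:7)
  df <- 40
  rwish <- function(S) {
    L <- chol(S)
    Z <- matrix(rnorm(df * 4), df, 4) %*% L
    crossprod(Z) / df
  }
  outer_n <- 100
  covered <- 0
  base_id <- test_id()
  for (rep in seq_len(outer_n)) {
    true_ids <- replicate(7, rwish(base_id), simplify = FALSE)
    hat_ids <- stats::setNames(lapply(true_ids, rwish), sp)
    ens <- lapply(hat_ids, function(m)
      replicate(40, rwish(m), simplify = FALSE))
    tree <- ape::rtree(7)
    tree$tip.label <- sp
    trees <- simulate_tree_posterior(tree, 15, jitter = 0.3)
    res <- phylo_signal(hat_ids, ens, tree, trees, "delta",
                        n_reps = 200)
    if (res$ci[1] <= 0 && res$ci[2] >= 0) covered <- covered + 1
  }
  band <- qbinom(c(0.025, 0.975), outer_n, 0.95)
  expect_gte(covered, band[1])
  expect_lte(covered, band[2])
})
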