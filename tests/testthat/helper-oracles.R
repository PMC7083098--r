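# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (brute-force counting, path enumeration,
# dense eigensolves) and never share code with the implementation they check.

# Simulate a species and return its table on the analysis (transformed) trait
# scale, which is what the model fits consume.
sim_sdu <- function(spec, seed) {
  tab <- simulate_species(spec, seed = seed)
  cbind(tab[c("species", "fish_id", "group", "order_in_group", "repeat")],
        attr(tab, "transformed"))
}

# Quick 4-trait species spec with optional shared defaults.
spec4 <- function(n, k, ID, R, name = "sim", group_size = 8,
                  means = c(0, 0, 0, 20), repeat_effects = NULL,
                  order_slope = rep(0, 4)) {
  species_spec(name, n, k, group_size, mean_sl = 20, trait_means = means,
               true_ID = ID, true_R = R, repeat_effects = repeat_effects,
               order_slope = order_slope)
}

# A well-conditioned non-trivial covariance pair used in several tests.
test_id <- function() {
  M <- matrix(c(0.30, 0.10, 0.05, 0.02,
                0.10, 0.25, 0.08, 0.03,
                0.05, 0.08, 0.20, 0.06,
                0.02, 0.03, 0.06, 0.35), 4, 4)
  dimnames(M) <- list(oft_traits(), oft_traits())
  M
}
test_resid <- function(rho = 0.25) {
  C <- matrix(rho, 4, 4); diag(C) <- 1
  0.7 * C
}

# Brute-force Kendall tau-b: concordant/discordant pair counting with the
# tie-corrected denominator.
taub_brute <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) nc <- nc + 1
    else nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  n1 <- n0 - (nc + nd + ty)
  n2 <- n0 - (nc + nd + tx)
  (nc - nd) / sqrt((n0 - n1) * (n0 - n2))
}

# Brute-force patristic distances: breadth-first path enumeration over the
# tree's edge list, summing branch lengths.
patristic_brute <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(nt)) {
    dist <- rep(NA_real_, nn); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        w <- adj[[v]][r, 1]
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + adj[[v]][r, 2]
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist[seq_len(nt)]
  }
  D
}

# The published between-species substitution-distance matrix, frozen here as
# the expected value for the reference-tree checks.
published_distances <- function() {
  sp <- fish7_species()$species
  D <- matrix(0, 7, 7, dimnames = list(sp, sp))
  set <- function(a, b, v) D[a, b] <<- D[b, a] <<- v
  for (s in sp[-1]) set("Danio_rerio", s, 0.132)
  set("Lima_nigrofasciata", "Poecilia_reticulata", 0.029)
  for (s in c("Xiphophorus_birchmanni", "Xiphophorus_hellerii",
              "Xiphophorus_maculatus")) {
    set("Lima_nigrofasciata", s, 0.045)
    set("Poecilia_reticulata", s, 0.045)
  }
  for (s in c("Lima_nigrofasciata", "Poecilia_reticulata",
              "Xiphophorus_birchmanni", "Xiphophorus_hellerii",
              "Xiphophorus_maculatus"))
    set("Xenotoca_eiseni", s, 0.129)
  set("Xiphophorus_birchmanni", "Xiphophorus_hellerii", 0.012)
  set("Xiphophorus_birchmanni", "Xiphophorus_maculatus", 0.012)
  set("Xiphophorus_hellerii", "Xiphophorus_maculatus", 0.001)
  D
}

# Random orthonormal n x x basis.
random_basis <- function(n, x) {
  qr.Q(qr(matrix(rnorm(n * n), n)))[, seq_len(x), drop = FALSE]
}
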