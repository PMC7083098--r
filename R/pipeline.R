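# End-to-end orchestration: simulate (or accept) trial data, standardize,
# fit per-species univariate and multivariate models, bootstrap, build the
# pairwise comparison tables, run the CVA and the phylogenetic-signal tests,
# and write everything as delimited text with a manifest. The run is a pure
# function of (inputs, config, seed): every random stage consumes a sub-seed
# derived from the single top-level seed via make_subseeds().

#' Configuration for a full comparative analysis
#'
#' @param specs named list of [species_spec()] objects used to simulate trial
#'   data (ignored when `trials` is supplied).
#' @param trials optional raw-unit trial table to analyse instead of
#'   simulating.
#' @param tree point phylogeny over the species labels.
#' @param n_tree_draws size of the pseudo-posterior tree set.
#' @param tree_jitter log-scale branch-length jitter of the tree set.
#' @param boot_draws parametric-bootstrap draws per species (publication
#'   scale 5000; desk-scale default 200).
#' @param signal_reps nested-bootstrap replicates for the signal tests.
#' @param x subspace dimension for the Krzanowski comparison (must be at most
#'   half the number of traits).
#' @param seed top-level integer seed.
#' @param fixed_effects fixed effects passed to the model fits.
#' @param pair_lrts fit the 21 blocked pair models and equality LRTs? (the
#'   most expensive stage; disable for quick runs).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(specs = fish7_species_specs(), trials = NULL,
                            tree = fish7_tree(), n_tree_draws = 100,
                            tree_jitter = 0.2, boot_draws = 200,
                            signal_reps = 1000, x = 2, seed = 1,
                            fixed_effects = c("repeat", "order"),
                            pair_lrts = TRUE) {
  n_traits <- length(oft_traits())
  if (x > n_traits / 2)
    stop("x must be at most half the number of traits")
  structure(list(specs = specs, trials = trials, tree = tree,
                 n_tree_draws = n_tree_draws, tree_jitter = tree_jitter,
                 boot_draws = boot_draws, signal_reps = signal_reps,
                 x = x, seed = seed, fixed_effects = fixed_effects,
                 pair_lrts = pair_lrts),
            class = "analysis_config")
}

#' Run the full comparative analysis
#'
#' Executes the pipeline: preprocessing to global SDU, univariate
#' repeatability models per species and trait (with boundary-corrected LRTs),
#' multivariate ID estimation with the 6-df covariance LRT, parametric
#' bootstraps, pairwise delta/theta/2-K tables with CIs, pairwise equality
#' LRTs, canonical variate analysis of individual mean behaviour, and the
#' three phylogenetic-signal tests. Species whose pair models fail to
#' converge are flagged in the equality table rather than aborting the run.
#'
#' @param config an [analysis_config()].
#' @return a named list (`results` bundle) with elements `trials`, `scaling`,
#'   `repeatability`, `fits`, `cov_lrt`, `ensembles`, `pairwise` (list of
#'   three [pairwise_table]s), `equality`, `cva`, `signal` (list of three
#'   `signal_result`s), `patristic`, `config`, `seeds`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  seeds <- make_subseeds(config$seed, 4)
  trials <- config$trials %||% simulate_trials(config$specs, seed = seeds[1])
  std <- global_standardize(trials)
  data <- std$data
  species <- sort(unique(as.character(data$species)))
  tabs <- split(data, data$species)[species]

  # univariate repeatabilities
  rep_rows <- list()
  for (s in species) for (tr in oft_traits()) {
    uf <- fit_univariate(tabs[[s]], tr, fixed_effects = config$fixed_effects)
    lrt <- lrt_mixture_p(uf$reml_loglik, uf$loglik_null)
    rep_rows[[length(rep_rows) + 1]] <- data.frame(
      species = s, trait = tr, V_I = uf$V_I, V_R = uf$V_R,
      repeatability = repeatability(uf), lrt_statistic = lrt$statistic,
      p = lrt$p, converged = uf$converged, stringsAsFactors = FALSE)
  }
  repeatability_table <- do.call(rbind, rep_rows)

  # multivariate ID fits and covariance LRT
  fits <- lapply(tabs, fit_multivariate, fixed_effects = config$fixed_effects)
  diag_fits <- lapply(tabs, fit_multivariate, constrain_diagonal = TRUE,
                      fixed_effects = config$fixed_effects)
  cov_lrt <- do.call(rbind, lapply(species, function(s) {
    lrt <- lrt_id_covariances(fits[[s]], diag_fits[[s]])
    data.frame(species = s, statistic = lrt$statistic, df = lrt$df,
               p = lrt$p, converged = fits[[s]]$converged,
               stringsAsFactors = FALSE)
  }))

  # parametric bootstrap ensembles (independent sub-seed per species)
  boot_seeds <- make_subseeds(seeds[2], length(species))
  ensembles <- stats::setNames(lapply(seq_along(species), function(i)
    parametric_bootstrap(fits[[species[i]]], n_draws = config$boot_draws,
                         seed = boot_seeds[i])), species)

  ids <- lapply(fits, function(f) f$ID)
  pairwise <- list(
    delta = pairwise_id_table(ids, "delta", ensembles = ensembles),
    theta = pairwise_id_table(ids, "theta", ensembles = ensembles),
    twoK = pairwise_id_table(ids, "twoK", ensembles = ensembles,
                             x = config$x))

  # pairwise equality LRTs (flag failures, keep going)
  equality <- NULL
  if (isTRUE(config$pair_lrts)) {
    eq_rows <- list()
    for (i in seq_along(species)[-length(species)])
      for (j in (i + 1):length(species)) {
        res <- tryCatch({
          unc <- fit_pair_blocked(tabs[[species[i]]], tabs[[species[j]]],
                                  fixed_effects = config$fixed_effects)
          con <- fit_pair_blocked(tabs[[species[i]]], tabs[[species[j]]],
                                  constrain_equal = TRUE,
                                  fixed_effects = config$fixed_effects)
          lrt <- lrt_id_equality(unc, con)
          data.frame(species_a = species[i], species_b = species[j],
                     statistic = lrt$statistic, df = lrt$df, p = lrt$p,
                     converged = unc$converged && con$converged,
                     stringsAsFactors = FALSE)
        }, error = function(e)
          data.frame(species_a = species[i], species_b = species[j],
                     statistic = NA_real_, df = NA_real_, p = NA_real_,
                     converged = FALSE, stringsAsFactors = FALSE))
        eq_rows[[length(eq_rows) + 1]] <- res
      }
    equality <- do.call(rbind, eq_rows)
  }

  # CVA of within-individual mean behaviour
  im <- individual_means(data)
  cva <- cva_fit(im[oft_traits()], im$species)
  ellipses <- lapply(split(cva$scores[, c("CV1", "CV2")], cva$scores$species),
                     confidence_ellipse)

  # phylogenetic signal for the three dissimilarity statistics
  trees <- simulate_tree_posterior(config$tree, config$n_tree_draws,
                                   config$tree_jitter, seed = seeds[3])
  sig_seeds <- make_subseeds(seeds[4], 3)
  signal <- list(
    delta = phylo_signal(ids, ensembles, config$tree, trees, "delta",
                         n_reps = config$signal_reps, seed = sig_seeds[1]),
    theta = phylo_signal(ids, ensembles, config$tree, trees, "theta",
                         n_reps = config$signal_reps, seed = sig_seeds[2]),
    twoK = phylo_signal(ids, ensembles, config$tree, trees, "twoK",
                        n_reps = config$signal_reps, x = config$x,
                        seed = sig_seeds[3]))

  list(trials = trials, scaling = std$scaling,
       repeatability = repeatability_table,
       fits = fits, diag_fits = diag_fits, cov_lrt = cov_lrt,
       ensembles = ensembles, pairwise = pairwise, equality = equality,
       cva = cva, ellipses = ellipses,
       patristic = patristic_distances(config$tree, species),
       signal = signal, config = config, seeds = seeds)
}

#' Write the analysis tables as delimited text
#'
#' Writes each pairwise table both in a lower-triangle layout with
#' "point (lower, upper)" cells and as a tidy long CSV, plus the
#' repeatability, covariance-LRT, equality and CVA tables, and a
#' `manifest.json` recording the seed and the MD5 of every written file.
#'
#' @param results bundle from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
write_tables <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1]] <<- p
  }
  fmt_pairwise <- function(pt) {
    m <- format(round(pt$point, 3), trim = TRUE)
    if (!is.null(pt$lo))
      m[] <- paste0(m, " (", format(round(pt$lo, 3), trim = TRUE), ", ",
                    format(round(pt$hi, 3), trim = TRUE), ")")
    m[upper.tri(m, diag = TRUE)] <- ""
    data.frame(species = pt$labels, m, check.names = FALSE,
               stringsAsFactors = FALSE)
  }
  for (nm in names(results$pairwise)) {
    pt <- results$pairwise[[nm]]
    put(fmt_pairwise(pt), paste0(nm, ".csv"))
    put(as.data.frame(pt), paste0(nm, "_long.csv"))
  }
  put(fmt_pairwise(results$patristic), "patristic.csv")
  put(as.data.frame(results$patristic), "patristic_long.csv")
  put(results$repeatability, "repeatability.csv")
  put(results$cov_lrt, "cov_lrt.csv")
  if (!is.null(results$equality)) put(results$equality, "equality_lrt.csv")
  put(results$cva$scores, "cva_scores.csv")
  put(data.frame(trait = rownames(results$cva$coefficients),
                 results$cva$coefficients), "cva_coefficients.csv")
  sig <- do.call(rbind, lapply(names(results$signal), function(nm) {
    s <- results$signal[[nm]]
    data.frame(statistic = nm, tau = s$tau, lo = s$ci[1], hi = s$ci[2],
               n_reps = s$n_reps, failed = s$failed)
  }))
  put(sig, "phylo_signal.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("idcomp")),
    seed = results$config$seed,
    subseeds = results$seeds,
    boot_draws = results$config$boot_draws,
    signal_reps = results$config$signal_reps,
    files = as.list(stats::setNames(unname(tools::md5sum(unlist(paths))),
                                    basename(unlist(paths)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a tidy long pairwise CSV back into a pairwise table
#'
#' Inverse of the `*_long.csv` files written by [write_tables()].
#'
#' @param path file path.
#' @return a [pairwise_table].
#' @export
read_pairwise_long <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sp <- sort(unique(c(df$species_a, df$species_b)))
  point <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  lo <- hi <- if ("lo" %in% names(df)) point else NULL
  for (r in seq_len(nrow(df))) {
    a <- df$species_a[r]; b <- df$species_b[r]
    point[a, b] <- point[b, a] <- df$point[r]
    if (!is.null(lo)) {
      lo[a, b] <- lo[b, a] <- df$lo[r]
      hi[a, b] <- hi[b, a] <- df$hi[r]
    }
  }
  pairwise_table(point, df$stat[1], lo = lo, hi = hi)
}

#' Comparison-only analysis from the bundled published eigenstructure
#'
#' Runs the matrix-comparison and phylogenetic-signal stages directly from
#' the published per-species eigenvectors and eigenvalues, with no raw trial
#' data: reconstructs each ID matrix ([reconstruct_id()]), computes the
#' pairwise theta, 2-K and delta tables, and correlates each (and the
#' published pairwise values) with the patristic distances of the reference
#' tree.
#'
#' @param x subspace dimension for the Krzanowski comparison.
#' @return list with `ids`, pairwise tables `theta`, `twoK`, `delta`,
#'   `patristic`, and `tau` / `tau_published` (named vectors of Kendall
#'   tau-b against phylogenetic distance, from the recomputed and the
#'   published dissimilarities respectively).
#' @export
compare_published <- function(x = 2) {
  sp <- fish7_species()$species
  ids <- stats::setNames(lapply(sp, reconstruct_id), sp)
  theta <- pairwise_id_table(ids, "theta")
  twoK <- pairwise_id_table(ids, "twoK", x = x)
  delta <- pairwise_id_table(ids, "delta")
  D <- patristic_distances(fish7_tree(), sp)
  tau <- c(delta = kendall_tau_b(D, delta),
           theta = kendall_tau_b(D, theta),
           twoK = kendall_tau_b(D, twoK))
  pub <- fish7_pairwise()
  pub_tab <- function(stat) {
    df <- pub[pub$stat == stat, ]
    point <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
    for (r in seq_len(nrow(df)))
      point[df$species_a[r], df$species_b[r]] <-
        point[df$species_b[r], df$species_a[r]] <- df$point[r]
    pairwise_table(point, stat)
  }
  tau_published <- c(delta = kendall_tau_b(D, pub_tab("delta")),
                     theta = kendall_tau_b(D, pub_tab("theta")),
                     twoK = kendall_tau_b(D, pub_tab("twoK")))
  list(ids = ids, theta = theta, twoK = twoK, delta = delta, patristic = D,
       tau = tau, tau_published = tau_published)
}
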