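# Bundled reference values from a published comparative open-field-trial
# study of seven freshwater fish species (three families: Poeciliidae,
# Goodeidae, Cyprinidae). The eigenvector table carries the first two
# eigenvectors of each species' among-individual covariance matrix (ID) in
# global standard deviation units; the pairwise table carries the published
# point estimates and approximate 95% CIs of the three ID dissimilarity
# statistics. These serve as inputs for the comparison-only analysis path.

#' The seven study species
#'
#' @return data.frame with columns `species` (underscored binomial, the label
#'   used throughout the package and on the phylogeny tips) and `code`
#'   (two-letter shorthand).
#' @export
fish7_species <- function() {
  data.frame(
    species = c("Danio_rerio", "Lima_nigrofasciata", "Poecilia_reticulata",
                "Xiphophorus_birchmanni", "Xenotoca_eiseni",
                "Xiphophorus_hellerii", "Xiphophorus_maculatus"),
    code = c("Dr", "Ln", "Pr", "Xb", "Xe", "Xh", "Xm"),
    stringsAsFactors = FALSE
  )
}

#' Published ID eigenstructure for the seven study species
#'
#' First and second eigenvectors of each species' among-individual behavioural
#' covariance matrix, with eigenvalues (squared standard deviation units) and
#' percent of total among-individual variance explained. Trait loadings are in
#' the fixed order [oft_traits()].
#'
#' @return data.frame with columns `species`, `axis` (1 or 2), `eigenvalue`,
#'   `percent`, and one loading column per trait.
#' @export
fish7_eigen <- function() {
  read.csv(system.file("extdata", "fish7_eigenvectors.csv",
                       package = "idcomp"), stringsAsFactors = FALSE)
}

#' Published pairwise ID dissimilarity statistics
#'
#' Point estimates and approximate 95% CIs of the trace difference (`delta`),
#' leading-eigenvector angle in degrees (`theta`), and two-dimensional
#' Krzanowski subspace dissimilarity (`twoK`) for all 21 species pairs.
#'
#' @param stat optional statistic tag to filter on ("delta", "theta", "twoK").
#' @return data.frame with columns `species_a`, `species_b`, `stat`, `point`,
#'   `lo`, `hi`.
#' @export
fish7_pairwise <- function(stat = NULL) {
  x <- read.csv(system.file("extdata", "fish7_pairwise.csv",
                            package = "idcomp"), stringsAsFactors = FALSE)
  if (!is.null(stat)) {
    stat <- match.arg(stat, c("delta", "theta", "twoK"))
    x <- x[x$stat == stat, , drop = FALSE]
    rownames(x) <- NULL
  }
  x
}

#' Loadings of one published eigenvector
#'
#' Returns the published trait loadings of a species' first or second ID
#' eigenvector, renormalized to unit length by default (printed loadings
#' carry rounding, so their norm is only approximately 1).
#'
#' @param species species label as in [fish7_species()].
#' @param axis 1 (leading) or 2.
#' @param renormalize rescale to unit norm?
#' @return numeric 4-vector in [oft_traits()] order.
#' @export
fish7_vector <- function(species, axis = 1, renormalize = TRUE) {
  ev <- fish7_eigen()
  row <- ev[ev$species == species & ev$axis == axis, , drop = FALSE]
  if (nrow(row) != 1) stop("no eigenvector for species ", species)
  v <- as.numeric(row[, oft_traits()])
  if (renormalize) v <- v / sqrt(sum(v^2))
  v
}

#' Reconstruct a species ID matrix from its published eigenstructure
#'
#' Rebuilds a full 4x4 among-individual covariance matrix consistent with the
#' published leading two eigenvectors and eigenvalues. The total variance
#' (trace) is recovered from the first eigenvalue and its percent of variance;
#' the remaining variance (the unreported third and fourth eigenvalues) is
#' split isotropically over the orthogonal complement of the leading plane.
#' The reconstruction reproduces the published eigenvectors, eigenvalues,
#' percent variances, and trace; only the (unreported) orientation within the
#' trailing two-dimensional subspace is arbitrary.
#'
#' @param species species label as in [fish7_species()].
#' @return symmetric positive semi-definite 4x4 matrix with trait dimnames.
#' @export
reconstruct_id <- function(species) {
  ev <- fish7_eigen()
  rows <- ev[ev$species == species, , drop = FALSE]
  if (nrow(rows) != 2) stop("unknown species: ", species)
  lam1 <- rows$eigenvalue[rows$axis == 1]
  lam2 <- rows$eigenvalue[rows$axis == 2]
  pct1 <- rows$percent[rows$axis == 1]
  total <- 100 * lam1 / pct1
  v1 <- fish7_vector(species, 1)
  v2 <- fish7_vector(species, 2)
  # printed vectors are orthogonal only to rounding; re-orthogonalize v2
  v2 <- v2 - sum(v1 * v2) * v1
  v2 <- v2 / sqrt(sum(v2^2))
  rest <- max(total - lam1 - lam2, 0)
  P <- tcrossprod(v1) + tcrossprod(v2)
  M <- lam1 * tcrossprod(v1) + lam2 * tcrossprod(v2) +
    (rest / 2) * (diag(4) - P)
  M <- (M + t(M)) / 2
  dimnames(M) <- list(oft_traits(), oft_traits())
  M
}
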