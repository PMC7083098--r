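# Phylogeny handling: the fixed seven-species reference tree and a
# branch-length-jittered stand-in for a posterior tree sample.

#' Ultrametric reference tree for the seven study species
#'
#' Constructs the seven-taxon ultrametric phylogeny whose patristic (cophenetic)
#' distances equal the published between-species nucleotide-substitution
#' distance matrix exactly. Under ultrametry each leaf pair's distance is twice
#' the depth of its most recent common ancestor, which determines all node
#' depths: the *X. hellerii*/*X. maculatus* ancestor sits at depth 0.0005,
#' joined by *X. birchmanni* at 0.006; *L. nigrofasciata*/*P. reticulata* join
#' at 0.0145 and meet the swordtail clade at 0.0225; *X. eiseni* attaches at
#' 0.0645 and *D. rerio* at the root depth 0.066.
#'
#' @return an [ape::read.tree()] `phylo` object with branch lengths in
#'   substitutions per site.
#' @export
fish7_tree <- function() {
  txt <- paste0(
    "(((((Xiphophorus_hellerii:0.0005,Xiphophorus_maculatus:0.0005):0.0055,",
    "Xiphophorus_birchmanni:0.006):0.0165,",
    "(Lima_nigrofasciata:0.0145,Poecilia_reticulata:0.0145):0.008):0.042,",
    "Xenotoca_eiseni:0.0645):0.0015,Danio_rerio:0.066);")
  ape::read.tree(text = txt)
}

#' Simulate a pseudo-posterior set of trees by branch-length jitter
#'
#' Stands in for a Bayesian posterior tree sample when only a point tree is
#' available: the topology is kept fixed and every branch length is multiplied
#' by an independent log-normal factor with median 1 and log-scale spread
#' `jitter`. With `jitter = 0` all draws equal the base tree.
#'
#' @param base a `phylo` tree with positive branch lengths.
#' @param n_draws number of trees to generate.
#' @param jitter non-negative log-scale standard deviation of the
#'   multiplicative branch-length noise.
#' @param seed optional integer seed; the same seed reproduces the same set.
#' @return an [ape::c.phylo()] `multiPhylo` list of `n_draws` trees.
#' @export
simulate_tree_posterior <- function(base, n_draws, jitter = 0.2, seed = NULL) {
  if (!inherits(base, "phylo")) stop("base must be a phylo tree")
  if (is.null(base$edge.length) || any(base$edge.length <= 0))
    stop("base tree must have positive branch lengths")
  if (!is.numeric(jitter) || length(jitter) != 1 || jitter < 0)
    stop("jitter must be a non-negative scalar")
  n_edge <- length(base$edge.length)
  trees <- with_seed(seed, lapply(seq_len(n_draws), function(i) {
    tr <- base
    tr$edge.length <- tr$edge.length * exp(rnorm(n_edge, 0, jitter))
    tr
  }))
  class(trees) <- "multiPhylo"
  trees
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths on the path between every pair of leaves
#' (the cophenetic distance), restricted and ordered to `labels`.
#'
#' @param tree a `phylo` object.
#' @param labels optional ordered species subset; defaults to all tips sorted
#'   alphabetically.
#' @return a [pairwise_table] with statistic tag `"patristic"`.
#' @export
patristic_distances <- function(tree, labels = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  labels <- labels %||% sort(tree$tip.label)
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing))
    stop("tree is missing leaves: ", paste(missing, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)[labels, labels, drop = FALSE]
  pairwise_table(point = D, statistic = "patristic")
}
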