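#' Simulate a set of candidate phylogenies
#'
#' Pure-birth (Yule) trees rescaled to unit root-to-tip depth, standing in
#' for a posterior sample of candidate trees when real phylogenies are not
#' part of the analysis. Only the branch-length structure matters for
#' phylogenetic-signal estimation; the unit-depth rescaling makes the
#' Brownian rate parameter comparable across trees.
#'
#' @param n_trees Number of trees.
#' @param n_tips Tips per tree (>= 3).
#' @param tip_labels Optional character vector of tip labels (length
#'   `n_tips`), e.g. species names from a phenotype table.
#' @param seed Integer seed.
#' @return A `multiPhylo` list of rooted ultrametric-depth-1 trees.
#' @export
simulate_trees <- function(n_trees, n_tips, tip_labels = NULL, seed = 1L) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 3) abort("n_tips must be >= 3")
  if (!is.null(tip_labels) && length(tip_labels) != n_tips) {
    abort("tip_labels must have length n_tips")
  }
  trees <- with_seed(as.integer(seed), {
    lapply(seq_len(n_trees), function(i) {
      tr <- ape::rphylo(n_tips, birth = 1, death = 0)
      depth <- max(ape::node.depth.edgelength(tr)[seq_len(n_tips)])
      tr$edge.length <- tr$edge.length / depth
      if (!is.null(tip_labels)) {
        tr$tip.label <- sample(tip_labels)
      }
      tr
    })
  })
  class(trees) <- "multiPhylo"
  trees
}

#' Simulate a trait under lambda-scaled Brownian motion
#'
#' Tip values are multivariate normal with mean `mu` and covariance
#' `sigma2 * C_lambda`, where `C_lambda` has root-to-tip path lengths on
#' the diagonal and `lambda` times the shared path length off the
#' diagonal (see [lambda_covariance()]). `lambda = 0` gives mutually
#' independent tips; `lambda = 1` gives plain Brownian motion.
#'
#' @param tree A rooted `phylo` with positive branch lengths.
#' @param lambda_true Pagel's lambda in \[0, 1\] used for simulation.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param mu Root state.
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_lambda_traits <- function(tree, lambda_true, sigma2 = 1, mu = 0,
                                   seed = 1L) {
  if (!inherits(tree, "phylo")) abort("tree must be a 'phylo' object")
  if (any(tree$edge.length <= 0)) abort("tree must have positive branch lengths")
  if (!is.numeric(lambda_true) || lambda_true < 0 || lambda_true > 1) {
    abort("lambda_true must lie in [0, 1]")
  }
  if (sigma2 <= 0) abort("sigma2 must be positive")
  C <- lambda_covariance(tree, lambda_true) * sigma2
  with_seed(as.integer(seed), {
    drop(rmvn(1, rep(mu, nrow(C)), C)) |> stats::setNames(rownames(C))
  })
}
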