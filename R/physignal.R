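#' Lambda-scaled tip covariance of a phylogeny
#'
#' The Brownian-motion tip covariance has root-to-tip path lengths on the
#' diagonal and shared root-to-MRCA path lengths off the diagonal.
#' Pagel's lambda multiplies only the off-diagonal entries: `lambda = 1`
#' is plain Brownian motion, `lambda = 0` leaves tips mutually
#' independent.
#'
#' @param tree Rooted `phylo` with positive branch lengths.
#' @param lambda Value in \[0, 1\].
#' @return Tip covariance matrix with tip labels as dimnames.
#' @export
lambda_covariance <- function(tree, lambda) {
  if (!inherits(tree, "phylo")) abort("tree must be a 'phylo' object")
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    abort("lambda must lie in [0, 1]")
  }
  C <- ape::vcv.phylo(tree)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# profile log-likelihood of lambda: mu and sigma2 by GLS closed form
.lambda_loglik <- function(lambda, C0, diagC, y) {
  Cl <- lambda * C0
  diag(Cl) <- diagC
  n <- length(y)
  U <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(U)) return(list(loglik = -Inf))
  one <- rep(1, n)
  z <- backsolve(U, y, transpose = TRUE)
  w <- backsolve(U, one, transpose = TRUE)
  mu <- sum(w * z) / sum(w * w)
  r <- z - mu * w
  s2 <- sum(r^2) / n
  logdet <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(loglik = ll, mu = mu, sigma2 = s2)
}

#' Maximum-likelihood estimate of Pagel's lambda for one trait
#'
#' For each candidate lambda, the root state and Brownian rate have
#' generalised-least-squares closed forms; the profile log-likelihood is
#' maximised over lambda in \[0, 1\] by bounded scalar optimisation
#' (tolerance 1e-8), with the boundary values checked explicitly so ties
#' resolve toward the bound. Likelihood-ratio statistics against
#' `lambda = 0` and `lambda = 1` give `p0` (evidence of any phylogenetic
#' signal) and `p1` (departure from plain Brownian motion), each against
#' chi-square with 1 df.
#'
#' @param tree Rooted `phylo` (>= 4 tips, positive branch lengths).
#' @param trait Named numeric vector of tip values; names must match tip
#'   labels.
#' @return One-row `egg_lambda` tibble: `lambda`, `sigma2`, `mu`,
#'   `loglik`, `loglik0`, `loglik1`, `p0`, `p1`.
#' @export
estimate_lambda <- function(tree, trait) {
  if (!inherits(tree, "phylo")) abort("tree must be a 'phylo' object")
  if (length(tree$tip.label) < 4) abort("need at least 4 tips")
  if (is.null(names(trait))) abort("trait vector must be named by tip label")
  unmatched <- setdiff(tree$tip.label, names(trait))
  if (length(unmatched)) {
    abort(paste0("tip(s) without trait values: ", paste(unmatched, collapse = ", ")))
  }
  y <- as.numeric(trait[tree$tip.label])
  if (sd(y) < 1e-12) abort("trait is constant across tips")
  C0 <- ape::vcv.phylo(tree)
  diagC <- diag(C0)
  ll_fun <- function(l) .lambda_loglik(l, C0, diagC, y)$loglik
  opt <- optimize(ll_fun, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(0, 1, opt$maximum)
  lls <- c(ll_fun(0), ll_fun(1), opt$objective)
  best <- which.max(lls)
  # prefer a boundary when likelihoods tie within optimiser tolerance
  if (best == 3) {
    if (lls[1] >= lls[3] - 1e-8) best <- 1
    else if (lls[2] >= lls[3] - 1e-8) best <- 2
  }
  lam <- cand[best]
  fit <- .lambda_loglik(lam, C0, diagC, y)
  ll0 <- lls[1]; ll1 <- lls[2]
  res <- tibble(
    lambda = lam, sigma2 = fit$sigma2, mu = fit$mu,
    loglik = fit$loglik, loglik0 = ll0, loglik1 = ll1,
    p0 = pchisq(2 * pmax(fit$loglik - ll0, 0), df = 1, lower.tail = FALSE),
    p1 = pchisq(2 * pmax(fit$loglik - ll1, 0), df = 1, lower.tail = FALSE)
  )
  class(res) <- c("egg_lambda", class(res))
  res
}

#' Per-species trait means of a phenotype table
#'
#' Species-level trait values (for phylogenetic-signal estimation) are
#' the per-species means of the cleaned egg table, excluding parasite
#' rows.
#'
#' @param data Phenotype tibble.
#' @param traits Trait columns.
#' @return Tibble with `species` and one mean column per trait.
#' @export
species_trait_means <- function(data, traits = egg_traits()) {
  data %>%
    filter(.data$role != "parasite") %>%
    group_by(.data$species) %>%
    summarise(across(all_of(traits), mean), .groups = "drop")
}

#' Phylogenetic signal per trait, aggregated over a tree set
#'
#' Estimates Pagel's lambda (with `p0` and `p1`) for every trait on every
#' candidate tree, then reports the mean and SD of each quantity across
#' trees — the standard way to propagate phylogenetic uncertainty through
#' a posterior sample of trees. Trees missing any species are skipped
#' with a warning.
#'
#' @param trees A `multiPhylo` or list of `phylo` trees.
#' @param trait_means Tibble from [species_trait_means()] (column
#'   `species` plus trait columns).
#' @param traits Trait columns to analyse.
#' @return A `lambda_summary` tibble: per trait, `mean_lambda`,
#'   `sd_lambda`, `mean_p0`, `sd_p0`, `mean_p1`, `sd_p1`,
#'   `n_trees_used`. The per-tree estimates are attached as
#'   `attr(, "per_tree")`.
#' @export
summarize_over_trees <- function(trees, trait_means, traits = egg_traits()) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  traits <- intersect(traits, names(trait_means))
  sp <- trait_means$species
  usable <- vapply(trees, function(tr) all(sp %in% tr$tip.label), logical(1))
  if (!all(usable)) {
    warn(sprintf("%d of %d trees skipped (missing species)",
                 sum(!usable), length(trees)))
  }
  trees <- trees[usable]
  if (!length(trees)) abort("no usable trees")
  per_tree <- purrr::map_dfr(seq_along(trees), function(i) {
    tr <- trees[[i]]
    purrr::map_dfr(traits, function(v) {
      est <- estimate_lambda(tr, stats::setNames(trait_means[[v]], sp))
      mutate(est, tree = i, trait = v)
    })
  })
  out <- per_tree %>%
    group_by(.data$trait) %>%
    summarise(
      mean_lambda = mean(.data$lambda), sd_lambda = sd(.data$lambda),
      mean_p0 = mean(.data$p0), sd_p0 = sd(.data$p0),
      mean_p1 = mean(.data$p1), sd_p1 = sd(.data$p1),
      n_trees_used = dplyr::n(), .groups = "drop"
    ) %>%
    arrange(match(.data$trait, traits))
  if (length(trees) == 1) {
    out$sd_lambda <- 0; out$sd_p0 <- 0; out$sd_p1 <- 0
  }
  attr(out, "per_tree") <- per_tree
  class(out) <- c("lambda_summary", class(out))
  out
}
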