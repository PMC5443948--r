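# core linear-discriminant computations on a numeric matrix; all
# user-facing wrappers are data-frame-first

.lda_stats <- function(X, f) {
  lev <- levels(f)
  k <- length(lev); n <- nrow(X); d <- ncol(X)
  counts <- tabulate(f, nbins = k)
  means <- matrix(0, k, d, dimnames = list(lev, colnames(X)))
  scatter <- matrix(0, d, d)
  for (g in seq_len(k)) {
    Xg <- X[f == lev[g], , drop = FALSE]
    means[g, ] <- colMeans(Xg)
    scatter <- scatter + crossprod(sweep(Xg, 2, means[g, ]))
  }
  W <- scatter / (n - k)
  list(levels = lev, counts = counts, means = means, W = W, n = n, d = d, k = k)
}

.ridge_if_singular <- function(W, quiet = FALSE) {
  ok <- tryCatch({ solve(W); TRUE }, error = function(e) FALSE)
  if (!ok) {
    if (!quiet) warn("pooled within-group covariance is singular; ridge-stabilising")
    W <- W + diag(1e-8 * sum(diag(W)) / ncol(W), ncol(W))
  }
  W
}

# discriminant scores under the Gaussian equal-covariance rule:
# x' W^-1 mu_g - mu_g' W^-1 mu_g / 2 + log prior_g
.lda_scores <- function(X, means, Winv, priors) {
  A <- means %*% Winv                       # k x d
  const <- -0.5 * rowSums(A * means) + log(priors)
  sweep(X %*% t(A), 2, const, `+`)
}

.lda_classify <- function(X, means, Winv, priors, lev) {
  sc <- .lda_scores(X, means, Winv, priors)
  factor(lev[max.col(sc, ties.method = "first")], levels = lev)
}

#' Fit a linear discriminant model
#'
#' From-scratch discriminant function analysis: the discriminant axes are
#' the solutions of the generalised eigenproblem `B v = theta W v`, where
#' `W` is the pooled within-group covariance and `B` the between-group
#' scatter of group means about the grand mean (weighted by group sizes).
#' There are `min(k - 1, d)` axes, ordered by decreasing eigenvalue and
#' scaled so that `v' W v = 1`. Classification uses the Gaussian
#' equal-covariance rule with priors proportional to group sample sizes
#' by default (so the chance expectation of correct assignment is driven
#' by relative group sizes, matching the chance null of
#' [expected_accuracy()]).
#'
#' @param data Data frame of observations.
#' @param group Name of the grouping column (default `"species"`).
#' @param traits Trait (predictor) columns.
#' @param priors Optional named or ordered numeric prior vector; default
#'   proportional to group sizes.
#' @return An `egg_lda` object with elements `levels`, `counts`, `means`,
#'   `W`, `Winv`, `axes`, `eigenvalues`, `priors`, `grand_mean`, `traits`.
#' @export
fit_lda <- function(data, group = "species", traits = egg_traits(),
                    priors = NULL) {
  assert_traits(data, traits)
  f <- factor(data[[group]])
  if (nlevels(f) < 2) abort("need at least 2 groups")
  if (any(table(f) < 2)) {
    small <- names(which(table(f) < 2))
    abort(paste0("group(s) with fewer than 2 rows: ", paste(small, collapse = ", ")))
  }
  X <- as.matrix(data[traits])
  st <- .lda_stats(X, f)
  W <- .ridge_if_singular(st$W)
  Winv <- solve(W)
  if (is.null(priors)) {
    priors <- st$counts / st$n
  } else {
    if (!is.null(names(priors))) priors <- priors[st$levels]
    priors <- priors / sum(priors)
  }
  grand <- colSums(st$means * st$counts) / st$n
  dev <- sweep(st$means, 2, grand)
  B <- crossprod(dev * sqrt(st$counts))    # sum_g n_g (mu_g - mu)(mu_g - mu)'
  U <- chol(W)
  Uinv <- backsolve(U, diag(st$d))
  Bstar <- t(Uinv) %*% B %*% Uinv
  ev <- eigen((Bstar + t(Bstar)) / 2, symmetric = TRUE)
  m <- min(st$k - 1, st$d)
  axes <- Uinv %*% ev$vectors[, seq_len(m), drop = FALSE]
  dimnames(axes) <- list(traits, paste0("DF", seq_len(m)))
  structure(
    list(levels = st$levels, counts = stats::setNames(st$counts, st$levels),
         means = st$means, W = W, Winv = Winv,
         axes = axes, eigenvalues = ev$values[seq_len(m)],
         priors = stats::setNames(priors, st$levels),
         grand_mean = grand, traits = traits, group = group, n = st$n),
    class = "egg_lda"
  )
}

#' @export
print.egg_lda <- function(x, ...) {
  cat("<egg_lda> ", length(x$levels), " groups, ", length(x$traits),
      " traits, ", ncol(x$axes), " discriminant axes\n", sep = "")
  invisible(x)
}

#' Predict group membership from a discriminant model
#'
#' @param object An `egg_lda` model.
#' @param newdata Data frame with the model's trait columns.
#' @param type `"class"` for labels, `"score"` for the per-group
#'   discriminant scores.
#' @param ... Unused.
#' @return Factor of assigned groups, or a score matrix.
#' @export
predict.egg_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$traits, names(newdata))
  if (length(missing)) {
    abort(paste0("newdata lacks trait column(s): ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(newdata[object$traits])
  if (type == "score") {
    return(.lda_scores(X, object$means, object$Winv, object$priors))
  }
  .lda_classify(X, object$means, object$Winv, object$priors, object$levels)
}

#' @exportS3Method generics::tidy
tidy.egg_lda <- function(x, ...) {
  axes <- x$axes
  tibble(
    axis = rep(colnames(axes), each = nrow(axes)),
    trait = rep(rownames(axes), times = ncol(axes)),
    coefficient = as.numeric(axes),
    eigenvalue = rep(x$eigenvalues, each = nrow(axes))
  )
}

#' @exportS3Method generics::glance
glance.egg_lda <- function(x, ...) {
  tibble(n = x$n, n_groups = length(x$levels), n_traits = length(x$traits),
         n_axes = ncol(x$axes))
}

new_confusion <- function(tab, lev) {
  correct <- sum(diag(tab))
  n <- sum(tab)
  structure(
    list(confusion = tab, n = n, correct = correct,
         accuracy_pct = 100 * correct / n),
    class = "egg_confusion"
  )
}

#' @export
print.egg_confusion <- function(x, ...) {
  cat("<egg_confusion> ", x$correct, "/", x$n, " correct (",
      sprintf("%.1f", x$accuracy_pct), "%)\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.egg_confusion <- function(x, ...) {
  tibble(n = x$n, correct = x$correct, accuracy_pct = x$accuracy_pct)
}

#' Leave-one-out jack-knifed classification
#'
#' Each observation is omitted in turn, the discriminant model refitted
#' on the remainder, and only the omitted observation classified. The
#' refit is exact (group means, pooled covariance and priors are fully
#' recomputed without the held-out row, via rank-one downdates).
#'
#' @inheritParams fit_lda
#' @return An `egg_confusion`: confusion matrix (rows = true group,
#'   columns = assigned), total correct and accuracy.
#' @export
jackknife_accuracy <- function(data, group = "species", traits = egg_traits(),
                               priors = NULL) {
  assert_traits(data, traits)
  f <- factor(data[[group]])
  lev <- levels(f)
  counts <- table(f)
  if (any(counts < 2)) {
    abort(paste0("group(s) of size 1 cannot be jack-knifed: ",
                 paste(names(which(counts < 2)), collapse = ", ")))
  }
  X <- as.matrix(data[traits])
  n <- nrow(X); d <- ncol(X); k <- length(lev)
  gi <- as.integer(f)
  sums <- rowsum(X, f)                          # k x d group sums
  Ts <- lapply(seq_len(k), function(g) crossprod(X[gi == g, , drop = FALSE]))
  nc <- as.integer(counts)
  means_full <- sums / nc
  scatters <- lapply(seq_len(k), function(g) {
    Ts[[g]] - nc[g] * tcrossprod(means_full[g, ])
  })
  scatter_tot <- Reduce(`+`, scatters)
  fixed_priors <- !is.null(priors)
  if (fixed_priors) {
    if (!is.null(names(priors))) priors <- priors[lev]
    priors <- priors / sum(priors)
  }
  assigned <- integer(n)
  for (i in seq_len(n)) {
    g <- gi[i]; xi <- X[i, ]
    ng <- nc[g] - 1L
    mu_g <- (sums[g, ] - xi) / ng
    scatter_g <- Ts[[g]] - tcrossprod(xi) - ng * tcrossprod(mu_g)
    W <- (scatter_tot - scatters[[g]] + scatter_g) / (n - 1 - k)
    W <- .ridge_if_singular(W, quiet = TRUE)
    means <- means_full
    means[g, ] <- mu_g
    pr <- if (fixed_priors) priors else {
      cc <- nc; cc[g] <- ng; cc / (n - 1)
    }
    sc <- .lda_scores(matrix(xi, 1), means, solve(W), pr)
    assigned[i] <- max.col(sc, ties.method = "first")
  }
  tab <- table(true = factor(lev[gi], levels = lev),
               assigned = factor(lev[assigned], levels = lev))
  new_confusion(tab, lev)
}

#' Monte-Carlo sample-splitting classification accuracy
#'
#' Repeated stratified random splits into training and test sets; the
#' discriminant model is fitted on the training rows and scored on the
#' held-out rows. A cross-check on jack-knifed accuracy that keeps the
#' test set disjoint from fitting.
#'
#' @inheritParams fit_lda
#' @param train_fraction Fraction of each group used for training.
#' @param n_reps Number of random splits.
#' @param seed Integer seed.
#' @return An `egg_mc_split` with `$accuracies` (tibble `rep`,
#'   `accuracy_pct`) and `$mean_pct`.
#' @export
monte_carlo_split_accuracy <- function(data, group = "species",
                                       traits = egg_traits(),
                                       train_fraction = 0.75, n_reps = 100,
                                       seed = 1L, priors = NULL) {
  assert_traits(data, traits)
  f <- factor(data[[group]])
  counts <- table(f)
  n_train <- pmax(2L, round(train_fraction * as.integer(counts)))
  if (any(n_train >= counts)) {
    abort("stratified split infeasible: a group would have an empty test set (need >= 3 rows per group)")
  }
  X <- as.matrix(data[traits])
  gi <- as.integer(f); lev <- levels(f)
  acc <- with_seed(as.integer(seed), {
    vapply(seq_len(n_reps), function(r) {
      tr_idx <- unlist(lapply(seq_along(lev), function(g) {
        idx <- which(gi == g)
        idx[sample.int(length(idx), n_train[g])]
      }))
      ftr <- factor(lev[gi[tr_idx]], levels = lev)
      st <- .lda_stats(X[tr_idx, , drop = FALSE], ftr)
      W <- .ridge_if_singular(st$W, quiet = TRUE)
      pr <- if (is.null(priors)) st$counts / st$n else {
        p <- if (!is.null(names(priors))) priors[lev] else priors
        p / sum(p)
      }
      pred <- .lda_classify(X[-tr_idx, , drop = FALSE], st$means, solve(W),
                            pr, lev)
      100 * mean(pred == lev[gi[-tr_idx]])
    }, numeric(1))
  })
  structure(
    list(accuracies = tibble(rep = seq_len(n_reps), accuracy_pct = acc),
         mean_pct = mean(acc), train_fraction = train_fraction,
         n_reps = n_reps),
    class = "egg_mc_split"
  )
}

#' @export
print.egg_mc_split <- function(x, ...) {
  cat("<egg_mc_split> ", x$n_reps, " splits, mean accuracy ",
      sprintf("%.1f", x$mean_pct), "%\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.egg_mc_split <- function(x, ...) {
  tibble(n_reps = x$n_reps, train_fraction = x$train_fraction,
         mean_accuracy_pct = x$mean_pct,
         sd_accuracy_pct = sd(x$accuracies$accuracy_pct))
}

#' Discriminant-function scores and one-SD ellipses
#'
#' Projects observations onto the first two discriminant axes (DF2 is 0
#' when only one axis exists) and summarises each group by its centroid
#' and the standard deviations of its scores — the one-SD ellipses of the
#' classic partitioning scatterplots.
#'
#' @param model An `egg_lda`.
#' @param data Data frame with the model's trait and group columns.
#' @return List with `scores` (tibble `group`, `df1`, `df2`) and
#'   `ellipses` (tibble `group`, `centroid_df1`, `centroid_df2`,
#'   `sd_df1`, `sd_df2`).
#' @export
df_scores <- function(model, data) {
  stopifnot(inherits(model, "egg_lda"))
  X <- sweep(as.matrix(data[model$traits]), 2, model$grand_mean)
  proj <- X %*% model$axes
  df2 <- if (ncol(proj) >= 2) proj[, 2] else rep(0, nrow(proj))
  scores <- tibble(group = as.character(data[[model$group]]),
                   df1 = proj[, 1], df2 = df2)
  ellipses <- scores %>%
    group_by(.data$group) %>%
    summarise(centroid_df1 = mean(.data$df1), centroid_df2 = mean(.data$df2),
              sd_df1 = sd(.data$df1), sd_df2 = sd(.data$df2),
              .groups = "drop")
  list(scores = scores, ellipses = ellipses)
}
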