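#' Select one egg per clutch
#'
#' Eggs within a clutch are pseudoreplicates; analyses use one egg per
#' clutch, chosen uniformly at random (deterministically for a given
#' seed).
#'
#' @param data Phenotype tibble with a `clutch_id` column.
#' @param seed Integer seed.
#' @return Tibble with exactly one row per clutch, in clutch order.
#' @export
select_one_egg_per_clutch <- function(data, seed = 1L) {
  if (!"clutch_id" %in% names(data)) abort("data must have a clutch_id column")
  with_seed(as.integer(seed), {
    data %>%
      group_by(.data$clutch_id) %>%
      slice_sample(n = 1) %>%
      ungroup() %>%
      arrange(match(.data$clutch_id, unique(data$clutch_id)))
  })
}

#' Flag and remove multivariate outliers by Mahalanobis distance
#'
#' Squared Mahalanobis distances to the pooled trait mean under the pooled
#' covariance are compared against the upper-`alpha` quantile of the
#' chi-square distribution with one degree of freedom per trait. Rows
#' above the cutoff are removed and reported.
#'
#' @param data Phenotype tibble.
#' @param alpha Upper tail probability for the chi-square cutoff
#'   (default 0.001, a conservative screen).
#' @param traits Trait columns to use.
#' @return List with `clean` (tibble of retained rows), `flagged` (tibble
#'   of removed rows with their `d2` distances), and `cutoff`.
#' @export
mahalanobis_outliers <- function(data, alpha = 0.001, traits = egg_traits()) {
  assert_traits(data, traits)
  X <- as.matrix(data[traits])
  if (nrow(X) <= ncol(X)) abort("need more rows than traits for a pooled covariance")
  S <- stats::cov(X)
  d2 <- tryCatch(
    stats::mahalanobis(X, colMeans(X), S),
    error = function(e) {
      abort(paste0("pooled covariance is singular; run collinearity_screen() ",
                   "and drop redundant traits first"))
    }
  )
  cutoff <- qchisq(1 - alpha, df = length(traits))
  out <- d2 > cutoff
  list(
    clean = as_tibble(data[!out, , drop = FALSE]),
    flagged = bind_cols(as_tibble(data[out, , drop = FALSE]),
                        tibble(d2 = d2[out])),
    cutoff = cutoff
  )
}

#' Screen trait pairs for collinearity
#'
#' Lists all trait pairs whose absolute Pearson correlation exceeds the
#' threshold and suggests one trait of each pair to drop. When exactly
#' the photon-catch pairs UV-MW and SW-LW trigger — the collinearity
#' structure real catches show — the suggestion is to drop MW and LW
#' (keeping the shorter-wavelength member of each pair); otherwise the
#' later trait (in canonical order) of each flagged pair is suggested.
#'
#' @param data Phenotype tibble (>= 3 rows).
#' @param r_threshold Absolute correlation threshold (default 0.8).
#' @param traits Trait columns to screen.
#' @return List with `pairs` (tibble `trait_a`, `trait_b`, `r`) and
#'   `suggested_drops` (character vector).
#' @export
collinearity_screen <- function(data, r_threshold = 0.8, traits = egg_traits()) {
  assert_traits(data, traits)
  if (nrow(data) < 3) abort("need at least 3 rows")
  X <- as.matrix(data[traits])
  const <- apply(X, 2, function(v) sd(v) < 1e-12)
  if (any(const)) {
    warn(paste0("constant column(s) excluded from correlations: ",
                paste(traits[const], collapse = ", ")))
    traits <- traits[!const]
    X <- X[, traits, drop = FALSE]
  }
  R <- cor(X)
  idx <- which(upper.tri(R) & abs(R) > r_threshold, arr.ind = TRUE)
  pairs <- tibble(
    trait_a = traits[idx[, 1]],
    trait_b = traits[idx[, 2]],
    r = R[idx]
  ) %>% arrange(dplyr::desc(abs(.data$r)))
  canonical <- nrow(pairs) == 2 &&
    setequal(paste(pairs$trait_a, pairs$trait_b),
             c("uv mw", "sw lw"))
  drops <- if (canonical) {
    c("mw", "lw")
  } else if (nrow(pairs)) {
    later <- function(a, b) {
      ord <- match(c(a, b), traits)
      c(a, b)[which.max(ord)]
    }
    unique(purrr::map2_chr(pairs$trait_a, pairs$trait_b, later))
  } else {
    character(0)
  }
  list(pairs = pairs, suggested_drops = drops)
}

#' Arcsine-square-root transform of the active traits
#'
#' Each trait is min-max scaled to \[0, 1\] (scaling recorded for the
#' inverse) and then mapped through `asin(sqrt(x))`, the classic
#' variance-stabilising transform for proportions.
#'
#' @param data Phenotype tibble.
#' @param traits Trait columns to transform.
#' @param scaling Optional scaling tibble (`trait`, `min`, `max`) from a
#'   previous call, to apply identical scaling to new data.
#' @return Transformed tibble carrying the scaling in
#'   `attr(, "scaling")`.
#' @export
arcsine_sqrt_transform <- function(data, traits = egg_traits(), scaling = NULL) {
  assert_traits(data, traits)
  if (is.null(scaling)) {
    scaling <- tibble(
      trait = traits,
      min = vapply(data[traits], min, numeric(1)),
      max = vapply(data[traits], max, numeric(1))
    )
  }
  out <- data
  for (i in seq_along(traits)) {
    tr <- traits[i]
    rng <- scaling[scaling$trait == tr, ]
    span <- rng$max - rng$min
    x <- if (span > 0) (out[[tr]] - rng$min) / span else rep(0, nrow(out))
    if (any(x < -1e-9 | x > 1 + 1e-9)) {
      abort(paste0("trait '", tr, "' falls outside [0, 1] after scaling"))
    }
    out[[tr]] <- asin(sqrt(pmin(pmax(x, 0), 1)))
  }
  attr(out, "scaling") <- scaling
  out
}

#' @rdname arcsine_sqrt_transform
#' @param transformed Output of `arcsine_sqrt_transform()` (or any tibble
#'   plus an explicit `scaling`).
#' @return `inverse_arcsine_sqrt()`: the back-transformed tibble.
#' @export
inverse_arcsine_sqrt <- function(transformed, traits = egg_traits(),
                                 scaling = attr(transformed, "scaling")) {
  if (is.null(scaling)) abort("no scaling attached; pass `scaling` explicitly")
  out <- transformed
  for (tr in traits) {
    rng <- scaling[scaling$trait == tr, ]
    x <- sin(out[[tr]])^2
    out[[tr]] <- x * (rng$max - rng$min) + rng$min
  }
  attr(out, "scaling") <- NULL
  out
}

#' One-call data hygiene
#'
#' Applies, in order: one egg per clutch, Mahalanobis outlier removal,
#' collinearity screening (optionally dropping the suggested traits), and
#' optionally the arcsine-square-root transform. The companion sidecar
#' records what was done.
#'
#' @param data Phenotype tibble.
#' @param outlier_alpha Chi-square tail for outlier removal; `NULL` skips.
#' @param drop_collinear Drop the traits suggested by
#'   [collinearity_screen()]?
#' @param transform Apply [arcsine_sqrt_transform()]?
#' @param r_threshold Collinearity threshold.
#' @param traits Trait columns.
#' @param seed Seed for the clutch selection.
#' @return List with `data` (cleaned tibble), `traits` (active trait set
#'   after drops), and `sidecar` (list recording flags, drops, scaling,
#'   seeds).
#' @export
preprocess_phenotypes <- function(data, outlier_alpha = 0.001,
                                  drop_collinear = FALSE, transform = FALSE,
                                  r_threshold = 0.8, traits = egg_traits(),
                                  seed = 1L) {
  sidecar <- list(seed = seed, outlier_alpha = outlier_alpha,
                  r_threshold = r_threshold)
  out <- select_one_egg_per_clutch(data, seed = seed)
  if (!is.null(outlier_alpha)) {
    mo <- mahalanobis_outliers(out, alpha = outlier_alpha, traits = traits)
    out <- mo$clean
    sidecar$outliers <- mo$flagged[c("species", "clutch_id", "d2")]
  }
  scr <- collinearity_screen(out, r_threshold = r_threshold, traits = traits)
  sidecar$collinear_pairs <- scr$pairs
  if (drop_collinear && length(scr$suggested_drops)) {
    traits <- setdiff(traits, scr$suggested_drops)
    sidecar$dropped_traits <- scr$suggested_drops
  }
  if (transform) {
    out <- arcsine_sqrt_transform(out, traits = traits)
    sidecar$scaling <- attr(out, "scaling")
  }
  list(data = out, traits = traits, sidecar = sidecar)
}
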