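# shared fixtures and independent oracles, all built in code

# simple Gaussian group data with generic trait names v1..vd
gauss_groups <- function(n_per, means, sd = 1, seed = 1) {
  d <- length(means[[1]])
  withr::with_seed(seed, {
    purrr::map_dfr(seq_along(means), function(g) {
      X <- matrix(rnorm(n_per * d, sd = sd), n_per, d)
      X <- sweep(X, 2, means[[g]], `+`)
      colnames(X) <- paste0("v", seq_len(d))
      dplyr::bind_cols(tibble::tibble(species = sprintf("g%d", g)),
                       tibble::as_tibble(X))
    })
  })
}

gtraits <- function(d) paste0("v", seq_len(d))

# literal leave-one-out loop: refit with fit_lda and classify the held-out
# row; the oracle jackknife_accuracy must match exactly
naive_jackknife_correct <- function(data, traits, group = "species") {
  n <- nrow(data)
  correct <- 0L
  for (i in seq_len(n)) {
    m <- fit_lda(data[-i, ], group = group, traits = traits)
    pred <- predict(m, data[i, ])
    if (as.character(pred) == as.character(data[[group]][i])) {
      correct <- correct + 1L
    }
  }
  correct
}

# brute-force Gaussian equal-covariance posterior classifier
posterior_classify <- function(X, means, W, priors, lev) {
  apply(X, 1, function(x) {
    dens <- vapply(seq_along(lev), function(g) {
      v <- x - means[g, ]
      exp(-0.5 * drop(v %*% solve(W, v))) * priors[g]
    }, numeric(1))
    lev[which.max(dens)]
  })
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  a_all <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(a_all, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Welch's t on midranks, written out from the formula
welch_on_ranks_manual <- function(a, b) {
  r <- rank(c(a, b))
  ra <- r[seq_along(a)]; rb <- r[-seq_along(a)]
  na <- length(ra); nb <- length(rb)
  va <- var(ra) / na; vb <- var(rb) / nb
  tstat <- (mean(ra) - mean(rb)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(statistic = tstat, df = df, p = p)
}

# small phenotype table wrapper: relabel generic columns as a host/unpar table
as_phenotype_roles <- function(data, parasitized_groups) {
  dplyr::mutate(data,
    clutch_id = sprintf("c%04d", dplyr::row_number()),
    role = ifelse(species %in% parasitized_groups, "host", "unparasitized"),
    target_host = NA_character_)
}

# an elliptical egg mask without spots
elliptical_mask_for_test <- function(h, w) {
  eggspace::generate_spot_image(w, h, 4, coverage_target = 0)$mask
}
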