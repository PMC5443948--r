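test_that("discriminant axes recover a mean difference along a single trait", {
  dat <- gauss_groups(60, list(c(0, 0, 0), c(3, 0, 0)), seed = 1)
  m <- fit_lda(dat, traits = gtraits(3))
  a <- m$axes[, 1] / sqrt(sum(m$axes[, 1]^2))
  expect_gt(abs(a[1]), 0.95)             # DF1 is essentially (1, 0, 0)
  expect_equal(ncol(m$axes), 1)          # min(k - 1, d) axes
  dat4 <- gauss_groups(30, list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), seed = 2)
  expect_equal(ncol(fit_lda(dat4, traits = gtraits(2))$axes), 2)
})

test_that("LDA coefficients and classifications agree with MASS::lda", {
  skip_if_not_installed("MASS")
  for (seed in c(3, 4)) {
    dat <- gauss_groups(50, list(c(0, 0, 0, 0), c(1.5, 0.5, 0, 0),
                                 c(0, 0, 1.5, -0.5)), seed = seed)
    m <- fit_lda(dat, traits = gtraits(4))
    ml <- MASS::lda(species ~ v1 + v2 + v3 + v4, dat)
    for (j in 1:2) {
      expect_gt(abs(cor(m$axes[, j], ml$scaling[, j])), 0.999)
    }
    expect_equal(as.character(predict(m, dat)),
                 as.character(predict(ml, dat)$class))
  }
})

test_that("classification equals the brute-force Gaussian posterior rule", {
  dat <- gauss_groups(40, list(c(0, 0, 0), c(1, 1, 0), c(-1, 0, 1)), seed = 5)
  m <- fit_lda(dat, traits = gtraits(3))
  set.seed(6)
  Xq <- matrix(rnorm(200 * 3, sd = 1.5), 200, 3)
  colnames(Xq) <- gtraits(3)
  oracle <- posterior_classify(Xq, m$means, m$W, m$priors, m$levels)
  ours <- as.character(predict(m, tibble::as_tibble(Xq)))
  expect_identical(ours, oracle)
})

test_that("point at a group mean and prior-weighted midpoints classify as specified", {
  dat <- gauss_groups(30, list(c(0, 0), c(2, 0)), seed = 7)
  m_eq <- fit_lda(dat, traits = gtraits(2), priors = c(0.5, 0.5))
  at_mean <- tibble::as_tibble(matrix(m_eq$means["g1", ], 1,
                                      dimnames = list(NULL, gtraits(2))))
  expect_equal(as.character(predict(m_eq, at_mean)), "g1")
  # exact midpoint with unequal priors goes to the larger prior
  m_un <- fit_lda(dat, traits = gtraits(2), priors = c(0.2, 0.8))
  mid <- tibble::as_tibble(matrix(colMeans(m_un$means), 1,
                                  dimnames = list(NULL, gtraits(2))))
  expect_equal(as.character(predict(m_un, mid)), "g2")
})

test_that("classification is invariant under nonsingular affine trait transforms", {
  dat <- gauss_groups(40, list(c(0, 0, 0), c(1.2, -0.4, 0.6)), seed = 8)
  m <- fit_lda(dat, traits = gtraits(3))
  set.seed(9)
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  b <- rnorm(3)
  X2 <- sweep(as.matrix(dat[gtraits(3)]) %*% A, 2, b, `+`)
  dat2 <- dat
  dat2[gtraits(3)] <- X2
  m2 <- fit_lda(dat2, traits = gtraits(3))
  expect_identical(as.character(predict(m, dat)),
                   as.character(predict(m2, dat2)))
})

test_that("jack-knife equals a naive per-row refit loop on a 60-row fixture", {
  dat <- gauss_groups(20, list(c(0, 0, 0), c(1, 0.5, 0), c(0.5, -1, 0.5)),
                      seed = 10)
  jk <- jackknife_accuracy(dat, traits = gtraits(3))
  expect_equal(jk$correct, naive_jackknife_correct(dat, gtraits(3)))
  expect_equal(sum(jk$confusion), 60)
  expect_equal(unname(rowSums(jk$confusion)), rep(20L, 3))
})

test_that("jack-knife hits the separability extremes and rejects singleton groups", {
  far <- gauss_groups(25, list(c(0, 0), c(20, 0)), seed = 11)
  expect_equal(jackknife_accuracy(far, traits = gtraits(2))$accuracy_pct, 100)
  same <- gauss_groups(50, list(c(0, 0), c(0, 0)), seed = 12)
  acc <- jackknife_accuracy(same, traits = gtraits(2))$accuracy_pct
  expect_lt(abs(acc - 50), 15)
  solo <- dplyr::bind_rows(far, tibble::tibble(species = "g9", v1 = 0, v2 = 0))
  expect_error(jackknife_accuracy(solo, traits = gtraits(2)), "g9")
})

test_that("jack-knife is no more optimistic than resubstitution on average", {
  diffs <- vapply(1:100, function(s) {
    dat <- gauss_groups(15, list(c(0, 0, 0), c(0.8, 0.4, 0)), seed = 100 + s)
    m <- fit_lda(dat, traits = gtraits(3))
    resub <- mean(predict(m, dat) == dat$species)
    jk <- jackknife_accuracy(dat, traits = gtraits(3))$accuracy_pct / 100
    resub - jk
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("Monte-Carlo splitting is deterministic, exact on separated data, and tracks the jack-knife", {
  far <- gauss_groups(20, list(c(0, 0), c(15, 0)), seed = 13)
  mc <- monte_carlo_split_accuracy(far, traits = gtraits(2), n_reps = 20, seed = 1)
  expect_equal(mc$mean_pct, 100)
  mc2 <- monte_carlo_split_accuracy(far, traits = gtraits(2), n_reps = 20, seed = 1)
  expect_identical(mc$accuracies, mc2$accuracies)

  mid <- gauss_groups(60, list(c(0, 0, 0), c(1.6, 0.8, 0)), seed = 14)
  jk <- jackknife_accuracy(mid, traits = gtraits(3))$accuracy_pct
  mc <- monte_carlo_split_accuracy(mid, traits = gtraits(3), n_reps = 100,
                                   seed = 2)
  expect_lt(abs(mc$mean_pct - jk), 5)
})

test_that("multinomial logistic fit satisfies its own optimality conditions", {
  dat <- gauss_groups(40, list(c(0, 0, 0), c(1, 0.6, 0), c(-0.8, 0.4, 0.8)),
                      seed = 15)
  fit <- fit_multinomial_logistic(dat, traits = gtraits(3))
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-6)

  # independent finite-difference gradient of the penalised log-likelihood
  X <- as.matrix(dat[gtraits(3)]); Xd <- cbind(1, X)
  y <- as.integer(factor(dat$species))
  ll <- function(Bvec) {
    B <- matrix(Bvec, ncol(Xd))
    eta <- cbind(Xd %*% B, 0)
    P <- exp(eta - apply(eta, 1, max))
    P <- P / rowSums(P)
    sum(log(P[cbind(seq_along(y), y)])) - 0.5 * fit$ridge * sum(B[-1, ]^2)
  }
  b0 <- as.numeric(fit$Beta)
  num_grad <- vapply(seq_along(b0), function(j) {
    h <- 1e-6
    e <- numeric(length(b0)); e[j] <- h
    (ll(b0 + e) - ll(b0 - e)) / (2 * h)
  }, numeric(1))
  expect_lt(sqrt(sum(num_grad^2)), 1e-3)
})

test_that("multinomial logistic handles separable and symmetric cases", {
  far <- gauss_groups(20, list(c(0, 0), c(10, 0)), seed = 16)
  fit <- fit_multinomial_logistic(far, traits = gtraits(2))
  expect_equal(mean(predict(fit, far) == far$species), 1)

  # mirror-symmetric two-group data: the grand centroid is a 50/50 point
  set.seed(99)
  base <- matrix(rnorm(60), 30, 2)
  sym <- tibble::tibble(
    species = rep(c("a", "b"), each = 30),
    v1 = c(base[, 1] + 1, -base[, 1] - 1),
    v2 = c(base[, 2], -base[, 2])
  )
  fit <- fit_multinomial_logistic(sym, traits = gtraits(2))
  centroid <- tibble::tibble(v1 = 0, v2 = 0)
  p <- predict(fit, centroid, type = "prob")
  expect_equal(unname(p[1, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("logistic regression agrees with nnet::multinom and with LDA accuracy", {
  skip_if_not_installed("nnet")
  dat <- gauss_groups(60, list(c(0, 0, 0), c(1.2, 0.6, 0), c(0, -1, 0.8)),
                      seed = 17)
  fit <- fit_multinomial_logistic(dat, traits = gtraits(3))
  nn <- nnet::multinom(species ~ v1 + v2 + v3, dat, trace = FALSE)
  agree <- mean(predict(fit, dat) == predict(nn, dat))
  expect_gt(agree, 0.98)
  acc_log <- 100 * mean(predict(fit, dat) == dat$species)
  acc_lda <- 100 * mean(predict(fit_lda(dat, traits = gtraits(3)), dat) ==
                          dat$species)
  expect_lt(abs(acc_log - acc_lda), 5)
})

test_that("discriminant scores and SD ellipses match direct recomputation", {
  dat <- gauss_groups(40, list(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)), seed = 18)
  m <- fit_lda(dat, traits = gtraits(3))
  ds <- df_scores(m, dat)
  for (g in unique(dat$species)) {
    sub <- ds$scores[ds$scores$group == g, ]
    ell <- ds$ellipses[ds$ellipses$group == g, ]
    expect_equal(ell$centroid_df1, mean(sub$df1))
    expect_equal(ell$sd_df1, sd(sub$df1))
    expect_equal(ell$sd_df2, sd(sub$df2))
  }
  # rescaling all traits rescales scores but not classifications
  dat2 <- dat
  dat2[gtraits(3)] <- dat[gtraits(3)] * 2
  m2 <- fit_lda(dat2, traits = gtraits(3))
  expect_identical(as.character(predict(m, dat)),
                   as.character(predict(m2, dat2)))
})

test_that("models round-trip through JSON serialisation", {
  dat <- gauss_groups(30, list(c(0, 0, 0), c(1.5, 0, 0)), seed = 19)
  m <- fit_lda(dat, traits = gtraits(3))
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_json(m, path)
  back <- read_lda_json(path)
  expect_identical(as.character(predict(back, dat)),
                   as.character(predict(m, dat)))
  expect_equal(back$axes, m$axes, tolerance = 1e-12)
})

test_that("tidy and glance methods return the documented shapes", {
  dat <- gauss_groups(30, list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), seed = 20)
  m <- fit_lda(dat, traits = gtraits(3))
  td <- generics::tidy(m)
  expect_equal(nrow(td), 2 * 3)          # 2 axes x 3 traits
  gl <- generics::glance(m)
  expect_equal(gl$n_axes, 2)
  fit <- fit_multinomial_logistic(dat, traits = gtraits(3))
  expect_equal(nrow(generics::tidy(fit)), 4 * 2)
  expect_true(generics::glance(fit)$converged)
})
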