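# softmax probabilities with the last class as reference
.softmax_probs <- function(Xd, Beta) {
  eta <- cbind(Xd %*% Beta, 0)
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta)
  P / rowSums(P)
}

.multinom_loglik <- function(Xd, Y, Beta, ridge) {
  P <- .softmax_probs(Xd, Beta)
  ll <- sum(log(pmax(P[Y], 1e-300)))
  pen <- 0.5 * ridge * sum(Beta[-1, ]^2)   # intercepts unpenalised
  ll - pen
}

.multinom_grad <- function(Xd, Ymat, Beta, ridge) {
  P <- .softmax_probs(Xd, Beta)
  Km1 <- ncol(Beta)
  G <- crossprod(Xd, Ymat[, seq_len(Km1), drop = FALSE] -
                   P[, seq_len(Km1), drop = FALSE])
  G[-1, ] <- G[-1, ] - ridge * Beta[-1, ]
  G
}

#' Multinomial logistic regression by penalised Newton iteration
#'
#' A from-scratch softmax classifier fitted by full Newton steps on the
#' ridge-penalised multinomial log-likelihood (intercepts unpenalised),
#' with step halving if a step does not improve the objective. A small
#' default ridge keeps the optimum finite on linearly separable data,
#' where the unpenalised likelihood has no maximiser; if fitting is
#' requested with `ridge = 0` and the coefficients diverge, a minimal
#' ridge is applied automatically with a warning.
#'
#' @inheritParams fit_lda
#' @param ridge Penalty on squared coefficients; default `1e-6 * n`.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the Euclidean norm of the
#'   penalised gradient.
#' @return An `egg_multinom` with coefficient matrix `Beta`
#'   ((1 + n_traits) x (k - 1), last group as reference), `levels`,
#'   `loglik`, `grad_norm`, `converged`, `n_iter`, `ridge`.
#' @export
fit_multinomial_logistic <- function(data, group = "species",
                                     traits = egg_traits(), ridge = NULL,
                                     max_iter = 100L, tol = 1e-6) {
  assert_traits(data, traits)
  f <- factor(data[[group]])
  lev <- levels(f)
  K <- length(lev); n <- nrow(data)
  if (K < 2) abort("need at least 2 groups")
  if (n < K) abort("need at least as many rows as groups")
  if (is.null(ridge)) ridge <- 1e-6 * n
  auto_ridge <- FALSE
  X <- as.matrix(data[traits])
  Xd <- cbind(`(intercept)` = 1, X)
  p <- ncol(Xd); Km1 <- K - 1
  Ymat <- matrix(0, n, K); Ymat[cbind(seq_len(n), as.integer(f))] <- 1
  Yidx <- cbind(seq_len(n), as.integer(f))

  fit_once <- function(ridge) {
    Beta <- matrix(0, p, Km1,
                   dimnames = list(colnames(Xd), lev[seq_len(Km1)]))
    ll <- .multinom_loglik(Xd, Yidx, Beta, ridge)
    iter <- 0L
    repeat {
      G <- .multinom_grad(Xd, Ymat, Beta, ridge)
      gnorm <- sqrt(sum(G^2))
      if (gnorm < tol || iter >= max_iter) break
      P <- .softmax_probs(Xd, Beta)
      H <- matrix(0, p * Km1, p * Km1)
      for (j in seq_len(Km1)) for (kk in j:Km1) {
        w <- P[, j] * ((j == kk) - P[, kk])
        blk <- crossprod(Xd, Xd * w)
        rows <- (j - 1) * p + seq_len(p)
        cols <- (kk - 1) * p + seq_len(p)
        H[rows, cols] <- blk
        if (kk != j) H[cols, rows] <- t(blk)
      }
      pen_diag <- rep(c(0, rep(ridge, p - 1)), Km1)
      H <- H + diag(pen_diag, p * Km1)
      step <- tryCatch(solve(H, as.numeric(G)), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      s <- 1
      repeat {
        Bnew <- Beta + matrix(s * step, p, Km1)
        llnew <- .multinom_loglik(Xd, Yidx, Bnew, ridge)
        if (is.finite(llnew) && llnew >= ll - 1e-12) break
        s <- s / 2
        if (s < 1e-10) { Bnew <- Beta; llnew <- ll; break }
      }
      if (max(abs(Bnew)) > 1e8) return(NULL)   # diverging
      Beta <- Bnew; ll <- llnew
      iter <- iter + 1L
    }
    gnorm <- sqrt(sum(.multinom_grad(Xd, Ymat, Beta, ridge)^2))
    list(Beta = Beta, loglik = ll, grad_norm = gnorm,
         converged = gnorm < tol, n_iter = iter)
  }

  res <- fit_once(ridge)
  if (is.null(res) || (!res$converged && ridge == 0)) {
    auto_ridge <- TRUE
    ridge <- 1e-6 * n
    warn("fit diverged without a ridge (separable data?); refitting with minimal ridge")
    res <- fit_once(ridge)
  }
  if (is.null(res)) abort("multinomial logistic fit failed")
  structure(
    c(res, list(levels = lev, traits = traits, group = group,
                ridge = ridge, auto_ridge = auto_ridge, n = n)),
    class = "egg_multinom"
  )
}

#' @export
print.egg_multinom <- function(x, ...) {
  cat("<egg_multinom> ", length(x$levels), " groups, loglik ",
      sprintf("%.2f", x$loglik), ", ",
      if (x$converged) "converged" else "max_iter reached",
      " after ", x$n_iter, " Newton steps\n", sep = "")
  invisible(x)
}

#' Predict from a multinomial logistic model
#'
#' @param object An `egg_multinom`.
#' @param newdata Data frame with the model's trait columns.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of classes or a matrix of class probabilities.
#' @export
predict.egg_multinom <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[object$traits])
  Xd <- cbind(1, X)
  P <- .softmax_probs(Xd, object$Beta)
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' @rdname predict.egg_multinom
#' @param model An `egg_multinom`.
#' @param data Data to classify.
#' @export
classify_logistic <- function(model, data) predict(model, data, type = "class")

#' @exportS3Method generics::tidy
tidy.egg_multinom <- function(x, ...) {
  B <- x$Beta
  tibble(
    group = rep(colnames(B), each = nrow(B)),
    term = rep(rownames(B), times = ncol(B)),
    estimate = as.numeric(B)
  )
}

#' @exportS3Method generics::glance
glance.egg_multinom <- function(x, ...) {
  tibble(n = x$n, n_groups = length(x$levels), loglik = x$loglik,
         grad_norm = x$grad_norm, converged = x$converged,
         n_iter = x$n_iter, ridge = x$ridge)
}
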