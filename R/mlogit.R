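# Weighted multinomial logistic regression by Newton-Raphson.
#
# Reference outcome is category 0 ("stay"); non-reference outcomes 1..J each
# get a coefficient vector, eta_j = X b_j, with
#   P(y = j | x) = exp(eta_j) / (1 + sum_k exp(eta_k)),   P(y = 0) = 1 / (...).
# The full (p*J) Newton system uses the exact Fisher information
#   I = sum_i w_i x_i x_i^T (x) (diag(P_i) - P_i P_i^T)
# which is small here (p <= 4, J <= 4), so each iteration is a handful of
# dense matrix products; step-halving guards the ascent.

row_max0 <- function(eta) {
  # rowwise max of cbind(0, eta) without apply(); J is tiny
  m <- pmax(0, eta[, 1])
  j <- 2L
  while (j <= ncol(eta)) { m <- pmax(m, eta[, j]); j <- j + 1L }
  m
}

mlogit_loglik <- function(eta, y, w) {
  # log-sum-exp with the implicit reference column of zeros
  m <- row_max0(eta)
  lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
  pick <- rep(0, length(y))
  nz <- y > 0L
  pick[nz] <- eta[cbind(which(nz), y[nz])]
  sum(w * (pick - lse))
}

mlogit_probs <- function(eta) {
  m <- row_max0(eta)
  denom <- exp(-m) + rowSums(exp(eta - m))
  exp(eta - m) / denom
}

#' Weighted multinomial logit fit (internal engine)
#'
#' @param X numeric design matrix (n x p), including the intercept column.
#' @param y integer outcome, 0 = reference ("stay"), 1..J = other outcomes.
#' @param w positive case weights.
#' @param tol convergence tolerance on the max absolute score component.
#' @param max_iter Newton iteration cap.
#' @param start optional p x J starting coefficient matrix (warm start).
#' @return list(coef = p x J matrix, converged, iterations, loglik,
#'   separation = TRUE if coefficients diverged).
#' @keywords internal
fit_mlogit <- function(X, y, w, tol = 1e-9, max_iter = 60L, start = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X); J <- max(y)
  stopifnot(J >= 1L, length(y) == n, length(w) == n, all(w > 0))
  Y <- matrix(0, n, J)
  nz <- y > 0L
  Y[cbind(which(nz), y[nz])] <- 1

  if (!is.null(start)) {
    stopifnot(nrow(start) == p, ncol(start) == J)
    B <- start
  } else {
    B <- matrix(0, p, J)
    # intercept warm start at the empirical weighted log-odds
    w0 <- sum(w[y == 0L])
    if (w0 > 0) {
      for (j in seq_len(J)) {
        wj <- sum(w[y == j])
        if (wj > 0) B[1, j] <- log(wj / w0)
      }
    }
  }

  ll <- mlogit_loglik(X %*% B, y, w)
  converged <- FALSE
  separation <- FALSE
  it <- 0L
  # score tolerance on the scale of the total weight (score entries are
  # weighted sums of residuals times covariates)
  gtol <- 1e-8 * max(1, sum(w))

  while (it < max_iter) {
    it <- it + 1L
    eta <- X %*% B
    P <- mlogit_probs(eta)                      # n x J
    G <- crossprod(X, w * (Y - P))              # p x J score
    if (max(abs(G)) < gtol) { converged <- TRUE; break }

    # Fisher information, (p*J) x (p*J)
    I <- matrix(0, p * J, p * J)
    for (j in seq_len(J)) {
      for (k in j:J) {
        v <- if (j == k) w * P[, j] * (1 - P[, j]) else -w * P[, j] * P[, k]
        blk <- crossprod(X, X * v)
        rj <- (j - 1L) * p + seq_len(p); rk <- (k - 1L) * p + seq_len(p)
        I[rj, rk] <- blk
        if (j != k) I[rk, rj] <- blk
      }
    }
    step <- tryCatch(solve(I + diag(1e-10, p * J), as.vector(G)),
                     error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }

    # step-halving line search on the log-likelihood
    alpha <- 1
    repeat {
      Bn <- B + matrix(alpha * step, p, J)
      lln <- mlogit_loglik(X %*% Bn, y, w)
      if (is.finite(lln) && lln >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8) break
    B <- Bn
    ll <- lln
    # a full, tiny Newton step means the optimum is resolved well past tol
    if (alpha == 1 && max(abs(step)) < tol) { converged <- TRUE; break }
    if (max(abs(B)) > 30) { separation <- TRUE; break }
  }

  list(coef = B, converged = converged, iterations = it,
       loglik = ll, separation = separation)
}
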