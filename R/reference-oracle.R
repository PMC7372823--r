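# Cleartext twins of the encrypted pipeline plus the original (exactly
# weighted) semi-parallel algorithm.  These are the ground truth the
# encrypted stages are tested against, and the comparator for the accuracy
# metrics: `oracle_modified` reproduces every approximation of the circuit
# (degree-7 sigmoid, fixed Hessian bound, Newton reciprocal, unweighted
# projection) in dense arithmetic, while `oracle_semi_parallel` runs the
# original algorithm with the exact logistic fit and the W-weighted
# projection.

recip_newton <- function(w, iters) {
  x <- rep(3, length(w))
  for (t in seq_len(iters)) x <- x * (2 - w * x)
  x
}

#' Cleartext approximate logistic recursion
#'
#' The dense-arithmetic twin of [hom_logistic_regression()]: zero-initial
#' coefficients, the fixed Newton step `4 (X'X)^{-1}`, and per iteration the
#' coefficient update from the current probabilities followed by the
#' probability refresh from the updated coefficients.
#'
#' @param X Design matrix (intercept first column).
#' @param y Binary response vector.
#' @param kappa Iterations.
#' @param exact_sigmoid Use the exact logistic function instead of the
#'   degree-7 polynomial (for approximation-quality checks).
#' @return A list with `beta` (coefficients) and `p` (probabilities, from
#'   the returned coefficients).
#' @export
oracle_logreg <- function(X, y, kappa = 3L, exact_sigmoid = FALSE) {
  X <- as.matrix(X)
  sig <- if (exact_sigmoid) stats::plogis else sigmoid7
  A4 <- 4 * precompute_xtx_inv(X)
  beta <- numeric(ncol(X))
  p <- rep(0.5, nrow(X))
  for (t in seq_len(kappa)) {
    beta <- beta + as.vector(A4 %*% crossprod(X, y - p))
    p <- as.vector(sig(X %*% beta))
  }
  list(beta = beta, p = p)
}

#' Original semi-parallel GWAS in clear
#'
#' Fits the covariate-only logistic model (full iteratively reweighted least
#' squares to convergence by default), then computes for every SNP column
#' the weighted-projection statistics
#' \deqn{S^* = S - X (X'WX)^{-1} X'WS, \quad z^* = z - X (X'WX)^{-1} X'Wz,}
#' \deqn{b = \frac{(W z^*)' S^*}{\mathrm{colsum}(W (S^*)^2)}, \qquad
#'   err = \frac{1}{\mathrm{colsum}(W (S^*)^2)} .}
#'
#' @param X Design matrix (intercept first).
#' @param y Binary response.
#' @param S Genotype matrix (n x k).
#' @param approx_logreg Use the approximate recursion of [oracle_logreg()]
#'   instead of the converged fit.
#' @param kappa Iterations for the approximate fit.
#' @param weights Optional override of the diagonal working weights.
#' @return A list with vectors `b`, `err`, and the fitted `beta`, `p`.
#' @export
oracle_semi_parallel <- function(X, y, S, approx_logreg = FALSE, kappa = 3L,
                                 weights = NULL) {
  X <- as.matrix(X)
  S <- as.matrix(S)
  if (approx_logreg) {
    fit <- oracle_logreg(X, y, kappa)
    beta <- fit$beta
    p <- fit$p
  } else {
    fit <- stats::glm.fit(X, y, family = stats::binomial(),
                          control = stats::glm.control(epsilon = 1e-10,
                                                       maxit = 50))
    beta <- unname(fit$coefficients)
    p <- fit$fitted.values
  }
  w <- if (is.null(weights)) p * (1 - p) else weights
  XtW <- t(X * w)
  Aw <- solve(XtW %*% X)
  proj <- function(v) v - X %*% (Aw %*% (XtW %*% v))
  S_star <- proj(S)
  z <- as.vector(X %*% beta) + (y - p) / w
  z_star <- as.vector(proj(z))
  den <- unname(colSums(w * S_star^2))
  b <- unname(colSums(S_star * (w * z_star))) / den
  list(b = b, err = 1 / den, beta = beta, p = unname(p))
}

#' Modified semi-parallel GWAS in clear
#'
#' The exact dense twin of the encrypted circuit: approximate logistic
#' recursion, Newton slot reciprocal with initial guess 3, unweighted
#' projection `M = I - X (X'X)^{-1} X'`, and the per-SNP statistics
#' \deqn{b' = \frac{(W z')' S'}{\mathrm{colsum}(W (S')^2)}, \qquad
#'   err' = \frac{1}{\mathrm{colsum}(W (S')^2)} .}
#'
#' @param X Design matrix (intercept first).
#' @param y Binary response.
#' @param S Genotype matrix.
#' @param kappa Logistic iterations.
#' @param recip_iters Newton reciprocal iterations.
#' @param weights Optional override of the working weights (also skips the
#'   Newton reciprocal for the override).
#' @param exact_sigmoid,exact_reciprocal Swap the approximations for their
#'   exact counterparts (approximation-quality guards).
#' @param numerator_weight `"w"` (the defining formula) or `"w_inv"` (the
#'   reciprocal-weight variant).
#' @return A list with `b_prime`, `err_prime`, `numerator`, `denominator`,
#'   `beta`, `p`. Zero-denominator SNPs get `NA` effects.
#' @export
oracle_modified <- function(X, y, S, kappa = 3L, recip_iters = 6L,
                            weights = NULL, exact_sigmoid = FALSE,
                            exact_reciprocal = FALSE,
                            numerator_weight = c("w", "w_inv")) {
  numerator_weight <- match.arg(numerator_weight)
  X <- as.matrix(X)
  S <- as.matrix(S)
  fit <- oracle_logreg(X, y, kappa, exact_sigmoid = exact_sigmoid)
  beta <- fit$beta
  p <- fit$p
  if (is.null(weights)) {
    w <- p * (1 - p)
    w_inv <- if (exact_reciprocal) 1 / w else recip_newton(w, recip_iters)
  } else {
    w <- weights
    w_inv <- 1 / w
  }
  A <- precompute_xtx_inv(X)
  proj <- function(v) v - X %*% (A %*% crossprod(X, v))
  z <- as.vector(X %*% beta) + w_inv * (y - p)
  z_prime <- as.vector(proj(z))
  S_prime <- proj(S)
  u <- if (numerator_weight == "w") w * z_prime else w_inv * z_prime
  numerator <- unname(colSums(S_prime * u))
  denominator <- unname(colSums(w * S_prime^2))
  ok <- abs(denominator) > 1e-8
  b_prime <- err_prime <- rep(NA_real_, ncol(S))
  b_prime[ok] <- numerator[ok] / denominator[ok]
  err_prime[ok] <- 1 / denominator[ok]
  list(b_prime = b_prime, err_prime = err_prime, numerator = numerator,
       denominator = denominator, beta = beta, p = p)
}
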