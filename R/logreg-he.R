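# Approximate logistic regression on the encrypted backend.  The Newton
# update is made HE-friendly twice over: the Hessian is replaced by the
# Boehning-Lindsay bound (X'X)/4, whose inverse is precomputed in clear and
# encrypted as an input, and the sigmoid by a degree-7 polynomial on x/8.

# Degree-7 sigmoid coefficients (odd polynomial in t = x/8 plus 0.5).
# The coefficient magnitudes are the standard least-squares fit on [-8, 8];
# the odd terms are oriented so the polynomial approximates the *increasing*
# logistic 1/(1 + exp(-x)) of the model equation (the source of the fit
# parameterized its sigmoid on the negated linear predictor, so the printed
# signs there belong to 1/(1 + exp(x)); the recursion only converges with
# the increasing orientation).
SIG7 <- c(a1 = 1.73496, a3 = -4.19407, a5 = 5.43402, a7 = -2.50739)

#' Degree-7 polynomial sigmoid
#'
#' \deqn{\sigma_7(x) = 0.5 + 1.73496 (x/8) - 4.19407 (x/8)^3
#'   + 5.43402 (x/8)^5 - 2.50739 (x/8)^7}
#'
#' A least-squares polynomial approximation of the logistic function
#' \eqn{1/(1+e^{-x})}, useful for |x| up to about 8; values outside that
#' range are not clipped. On a cipher it is evaluated as one plaintext
#' multiplication (`x/8`), the square `t^2`, and a nested odd polynomial in
#' `t^2` — four sequential ciphertext-multiplication levels in total.
#'
#' @param x A numeric vector or a `slot_cipher`.
#' @return Same type as `x`.
#' @export
sigmoid7 <- function(x) UseMethod("sigmoid7")

#' @export
sigmoid7.default <- function(x) {
  t <- x / 8
  s <- t * t
  0.5 + t * (SIG7[["a1"]] + s * (SIG7[["a3"]] + s * (SIG7[["a5"]] +
                                                       s * SIG7[["a7"]])))
}

#' @export
sigmoid7.slot_cipher <- function(x) {
  t <- ct_mult(x, 1 / 8)                      # pt-mult
  s <- ct_mult(t, t)                          # ct level 1
  q <- ct_add_plain(ct_mult(s, SIG7[["a7"]]), SIG7[["a5"]])  # pt-mult
  q <- ct_add_plain(ct_mult(s, q), SIG7[["a3"]])             # ct level 2
  q <- ct_add_plain(ct_mult(s, q), SIG7[["a1"]])             # ct level 3
  ct_add_plain(ct_mult(t, q), 0.5)                           # ct level 4
}

#' Precompute the inverse Gram matrix of the design
#'
#' Computed in clear (it depends only on the public-by-assumption covariate
#' design) and later encrypted as a pipeline input; the scaled inverse
#' `4 (X'X)^{-1}` is the fixed Newton step implied by the Boehning-Lindsay
#' Hessian bound `X'X / 4`.
#'
#' @param X Dense design matrix (samples x coefficients, intercept included).
#' @return `solve(crossprod(X))`.
#' @export
precompute_xtx_inv <- function(X) {
  X <- as.matrix(X)
  xtx <- crossprod(X)
  rc <- rcond(xtx)
  if (!is.finite(rc) || rc < .Machine$double.eps * 100) {
    stop("X'X is numerically singular; check for collinear or constant ",
         "covariates", call. = FALSE)
  }
  solve(xtx)
}

#' Encrypt the design inputs of the pipeline
#'
#' Packs the standardized design matrix `X` (intercept column first) as a CP
#' matrix, its transpose as both an RP matrix (for gradient products) and a
#' REP matrix (for the projection matmul), the phenotype as a cipher, and
#' the cleartext-precomputed `(X'X)^{-1}` as a CP matrix. Also carries the
#' 0/1 sample mask used to re-zero padding slots.
#'
#' @param cohort A `cohort_data` object (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param ctx A [ckks_context()].
#' @return A list of class `design_inputs`.
#' @export
design_inputs <- function(cohort, ctx) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(ctx, "ckks_context"))
  X <- cohort$X
  n <- nrow(X)
  pad <- next_pow2(n)
  if (pad > ctx$params$slot_count) {
    stop("capacity error: padded sample count exceeds slot count",
         call. = FALSE)
  }
  mask <- numeric(ctx$params$slot_count)
  mask[seq_len(n)] <- 1
  structure(list(
    X_cp = cp_pack(X, ctx),
    Xt_rp = rp_pack(t(X), ctx),
    Xt_rep = rep_pack(t(X), pad, ctx),
    y = ct_encrypt(cohort$y, ctx),
    xtx_inv_cp = cp_pack(precompute_xtx_inv(X), ctx),
    sample_mask = mask,
    n = n, d = ncol(X) - 1L, padded_n = pad,
    ctx = ctx
  ), class = "design_inputs")
}

#' Homomorphic logistic regression
#'
#' Runs `kappa` fixed-Hessian Newton iterations on encrypted data. The
#' coefficient vector starts from an encryption of zeros, for which the
#' first probability vector is the constant 0.5, so each iteration first
#' updates the coefficients from the current probabilities and then
#' refreshes the probabilities from the updated coefficients:
#' \deqn{\beta \leftarrow \beta + 4 (X'X)^{-1} X'(y - p), \qquad
#'   p \leftarrow \sigma_7(X \beta).}
#' The returned probabilities therefore correspond to the returned
#' coefficients. Padding slots of `p` are re-masked to zero every iteration
#' (the sigmoid maps the zero padding to 0.5, which would otherwise leak
#' phantom samples into the downstream column sums).
#'
#' @param inputs A [design_inputs()] object.
#' @param kappa Number of iterations (default 3).
#' @param debug If `TRUE`, decrypted per-iteration coefficients are attached.
#' @return A list of class `logistic_state` with cipher elements `beta`
#'   (slots 1..d+1) and `p` (slots 1..n), and the iteration count.
#' @export
hom_logistic_regression <- function(inputs, kappa = 3L, debug = FALSE) {
  stopifnot(inherits(inputs, "design_inputs"), kappa >= 1L)
  ctx <- inputs$ctx
  mask <- inputs$sample_mask
  beta <- ct_encrypt(numeric(inputs$d + 1L), ctx)
  p <- NULL
  trace <- if (debug) vector("list", kappa) else NULL
  for (it in seq_len(kappa)) {
    r <- tryCatch({
      r <- if (is.null(p)) {
        ct_add_plain(inputs$y, -0.5 * mask)      # y - sigma7(X * 0)
      } else {
        ct_sub(inputs$y, p)
      }
      g <- rp_matvec(inputs$Xt_rp, r)
      delta <- cp_matvec(inputs$xtx_inv_cp, g)
      beta <- ct_add(beta, ct_mult(delta, 4))
      u <- cp_matvec(inputs$X_cp, beta)
      p <- ct_mult(sigmoid7(u), mask)
    }, error = function(e) {
      stop(sprintf("logistic regression failed at iteration %d: %s",
                   it, conditionMessage(e)), call. = FALSE)
    })
    if (debug) {
      trace[[it]] <- Re(ct_decrypt(beta, inputs$d + 1L))
    }
  }
  structure(list(beta = beta, p = p, iterations = as.integer(kappa),
                 trace = trace),
            class = "logistic_state")
}

#' @export
print.logistic_state <- function(x, ...) {
  cat(sprintf("logistic_state after %d iteration(s)\n", x$iterations))
  cat("  beta cipher depth: ct =", x$beta$depth[["ct"]],
      ", pt =", x$beta$depth[["pt"]], "\n")
  invisible(x)
}
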