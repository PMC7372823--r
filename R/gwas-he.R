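# The modified semi-parallel GWAS circuit.  After the encrypted logistic
# fit, per-SNP effects are obtained through shared matrix algebra instead of
# per-SNP refits: working weights w = p(1-p) are inverted slot-wise by
# Newton iteration, the working response z is orthogonalized against the
# covariates with the *unweighted* projection M = I - X (X'X)^{-1} X'
# (the same fixed-curvature idea that replaces the Hessian), SNPs are packed
# two per complex slot, and each batch reduces to slot products plus column
# sums.  Numerators and denominators are decrypted separately; the division
# happens in clear.

#' Pipeline configuration
#'
#' @param log_ring_degree `log2 N`; `NULL` (default) picks the smallest ring
#'   for which the projection fits, i.e. the padded sample count squared
#'   slots.
#' @param initial_budget_bits Fresh-cipher budget in bits (default 2440).
#' @param ct_rescale_bits,pt_rescale_bits Rescale amounts (defaults 45/10).
#' @param noise_sigma Per-rescale Gaussian perturbation; 0 = exact mode.
#' @param kappa Logistic iterations (default 3).
#' @param recip_iters Newton iterations for the slot reciprocal (default 6:
#'   from the initial guess 3, the residual over w in [0.05, 0.25] is below
#'   1e-6 after six steps).
#' @param batch_size_override Optional cap on SNPs per batch (at most the
#'   packing limit).
#' @param numerator_weight `"w"` multiplies the orthogonalized working
#'   response by the working weights, as the defining effect formula
#'   requires; `"w_inv"` reproduces a variant that uses the reciprocal
#'   weights instead.
#' @return A list of class `gwas_config`.
#' @export
gwas_config <- function(log_ring_degree = NULL,
                        initial_budget_bits = 2440L,
                        ct_rescale_bits = 45L,
                        pt_rescale_bits = 10L,
                        noise_sigma = 0,
                        kappa = 3L,
                        recip_iters = 6L,
                        batch_size_override = NULL,
                        numerator_weight = c("w", "w_inv")) {
  numerator_weight <- match.arg(numerator_weight)
  stopifnot(kappa >= 1L, recip_iters >= 1L)
  structure(list(
    log_ring_degree = if (is.null(log_ring_degree)) NULL else
      as.integer(log_ring_degree),
    initial_budget_bits = as.integer(initial_budget_bits),
    ct_rescale_bits = as.integer(ct_rescale_bits),
    pt_rescale_bits = as.integer(pt_rescale_bits),
    noise_sigma = noise_sigma,
    kappa = as.integer(kappa),
    recip_iters = as.integer(recip_iters),
    batch_size_override = if (is.null(batch_size_override)) NULL else
      as.integer(batch_size_override),
    numerator_weight = numerator_weight
  ), class = "gwas_config")
}

#' Slot-wise reciprocal by Newton iteration
#'
#' Iterates \eqn{x_{t+1} = x_t (2 - w x_t)} from the initial guess
#' \eqn{x_0 = 3}, chosen for the working-weight range: slots hold
#' \eqn{p(1-p) \le 0.25}, so 3 is close to the reciprocal near the upper
#' bound and the iteration converges quadratically on (0, 0.25]. Each
#' iteration costs two ciphertext multiplications. Slots holding 0 diverge;
#' callers guard padding slots (see [compute_w_and_z()]).
#'
#' @param w A `slot_cipher` with positive slots at most 0.25 on the
#'   positions of interest.
#' @param iters Number of iterations.
#' @return A `slot_cipher` approximating `1/w` slot-wise.
#' @export
inverse_slots <- function(w, iters = 6L) {
  x <- ct_encrypt(rep(3, length(w$slots)), w$ctx)
  for (t in seq_len(iters)) {
    m <- ct_mult(w, x)
    x <- ct_mult(x, ct_add_plain(ct_neg(m), 2))
  }
  x
}

#' Working weights and working response
#'
#' From the logistic state computes `w = p (1 - p)` (masked to the sample
#' slots), its slot reciprocal, and the working response
#' `z = X beta + w^{-1} (y - p)`. Padding slots of `w` are set to 1/3 before
#' the Newton reciprocal — the iteration's fixed point from the initial
#' guess 3, so padding neither diverges nor contaminates neighbours — and
#' masked back to zero afterwards; `z` is likewise masked to the samples.
#'
#' @param state A [hom_logistic_regression()] result.
#' @param inputs The matching [design_inputs()].
#' @param iters Newton iterations for the reciprocal.
#' @return A list of class `work_vectors` with ciphers `w`, `w_inv`, `z`.
#' @export
compute_w_and_z <- function(state, inputs, iters = 6L) {
  stopifnot(inherits(state, "logistic_state"))
  mask <- inputs$sample_mask
  p <- state$p
  w <- ct_mult(p, ct_add_plain(ct_neg(p), 1))
  w <- ct_mult(w, mask)
  w_guarded <- ct_add_plain(w, (1 - mask) / 3)
  w_inv <- ct_mult(inverse_slots(w_guarded, iters), mask)
  xb <- cp_matvec(inputs$X_cp, state$beta)
  z <- ct_add(xb, ct_mult(w_inv, ct_sub(inputs$y, p)))
  z <- ct_mult(z, mask)
  structure(list(w = w, w_inv = w_inv, z = z), class = "work_vectors")
}

#' Encrypted covariate projection matrix
#'
#' Builds `M = I - X (X'X)^{-1} X'` as a CP matrix:
#' `T = X (X'X)^{-1}` by CP matrix product, `P = T X'` by CP x REP product
#' (a CCP matrix with column stride equal to the padded sample count), the
#' identity is subtracted in plaintext CCP layout, and the result is
#' converted to CP form for the per-batch products.
#'
#' @param inputs A [design_inputs()] object.
#' @return A `cp_matrix` holding the n x n projection.
#' @export
build_projection <- function(inputs) {
  pad <- inputs$padded_n
  S <- inputs$ctx$params$slot_count
  if (pad^2 > S) {
    stop(sprintf(
      "capacity error: projection needs %d slots (padded n = %d squared) but only %d are available",
      pad^2, pad, S), call. = FALSE)
  }
  T_cp <- cp_matmul(inputs$X_cp, inputs$xtx_inv_cp)
  P <- cp_rep_matmul(T_cp, inputs$Xt_rep)
  id_slots <- numeric(S)
  id_slots[(seq_len(inputs$n) - 1L) * pad + seq_len(inputs$n)] <- 1
  body <- ct_add_plain(ct_neg(P$body), id_slots)
  M_ccp <- structure(list(body = body, n_rows = inputs$n, n_cols = inputs$n,
                          col_size = pad),
                     class = "ccp_matrix")
  ccp_to_cp(M_ccp)
}

#' SNPs per batch
#'
#' A batch of `tau` SNPs is stored, two per complex slot, as a CCP matrix
#' whose columns are padded to the power-of-two sample stride; the cipher
#' must hold `ceil(n) * tau / 2` entries, so
#' \deqn{\tau = 2 \cdot \mathrm{slots} / \lceil n \rceil .}
#'
#' @param n Sample count.
#' @param params A [scheme_params()].
#' @return Integer batch width (a power of two).
#' @export
batch_size <- function(n, params) {
  pad <- next_pow2(n)
  if (pad > params$slot_count) {
    stop("capacity error: one padded column exceeds the slot count",
         call. = FALSE)
  }
  as.integer(2 * params$slot_count / pad)
}

#' Pack a block of SNP columns into complex-paired REP form
#'
#' Column `2t-1` becomes the real part and column `2t` the imaginary part of
#' complex column `t` (an odd trailing column gets a zero imaginary part);
#' the complex matrix is encoded as a REP matrix with repetition factor
#' equal to the padded sample count, ready for the CP x REP projection
#' product.
#'
#' @param S_block Dense n x m genotype block (values 0/1/2).
#' @param inputs A [design_inputs()] object.
#' @param index Batch index (bookkeeping).
#' @return A list of class `snp_batch`.
#' @export
pack_snp_block <- function(S_block, inputs, index = 1L) {
  S_block <- as.matrix(S_block)
  if (nrow(S_block) != inputs$n) {
    stop(sprintf("shape error: block has %d rows but the design has %d samples",
                 nrow(S_block), inputs$n), call. = FALSE)
  }
  m <- ncol(S_block)
  tau <- batch_size(inputs$n, inputs$ctx$params)
  if (m > tau) {
    stop(sprintf("batch of %d SNPs exceeds the packing limit tau = %d",
                 m, tau), call. = FALSE)
  }
  mc <- ceiling(m / 2)
  C <- matrix(0i, nrow(S_block), mc)
  for (t in seq_len(mc)) {
    re <- S_block[, 2L * t - 1L]
    im <- if (2L * t <= m) S_block[, 2L * t] else 0
    C[, t] <- complex(real = re, imaginary = im)
  }
  structure(list(S_rep = rep_pack(C, inputs$padded_n, inputs$ctx),
                 n_snps = m, n_complex = mc, index = as.integer(index)),
            class = "snp_batch")
}

unpack_snp_block <- function(batch) {
  C <- rep_unpack(batch$S_rep)
  m <- batch$n_snps
  out <- matrix(0, nrow(C), m)
  for (t in seq_len(batch$n_complex)) {
    out[, 2L * t - 1L] <- Re(C[, t])
    if (2L * t <= m) out[, 2L * t] <- Im(C[, t])
  }
  out
}

#' Orthogonalize a SNP batch against the covariates
#'
#' `S' = M S` via the CP x REP product; both SNPs of a complex pair are
#' projected at once because the projection is real and linear.
#'
#' @param M_cp The [build_projection()] output.
#' @param batch A [pack_snp_block()] result.
#' @return A `ccp_matrix` of the orthogonalized complex-paired block.
#' @export
orthogonalize_snps <- function(M_cp, batch) {
  cp_rep_matmul(M_cp, batch$S_rep)
}

#' Slot-wise squares of the two packed SNPs
#'
#' For `z = x + iy` the conjugate trick
#' \deqn{x^2 = Re(z \bar z + z^2)/2, \qquad y^2 = Re(z \bar z - z^2)/2}
#' recovers both squares with one conjugation and two ciphertext
#' multiplications; the imaginary parts (`xy` terms) ride along and are
#' dropped at decryption.
#'
#' @param S_prime A `ccp_matrix` of the orthogonalized complex block.
#' @return A list with `ccp_matrix` elements `even` (real parts `x^2`) and
#'   `odd` (real parts `y^2`).
#' @export
snp_square_split <- function(S_prime) {
  z <- S_prime$body
  zz <- ct_mult(z, ct_conj(z))
  z2 <- ct_mult(z, z)
  wrap <- function(body) {
    structure(list(body = body, n_rows = S_prime$n_rows,
                   n_cols = S_prime$n_cols, col_size = S_prime$col_size),
              class = "ccp_matrix")
  }
  list(even = wrap(ct_mult(ct_add(zz, z2), 0.5)),
       odd = wrap(ct_mult(ct_sub(zz, z2), 0.5)))
}

#' Per-batch association sums
#'
#' The numerator cipher is `colSum(u * S')` where `u` is the duplicated
#' weighted working response: its column sums are complex numbers whose real
#' part is the even SNP's numerator and imaginary part the odd SNP's. The
#' denominators come from `colSum(w * x^2)` and `colSum(w * y^2)` (real
#' parts). Returns the decrypted stride values.
#'
#' @param u_dup Duplicated cipher of the weighted working response.
#' @param w_dup Duplicated cipher of the working weights.
#' @param S_prime Orthogonalized batch (`ccp_matrix`).
#' @param squares [snp_square_split()] output.
#' @return A list with complex vectors `numerator`, `den_even`, `den_odd`
#'   of length `S_prime$n_cols`.
#' @export
assoc_stats <- function(u_dup, w_dup, S_prime, squares) {
  wrap <- function(body) {
    structure(list(body = body, n_rows = S_prime$n_rows,
                   n_cols = S_prime$n_cols, col_size = S_prime$col_size),
              class = "ccp_matrix")
  }
  num_ct <- ccp_colsum(wrap(ct_mult(u_dup, S_prime$body)))
  den_even_ct <- ccp_colsum(wrap(ct_mult(w_dup, squares$even$body)))
  den_odd_ct <- ccp_colsum(wrap(ct_mult(w_dup, squares$odd$body)))
  idx <- (seq_len(S_prime$n_cols) - 1L) * S_prime$col_size + 1L
  list(numerator = ct_decrypt(num_ct)[idx],
       den_even = ct_decrypt(den_even_ct)[idx],
       den_odd = ct_decrypt(den_odd_ct)[idx])
}

interleave_batch <- function(stats, m) {
  mc <- length(stats$numerator)
  num <- den <- numeric(2L * mc)
  num[seq(1L, by = 2L, length.out = mc)] <- Re(stats$numerator)
  num[seq(2L, by = 2L, length.out = mc)] <- Im(stats$numerator)
  den[seq(1L, by = 2L, length.out = mc)] <- Re(stats$den_even)
  den[seq(2L, by = 2L, length.out = mc)] <- Re(stats$den_odd)
  list(numerator = num[seq_len(m)], denominator = den[seq_len(m)])
}

#' Run the encrypted semi-parallel GWAS pipeline
#'
#' Executes the full circuit on a cohort: encrypted logistic regression,
#' working weights/response with the Newton reciprocal, orthogonalization of
#' the working response and of each complex-packed SNP batch against the
#' covariates, and per-batch numerator/denominator column sums. Numerators
#' and denominators are decrypted and concatenated, and the per-SNP effect
#' `b' = numerator / denominator` and error term `err' = 1 / denominator`
#' are computed in clear (a conventional standard error would be
#' `sqrt(err')`). SNPs whose denominator is numerically zero (monomorphic
#' columns) get `NA` effects rather than an error.
#'
#' @param cohort A `cohort_data` object.
#' @param config A [gwas_config()].
#' @return A list of class `gwas_result` with the per-SNP `table`
#'   (snp_id, numerator, denominator, beta, err, batch_index), the
#'   [depth_report()], the config echo and batch bookkeeping.
#' @export
run_gwas <- function(cohort, config = gwas_config()) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(config, "gwas_config"))
  n <- nrow(cohort$X)
  pad <- next_pow2(n)
  lrd <- config$log_ring_degree
  if (is.null(lrd)) lrd <- as.integer(2 * log2(pad) + 1)
  params <- scheme_params(lrd, config$initial_budget_bits,
                          config$ct_rescale_bits, config$pt_rescale_bits)
  if (pad^2 > params$slot_count) {
    stop(sprintf(
      "stage setup: padded n = %d needs %d slots for the projection but log_ring_degree %d gives %d",
      pad, pad^2, lrd, params$slot_count), call. = FALSE)
  }
  ctx <- ckks_context(params, noise_sigma = config$noise_sigma)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  inputs <- stage("encrypt-inputs", design_inputs(cohort, ctx))
  state <- stage("logistic-regression",
                 hom_logistic_regression(inputs, config$kappa))
  wv <- stage("working-vectors",
              compute_w_and_z(state, inputs, config$recip_iters))

  zp <- stage("orthogonalize-z", {
    t1 <- rp_matvec(inputs$Xt_rp, wv$z)
    v1 <- cp_matvec(inputs$xtx_inv_cp, t1)
    v2 <- cp_matvec(inputs$X_cp, v1)
    ct_mult(ct_sub(wv$z, v2), inputs$sample_mask)
  })

  M_cp <- stage("projection-matrix", build_projection(inputs))

  weight_ct <- if (config$numerator_weight == "w") wv$w else wv$w_inv
  u_dup <- stage("numerator-weights", {
    u <- ct_mult(weight_ct, zp)
    u <- ct_mult(u, inputs$sample_mask)
    ct_duplicate(u, pad)
  })
  w_dup <- stage("denominator-weights", ct_duplicate(wv$w, pad))

  tau <- batch_size(n, params)
  if (!is.null(config$batch_size_override)) {
    if (config$batch_size_override > tau) {
      stop(sprintf("batch size override %d exceeds the packing limit %d",
                   config$batch_size_override, tau), call. = FALSE)
    }
    tau <- config$batch_size_override
  }
  k <- ncol(cohort$S)
  n_batches <- ceiling(k / tau)
  numerator <- denominator <- numeric(0)
  batch_index <- integer(0)
  for (b in seq_len(n_batches)) {
    cols <- seq.int((b - 1L) * tau + 1L, min(b * tau, k))
    res <- stage(sprintf("snp-batch %d", b), {
      batch <- pack_snp_block(cohort$S[, cols, drop = FALSE], inputs,
                              index = b)
      S_prime <- orthogonalize_snps(M_cp, batch)
      squares <- snp_square_split(S_prime)
      stats <- assoc_stats(u_dup, w_dup, S_prime, squares)
      interleave_batch(stats, length(cols))
    })
    numerator <- c(numerator, res$numerator)
    denominator <- c(denominator, res$denominator)
    batch_index <- c(batch_index, rep(b, length(cols)))
  }

  ok <- abs(denominator) > 1e-8
  beta <- err <- rep(NA_real_, k)
  beta[ok] <- numerator[ok] / denominator[ok]
  err[ok] <- 1 / denominator[ok]

  snp_id <- if (!is.null(colnames(cohort$S))) colnames(cohort$S) else
    paste0("snp", seq_len(k))
  structure(list(
    table = data.frame(snp_id = snp_id, numerator = numerator,
                       denominator = denominator, beta = beta, err = err,
                       batch_index = batch_index,
                       stringsAsFactors = FALSE),
    depth = depth_report(ctx),
    config = config,
    params = params,
    batches = list(tau = tau, n_batches = n_batches)
  ), class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("Encrypted semi-parallel GWAS: %d SNPs in %d batch(es) of up to %d\n",
              nrow(x$table), x$batches$n_batches, x$batches$tau))
  cat(sprintf("  circuit depth: %d ciphertext mults, %d plaintext mults\n",
              x$depth$ct_mult_depth, x$depth$pt_mult_depth))
  cat(sprintf("  flagged (zero-denominator) SNPs: %d\n",
              sum(is.na(x$table$beta))))
  print(utils::head(x$table, 5))
  if (nrow(x$table) > 5) cat("  ...\n")
  invisible(x)
}
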