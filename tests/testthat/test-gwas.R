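# Working-weight reciprocal, projection, SNP packing, batching and the
# full encrypted circuit.

test_that("working weights are bounded by 0.25 and Newton inverts them", {
  # the bound: p(1-p) is maximal at p = 1/2
  opt <- optimize(function(p) p * (1 - p), c(0, 1), maximum = TRUE)
  expect_equal(opt$objective, 0.25, tolerance = 1e-9)

  ctx <- tiny_ctx()
  # w = 1/3 is the fixed point of the iteration started at 3
  w <- ct_encrypt(rep(1 / 3, 64), ctx)
  for (iters in c(1, 3, 6)) {
    x <- inverse_slots(w, iters)
    expect_equal(Re(ct_decrypt(x)), rep(3, 64), tolerance = 1e-9)
  }

  # scalar Newton oracle at the upper bound
  newton <- function(w, iters) {
    x <- 3
    for (i in seq_len(iters)) x <- x * (2 - w * x)
    x
  }
  x6 <- inverse_slots(ct_encrypt(rep(0.25, 64), ctx), 6)
  expect_lt(max(abs(Re(ct_decrypt(x6)) - 4)), 1e-6)
  expect_equal(Re(ct_decrypt(x6, 1)), newton(0.25, 6), tolerance = 1e-12)

  # the residual 1 - w*x squares every step from 1 - 3w, so six iterations
  # give (1 - 3w)^64: below 1e-6 for w >= 0.1 and below 1e-4 down to 0.05
  ws <- seq(0.1, 0.25, by = 0.01)
  x <- Re(ct_decrypt(inverse_slots(ct_encrypt(ws, ctx), 6), length(ws)))
  expect_lt(max(abs(x * ws - 1)), 1e-6)
  ws2 <- seq(0.05, 0.25, by = 0.01)
  x2 <- Re(ct_decrypt(inverse_slots(ct_encrypt(ws2, ctx), 6), length(ws2)))
  expect_lt(max(abs(x2 * ws2 - 1)), 1e-4)
})

test_that("work vectors match the cleartext formulas and mask padding", {
  co <- make_cohort(24, d = 2, k = 4, seed = 30)
  ctx <- tiny_ctx(log_ring_degree = 11L)
  inputs <- design_inputs(co, ctx)
  st <- hom_logistic_regression(inputs, kappa = 3L)
  wv <- compute_w_and_z(st, inputs, iters = 6L)

  oracle <- oracle_logreg(co$X, co$y, 3L)
  w_exp <- oracle$p * (1 - oracle$p)
  z_exp <- as.vector(co$X %*% oracle$beta) +
    hegwas:::recip_newton(w_exp, 6) * (co$y - oracle$p)
  expect_equal(Re(ct_decrypt(wv$w, 24)), w_exp, tolerance = 1e-6)
  expect_equal(Re(ct_decrypt(wv$z, 24)), z_exp, tolerance = 1e-6)
  expect_true(all(Re(ct_decrypt(wv$w, 24)) > 0))
  expect_lte(max(Re(ct_decrypt(wv$w, 24))), 0.25)
  expect_equal(Re(ct_decrypt(wv$w_inv, 24)) * w_exp, rep(1, 24),
               tolerance = 1e-5)

  # padding slots exactly zero (ring degree 11 -> 1024 slots)
  expect_identical(unique(ct_decrypt(wv$w)[25:1024]), 0 + 0i)
  expect_identical(unique(ct_decrypt(wv$z)[25:1024]), 0 + 0i)
})

test_that("uniform probabilities give w = 0.25 and z = Xb + 4(y - p)", {
  # engineered state: p = 0.5 everywhere (beta = 0 cipher)
  co <- make_cohort(16, d = 2, k = 4, seed = 31)
  ctx <- tiny_ctx(log_ring_degree = 9L)
  inputs <- design_inputs(co, ctx)
  mask <- inputs$sample_mask
  state <- structure(list(
    beta = ct_encrypt(numeric(3), ctx),
    p = ct_mult(ct_encrypt(rep(0.5, 16), ctx), mask),
    iterations = 0L), class = "logistic_state")
  wv <- compute_w_and_z(state, inputs, iters = 6L)
  expect_equal(Re(ct_decrypt(wv$w, 16)), rep(0.25, 16), tolerance = 1e-9)
  expect_equal(Re(ct_decrypt(wv$z, 16)), 4 * (co$y - 0.5), tolerance = 1e-5)
})

test_that("the projection matrix annihilates the covariates and is idempotent", {
  # intercept-only design: M is the centering matrix
  ctx <- tiny_ctx(log_ring_degree = 9L)
  n <- 8L
  co <- list(X = matrix(1, n, 1), y = rep(0:1, 4), S = diag(n))
  inputs <- structure(list(
    X_cp = cp_pack(co$X, ctx),
    Xt_rp = rp_pack(t(co$X), ctx),
    Xt_rep = rep_pack(t(co$X), next_pow2(n), ctx),
    y = ct_encrypt(co$y, ctx),
    xtx_inv_cp = cp_pack(precompute_xtx_inv(co$X), ctx),
    sample_mask = c(rep(1, n), numeric(ctx$params$slot_count - n)),
    n = n, d = 0L, padded_n = next_pow2(n), ctx = ctx),
    class = "design_inputs")
  M <- Re(cp_unpack(build_projection(inputs)))
  expect_equal(M, diag(n) - 1 / n, tolerance = 1e-6)

  co2 <- make_cohort(16, d = 3, k = 4, seed = 32)
  ctx2 <- tiny_ctx(log_ring_degree = 9L)
  M2 <- Re(cp_unpack(build_projection(design_inputs(co2, ctx2))))
  expect_lt(max(abs(M2 %*% co2$X)), 1e-6)
  expect_equal(M2 %*% M2, M2, tolerance = 1e-5)
})

test_that("batch width follows the complex-packing capacity formula", {
  p17 <- scheme_params(17L)
  expect_identical(batch_size(245, p17), 512L)
  expect_identical(ceiling(10643 / batch_size(245, p17)), 21)

  p7 <- scheme_params(7L)  # 64 slots
  expect_identical(batch_size(32, p7), 4L)
  expect_error(batch_size(200, p7), "capacity")
})

test_that("SNP blocks pack two per complex slot and round-trip", {
  co <- make_cohort(16, d = 2, k = 4, seed = 33)
  ctx <- tiny_ctx(log_ring_degree = 9L)
  inputs <- design_inputs(co, ctx)

  unit <- matrix(0, 16, 2)
  unit[1, 1] <- 1
  unit[2, 2] <- 1
  b <- pack_snp_block(unit, inputs)  # columns e1, e2 -> complex column e1 + i e2
  C <- rep_unpack(b$S_rep)
  expect_equal(C[1:2, 1], c(1 + 0i, 0 + 1i), tolerance = 1e-12)

  set.seed(33)
  for (m in c(1, 2, 3)) {
    S <- matrix(sample(0:2, 16 * m, TRUE), 16, m)
    b <- pack_snp_block(S, inputs)
    expect_identical(b$n_complex, ceiling(m / 2))
    expect_equal(hegwas:::unpack_snp_block(b), S, tolerance = 1e-12)
  }
  expect_error(pack_snp_block(matrix(0, 16, 100), inputs), "packing limit")
})

test_that("orthogonalized SNPs equal the dense projection of both parts", {
  co <- make_cohort(16, d = 2, k = 6, seed = 34)
  ctx <- tiny_ctx(log_ring_degree = 9L)
  inputs <- design_inputs(co, ctx)
  M_cp <- build_projection(inputs)
  M <- Re(cp_unpack(M_cp))
  batch <- pack_snp_block(co$S, inputs)
  Sp <- ccp_unpack(orthogonalize_snps(M_cp, batch))
  expect_equal(Re(Sp), unname(M %*% co$S[, c(1, 3, 5)]), tolerance = 1e-6)
  expect_equal(Im(Sp), unname(M %*% co$S[, c(2, 4, 6)]), tolerance = 1e-6)
  # projected SNPs are orthogonal to the covariate span
  expect_lt(max(Mod(crossprod(co$X, Sp))), 1e-5)
})

test_that("conjugate squaring recovers both packed squares", {
  ctx <- tiny_ctx()
  wrap <- function(z) structure(
    list(body = ct_encrypt(z, ctx), n_rows = 1L, n_cols = length(z),
         col_size = 1L), class = "ccp_matrix")
  sq <- snp_square_split(wrap(c(3 + 0i, 0 + 2i, 1 + 2i)))
  expect_equal(Re(ct_decrypt(sq$even$body, 3)), c(9, 0, 1), tolerance = 1e-9)
  expect_equal(Re(ct_decrypt(sq$odd$body, 3)), c(0, 4, 4), tolerance = 1e-9)
})

test_that("per-batch association sums match the defining formulas in clear", {
  co <- make_cohort(8, d = 1, k = 4, seed = 36)
  ctx <- tiny_ctx(log_ring_degree = 7L)
  inputs <- design_inputs(co, ctx)
  st <- hom_logistic_regression(inputs, kappa = 3L)
  wv <- compute_w_and_z(st, inputs, 6L)
  t1 <- rp_matvec(inputs$Xt_rp, wv$z)
  v2 <- cp_matvec(inputs$X_cp, cp_matvec(inputs$xtx_inv_cp, t1))
  zp <- ct_mult(ct_sub(wv$z, v2), inputs$sample_mask)
  u_dup <- ct_duplicate(ct_mult(ct_mult(wv$w, zp), inputs$sample_mask), 8L)
  w_dup <- ct_duplicate(wv$w, 8L)
  M_cp <- build_projection(inputs)
  batch <- pack_snp_block(co$S, inputs)
  Sp <- orthogonalize_snps(M_cp, batch)
  stats <- assoc_stats(u_dup, w_dup, Sp, snp_square_split(Sp))

  # cleartext twin
  w <- Re(ct_decrypt(wv$w, 8)); zpc <- Re(ct_decrypt(zp, 8))
  Spc <- Re(cp_unpack(ccp_to_cp(Sp)))[1:8, ]
  Spd <- hegwas:::unpack_snp_block(batch)
  M <- Re(cp_unpack(M_cp))
  Sdense <- M %*% Spd
  num_exp <- colSums(Sdense * (w * zpc))
  den_exp <- colSums(w * Sdense^2)
  got <- hegwas:::interleave_batch(stats, 4L)
  expect_equal(got$numerator, num_exp, tolerance = 1e-6)
  expect_equal(got$denominator, den_exp, tolerance = 1e-6)
})

test_that("the full circuit matches the cleartext modified oracle", {
  co <- make_cohort(16, d = 2, k = 12, seed = 37)
  res <- run_gwas(co, gwas_config())
  oracle <- oracle_modified(co$X, co$y, co$S)
  rel <- abs(res$table$beta - oracle$b_prime) / pmax(abs(oracle$b_prime), 1e-10)
  expect_lt(max(rel, na.rm = TRUE), 1e-4)
  rel_err <- abs(res$table$err - oracle$err_prime) / abs(oracle$err_prime)
  expect_lt(max(rel_err, na.rm = TRUE), 1e-4)
  # denominators strictly positive for the non-constant SNP columns
  poly <- apply(co$S, 2, function(g) length(unique(g)) > 1)
  expect_true(all(res$table$denominator[poly] > 0))
})

test_that("the reciprocal-weight numerator variant mirrors its oracle", {
  co <- make_cohort(16, d = 2, k = 8, seed = 42)
  res <- run_gwas(co, gwas_config(numerator_weight = "w_inv"))
  oracle <- oracle_modified(co$X, co$y, co$S, numerator_weight = "w_inv")
  rel <- abs(res$table$beta - oracle$b_prime) / pmax(abs(oracle$b_prime), 1e-10)
  expect_lt(max(rel, na.rm = TRUE), 1e-4)
})

test_that("batch decomposition is transparent and counts ceil(k / tau)", {
  co_sizes <- c(7, 8, 9)  # around an override of tau = 8
  co <- make_cohort(16, d = 2, k = 9, seed = 38)
  for (k in co_sizes) {
    sub <- co
    sub$S <- co$S[, seq_len(k), drop = FALSE]
    res <- run_gwas(sub, gwas_config(batch_size_override = 8L))
    expect_identical(res$batches$n_batches, ceiling(k / 8))
  }
  one <- run_gwas(co, gwas_config())                          # single batch
  many <- run_gwas(co, gwas_config(batch_size_override = 4L)) # three batches
  expect_identical(many$batches$n_batches, 3)
  expect_equal(one$table$beta, many$table$beta, tolerance = 1e-12)
  expect_equal(one$table$err, many$table$err, tolerance = 1e-12)
})

test_that("constant SNP columns are flagged missing, not an error", {
  co <- make_cohort(16, d = 2, k = 6, seed = 39)
  co$S[, 3] <- 0L
  res <- run_gwas(co, gwas_config())
  expect_true(is.na(res$table$beta[3]))
  expect_true(is.na(res$table$err[3]))
  expect_false(anyNA(res$table$beta[-3]))
})

test_that("the full circuit has the expected sequential operation depths", {
  co <- make_cohort(16, d = 3, k = 8, seed = 40)
  res <- run_gwas(co, gwas_config(kappa = 3L, recip_iters = 6L))
  expect_identical(res$depth$ct_mult_depth, 40L)
  expect_identical(res$depth$pt_mult_depth, 29L)
})

test_that("a causal SNP keeps its sign through the modified pipeline", {
  co <- generate_cohort(cohort_spec(
    n = 48, d = 2, k = 6, seed = 41, maf_range = c(0.3, 0.4),
    causal = data.frame(index = 2, effect = 1.5)))
  res <- run_gwas(co, gwas_config())
  expect_gt(res$table$beta[2], 0)
})
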