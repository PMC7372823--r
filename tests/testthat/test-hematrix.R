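# Packed-matrix operations against dense-algebra oracles.

test_that("replicate broadcasts each entry into a constant cipher", {
  ctx <- tiny_ctx()
  one <- ct_replicate(ct_encrypt(7, ctx), 1)
  expect_equal(Re(ct_decrypt(one[[1]])), rep(7, 64), tolerance = 1e-12)

  pair <- ct_replicate(ct_encrypt(c(2, 5), ctx), 2)
  expect_equal(Re(ct_decrypt(pair[[1]])), rep(2, 64), tolerance = 1e-12)
  expect_equal(Re(ct_decrypt(pair[[2]])), rep(5, 64), tolerance = 1e-12)

  set.seed(10)
  v <- rand_cplx(8)
  reps <- ct_replicate(ct_encrypt(v, ctx), 8)
  for (i in 1:8) {
    expect_equal(ct_decrypt(reps[[i]]), rep(v[i], 64), tolerance = 1e-12)
  }
  expect_error(ct_replicate(ct_encrypt(1, ctx), 65), "capacity")
})

test_that("duplicate tiles the leading k slots with log2(S/k) rotations", {
  ctx <- tiny_ctx()
  filled <- ct_duplicate(ct_encrypt(3, ctx), 1)
  expect_equal(Re(ct_decrypt(filled)), rep(3, 64), tolerance = 1e-12)

  set.seed(11)
  for (k in c(2, 4, 8)) {
    ctx <- tiny_ctx()
    v <- rand_cplx(k)
    before <- ctx$totals[["rotations"]]
    tiled <- ct_duplicate(ct_encrypt(v, ctx), k)
    expect_identical(ctx$totals[["rotations"]] - before, log2(64 / k))
    expect_equal(ct_decrypt(tiled), rep(v, 64 / k), tolerance = 1e-12)
  }
  expect_error(ct_duplicate(ct_encrypt(1:3, tiny_ctx()), 3), "power-of-two")
})

test_that("CP matrix-vector product matches dense algebra", {
  ctx <- tiny_ctx()
  I2 <- cp_pack(diag(2), ctx)
  out <- cp_matvec(I2, ct_encrypt(c(5, 6), ctx))
  expect_equal(Re(ct_decrypt(out, 2)), c(5, 6), tolerance = 1e-9)

  A <- matrix(c(1, 3, 2, 4), 2)  # columns (1,3) and (2,4)
  out <- cp_matvec(cp_pack(A, ctx), ct_encrypt(c(1, 1), ctx))
  expect_equal(Re(ct_decrypt(out, 2)), c(3, 7), tolerance = 1e-9)

  set.seed(12)
  for (i in 1:50) {
    A <- matrix(rnorm(40), 8, 5)
    v <- rnorm(5)
    out <- cp_matvec(cp_pack(A, ctx), ct_encrypt(v, ctx))
    expect_equal(Re(ct_decrypt(out, 8)), as.vector(A %*% v),
                 tolerance = 1e-9)
    # padding slots beyond the padded row count stay zero
    expect_equal(ct_decrypt(out)[9:64], rep(0 + 0i, 56), tolerance = 1e-12)
  }
})

test_that("CP matrix product iterates matvec over right-hand columns", {
  ctx <- tiny_ctx()
  A <- matrix(rnorm(16), 4)
  prodI <- cp_matmul(cp_pack(A, ctx), cp_pack(diag(4), ctx))
  expect_equal(Re(cp_unpack(prodI)), A, tolerance = 1e-9)

  A2 <- matrix(c(1, 3, 2, 4), 2)
  B2 <- matrix(c(5, 7, 6, 8), 2)
  out <- cp_matmul(cp_pack(A2, ctx), cp_pack(B2, ctx))
  expect_equal(Re(cp_unpack(out)), A2 %*% B2, tolerance = 1e-9)

  set.seed(13)
  A <- matrix(rnorm(24), 6, 4)
  B <- matrix(rnorm(12), 4, 3)
  out <- cp_matmul(cp_pack(A, ctx), cp_pack(B, ctx))
  expect_equal(Re(cp_unpack(out)), A %*% B, tolerance = 1e-9)
  expect_error(cp_matmul(cp_pack(A, ctx), cp_pack(diag(3), ctx)), "shape")
})

test_that("CCP column sums land at the stride positions in log2(colSize) rotations", {
  ctx <- tiny_ctx()
  M <- ccp_pack(matrix(c(1, 2, 3), 3, 1), ctx, col_size = 4)
  s <- ccp_colsum(M)
  expect_equal(Re(ct_decrypt(s, 1)), 6, tolerance = 1e-9)

  M2 <- ccp_pack(matrix(c(1, 1, 2, 2), 2, 2), ctx, col_size = 2)
  s2 <- Re(ct_decrypt(ccp_colsum(M2)))
  expect_equal(s2[c(1, 3)], c(2, 4), tolerance = 1e-9)

  set.seed(14)
  for (i in 1:20) {
    nr <- sample(2:7, 1); nc <- sample(1:4, 1)
    A <- matrix(rnorm(nr * nc), nr, nc)
    cs <- next_pow2(nr)
    ctx <- tiny_ctx()
    M <- ccp_pack(A, ctx, col_size = cs)
    before <- ctx$totals[["rotations"]]
    s <- ccp_colsum(M)
    expect_identical(ctx$totals[["rotations"]] - before, log2(cs))
    got <- Re(ct_decrypt(s))[(seq_len(nc) - 1) * cs + 1]
    expect_equal(got, colSums(A), tolerance = 1e-9)
  }
})

test_that("dot product fills every slot with the sum of products", {
  ctx <- tiny_ctx()
  orth <- ct_dotprod(ct_encrypt(c(1, 0), ctx), ct_encrypt(c(0, 1), ctx), 2)
  expect_equal(Re(ct_decrypt(orth)), rep(0, 64), tolerance = 1e-12)

  d <- ct_dotprod(ct_encrypt(c(1, 2, 3, 0), ctx),
                  ct_encrypt(c(4, 5, 6, 0), ctx), 4)
  expect_equal(Re(ct_decrypt(d)), rep(32, 64), tolerance = 1e-9)

  set.seed(15)
  for (len in c(4, 8, 16)) {
    u <- rnorm(len); v <- rnorm(len)
    d <- ct_dotprod(ct_encrypt(u, ctx), ct_encrypt(v, ctx), len)
    expect_equal(Re(ct_decrypt(d)), rep(sum(u * v), 64), tolerance = 1e-9)
  }
})

test_that("RP matrix-vector product matches dense algebra", {
  ctx <- tiny_ctx()
  v <- rnorm(3)
  out <- rp_matvec(rp_pack(diag(3), ctx), ct_encrypt(v, ctx))
  expect_equal(Re(ct_decrypt(out, 3)), v, tolerance = 1e-9)

  A <- matrix(c(1, 3, 2, 4), 2)
  out <- rp_matvec(rp_pack(A, ctx), ct_encrypt(c(1, 1), ctx))
  expect_equal(Re(ct_decrypt(out, 2)), c(3, 7), tolerance = 1e-9)

  set.seed(16)
  A <- matrix(rnorm(40), 5, 8)
  v <- rnorm(8)
  out <- rp_matvec(rp_pack(A, ctx), ct_encrypt(v, ctx))
  expect_equal(Re(ct_decrypt(out, 5)), as.vector(A %*% v), tolerance = 1e-9)
  expect_equal(ct_decrypt(out)[6:64], rep(0 + 0i, 59), tolerance = 1e-9)
})

test_that("CP x REP product yields the dense product in CCP layout", {
  ctx <- tiny_ctx()
  A <- matrix(rnorm(8), 4, 2)
  repI <- rep_pack(diag(2), next_pow2(4), ctx)
  out <- cp_rep_matmul(cp_pack(A, ctx), repI)
  expect_equal(Re(ccp_unpack(out)), A, tolerance = 1e-9)

  A2 <- matrix(c(1, 3, 2, 4), 2)
  B2 <- matrix(c(5, 7, 6, 8), 2)
  out2 <- cp_rep_matmul(cp_pack(A2, ctx), rep_pack(B2, 2, ctx))
  expect_equal(Re(ccp_unpack(out2)), A2 %*% B2, tolerance = 1e-9)

  set.seed(17)
  A <- matrix(rnorm(12), 4, 3)
  B <- matrix(rnorm(12), 3, 4)
  out3 <- cp_rep_matmul(cp_pack(A, ctx), rep_pack(B, 4, ctx))
  expect_equal(Re(ccp_unpack(out3)), A %*% B, tolerance = 1e-9)
  expect_identical(out3$col_size, 4L)

  badB <- rep_pack(B, 8, ctx)
  expect_error(cp_rep_matmul(cp_pack(A, ctx), badB), "layout")
})

test_that("CCP to CP conversion is a layout inverse", {
  ctx <- tiny_ctx()
  one <- ccp_pack(matrix(rnorm(4), 4, 1), ctx)
  ascp <- ccp_to_cp(one)
  expect_equal(cp_unpack(ascp), ccp_unpack(one), tolerance = 1e-9)

  set.seed(18)
  A <- matrix(rnorm(12), 4, 3)
  M <- ccp_pack(A, ctx)
  round_trip <- ccp_pack(Re(cp_unpack(ccp_to_cp(M))), ctx)
  expect_equal(ct_decrypt(round_trip$body), ct_decrypt(M$body),
               tolerance = 1e-9)

  for (i in 1:10) {
    nr <- sample(2:8, 1); nc <- sample(1:5, 1)
    A <- matrix(rnorm(nr * nc), nr, nc)
    got <- cp_unpack(ccp_to_cp(ccp_pack(A, ctx)))
    expect_equal(Re(got), A, tolerance = 1e-9)
  }
})
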