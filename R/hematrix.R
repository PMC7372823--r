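# Packed-matrix encodings over slot ciphers and the matrix algorithms that
# operate on them.  Four layouts are used by the pipeline:
#   CP  - one cipher per column, rows zero-padded to a power of two;
#   CCP - all columns concatenated into one cipher with a power-of-two
#         column stride;
#   RP  - one cipher per row;
#   REP - one cipher per row with every entry repeated q times contiguously
#         (q a power of two), so a CP x REP product needs no replication.
# Packing is responsible for zeroing padding slots; the algorithms assume it.

## ---- packing -------------------------------------------------------------

#' Pack a dense matrix column-wise (CP)
#'
#' @param A Dense numeric or complex matrix.
#' @param ctx A [ckks_context()].
#' @return A `cp_matrix`: one cipher per column, rows padded with zeros to
#'   the next power of two.
#' @export
cp_pack <- function(A, ctx) {
  A <- as.matrix(A)
  padded <- next_pow2(nrow(A))
  cols <- lapply(seq_len(ncol(A)), function(j) ct_encrypt(A[, j], ctx))
  structure(list(columns = cols, n_rows = nrow(A), n_cols = ncol(A),
                 padded_rows = padded),
            class = "cp_matrix")
}

#' Decrypt a CP matrix to dense form
#' @param A A `cp_matrix`.
#' @return A complex matrix of the original dimensions.
#' @export
cp_unpack <- function(A) {
  out <- vapply(A$columns, function(ct) ct_decrypt(ct, A$n_rows),
                complex(A$n_rows))
  matrix(out, nrow = A$n_rows, ncol = A$n_cols)
}

#' Pack a dense matrix column-compactly (CCP)
#'
#' Columns are concatenated in a single cipher at a power-of-two stride
#' `col_size`; slot `(j-1) * col_size + i` holds entry `(i, j)`.
#'
#' @param A Dense matrix.
#' @param ctx A [ckks_context()].
#' @param col_size Column stride; defaults to the padded row count.
#' @return A `ccp_matrix`.
#' @export
ccp_pack <- function(A, ctx, col_size = next_pow2(nrow(A))) {
  A <- as.matrix(A)
  stopifnot(is_pow2(col_size), col_size >= nrow(A))
  if (ncol(A) * col_size > ctx$params$slot_count) {
    stop("capacity error: CCP layout exceeds slot count", call. = FALSE)
  }
  slots <- complex(ncol(A) * col_size)
  for (j in seq_len(ncol(A))) {
    slots[(j - 1L) * col_size + seq_len(nrow(A))] <- as.complex(A[, j])
  }
  structure(list(body = ct_encrypt(slots, ctx), n_rows = nrow(A),
                 n_cols = ncol(A), col_size = as.integer(col_size)),
            class = "ccp_matrix")
}

#' Decrypt a CCP matrix to dense form
#' @param M A `ccp_matrix`.
#' @return A complex matrix.
#' @export
ccp_unpack <- function(M) {
  slots <- ct_decrypt(M$body)
  out <- vapply(seq_len(M$n_cols), function(j) {
    slots[(j - 1L) * M$col_size + seq_len(M$n_rows)]
  }, complex(M$n_rows))
  matrix(out, nrow = M$n_rows, ncol = M$n_cols)
}

#' Pack a dense matrix row-wise (RP)
#' @param A Dense matrix.
#' @param ctx A [ckks_context()].
#' @return An `rp_matrix`: one cipher per row, columns zero-padded.
#' @export
rp_pack <- function(A, ctx) {
  A <- as.matrix(A)
  rows <- lapply(seq_len(nrow(A)), function(i) ct_encrypt(A[i, ], ctx))
  structure(list(rows = rows, n_rows = nrow(A), n_cols = ncol(A),
                 padded_cols = next_pow2(ncol(A))),
            class = "rp_matrix")
}

#' Decrypt an RP matrix to dense form
#' @param A An `rp_matrix`.
#' @return A complex matrix.
#' @export
rp_unpack <- function(A) {
  out <- vapply(A$rows, function(ct) ct_decrypt(ct, A$n_cols),
                complex(A$n_cols))
  t(matrix(out, nrow = A$n_cols, ncol = A$n_rows))
}

#' Pack a dense matrix row-expanded (REP)
#'
#' Row `i` is encoded with entry `(i, j)` repeated `rep_factor` times
#' contiguously, so slot `(j-1) * rep_factor + t` holds entry `(i, j)`.
#'
#' @param A Dense matrix.
#' @param rep_factor Power-of-two repetition count `q`.
#' @param ctx A [ckks_context()].
#' @return A `rep_matrix`.
#' @export
rep_pack <- function(A, rep_factor, ctx) {
  A <- as.matrix(A)
  stopifnot(is_pow2(rep_factor))
  if (ncol(A) * rep_factor > ctx$params$slot_count) {
    stop("capacity error: REP layout exceeds slot count", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(A)), function(i) {
    ct_encrypt(rep(as.complex(A[i, ]), each = rep_factor), ctx)
  })
  structure(list(rows = rows, n_rows = nrow(A), n_cols = ncol(A),
                 rep_factor = as.integer(rep_factor)),
            class = "rep_matrix")
}

#' Decrypt a REP matrix to dense form
#' @param A A `rep_matrix`.
#' @return A complex matrix.
#' @export
rep_unpack <- function(A) {
  out <- vapply(A$rows, function(ct) {
    ct_decrypt(ct, A$n_cols * A$rep_factor)[seq(1L, by = A$rep_factor,
                                                length.out = A$n_cols)]
  }, complex(A$n_cols))
  t(matrix(out, nrow = A$n_cols, ncol = A$n_rows))
}

#' Dump a packed matrix's decrypted dense form to delimited text
#'
#' Debug helper: writes the real part (and the imaginary part alongside when
#' nonzero) as tab-separated text for inspection.
#'
#' @param x A packed matrix (`cp_matrix`, `ccp_matrix`, `rp_matrix`,
#'   `rep_matrix`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_packed <- function(x, path) {
  dense <- switch(class(x)[1],
                  cp_matrix = cp_unpack(x),
                  ccp_matrix = ccp_unpack(x),
                  rp_matrix = rp_unpack(x),
                  rep_matrix = rep_unpack(x),
                  stop("not a packed matrix"))
  out <- if (max(abs(Im(dense))) > 0) {
    cbind(Re(dense), Im(dense))
  } else {
    Re(dense)
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

## ---- slot algorithms -----------------------------------------------------

log2_int <- function(x) as.integer(round(log2(x)))

#' Replicate: broadcast each entry of a vector into its own cipher
#'
#' The naive form: entry `i` is isolated with a plaintext indicator mask
#' (one plaintext rescale) and then spread to every slot with
#' `log2(slot_count)` power-of-two rotations and additions.
#'
#' @param v A `slot_cipher` holding `n` values in its leading slots.
#' @param n Number of entries to replicate.
#' @return A list of `n` ciphers; cipher `i` holds `v[i]` in every slot.
#' @export
ct_replicate <- function(v, n) {
  S <- length(v$slots)
  if (n > S) stop("capacity error: cannot replicate beyond slot count",
                  call. = FALSE)
  lapply(seq_len(n), function(i) {
    mask <- numeric(S)
    mask[i] <- 1
    m <- ct_mult(v, mask)
    for (j in seq_len(log2_int(S)) - 1L) {
      m <- ct_add(m, ct_rotate(m, 2L^j))
    }
    m
  })
}

#' Duplicate: tile the leading k slots across the whole cipher
#'
#' Requires the `k` leading slots to be the only nonzero ones and `k` to be
#' a power of two dividing the slot count; realised with
#' `log2(slot_count / k)` rotation-and-addition rounds.
#'
#' @param v A `slot_cipher` with `k` filled slots.
#' @param k Power-of-two tile width.
#' @return A `slot_cipher` with slot `j` equal to `v[j mod k]`.
#' @export
ct_duplicate <- function(v, k) {
  S <- length(v$slots)
  if (!is_pow2(k) || S %% k != 0) {
    stop("duplicate requires a power-of-two tile width dividing the slot count",
         call. = FALSE)
  }
  rounds <- log2_int(S / k)
  for (j in seq_len(rounds)) {
    v <- ct_add(v, ct_rotate(v, k * 2L^(j - 1L)))
  }
  v
}

#' CP matrix-vector product
#'
#' Replicates the vector, multiplies each column cipher by its replicated
#' entry and sums: one ciphertext-multiplication level and one plaintext
#' level (the replicate masks).
#'
#' @param A A `cp_matrix` (n x m).
#' @param v A `slot_cipher` holding `m` values.
#' @return A `slot_cipher` whose leading `n` slots hold `A %*% v`.
#' @export
cp_matvec <- function(A, v) {
  nu <- ct_replicate(v, A$n_cols)
  acc <- ct_mult(A$columns[[1L]], nu[[1L]])
  for (j in seq_len(A$n_cols - 1L) + 1L) {
    acc <- ct_add(acc, ct_mult(A$columns[[j]], nu[[j]]))
  }
  acc
}

#' CP matrix product
#'
#' Iterated [cp_matvec()] over the right-hand side's columns.
#'
#' @param A,B `cp_matrix` objects with `A$n_cols == B$n_rows`.
#' @return A `cp_matrix` holding `A %*% B`.
#' @export
cp_matmul <- function(A, B) {
  if (A$n_cols != B$n_rows) {
    stop("shape error: A has ", A$n_cols, " columns but B has ", B$n_rows,
         " rows", call. = FALSE)
  }
  cols <- lapply(B$columns, function(bj) cp_matvec(A, bj))
  structure(list(columns = cols, n_rows = A$n_rows, n_cols = B$n_cols,
                 padded_rows = A$padded_rows),
            class = "cp_matrix")
}

#' Column sums of a CCP matrix
#'
#' `log2(col_size)` left-rotation-and-addition rounds; afterwards slot
#' `(j-1) * col_size` holds the sum of column `j` (other slots carry partial
#' cross-column sums and are ignored).
#'
#' @param M A `ccp_matrix`.
#' @return A `slot_cipher` with the column sums at stride `col_size`.
#' @export
ccp_colsum <- function(M) {
  v <- if (inherits(M, "ccp_matrix")) M$body else M
  cs <- if (inherits(M, "ccp_matrix")) M$col_size else
    stop("ccp_colsum expects a ccp_matrix")
  for (j in seq_len(log2_int(cs))) {
    v <- ct_add(v, ct_rotate(v, 2L^(j - 1L), direction = "left"))
  }
  v
}

#' Dot product of two slot vectors
#'
#' Multiplies slot-wise, tiles the `len`-slot segment across the cipher with
#' [ct_duplicate()] and rotate-sums within the tile, leaving the dot product
#' in every slot.
#'
#' @param u,v `slot_cipher` objects whose nonzero slots lie in the first
#'   `len` positions.
#' @param len Power-of-two segment length.
#' @return A `slot_cipher` with every slot equal to `sum(u * v)`.
#' @export
ct_dotprod <- function(u, v, len) {
  stopifnot(is_pow2(len))
  m <- ct_mult(u, v)
  m <- ct_duplicate(m, len)
  for (j in seq_len(log2_int(len))) {
    m <- ct_add(m, ct_rotate(m, 2L^(j - 1L), direction = "left"))
  }
  m
}

#' RP matrix-vector product
#'
#' Applies [ct_dotprod()] to every row, then combines the per-row results
#' with plaintext indicator masks and additions; one ciphertext level plus
#' one plaintext (mask) level.
#'
#' @param A An `rp_matrix` (n x m).
#' @param v A `slot_cipher` holding `m` values.
#' @return A `slot_cipher` whose slot `i` holds `row_i . v`.
#' @export
rp_matvec <- function(A, v) {
  S <- length(v$slots)
  acc <- NULL
  for (i in seq_len(A$n_rows)) {
    d <- ct_dotprod(A$rows[[i]], v, A$padded_cols)
    mask <- numeric(S)
    mask[i] <- 1
    term <- ct_mult(d, mask)
    acc <- if (is.null(acc)) term else ct_add(acc, term)
  }
  acc
}

#' CP x REP matrix product, producing a CCP matrix
#'
#' Each CP column is tiled across the cipher with [ct_duplicate()] and
#' multiplied with the matching REP row; the terms sum to the product in CCP
#' layout with column stride equal to the CP matrix's padded row count.
#'
#' @param A A `cp_matrix` (n x m).
#' @param B A `rep_matrix` (m x p) with `rep_factor == A$padded_rows`.
#' @return A `ccp_matrix` holding `A %*% B`.
#' @export
cp_rep_matmul <- function(A, B) {
  if (A$n_cols != B$n_rows) {
    stop("shape error: A has ", A$n_cols, " columns but B has ", B$n_rows,
         " rows", call. = FALSE)
  }
  if (B$rep_factor != A$padded_rows) {
    stop("layout error: REP rep_factor ", B$rep_factor,
         " does not match CP padded row count ", A$padded_rows,
         call. = FALSE)
  }
  acc <- NULL
  for (j in seq_len(A$n_cols)) {
    d <- ct_duplicate(A$columns[[j]], A$padded_rows)
    term <- ct_mult(d, B$rows[[j]])
    acc <- if (is.null(acc)) term else ct_add(acc, term)
  }
  structure(list(body = acc, n_rows = A$n_rows, n_cols = B$n_cols,
                 col_size = A$padded_rows),
            class = "ccp_matrix")
}

#' Convert a CCP matrix to CP form
#'
#' Column `j` is isolated with a plaintext mask over its stride window and
#' rotated down to the leading slots.
#'
#' @param M A `ccp_matrix`.
#' @return A `cp_matrix` with `padded_rows == M$col_size`.
#' @export
ccp_to_cp <- function(M) {
  S <- length(M$body$slots)
  cols <- lapply(seq_len(M$n_cols), function(j) {
    mask <- numeric(S)
    mask[(j - 1L) * M$col_size + seq_len(M$col_size)] <- 1
    ct <- ct_mult(M$body, mask)
    ct_rotate(ct, (j - 1L) * M$col_size, direction = "left")
  })
  structure(list(columns = cols, n_rows = M$n_rows, n_cols = M$n_cols,
                 padded_rows = M$col_size),
            class = "cp_matrix")
}

#' @export
print.cp_matrix <- function(x, ...) {
  cat(sprintf("cp_matrix: %d x %d (padded rows %d), %d ciphers\n",
              x$n_rows, x$n_cols, x$padded_rows, length(x$columns)))
  invisible(x)
}

#' @export
print.ccp_matrix <- function(x, ...) {
  cat(sprintf("ccp_matrix: %d x %d, column stride %d, 1 cipher\n",
              x$n_rows, x$n_cols, x$col_size))
  invisible(x)
}

#' @export
print.rp_matrix <- function(x, ...) {
  cat(sprintf("rp_matrix: %d x %d (padded cols %d), %d ciphers\n",
              x$n_rows, x$n_cols, x$padded_cols, length(x$rows)))
  invisible(x)
}

#' @export
print.rep_matrix <- function(x, ...) {
  cat(sprintf("rep_matrix: %d x %d, rep factor %d, %d ciphers\n",
              x$n_rows, x$n_cols, x$rep_factor, length(x$rows)))
  invisible(x)
}
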