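# Simulated CKKS slot semantics: exact complex slot arithmetic plus the
# level (noise-budget) bookkeeping and operation metering of the real
# scheme.  The simulator models what the slots *hold*, not the lattice
# encryption around them, so decode(encode(v)) is exact and an optional
# Gaussian perturbation per rescale stands in for CKKS approximation error.

#' Scheme parameters for the slot simulator
#'
#' Mirrors the parameters a CKKS context is built from: the ring degree
#' \eqn{N} (a power of two; a ciphertext carries \eqn{N/2} complex slots),
#' the initial noise budget \eqn{\log L} in bits, and the rescale amounts
#' \eqn{\log p} consumed by ciphertext-ciphertext and ciphertext-plaintext
#' multiplications.
#'
#' @param log_ring_degree Integer, \eqn{\log_2 N}. The slot count is
#'   `2^(log_ring_degree - 1)`.
#' @param initial_budget_bits Integer, the fresh-ciphertext level in bits
#'   (default 2440, the configuration used for the full-size circuit).
#' @param ct_rescale_bits Bits consumed by a ciphertext-ciphertext
#'   multiplication (default 45).
#' @param pt_rescale_bits Bits consumed by a ciphertext-plaintext
#'   multiplication, including masking (default 10).
#' @return An object of class `scheme_params`.
#' @export
scheme_params <- function(log_ring_degree = 17L,
                          initial_budget_bits = 2440L,
                          ct_rescale_bits = 45L,
                          pt_rescale_bits = 10L) {
  log_ring_degree <- as.integer(log_ring_degree)
  initial_budget_bits <- as.integer(initial_budget_bits)
  ct_rescale_bits <- as.integer(ct_rescale_bits)
  pt_rescale_bits <- as.integer(pt_rescale_bits)
  stopifnot(log_ring_degree >= 2L)
  if (!(initial_budget_bits > ct_rescale_bits &&
        ct_rescale_bits > pt_rescale_bits && pt_rescale_bits > 0L)) {
    stop("scheme_params requires initial_budget_bits > ct_rescale_bits > ",
         "pt_rescale_bits > 0", call. = FALSE)
  }
  structure(
    list(
      log_ring_degree = log_ring_degree,
      slot_count = as.integer(2^(log_ring_degree - 1L)),
      initial_budget_bits = initial_budget_bits,
      ct_rescale_bits = ct_rescale_bits,
      pt_rescale_bits = pt_rescale_bits
    ),
    class = "scheme_params"
  )
}

#' @export
print.scheme_params <- function(x, ...) {
  cat(sprintf(
    "CKKS scheme parameters: log N = %d (%d slots), log L = %d, log p = %d (ct) / %d (pt)\n",
    x$log_ring_degree, x$slot_count, x$initial_budget_bits,
    x$ct_rescale_bits, x$pt_rescale_bits))
  invisible(x)
}

#' Create a simulator context
#'
#' The context owns the scheme parameters and the operation meter. Every
#' cipher created under a context is metered against it; a fresh context
#' means fresh counters, so one circuit per context gives a clean depth
#' report.
#'
#' @param params A [scheme_params()] object.
#' @param noise_sigma Standard deviation of an optional zero-mean Gaussian
#'   perturbation added to every slot at each rescale, emulating CKKS
#'   approximation error. The default 0 keeps the simulator exact.
#' @return An environment of class `ckks_context`.
#' @export
ckks_context <- function(params = scheme_params(), noise_sigma = 0) {
  stopifnot(inherits(params, "scheme_params"), noise_sigma >= 0)
  ctx <- new.env(parent = emptyenv())
  ctx$params <- params
  ctx$noise_sigma <- noise_sigma
  ctx$totals <- c(ct_mult = 0, pt_mult = 0, rotations = 0, conjugations = 0)
  ctx$rescale_counts <- integer(0)  # named by rescale amount
  ctx$max_depth <- c(ct = 0, pt = 0, rot = 0, rescale = 0)
  class(ctx) <- c("ckks_context", "environment")
  ctx
}

#' @export
print.ckks_context <- function(x, ...) {
  cat("CKKS simulator context\n")
  print(x$params)
  cat(sprintf("  totals: %s\n",
              paste(names(x$totals), x$totals, sep = "=", collapse = ", ")))
  cat(sprintf("  max depth: ct-mult %d, pt-mult %d\n",
              x$max_depth[["ct"]], x$max_depth[["pt"]]))
  invisible(x)
}

meter_bump <- function(ctx, what, amount = 1) {
  ctx$totals[[what]] <- ctx$totals[[what]] + amount
}

meter_rescale <- function(ctx, bits) {
  key <- as.character(bits)
  cur <- ctx$rescale_counts
  cur[key] <- (if (key %in% names(cur)) cur[[key]] else 0L) + 1L
  ctx$rescale_counts <- cur
}

new_cipher <- function(ctx, slots, level, depth) {
  ctx$max_depth <- pmax(ctx$max_depth, depth[names(ctx$max_depth)])
  structure(
    list(slots = slots, level = as.integer(level), depth = depth, ctx = ctx),
    class = "slot_cipher"
  )
}

zero_depth <- function() c(ct = 0, pt = 0, rot = 0, rescale = 0)

#' Encode a value vector into slots
#'
#' Pads a numeric or complex vector with zeros up to the slot count. In the
#' simulator encoding is exact, so `decode(encode(v))` returns `v`.
#'
#' @param values Numeric or complex vector of length at most the slot count.
#' @param params A [scheme_params()] object.
#' @return A complex vector of length `params$slot_count`.
#' @export
encode_slots <- function(values, params) {
  stopifnot(inherits(params, "scheme_params"))
  n <- length(values)
  if (n > params$slot_count) {
    stop(sprintf("capacity error: %d values exceed the %d available slots",
                 n, params$slot_count), call. = FALSE)
  }
  slots <- complex(params$slot_count)
  if (n > 0) slots[seq_len(n)] <- as.complex(values)
  slots
}

#' Decode slots back to a value vector
#'
#' @param slots Complex slot vector.
#' @param n Number of leading slots to return (default all).
#' @return Complex vector of length `n`.
#' @export
decode_slots <- function(slots, n = length(slots)) {
  slots[seq_len(n)]
}

#' Encrypt a vector into a fresh cipher
#'
#' Slot-level lift: the values are encoded into slots and the cipher starts
#' at the full initial budget with empty operation history. No key material
#' is simulated.
#'
#' @param values Numeric or complex vector (length at most the slot count).
#' @param ctx A [ckks_context()].
#' @return A `slot_cipher`.
#' @export
ct_encrypt <- function(values, ctx) {
  stopifnot(inherits(ctx, "ckks_context"))
  new_cipher(ctx, encode_slots(values, ctx$params),
             ctx$params$initial_budget_bits, zero_depth())
}

#' Decrypt a cipher to its slot values
#'
#' @param ct A `slot_cipher`.
#' @param n Number of leading slots to return (default all).
#' @return Complex vector.
#' @export
ct_decrypt <- function(ct, n = length(ct$slots)) {
  stopifnot(inherits(ct, "slot_cipher"))
  decode_slots(ct$slots, n)
}

#' @export
print.slot_cipher <- function(x, ...) {
  head_n <- min(8L, length(x$slots))
  cat(sprintf(
    "slot_cipher: %d slots, level %d bits, depth ct=%d pt=%d rot=%d\n",
    length(x$slots), x$level,
    x$depth[["ct"]], x$depth[["pt"]], x$depth[["rot"]]))
  cat("  slots[1..", head_n, "]: ",
      paste(format(x$slots[seq_len(head_n)], digits = 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

check_same_ctx <- function(a, b) {
  if (!identical(a$ctx, b$ctx)) {
    stop("operands belong to different simulator contexts", call. = FALSE)
  }
  if (length(a$slots) != length(b$slots)) {
    stop("shape error: mismatched slot counts", call. = FALSE)
  }
}

# Plaintext operand lifted to a full slot vector (zero padded).
as_plain_slots <- function(x, params) {
  if (length(x) == 1L) return(rep(as.complex(x), params$slot_count))
  encode_slots(x, params)
}

maybe_noise <- function(ctx, slots) {
  if (ctx$noise_sigma > 0) {
    n <- length(slots)
    slots <- slots + complex(real = stats::rnorm(n, 0, ctx$noise_sigma),
                             imaginary = stats::rnorm(n, 0, ctx$noise_sigma))
  }
  slots
}

#' Add two ciphers
#'
#' Slot-wise sum. Addition is level-free: no counters move, and operands at
#' unequal levels are silently aligned to the lower one (the mod-switch
#' analogue).
#'
#' @param a,b `slot_cipher` objects under the same context.
#' @return A `slot_cipher`.
#' @export
ct_add <- function(a, b) {
  check_same_ctx(a, b)
  new_cipher(a$ctx, a$slots + b$slots, min(a$level, b$level),
             pmax(a$depth, b$depth))
}

#' Subtract one cipher from another
#'
#' @param a,b `slot_cipher` objects under the same context.
#' @return A `slot_cipher` holding `a - b` slot-wise.
#' @export
ct_sub <- function(a, b) {
  check_same_ctx(a, b)
  new_cipher(a$ctx, a$slots - b$slots, min(a$level, b$level),
             pmax(a$depth, b$depth))
}

#' Negate a cipher
#'
#' Negation is additive and therefore free: no level or counter change.
#'
#' @param a A `slot_cipher`.
#' @return A `slot_cipher` holding `-a`.
#' @export
ct_neg <- function(a) {
  new_cipher(a$ctx, -a$slots, a$level, a$depth)
}

#' Add a plaintext vector or scalar to a cipher
#'
#' Plaintext addition does not consume budget and is not metered.
#'
#' @param a A `slot_cipher`.
#' @param plain Numeric or complex scalar or vector.
#' @return A `slot_cipher`.
#' @export
ct_add_plain <- function(a, plain) {
  new_cipher(a$ctx, a$slots + as_plain_slots(plain, a$ctx$params),
             a$level, a$depth)
}

#' Multiply a cipher by a cipher or a plaintext
#'
#' Slot-wise product followed by the automatic rescale: `ct_rescale_bits`
#' when both operands are ciphers, `pt_rescale_bits` when the second operand
#' is a plaintext vector or scalar (the cheap-plaintext-rescale
#' optimisation). Levels are first aligned to the lower operand. An
#' operation that would leave a negative level raises a noise-budget error.
#'
#' @param a A `slot_cipher`.
#' @param b A `slot_cipher`, or a numeric/complex plaintext (scalar or
#'   vector, zero-padded to the slot count).
#' @return A `slot_cipher`.
#' @export
ct_mult <- function(a, b) {
  ctx <- a$ctx
  p <- ctx$params
  if (inherits(b, "slot_cipher")) {
    check_same_ctx(a, b)
    lv <- min(a$level, b$level)
    if (lv < p$ct_rescale_bits) {
      stop(sprintf(
        "noise budget exhausted in ct_mult: level %d < rescale %d bits",
        lv, p$ct_rescale_bits), call. = FALSE)
    }
    meter_bump(ctx, "ct_mult")
    meter_rescale(ctx, p$ct_rescale_bits)
    depth <- pmax(a$depth, b$depth) +
      c(ct = 1, pt = 0, rot = 0, rescale = 1)
    slots <- maybe_noise(ctx, a$slots * b$slots)
    new_cipher(ctx, slots, lv - p$ct_rescale_bits, depth)
  } else {
    lv <- a$level
    if (lv < p$pt_rescale_bits) {
      stop(sprintf(
        "noise budget exhausted in ct_mult (plaintext): level %d < rescale %d bits",
        lv, p$pt_rescale_bits), call. = FALSE)
    }
    meter_bump(ctx, "pt_mult")
    meter_rescale(ctx, p$pt_rescale_bits)
    depth <- a$depth + c(ct = 0, pt = 1, rot = 0, rescale = 1)
    slots <- maybe_noise(ctx, a$slots * as_plain_slots(b, p))
    new_cipher(ctx, slots, lv - p$pt_rescale_bits, depth)
  }
}

#' Mask a cipher with a plaintext 0/1 indicator
#'
#' A convenience wrapper around plaintext multiplication; costs one
#' plaintext rescale.
#'
#' @param a A `slot_cipher`.
#' @param mask Numeric 0/1 vector (zero-padded to the slot count).
#' @return A `slot_cipher`.
#' @export
ct_mask <- function(a, mask) ct_mult(a, mask)

#' Rotate cipher slots
#'
#' Right rotation: slot `i` moves to slot `(i + r) mod slot_count`. Left
#' rotation (`direction = "left"`) moves slot `i + r` into slot `i`; both
#' directions are native power-of-two key switches, so either costs
#' `popcount_rotations(r)` metered rotations. `r` outside
#' `[0, slot_count)` is reduced modulo the slot count with a warning.
#'
#' @param a A `slot_cipher`.
#' @param r Integer rotation amount.
#' @param direction `"right"` (default) or `"left"`.
#' @return A `slot_cipher`.
#' @export
ct_rotate <- function(a, r, direction = c("right", "left")) {
  direction <- match.arg(direction)
  S <- length(a$slots)
  if (r < 0 || r >= S) {
    warning(sprintf("rotation amount %d reduced modulo slot count %d", r, S))
    r <- ((r %% S) + S) %% S
  }
  if (r == 0) return(a)
  cost <- popcount_rotations(r)
  meter_bump(a$ctx, "rotations", cost)
  idx <- if (direction == "right") {
    ((seq_len(S) - 1L - r) %% S) + 1L
  } else {
    ((seq_len(S) - 1L + r) %% S) + 1L
  }
  depth <- a$depth + c(ct = 0, pt = 0, rot = cost, rescale = 0)
  new_cipher(a$ctx, a$slots[idx], a$level, depth)
}

#' Conjugate cipher slots
#'
#' Slot-wise complex conjugation; level-free, counted by the meter.
#'
#' @param a A `slot_cipher`.
#' @return A `slot_cipher`.
#' @export
ct_conj <- function(a) {
  meter_bump(a$ctx, "conjugations")
  new_cipher(a$ctx, Conj(a$slots), a$level, a$depth)
}

#' Circuit depth report
#'
#' Summarises the meter of a context: the longest sequential chain of each
#' operation class over all ciphers produced (the critical path of the
#' circuit DAG: each multiplication adds one to the deeper of its operands'
#' chains) together with operation totals and rescale counts by amount.
#'
#' @param ctx A [ckks_context()] after a circuit has run.
#' @return A list of class `depth_report` with elements `ct_mult_depth`,
#'   `pt_mult_depth`, `rotation_depth`, `rescale_depth`, `rescale_counts`
#'   and `totals`.
#' @export
depth_report <- function(ctx) {
  stopifnot(inherits(ctx, "ckks_context"))
  structure(
    list(
      ct_mult_depth = as.integer(ctx$max_depth[["ct"]]),
      pt_mult_depth = as.integer(ctx$max_depth[["pt"]]),
      rotation_depth = as.integer(ctx$max_depth[["rot"]]),
      rescale_depth = as.integer(ctx$max_depth[["rescale"]]),
      rescale_counts = as.list(ctx$rescale_counts),
      totals = as.list(ctx$totals)
    ),
    class = "depth_report"
  )
}

#' @export
print.depth_report <- function(x, ...) {
  cat("Circuit depth (longest sequential chains)\n")
  cat(sprintf("  ciphertext multiplications: %d\n", x$ct_mult_depth))
  cat(sprintf("  plaintext multiplications:  %d\n", x$pt_mult_depth))
  cat(sprintf("  rotations (power-of-two):   %d\n", x$rotation_depth))
  cat(sprintf("  rescales:                   %d\n", x$rescale_depth))
  if (length(x$rescale_counts)) {
    cat("  rescale totals by amount: ",
        paste(sprintf("log p=%s: %d", names(x$rescale_counts),
                      unlist(x$rescale_counts)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a depth report as JSON
#'
#' @param report A [depth_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_report <- function(report, path) {
  stopifnot(inherits(report, "depth_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
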