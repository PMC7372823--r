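# Small power-of-two helpers shared across packings and the meter.

#' Round up to the nearest power of two
#'
#' Packed encodings pad column and row strides to a power of two so that
#' rotate-and-add reductions and tilings stay aligned.
#'
#' @param n A non-negative integer.
#' @return The smallest power of two that is `>= n` (and `>= 1`).
#' @export
next_pow2 <- function(n) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 0)
  if (n <= 1) return(1L)
  as.integer(2^ceiling(log2(n)))
}

is_pow2 <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

#' Number of power-of-two rotations composing a rotation
#'
#' A cyclic rotation by `r` slots is realised as the composition of the
#' power-of-two rotations named by the ones in the binary expansion of `r`,
#' so its cost is the popcount of `r`.
#'
#' @param r A non-negative integer rotation amount.
#' @return Integer count of power-of-two rotations required.
#' @examples
#' popcount_rotations(245)  # 6: 245 = 11110101b
#' popcount_rotations(256)  # 1
#' @export
popcount_rotations <- function(r) {
  stopifnot(length(r) == 1L, is.finite(r), r >= 0)
  r <- as.integer(r)
  count <- 0L
  while (r > 0L) {
    count <- count + bitwAnd(r, 1L)
    r <- bitwShiftR(r, 1L)
  }
  count
}
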