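# Shared fixtures: small simulator contexts and synthetic cohorts built in
# code at test time.

tiny_ctx <- function(log_ring_degree = 7L, initial_budget_bits = 2440L,
                     ...) {
  ckks_context(scheme_params(log_ring_degree = log_ring_degree,
                             initial_budget_bits = initial_budget_bits),
               ...)
}

rand_cplx <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))

make_cohort <- function(n, d = 2L, k = 8L, seed = 1L, ...) {
  generate_cohort(cohort_spec(n = n, d = d, k = k, seed = seed, ...))
}
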