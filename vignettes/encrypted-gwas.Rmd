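---
title: "Semi-parallel GWAS on a simulated CKKS backend: model, circuit and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-parallel GWAS on a simulated CKKS backend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegwas)
```

## What the package computes

A genome-wide association study fits, for each SNP `g_j`, the logistic model
`logit P(y=1) = x'β + s_j g_j` and reports the SNP effect and its error.
Refitting per SNP is prohibitively expensive under homomorphic encryption,
so the package implements the *semi-parallel* reformulation: fit the
covariate-only model once, then obtain every `s_j` from one round of shared
matrix algebra — a weighted least-squares step on the working response of
the logistic fit. All heavy computation is expressed as slot-wise
ciphertext operations of the CKKS scheme; this package executes them on a
simulated backend so that results, noise budgets and operation depths can
be verified exactly against cleartext oracles.

## The backend model and its assumptions

A ciphertext is modelled as a vector of `N/2` complex slots plus an integer
level (remaining noise budget in bits). The simulator is faithful to the
scheme's *semantics*, not its cryptography:

* Slot arithmetic (add, multiply, rotate, conjugate) is exact complex
  arithmetic; `decode(encode(v)) == v`. An optional mode adds a zero-mean
  Gaussian perturbation per rescale (`noise_sigma`) to emulate CKKS
  approximation error; the default is exact, which is what a clean oracle
  needs.
* Every ciphertext–ciphertext multiplication rescales by
  `ct_rescale_bits` (default 45) and every ciphertext–plaintext
  multiplication — including 0/1 masks — by `pt_rescale_bits` (default 10),
  against a fresh budget of `initial_budget_bits` (default 2440). An
  operation that would drive the level negative raises a "noise budget
  exhausted" error naming the operation; the pipeline annotates it with the
  stage. When operands sit at unequal levels the higher one is silently
  aligned down (the mod-switch analogue), so callers never manage levels.
* Key generation, lattice sampling and security estimation are not
  simulated; `ct_encrypt`/`ct_decrypt` are slot-level lift and open.
* A rotation by `r` is metered as `popcount(r)` power-of-two rotations
  (both directions are native key switches); the value-level result is a
  cyclic shift, with "right" meaning slot `i` moves to `(i + r) mod N/2`.

The meter attributes depth per cipher: each multiplication records one more
than the deeper of its operands' chains, so the report is the critical path
of the circuit DAG even when stages branch and re-join.

## Packings

Four encodings cover the pipeline's needs: **CP** (one cipher per column,
rows zero-padded to a power of two), **CCP** (all columns concatenated in
one cipher at a power-of-two stride), **RP** (one cipher per row) and
**REP** (one cipher per row with each entry repeated `q` times, `q` a power
of two). Packing is responsible for zeroing padding slots; every algorithm
assumes and preserves that invariant. `Replicate` (mask + spread, the naive
form) feeds CP matrix–vector products; `Duplicate` (tile the leading `k`
slots, `log2(slots/k)` rotations) feeds dot products and the CP×REP matrix
product, which lands directly in CCP layout. Column sums of a CCP matrix
take `log2(col_size)` rotate-and-add rounds and leave each column's sum at
its stride position.

## The logistic stage

Newton–Raphson is made HE-friendly by (i) the fixed curvature bound
`X'X/4`, whose inverse is computed in clear (`precompute_xtx_inv`) and
encrypted as an input, and (ii) a degree-7 polynomial sigmoid on `x/8`.

Two details are deliberate:

* **Sigmoid orientation.** The widely used magnitude-coefficients of the
  degree-7 least-squares fit are conventionally quoted for a sigmoid
  parameterized on the *negated* linear predictor. This package's
  `sigmoid7` is oriented to approximate the increasing logistic
  `1/(1+e^{-x})` of the model equation — with the decreasing orientation
  the fixed-step recursion moves against the gradient and diverges within
  three iterations, which we verified numerically. `σ₇(0) = 0.5` and the
  symmetry `σ₇(x) + σ₇(−x) = 1` hold either way.
* **Iteration ordering.** Each iteration first updates the coefficients
  from the current probabilities, then refreshes the probabilities from the
  updated coefficients, starting from `β = 0` whose probability vector is
  the constant 0.5 (a plaintext, since `σ₇(0) = 0.5`):
  `β ← β + 4(X'X)⁻¹X'(y − p)`, then `p ← σ₇(Xβ)` re-masked to the sample
  slots. This is the same coefficient recursion as sigmoid-first ordering,
  but the returned probabilities correspond to the returned coefficients,
  and the downstream working weights then ride on the full three-iteration
  chain — which pins the metered depth of the full circuit (below). The
  sigmoid re-mask is forced by correctness:
  `σ₇(0) = 0.5` would otherwise plant phantom half-samples in every padding
  slot and leak into all later column sums.

The recursion contracts to its own fixed point — the maximizer under the
polynomial sigmoid — which carries a small bias relative to the exact MLE
(the tests bound it by 0.05 per coefficient on a moderate-signal cohort).
The distance to the *exact* MLE is typically not monotone over iterations:
the first fixed step is nearly unbiased, later steps converge to the
polynomial's optimum. Three iterations (`kappa = 3`, the default) land
within the accuracy the association stage needs.

## The association stage

From the final state: `w = p(1−p)` masked to the samples; `w⁻¹` by the
Newton iteration `x ← x(2 − wx)` from `x₀ = 3` (sensible because
`w ≤ 0.25`, so `1/w ≥ 4`); `z = Xβ + w⁻¹(y − p)`;
`z' = z − X(X'X)⁻¹X'z` via one RP and two CP matrix–vector products; the
projection `M = I − X(X'X)⁻¹X'` assembled once per run as a CP×CP product
followed by a CP×REP product (CCP, stride `⌈n⌉`), an identity subtraction
in plaintext layout and a CCP→CP conversion.

Each batch of `τ = 2·slots/⌈n⌉` SNPs is packed two per complex slot,
projected with `S' = M S` (one CP×REP product — the projection is real, so
both packed SNPs project at once), squared per packed component with the
conjugate trick, and reduced by column sums:
`numerator = colSum((w ⊙ z') ⊗ S')` (real part: even SNPs; imaginary part:
odd SNPs) and `denominator = colSum(w ⊗ x²)`, `colSum(w ⊗ y²)`. Numerators
and denominators are decrypted and divided in clear; `err' = 1/denominator`
is reported as-is (a conventional standard error would be its square root).
A flag (`numerator_weight = "w_inv"`) reproduces a variant that weights the
numerator by the reciprocal weights instead; the default follows the
defining formula, and the cleartext oracle mirrors whichever is chosen.

Numerical edge cases: a monomorphic SNP column projects to (numerically)
zero, so denominators below `1e-8` yield `NA` effects rather than an error;
the ragged final batch is zero-padded, and padded columns produce exactly
zero sums.

### Reciprocal accuracy and the padding guard

The Newton residual satisfies `1 − w·x_t = (1 − 3w)^{2^t}`, so with the
default six iterations the relative error is below `1e-6` for `w ≥ 0.1` and
below `1e-4` down to `w = 0.05`; fitted weights below ~0.05 (probabilities
beyond roughly 0.95) would need a seventh iteration, at the cost of two
more ciphertext levels. Padding slots of `w` are zero, where the iteration
started at 3 diverges; they are set to `1/3` — the iteration's fixed point
from that start — before inversion and masked back to zero afterwards.

### Masking policy

Plaintext masks cost a 10-bit rescale each, so they are placed exactly
where an invariant requires them: the probability vector each iteration
(sigmoid pollution), `w` (products of masked factors are re-masked to keep
the invariant explicit for a real backend, where padding slots hold noise
rather than exact zeros), `w⁻¹` (padding guard removal), `z` and `z'` (work
vectors consumed by tiling), and the weighted response `u = w ⊙ z'` before
`Duplicate`, whose tiling precondition is that slots beyond the stride are
zero.

## Depth accounting

With `kappa = 3`, the four-level sigmoid, six reciprocal iterations and the
stage order and masking policy above, the meter reports a critical path of
**40 ciphertext multiplications** and **29 plaintext multiplications**
for the full circuit. The path runs through the
three logistic iterations (7 ciphertext, 7 plaintext levels each), the
weight product, the reciprocal (2 ciphertext levels per iteration), the
working response, its three-product orthogonalization, the numerator weight
and the final batch product. The depths are a property of the circuit
shape, not of the data or the cohort size, which is why the acceptance
script meters a small cohort. Budget check: `40×45 + 29×10 = 2090 ≤ 2440`
bits, leaving 350 bits of headroom on the deepest cipher. Rotation depth is
reported but not asserted: it depends on conventions (which rotations are
counted as native) that the value-level results cannot distinguish.

## Scheme and pipeline parameters

| parameter | default | meaning |
|---|---|---|
| `log_ring_degree` | smallest with `⌈n⌉² ≤ N/2` (17 at n = 245) | ring degree; `N/2` slots; the projection needs `⌈n⌉²` slots, capping n at 256 for `N = 2¹⁷` |
| `initial_budget_bits` | 2440 | fresh-cipher level (log L) |
| `ct_rescale_bits` / `pt_rescale_bits` | 45 / 10 | rescale per ciphertext / plaintext multiplication |
| `kappa` | 3 | logistic iterations |
| `recip_iters` | 6 | Newton reciprocal iterations |
| `noise_sigma` | 0 | per-rescale Gaussian emulation of CKKS error |
| `batch_size_override` | packing limit `2·slots/⌈n⌉` | SNPs per batch |

## The synthetic generator

Real genotype panels of this kind are not redistributable, so cohorts are
generated with the statistical structure the pipeline assumes: standardized
Gaussian covariates behind an intercept, per-SNP minor-allele frequencies
uniform on `maf_range`, genotypes `Binomial(2, maf)` kept on the 0/1/2
scale (the pipeline applies no SNP normalization; standardization enters
only the construction of planted causal effects), and a Bernoulli phenotype
from the *exact* logistic link — the generator models the truth, the
pipeline the approximation. It does not model linkage disequilibrium,
population stratification or missing genotypes, so passing tests certify
the algebra and the approximations, not robustness to those features of
real data.

Problem sizes in the tests are the package's choices for exhaustive
verification at interactive speed: slot-level properties on 64-slot rings,
end-to-end encrypted-vs-oracle equivalence on twenty cohorts with
`n ≤ 64, k ≤ 64`, depth metering at `n = 16`, and the statistical sign
check (a planted effect of 0.5 at allele frequency 0.3, `n = 245`, 200
replicates, run through the cleartext twin whose equivalence to the
encrypted pipeline the other tests establish — the encrypted run at
`n = 245` is exercised once in the examples).

## Evaluation metrics

`accuracy_count` counts entries of two effect vectors differing by more
than a threshold `e` (missing pairs count as differing) and reports the
complementary percentage; `best_fit` reports the least-squares line of one
vector against the other, ideally `y = x`. The metrics operate on whatever
vectors are passed — conventionally the modified effects `b'` against the
original algorithm's `b`; the corresponding error terms could be compared
the same way.

## Known limitations

* The sample count is capped by the ring (`⌈n⌉² ≤ N/2`): 256 subjects at
  `log N = 17`; larger cohorts need the next ring size.
* `err'` is the reciprocal denominator, not a variance estimate under the
  polynomial-sigmoid fit; treat it as the algorithm's reported error term.
* Weights below ~0.05 exceed the six-iteration reciprocal's comfort zone
  (see above).
* The simulator validates semantics and depth, not security or timing; a
  real-backend adapter would additionally need explicit rescale placement
  and rotation-key management.
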