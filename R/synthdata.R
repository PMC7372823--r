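# Synthetic cohort generation.  Genotype panels of the kind the pipeline
# was designed around are not redistributable, so cohorts with the same
# statistical shape are generated: standardized Gaussian covariates with an
# intercept, per-SNP minor-allele frequencies drawn uniformly from a range,
# genotypes Binomial(2, maf), and a Bernoulli phenotype from a logistic
# model.  The phenotype link uses the exact sigmoid: the generator models
# the truth, the pipeline models the approximation.

#' Specify a synthetic cohort
#'
#' @param n Samples (must exceed the coefficient count by at least one).
#' @param d Covariates (the design adds an intercept).
#' @param k SNPs.
#' @param maf_range Minor-allele-frequency interval within (0, 0.5];
#'   per-SNP frequencies are drawn uniformly from it.
#' @param beta_true True covariate coefficients, length `d + 1` (intercept
#'   first). Default: intercept -0.2 and alternating +/-0.3 covariate
#'   effects, giving a roughly balanced phenotype with modest covariate
#'   signal.
#' @param causal Optional `data.frame(index, effect)` of causal SNPs; each
#'   contributes `effect * standardized genotype` to the linear predictor
#'   (standardization only affects the construction of the truth — the
#'   pipeline sees genotypes on the 0/1/2 scale).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, d, k, maf_range = c(0.05, 0.5),
                        beta_true = NULL, causal = NULL, seed = 1L) {
  n <- as.integer(n); d <- as.integer(d); k <- as.integer(k)
  stopifnot(n >= d + 2L, d >= 1L, k >= 1L)
  if (!(length(maf_range) == 2L && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2])) {
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  }
  if (is.null(beta_true)) {
    beta_true <- c(-0.2, rep_len(c(0.3, -0.3), d))
  }
  stopifnot(length(beta_true) == d + 1L)
  if (!is.null(causal)) {
    causal <- as.data.frame(causal)
    stopifnot(all(c("index", "effect") %in% names(causal)),
              all(causal$index >= 1L), all(causal$index <= k))
  }
  structure(list(n = n, d = d, k = k, maf_range = maf_range,
                 beta_true = beta_true, causal = causal,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_data` object: raw covariates `Z`, standardized design
#'   `X` (intercept first), phenotype `y`, genotypes `S` and the spec echo.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(spec$n * spec$d), spec$n, spec$d,
              dimnames = list(NULL, paste0("cov", seq_len(spec$d))))
  maf <- stats::runif(spec$k, spec$maf_range[1], spec$maf_range[2])
  S <- vapply(maf, function(f) stats::rbinom(spec$n, 2L, f),
              integer(spec$n))
  colnames(S) <- paste0("snp", seq_len(spec$k))
  cohort <- new_cohort_data(Z, y = integer(spec$n), S = S, spec = spec)
  eta <- as.vector(cohort$X %*% spec$beta_true)
  if (!is.null(spec$causal)) {
    for (i in seq_len(nrow(spec$causal))) {
      g <- S[, spec$causal$index[i]]
      sg <- stats::sd(g)
      if (sg == 0) {
        stop("causal SNP ", spec$causal$index[i],
             " is monomorphic in this draw; raise maf or n", call. = FALSE)
      }
      eta <- eta + spec$causal$effect[i] * (g - mean(g)) / sg
    }
  }
  cohort$y <- as.numeric(stats::rbinom(spec$n, 1L, stats::plogis(eta)))
  cohort
}
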