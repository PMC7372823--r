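# Accuracy metrics for comparing the modified algorithm's effects against
# the original algorithm's: thresholded disagreement counts and the
# least-squares best-fit line of one effect vector against the other
# (ideally y = x).

#' Thresholded disagreement count
#'
#' Counts the entries where two effect vectors differ by more than `e`
#' (pairs with a missing value in either vector count as differing) and
#' reports the complementary accuracy percentage.
#'
#' @param b,b_prime Effect vectors of equal length (original and modified
#'   algorithm; the metric applies to whatever vectors are passed).
#' @param e Error threshold.
#' @return A list of class `accuracy_report` with `error_threshold`,
#'   `n_diff`, `accuracy_pct`.
#' @export
accuracy_count <- function(b, b_prime, e) {
  if (length(b) != length(b_prime)) {
    stop("length mismatch: ", length(b), " vs ", length(b_prime),
         call. = FALSE)
  }
  diff <- abs(b - b_prime)
  n_diff <- sum(diff > e | is.na(diff))
  structure(list(error_threshold = e, n_diff = as.integer(n_diff),
                 accuracy_pct = 100 * (length(b) - n_diff) / length(b)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy at e = %g: %d differing entries, %.2f%%\n",
              x$error_threshold, x$n_diff, x$accuracy_pct))
  if (!is.null(x$slope)) {
    cat(sprintf("best fit: y = %.6g x + %.6g\n", x$slope, x$intercept))
  }
  invisible(x)
}

#' Best-fit line of one effect vector against another
#'
#' Ordinary least-squares degree-1 fit of `b_prime` on `b`; for identical
#' vectors the line is `y = x`.
#'
#' @param b,b_prime Effect vectors (missing pairs dropped).
#' @return A list with `slope` and `intercept`.
#' @export
best_fit <- function(b, b_prime) {
  if (length(b) != length(b_prime)) {
    stop("length mismatch: ", length(b), " vs ", length(b_prime),
         call. = FALSE)
  }
  keep <- is.finite(b) & is.finite(b_prime)
  b <- b[keep]; b_prime <- b_prime[keep]
  if (length(b) < 2L) stop("need at least two finite pairs", call. = FALSE)
  vb <- stats::var(b)
  if (vb == 0) stop("undefined slope: reference effects are constant",
                    call. = FALSE)
  slope <- stats::cov(b, b_prime) / vb
  list(slope = slope, intercept = mean(b_prime) - slope * mean(b))
}

#' Compare two result files
#'
#' Reads two result TSVs (see [write_gwas_results()]), computes the
#' disagreement count at `e` and the best-fit line of the test effects
#' against the reference effects, and optionally writes a JSON report and a
#' scatter plot.
#'
#' @param reference_path,test_path Result TSV paths; effects are taken from
#'   the `beta` column, matched by `snp_id`.
#' @param e Error threshold.
#' @param json_path Optional JSON output path.
#' @param plot_path Optional PNG scatter-plot path.
#' @return An `accuracy_report` with `slope` and `intercept` attached.
#' @export
compare_results <- function(reference_path, test_path, e = 0.01,
                            json_path = NULL, plot_path = NULL) {
  ref <- read_gwas_results(reference_path)
  tst <- read_gwas_results(test_path)
  tst <- tst[match(ref$snp_id, tst$snp_id), ]
  report <- accuracy_count(ref$beta, tst$beta, e)
  fit <- best_fit(ref$beta, tst$beta)
  report$slope <- fit$slope
  report$intercept <- fit$intercept
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 600, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(ref$beta, tst$beta, pch = 20,
         xlab = "reference effect b", ylab = "test effect b'",
         main = sprintf("best fit: y = %.4g x + %.4g", fit$slope,
                        fit$intercept))
    graphics::abline(0, 1, col = "grey60")
    graphics::abline(fit$intercept, fit$slope, col = "red3")
  }
  report
}
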