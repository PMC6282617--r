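#' Consensus leaf-counting metrics
#'
#' Computes the community-standard counting metrics on integer
#' predictions versus ground truth. With errors `d_i = predicted_i -
#' truth_i`:
#' * **DiC** — mean and SD of `d_i` (signed leaves);
#' * **|DiC|** — mean and SD of `|d_i|`;
#' * **MSE** — mean of `d_i^2`;
#' * **agreement** — percentage of exactly correct counts;
#' * **within-one** — percentage with `|d_i| <= 1`;
#' * **R²** — coefficient of determination `1 - SS_res/SS_tot` of
#'   predicted versus truth.
#'
#' Standard deviations use the population convention (divide by `n`),
#' under which the identity `MSE = DiC_mean² + DiC_sd²` holds exactly.
#'
#' @param predicted,truth Equal-length numeric vectors of counts.
#' @return An object of class `metrics_report` with fields `dic_mean`,
#'   `dic_sd`, `abs_dic_mean`, `abs_dic_sd`, `mse`, `agreement_pct`,
#'   `within_one_pct`, `r_squared`, `n`.
#' @export
compute_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(predicted) == 0)
    stop("invalid-input: predicted and truth must be nonempty and equal length")
  d <- as.numeric(predicted) - as.numeric(truth)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sst <- sum((truth - mean(truth))^2)
  r2 <- if (all(d == 0)) 1
        else if (sst == 0) 0
        else 1 - sum(d^2) / sst
  structure(list(
    dic_mean = mean(d),
    dic_sd = pop_sd(d),
    abs_dic_mean = mean(abs(d)),
    abs_dic_sd = pop_sd(abs(d)),
    mse = mean(d^2),
    agreement_pct = 100 * mean(d == 0),
    within_one_pct = 100 * mean(abs(d) <= 1),
    r_squared = r2,
    n = length(d)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Leaf counting metrics (n = %d)\n", x$n))
  cat(sprintf("  DiC:        %.2f (%.2f)\n", x$dic_mean, x$dic_sd))
  cat(sprintf("  |DiC|:      %.2f (%.2f)\n", x$abs_dic_mean, x$abs_dic_sd))
  cat(sprintf("  MSE:        %.2f\n", x$mse))
  cat(sprintf("  agreement:  %.1f%%   within +/-1: %.1f%%\n",
              x$agreement_pct, x$within_one_pct))
  cat(sprintf("  R-squared:  %.3f\n", x$r_squared))
  invisible(x)
}

## Mean of several metrics reports, field by field.
mean_metrics <- function(reports) {
  fields <- c("dic_mean", "dic_sd", "abs_dic_mean", "abs_dic_sd", "mse",
              "agreement_pct", "within_one_pct", "r_squared")
  out <- lapply(fields, function(f)
    mean(vapply(reports, `[[`, numeric(1), f)))
  names(out) <- fields
  out$n <- sum(vapply(reports, `[[`, numeric(1), "n"))
  structure(out, class = "metrics_report")
}

#' Distribution of signed count errors
#'
#' Integer-binned histogram of `predicted - truth` plus the fraction of
#' errors within one leaf of zero (the headline error band).
#'
#' @inheritParams compute_metrics
#' @return List with `histogram` (named integer vector over the error
#'   range; bins sum to `n`) and `within_one` (fraction in \[0, 1\]).
#' @export
error_distribution <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(predicted) == 0)
    stop("invalid-input: predicted and truth must be nonempty and equal length")
  d <- as.integer(round(predicted - truth))
  bins <- table(factor(d, levels = seq(min(d), max(d))))
  hist <- as.integer(bins)
  names(hist) <- names(bins)
  list(histogram = hist, within_one = mean(abs(d) <= 1))
}

#' Paired comparison of two methods' absolute count errors
#'
#' Two-sided t-test on per-image error differences, as used to compare
#' counting methods over a shared test set. In the degenerate case of
#' zero-variance differences (e.g. identical error vectors) the test is
#' undefined and `p = 1` is returned by convention, with a warning.
#'
#' @param abs_errors_a,abs_errors_b Per-image absolute errors of the two
#'   methods.
#' @param paired Must cover the same images in the same order when
#'   `TRUE` (the default).
#' @return List with `t`, `df`, `p_value`, `mean_difference`.
#' @export
compare_methods <- function(abs_errors_a, abs_errors_b, paired = TRUE) {
  if (paired && length(abs_errors_a) != length(abs_errors_b))
    stop("pairing error: paired comparison requires equal-length error vectors")
  if (paired) {
    dif <- abs_errors_a - abs_errors_b
    if (stats::sd(dif) == 0) {
      warning("zero-variance differences; returning p = 1 by convention")
      return(list(t = 0, df = length(dif) - 1L, p_value = 1,
                  mean_difference = mean(dif)))
    }
    tt <- stats::t.test(abs_errors_a, abs_errors_b, paired = TRUE)
  } else {
    if (stats::sd(abs_errors_a) == 0 && stats::sd(abs_errors_b) == 0) {
      warning("zero-variance samples; returning p = 1 by convention")
      return(list(t = 0,
                  df = length(abs_errors_a) + length(abs_errors_b) - 2L,
                  p_value = 1,
                  mean_difference = mean(abs_errors_a) - mean(abs_errors_b)))
    }
    tt <- stats::t.test(abs_errors_a, abs_errors_b)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(mean(abs_errors_a) -
                                                        mean(abs_errors_b)))
}

#' Evaluate a model on labeled samples
#'
#' Convenience wrapper: predicts rounded counts for the given samples
#' and summarizes them against their ground truth.
#'
#' @param model A `counting_model`.
#' @param samples List of labeled `multimodal_sample`.
#' @param ids Optional subset of sample ids to evaluate.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, samples, ids = NULL) {
  if (!is.null(ids)) {
    sid <- vapply(samples, `[[`, character(1), "sample_id")
    samples <- samples[match(ids, sid)]
  }
  truth <- vapply(samples, `[[`, integer(1), "leaf_count")
  pred <- predict_count(model, samples)
  compute_metrics(pred$rounded_count, truth)
}
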