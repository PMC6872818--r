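check_pair <- function(actual, predicted, min_n = 1L) {
  if (length(actual) != length(predicted)) {
    abort(sprintf("`actual` (n = %d) and `predicted` (n = %d) differ in length.",
                  length(actual), length(predicted)),
          class = "capsonet_contract_error")
  }
  if (length(actual) < min_n) {
    abort(sprintf("At least %d observation(s) required.", min_n),
          class = "capsonet_contract_error")
  }
  invisible(NULL)
}

#' Absolute average relative deviation (AARD)
#'
#' `mean(|predicted - actual| / actual)`: the relative error is taken
#' against the actual value, so the metric is scale-invariant but not
#' symmetric in its arguments. Actual values must be strictly positive
#' (absorption energies in eV are); zeros or negatives are a domain error,
#' never silently dropped.
#'
#' @param actual Observed values (strictly positive).
#' @param predicted Model predictions, same length.
#' @return Dimensionless non-negative scalar.
#' @examples
#' aard(c(1, 2), c(1.1, 1.8))  # 0.1
#' @export
aard <- function(actual, predicted) {
  check_pair(actual, predicted)
  if (any(actual <= 0)) {
    abort("AARD requires strictly positive actual values.",
          class = "capsonet_domain_error")
  }
  mean(abs(predicted - actual) / actual)
}

#' Root-mean-square error of prediction (RMSEP)
#'
#' @inheritParams aard
#' @return Non-negative scalar in the units of the target.
#' @export
rmsep <- function(actual, predicted) {
  check_pair(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' Mean squared error
#'
#' The quantity the trainer minimizes; identically `rmsep(...)^2`.
#'
#' @inheritParams aard
#' @return Non-negative scalar.
#' @export
mse <- function(actual, predicted) {
  check_pair(actual, predicted)
  mean((actual - predicted)^2)
}

#' Squared Pearson correlation between actual and predicted values
#'
#' The centered cross-product squared over the product of centered sums of
#' squares; symmetric in its arguments and in \[0, 1\]. A constant vector
#' has no defined correlation and raises an error rather than returning 0.
#'
#' @inheritParams aard
#' @return Scalar in \[0, 1\].
#' @export
r_squared <- function(actual, predicted) {
  check_pair(actual, predicted, min_n = 2L)
  if (sd(actual) == 0 || sd(predicted) == 0) {
    abort("R-squared is undefined for a constant vector (zero variance).",
          class = "capsonet_domain_error")
  }
  num <- sum((actual - mean(actual)) * (predicted - mean(predicted)))^2
  den <- sum((actual - mean(actual))^2) * sum((predicted - mean(predicted))^2)
  num / den
}

#' Per-subset evaluation report
#'
#' Computes AARD, R-squared and RMSEP for each split subset on the original
#' (eV) target scale, plus an `average` row holding the arithmetic mean of
#' the subset metric values (and the total count). Subsets absent from the
#' data are omitted, not reported as zero.
#'
#' @param model A fitted [capso_train()] model.
#' @param data A descriptor table with a `split` column.
#' @return A tibble with columns `subset`, `n`, `aard`, `r_squared`,
#'   `rmsep`.
#' @export
evaluate_model <- function(model, data) {
  data <- as_tibble(data)
  if (!"split" %in% names(data)) {
    abort("`data` needs a `split` column; see stratified_split().",
          class = "capsonet_data_error")
  }
  subsets <- c("train", "validation", "test")
  rows <- purrr::map(subsets, function(s) {
    d <- data[data$split == s, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    pred <- predict(model, d)
    tibble(
      subset = s, n = nrow(d),
      aard = aard(d[[model$target]], pred),
      r_squared = r_squared(d[[model$target]], pred),
      rmsep = rmsep(d[[model$target]], pred)
    )
  })
  report <- dplyr::bind_rows(rows)
  if (nrow(report) > 0L) {
    avg <- tibble(
      subset = "average", n = sum(report$n),
      aard = mean(report$aard),
      r_squared = mean(report$r_squared),
      rmsep = mean(report$rmsep)
    )
    report <- dplyr::bind_rows(report, avg)
  }
  report
}

#' Write an evaluation report to CSV
#'
#' @param report A tibble from [evaluate_model()].
#' @param path Output CSV path.
#' @export
write_report <- function(report, path) {
  readr::write_csv(report, path)
  invisible(path)
}
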