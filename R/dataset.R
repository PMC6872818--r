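#' Names of the eight molecular descriptors
#'
#' In modelling order: `Ec` (theoretical absorption energy, eV), `Ne`
#' (electron count), `Os` (oscillator strength), `Ndb` (double bonds), `Na`
#' (total atoms), `Nh` (hydrogens), `Nc` (carbons), `NN` (nitrogens). The
#' regression target is the experimental absorption energy `E` (eV).
#'
#' @return Character vector of column names.
#' @export
qspr_descriptors <- function() {
  c("Ec", "Ne", "Os", "Ndb", "Na", "Nh", "Nc", "NN")
}

required_columns <- function() c("id", qspr_descriptors(), "E")

#' Validate a descriptor table
#'
#' Checks the column contract (all required columns present and numeric,
#' unique molecule ids), the composition invariant `Na >= Nh + Nc + NN`, and
#' warns when a target energy falls outside the plausible 1-10 eV window.
#'
#' @param data A data frame of molecules.
#' @return The validated data, invisibly, as a tibble.
#' @export
check_descriptors <- function(data) {
  missing <- setdiff(required_columns(), names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")),
          class = "capsonet_data_error")
  }
  data <- as_tibble(data)
  if (anyDuplicated(data$id)) {
    dup <- data$id[duplicated(data$id)][1]
    abort(sprintf("Duplicate molecule id: '%s'.", dup),
          class = "capsonet_data_error")
  }
  for (col in c(qspr_descriptors(), "E")) {
    if (!is.numeric(data[[col]])) {
      abort(sprintf("Column '%s' must be numeric.", col),
            class = "capsonet_data_error")
    }
    if (anyNA(data[[col]])) {
      abort(sprintf("Column '%s' contains missing values (first at row %d).",
                    col, which(is.na(data[[col]]))[1]),
            class = "capsonet_data_error")
    }
  }
  bad <- which(data$Na < data$Nh + data$Nc + data$NN)
  if (length(bad) > 0) {
    abort(sprintf("Row %d violates Na >= Nh + Nc + NN.", bad[1]),
          class = "capsonet_data_error")
  }
  if (nrow(data) > 0 && any(data$E < 1 | data$E > 10)) {
    warn("Some target energies fall outside the plausible 1-10 eV window.")
  }
  invisible(data)
}

#' Read and write descriptor tables
#'
#' The on-disk format is a UTF-8 CSV with a header naming at least the
#' columns `id`, the eight descriptors of [qspr_descriptors()] and the
#' target `E`; an optional `split` column carries `train` / `validation` /
#' `test` labels. Column order is free. Writing then reading a table is
#' value-identical.
#'
#' @param path File path.
#' @return `read_descriptors()`: a validated tibble.
#' @export
read_descriptors <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed cell at row %d, column %s of '%s'.",
                  probs$row[1], probs$col[1], path),
          class = "capsonet_data_error")
  }
  data$id <- as.character(data$id)
  check_descriptors(data)
  data
}

#' @rdname read_descriptors
#' @param data A descriptor table.
#' @export
write_descriptors <- function(data, path) {
  check_descriptors(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Specify an energy-binned stratified split
#'
#' Molecules are grouped into strata by target energy and each stratum is
#' split 70/15/15 (by default) into training, validation and test. The
#' default breaks follow the five published energy bands
#' 2.69-2.99, 3.01-3.96, 4.00-4.68, 4.70-5.08 and 5.10-6.66 eV; values in
#' the small gaps between bands go to the nearest band, which the default
#' breaks implement by cutting at the gap midpoints.
#'
#' @param breaks Increasing numeric vector of stratum boundaries covering
#'   the data range (first/last may be infinite).
#' @param fractions Named fractions for `train`, `validation`, `test`;
#'   must sum to 1.
#' @param seed Integer seed for the within-stratum random assignment.
#' @return A `split_spec` object.
#' @export
split_spec <- function(breaks = c(-Inf, 3.00, 3.98, 4.69, 5.09, Inf),
                       fractions = c(train = 0.70, validation = 0.15,
                                     test = 0.15),
                       seed = 0L) {
  if (is.unsorted(breaks, strictly = TRUE) || length(breaks) < 2) {
    abort("`breaks` must be strictly increasing with at least 2 values.",
          class = "capsonet_config_error")
  }
  need <- c("train", "validation", "test")
  if (!all(need %in% names(fractions))) {
    abort("`fractions` must be named train/validation/test.",
          class = "capsonet_config_error")
  }
  fractions <- fractions[need]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be non-negative and sum to 1.",
          class = "capsonet_config_error")
  }
  structure(list(breaks = as.numeric(breaks), fractions = fractions,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' Within each energy stratum of size `n`, the validation and test quotas
#' are `round(0.15 * n)` under round-half-to-even and training takes the
#' remainder; members are then assigned uniformly at random within the
#' stratum. Quotas are deterministic given the stratum sizes, so two seeds
#' give identical subset counts (possibly different membership), and the
#' same seed reproduces the membership exactly. With stratum sizes
#' 12/30/33/39/46 this yields training counts 8/22/23/27/32 and subset
#' totals 112/24/24.
#'
#' @param data A descriptor table (see [check_descriptors()]).
#' @param spec A [split_spec()].
#' @return The input tibble with a `split` column of labels
#'   `train` / `validation` / `test`.
#' @export
stratified_split <- function(data, spec = split_spec()) {
  data <- as_tibble(data)
  if (!"E" %in% names(data)) {
    abort("`data` needs a target column `E`.", class = "capsonet_data_error")
  }
  stratum <- cut(data$E, breaks = spec$breaks, labels = FALSE,
                 include.lowest = TRUE)
  if (anyNA(stratum)) {
    abort(sprintf("Row %d falls outside every stratum.",
                  which(is.na(stratum))[1]),
          class = "capsonet_data_error")
  }
  split <- character(nrow(data))
  withr::local_seed(spec$seed)
  for (s in sort(unique(stratum))) {
    rows <- which(stratum == s)
    n <- length(rows)
    q_val <- round(spec$fractions[["validation"]] * n)
    q_test <- round(spec$fractions[["test"]] * n)
    if (q_val + q_test > n) {
      abort(sprintf("Stratum %d (n = %d) is smaller than its quota %d.",
                    s, n, q_val + q_test),
            class = "capsonet_data_error")
    }
    shuffled <- rows[sample.int(n)]
    split[shuffled[seq_len(q_val)]] <- "validation"
    split[shuffled[q_val + seq_len(q_test)]] <- "test"
    split[shuffled[-seq_len(q_val + q_test)]] <- "train"
    if (q_val + q_test == 0L) split[shuffled] <- "train"
  }
  data$split <- split
  data
}

#' Column normalization fitted on training rows only
#'
#' `fit_normalization()` learns per-column statistics from the supplied
#' (training) rows; `apply_normalization()` transforms any table with those
#' statistics and `invert_normalization()` undoes it. Validation or test
#' rows may map outside \[0, 1\] under min-max scaling; that is expected
#' extrapolation, not an error. A constant column under min-max maps to 0.5
#' (with a warning at fit time).
#'
#' @param data Training rows.
#' @param method `"minmax"` (to \[0, 1\]) or `"zscore"`.
#' @param columns Columns to normalize; defaults to the eight descriptors
#'   plus the target `E`.
#' @return A `qspr_normalizer` object.
#' @export
fit_normalization <- function(data, method = c("minmax", "zscore"),
                              columns = c(qspr_descriptors(), "E")) {
  method <- match.arg(method)
  data <- as_tibble(data)
  if (nrow(data) == 0L) {
    abort("Cannot fit normalization on zero rows.", class = "capsonet_data_error")
  }
  missing <- setdiff(columns, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")),
          class = "capsonet_data_error")
  }
  center <- scale <- stats::setNames(numeric(length(columns)), columns)
  for (col in columns) {
    x <- data[[col]]
    if (method == "minmax") {
      center[col] <- min(x)
      scale[col] <- max(x) - min(x)
    } else {
      center[col] <- mean(x)
      scale[col] <- sd(x)
    }
    if (scale[col] == 0 || is.na(scale[col])) {
      warn(sprintf("Column '%s' is constant; it will map to %s.",
                   col, if (method == "minmax") "0.5" else "0"))
      scale[col] <- 0
    }
  }
  structure(list(method = method, columns = columns,
                 center = center, scale = scale),
            class = "qspr_normalizer")
}

#' @rdname fit_normalization
#' @param norm A fitted `qspr_normalizer`.
#' @export
apply_normalization <- function(data, norm) {
  data <- as_tibble(data)
  for (col in intersect(norm$columns, names(data))) {
    if (norm$scale[col] == 0) {
      data[[col]] <- rep(if (norm$method == "minmax") 0.5 else 0, nrow(data))
    } else {
      data[[col]] <- (data[[col]] - norm$center[col]) / norm$scale[col]
    }
  }
  data
}

#' @rdname fit_normalization
#' @export
invert_normalization <- function(data, norm) {
  data <- as_tibble(data)
  for (col in intersect(norm$columns, names(data))) {
    if (norm$scale[col] == 0) {
      data[[col]] <- rep(norm$center[col], nrow(data))
    } else {
      data[[col]] <- data[[col]] * norm$scale[col] + norm$center[col]
    }
  }
  data
}

# Invert a single normalized column (used for the target).
invert_column <- function(x, norm, col) {
  if (norm$scale[col] == 0) rep(norm$center[col], length(x))
  else x * norm$scale[col] + norm$center[col]
}

apply_column <- function(x, norm, col) {
  if (norm$scale[col] == 0) {
    rep(if (norm$method == "minmax") 0.5 else 0, length(x))
  } else {
    (x - norm$center[col]) / norm$scale[col]
  }
}
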