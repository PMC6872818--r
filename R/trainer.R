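#' Training objective: mean squared error of a parameter vector
#'
#' The quantity the swarm minimizes: the MSE of the network's predictions
#' against the (normalized) targets. Identical to `rmsep(y, yhat)^2`.
#'
#' @param params Flat parameter vector.
#' @param arch A [network_arch()] or vector of layer sizes.
#' @param x Descriptor matrix (rows are molecules).
#' @param y Target vector, one per row.
#' @return Non-negative scalar; zero only for a perfect fit.
#' @export
training_objective <- function(params, arch, x, y) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || length(y) == 0L) {
    abort("Cannot evaluate the training objective on an empty dataset.",
          class = "capsonet_data_error")
  }
  if (nrow(x) != length(y)) {
    abort("`x` and `y` disagree on the number of molecules.",
          class = "capsonet_contract_error")
  }
  mse(y, predict_batch(arch, params, x))
}

model_frame <- function(data, descriptors, target, norm) {
  data <- as_tibble(data)
  missing <- setdiff(c(descriptors, target), names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing model column(s): ", paste(missing, collapse = ", ")),
          class = "capsonet_data_error")
  }
  X <- if (nrow(data) == 0L) {
    matrix(numeric(0), 0L, length(descriptors),
           dimnames = list(NULL, descriptors))
  } else {
    matrix(sapply(descriptors, function(col) apply_column(data[[col]], norm, col)),
           nrow = nrow(data), dimnames = list(NULL, descriptors))
  }
  list(x = X, y = apply_column(data[[target]], norm, target))
}

#' Train a deep regression network with the chaotic swarm
#'
#' Wires the swarm to the network: descriptors and target are normalized
#' with statistics of the training rows only, the flat parameter vector is
#' searched by [capso_optimize()] with the training-set MSE as the
#' objective, and the best particle becomes the model. Validation rows are
#' used for monitoring and reporting only; there is no early stopping.
#' Optionally the best particle is polished by full-batch gradient descent
#' ([gradient_refine()]); this is off by default, the swarm being the
#' trainer.
#'
#' The default search box of +/-3 per weight keeps sigmoid units in their
#' responsive range for min-max-normalized inputs; a much wider box
#' saturates every hidden unit at initialization and leaves the swarm on a
#' flat landscape.
#'
#' @param data Training rows: a descriptor table with the target column.
#' @param validation Optional validation rows with the same columns.
#' @param arch A [network_arch()]; defaults to the 8-4-4-4-4-4-1 net.
#' @param control A [swarm_control()]; defaults to the standard swarm
#'   settings with the +/-3 weight box.
#' @param target Name of the target column.
#' @param descriptors Names of the input columns.
#' @param normalize `"minmax"` or `"zscore"`.
#' @param refine If `TRUE`, run [gradient_refine()] on the swarm's best
#'   parameters afterwards.
#' @param refine_rate,refine_epochs Learning rate and epoch cap for the
#'   optional refinement.
#' @param checkpoint_every Record train/validation MSE every this many
#'   iterations (0 disables checkpoints).
#' @return A `capso_dnn` model: architecture, best flat parameters,
#'   normalization statistics, best-objective trace, checkpoint table,
#'   final train/validation MSE and the configuration snapshot.
#' @examples
#' \donttest{
#' mols <- simulate_qspr(n = 60, seed = 1)
#' mols <- stratified_split(mols, split_spec(seed = 1))
#' fit <- capso_train(dplyr::filter(mols, split == "train"),
#'                    validation = dplyr::filter(mols, split == "validation"),
#'                    control = swarm_control(particles = 20, iterations = 200,
#'                                            lower = -3, upper = 3))
#' glance(fit)
#' }
#' @export
capso_train <- function(data, validation = NULL,
                        arch = network_arch(),
                        control = NULL,
                        target = "E", descriptors = qspr_descriptors(),
                        normalize = c("minmax", "zscore"),
                        refine = FALSE, refine_rate = 0.5,
                        refine_epochs = 100L,
                        checkpoint_every = 50L) {
  normalize <- match.arg(normalize)
  if (is.null(control)) control <- swarm_control(lower = -3, upper = 3)
  data <- as_tibble(data)
  layers <- arch_layers(arch)
  if (layers[1] != length(descriptors)) {
    abort(sprintf("Architecture expects %d inputs but %d descriptors given.",
                  layers[1], length(descriptors)),
          class = "capsonet_config_error")
  }
  if (nrow(data) == 0L) {
    abort("Training set is empty.", class = "capsonet_data_error")
  }

  norm <- fit_normalization(data, method = normalize,
                            columns = c(descriptors, target))
  train <- model_frame(data, descriptors, target, norm)
  val <- if (!is.null(validation)) {
    model_frame(validation, descriptors, target, norm)
  }

  fwd_train <- make_batch_forward(train$x, layers, arch_output(arch))
  y_train <- train$y
  objective <- function(theta) mean((y_train - fwd_train(theta))^2)

  snap <- if (checkpoint_every > 0) as.integer(checkpoint_every) else 0L
  res <- capso_optimize(objective, parameter_count(layers), control,
                        snapshot_every = snap)

  checkpoints <- NULL
  if (snap > 0L && length(res$snapshots) > 0L) {
    fwd_val <- if (!is.null(val)) make_batch_forward(val$x, layers, arch_output(arch))
    checkpoints <- dplyr::bind_rows(purrr::map(res$snapshots, function(s) {
      tibble(
        iteration = s$iteration,
        train_mse = mean((y_train - fwd_train(s$position))^2),
        val_mse = if (!is.null(val)) mean((val$y - fwd_val(s$position))^2) else NA_real_
      )
    }))
  }

  model <- structure(
    list(
      arch = if (inherits(arch, "network_arch")) arch else network_arch(layers),
      theta = res$best_position,
      norm = norm, target = target, descriptors = descriptors,
      trace = res$trace, checkpoints = checkpoints,
      train_mse = res$best_value,
      val_mse = if (!is.null(val)) {
        mean((val$y - make_batch_forward(val$x, layers, arch_output(arch))(res$best_position))^2)
      } else NA_real_,
      control = control, evaluations = res$evaluations,
      iterations_run = res$iterations_run,
      converged_by_error = res$converged_by_error,
      refined = FALSE
    ),
    class = "capso_dnn"
  )

  if (isTRUE(refine)) {
    model <- gradient_refine(model, data, rate = refine_rate,
                             epochs = refine_epochs)
    if (!is.null(val)) {
      model$val_mse <- mean((val$y - make_batch_forward(val$x, layers, arch_output(arch))(model$theta))^2)
    }
  }
  model
}

#' @export
print.capso_dnn <- function(x, ...) {
  cat(sprintf("<capso_dnn: %s, %s output>\n",
              paste(x$arch$layers, collapse = "-"), x$arch$output))
  cat(sprintf("  train MSE (normalized): %.4e", x$train_mse))
  if (!is.na(x$val_mse)) cat(sprintf("   validation MSE: %.4e", x$val_mse))
  cat(sprintf("\n  swarm: %d iterations, %d evaluations%s\n",
              x$iterations_run, x$evaluations,
              if (x$refined) ", gradient-refined" else ""))
  invisible(x)
}

#' Predict absorption energies for new molecules
#'
#' Normalizes the descriptors with the training statistics stored in the
#' model, runs the forward pass and returns predictions on the original
#' target (eV) scale.
#'
#' @param object A `capso_dnn` model.
#' @param data A descriptor table.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `data`.
#' @export
predict.capso_dnn <- function(object, data, ...) {
  data <- as_tibble(data)
  missing <- setdiff(object$descriptors, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing descriptor column(s): ",
                 paste(missing, collapse = ", ")),
          class = "capsonet_data_error")
  }
  if (nrow(data) == 0L) return(numeric(0))
  X <- sapply(object$descriptors,
              function(col) apply_column(data[[col]], object$norm, col))
  X <- matrix(X, nrow = nrow(data))
  raw <- predict_batch(object$arch, object$theta, X)
  invert_column(raw, object$norm, object$target)
}

#' @rdname predict.capso_dnn
#' @param x A `capso_dnn` model.
#' @method augment capso_dnn
#' @export
augment.capso_dnn <- function(x, data, ...) {
  data <- as_tibble(data)
  data$.pred <- predict(x, data)
  if (x$target %in% names(data)) {
    data$.resid <- data[[x$target]] - data$.pred
  }
  data
}

#' @rdname predict.capso_dnn
#' @method tidy capso_dnn
#' @export
tidy.capso_dnn <- function(x, ...) {
  par <- decode_params(x$theta, x$arch)
  dplyr::bind_rows(purrr::imap(par$weights, function(W, l) {
    dplyr::bind_rows(
      tibble(
        term = paste0("w", l, "[", rep(seq_len(nrow(W)), ncol(W)), ",",
                      rep(seq_len(ncol(W)), each = nrow(W)), "]"),
        layer = l, estimate = as.numeric(W)
      ),
      tibble(
        term = paste0("b", l, "[", seq_along(par$biases[[l]]), "]"),
        layer = l, estimate = par$biases[[l]]
      )
    )
  }))
}

#' @rdname predict.capso_dnn
#' @method glance capso_dnn
#' @export
glance.capso_dnn <- function(x, ...) {
  tibble(
    architecture = paste(x$arch$layers, collapse = "-"),
    n_params = parameter_count(x$arch),
    train_mse = x$train_mse,
    val_mse = x$val_mse,
    iterations_run = x$iterations_run,
    evaluations = x$evaluations,
    converged_by_error = x$converged_by_error,
    refined = x$refined
  )
}

#' @rdname predict.capso_dnn
#' @method autoplot capso_dnn
#' @export
autoplot.capso_dnn <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    p <- ggplot2::ggplot(object$trace,
                         ggplot2::aes(x = .data$iteration, y = .data$best_value)) +
      ggplot2::geom_line(colour = "#2c7fb8") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "Iteration", y = "Training MSE (normalized)",
                    title = "Swarm training trace") +
      ggplot2::theme_minimal()
    return(p)
  }
  aug <- augment(object, data)
  p <- ggplot2::ggplot(aug, ggplot2::aes(x = .data[[object$target]],
                                         y = .data$.pred))
  p <- if ("split" %in% names(aug)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$split), alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Observed E (eV)", y = "Predicted E (eV)") +
    ggplot2::theme_minimal()
}

# Full-batch MSE gradient by backpropagation, on the normalized scale.
mse_gradient <- function(theta, layers, output, X, y) {
  n <- nrow(X)
  idx <- param_indices(layers)
  L <- length(layers)
  H <- vector("list", L)
  H[[1]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- H[[l]] %*% matrix(theta[idx[[l]]$w], layers[l], layers[l + 1L]) +
      rep(theta[idx[[l]]$b], each = n)
    H[[l + 1L]] <- if (l < L - 1L || output == "sigmoid") 1 / (1 + exp(-Z)) else Z
  }
  pred <- H[[L]][, 1]
  grad <- numeric(length(theta))
  D <- matrix(2 * (pred - y) / n, n, 1)
  if (output == "sigmoid") D <- D * H[[L]] * (1 - H[[L]])
  for (l in rev(seq_len(L - 1L))) {
    grad[idx[[l]]$w] <- as.numeric(crossprod(H[[l]], D))
    grad[idx[[l]]$b] <- colSums(D)
    if (l > 1L) {
      W <- matrix(theta[idx[[l]]$w], layers[l], layers[l + 1L])
      D <- (D %*% t(W)) * H[[l]] * (1 - H[[l]])
    }
  }
  list(grad = grad, mse = mean((pred - y)^2))
}

#' Polish a trained model by full-batch gradient descent
#'
#' Back-propagates the training MSE through the sigmoid layers and takes
#' full-batch steps with backtracking (the step is halved until the MSE
#' does not increase), so the returned model's training MSE never exceeds
#' the input model's. Zero epochs return the model unchanged.
#'
#' @param model A `capso_dnn` model.
#' @param data The training rows the model was fitted on.
#' @param rate Initial learning rate.
#' @param epochs Number of full-batch epochs.
#' @return The refined `capso_dnn`.
#' @export
gradient_refine <- function(model, data, rate = 0.5, epochs = 100L) {
  epochs <- as.integer(epochs)
  if (epochs < 0L) abort("`epochs` must be non-negative.",
                         class = "capsonet_config_error")
  layers <- model$arch$layers
  frame <- model_frame(data, model$descriptors, model$target, model$norm)
  theta <- model$theta
  if (epochs == 0L) return(model)

  current <- training_objective(theta, model$arch, frame$x, frame$y)
  for (e in seq_len(epochs)) {
    g <- mse_gradient(theta, layers, arch_output(model$arch), frame$x, frame$y)
    if (any(!is.finite(g$grad))) {
      abort(sprintf("Non-finite gradient at epoch %d; aborting refinement.", e),
            class = "capsonet_optim_error")
    }
    if (all(g$grad == 0)) break
    step <- rate
    repeat {
      cand <- theta - step * g$grad
      cand_mse <- training_objective(cand, model$arch, frame$x, frame$y)
      if (cand_mse <= current) {
        theta <- cand
        current <- cand_mse
        break
      }
      step <- step / 2
      if (step < rate * 2^-30) break
    }
    if (step < rate * 2^-30) break
  }
  model$theta <- theta
  model$train_mse <- current
  model$refined <- TRUE
  model
}

#' Search the shared hidden-node count
#'
#' Trains one model per candidate node count `n` with the architecture
#' `input - n - ... - n - output` (all hidden layers share `n`), reusing the
#' same swarm seeds so candidates differ only in topology, and selects the
#' candidate minimizing validation MSE; ties break toward fewer nodes. A
#' failed candidate is recorded, not fatal, unless every candidate fails.
#'
#' @param data Training rows.
#' @param validation Validation rows (drive the selection).
#' @param nodes Candidate hidden-node counts.
#' @param hidden_layers Number of hidden layers.
#' @param control A [swarm_control()] shared by all candidates.
#' @param ... Passed on to [capso_train()].
#' @return An `arch_search` object: a `results` tibble (`nodes`,
#'   `n_params`, `train_mse`, `val_mse`, `error`) and the `selected` node
#'   count.
#' @export
search_architecture <- function(data, validation, nodes = 2:8,
                                hidden_layers = 5L, control = NULL, ...) {
  if (length(nodes) == 0L) {
    abort("`nodes` must be non-empty.", class = "capsonet_config_error")
  }
  if (is.null(control)) control <- swarm_control(lower = -3, upper = 3)
  dots <- list(...)
  n_in <- length(dots$descriptors %||% qspr_descriptors())
  rows <- purrr::map(sort(unique(as.integer(nodes))), function(k) {
    arch <- network_arch(c(n_in, rep(k, hidden_layers), 1L))
    fit <- tryCatch(
      capso_train(data, validation = validation, arch = arch,
                  control = control, ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      tibble(nodes = k, n_params = parameter_count(arch),
             train_mse = NA_real_, val_mse = NA_real_,
             error = conditionMessage(fit))
    } else {
      tibble(nodes = k, n_params = parameter_count(arch),
             train_mse = fit$train_mse, val_mse = fit$val_mse,
             error = NA_character_)
    }
  })
  results <- dplyr::bind_rows(rows)
  ok <- results[is.na(results$error), , drop = FALSE]
  if (nrow(ok) == 0L) {
    abort("Every candidate architecture failed to train.",
          class = "capsonet_optim_error")
  }
  ok <- ok[order(ok$val_mse, ok$nodes), , drop = FALSE]
  structure(list(results = results, selected = ok$nodes[1]),
            class = "arch_search")
}

#' @export
print.arch_search <- function(x, ...) {
  cat(sprintf("<arch_search: selected %d hidden nodes>\n", x$selected))
  print(x$results)
  invisible(x)
}

#' @rdname search_architecture
#' @param x,object An `arch_search`.
#' @method tidy arch_search
#' @export
tidy.arch_search <- function(x, ...) x$results

#' @rdname search_architecture
#' @method glance arch_search
#' @export
glance.arch_search <- function(x, ...) {
  sel <- x$results[x$results$nodes == x$selected, , drop = FALSE]
  tibble(selected = x$selected, val_mse = sel$val_mse,
         train_mse = sel$train_mse, candidates = nrow(x$results))
}

#' @rdname search_architecture
#' @method autoplot arch_search
#' @export
autoplot.arch_search <- function(object, ...) {
  long <- tidyr::pivot_longer(object$results, c("train_mse", "val_mse"),
                              names_to = "set", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$nodes, y = .data$mse,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected, linetype = 2) +
    ggplot2::labs(x = "Hidden nodes per layer", y = "MSE (normalized)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save and load a trained model
#'
#' The on-disk format is JSON: architecture, output activation, flat
#' parameters at full precision, normalization statistics, and creation
#' metadata (seed, package version). Parameters and normalization
#' statistics round-trip bit-exactly; the training trace is not persisted.
#'
#' @param model A `capso_dnn` model.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  payload <- list(
    layers = model$arch$layers,
    output = model$arch$output,
    theta = model$theta,
    target = model$target,
    descriptors = model$descriptors,
    norm = list(method = model$norm$method, columns = model$norm$columns,
                center = as.list(model$norm$center),
                scale = as.list(model$norm$scale)),
    train_mse = model$train_mse, val_mse = model$val_mse,
    refined = model$refined,
    meta = list(
      package = "capsonet",
      version = as.character(packageVersion("capsonet")),
      seed = model$control$seed,
      chaos_seed = model$control$chaos_seed
    )
  )
  # I(17) = 17 *significant* digits, enough to round-trip any double exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- structure(
    list(method = p$norm$method, columns = p$norm$columns,
         center = unlist(p$norm$center), scale = unlist(p$norm$scale)),
    class = "qspr_normalizer"
  )
  structure(
    list(
      arch = network_arch(p$layers, p$output),
      theta = as.numeric(p$theta),
      norm = norm, target = p$target, descriptors = p$descriptors,
      trace = NULL, checkpoints = NULL,
      train_mse = p$train_mse, val_mse = p$val_mse %||% NA_real_,
      control = NULL, evaluations = NA_integer_,
      iterations_run = NA_integer_, converged_by_error = NA,
      refined = isTRUE(p$refined)
    ),
    class = "capso_dnn"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
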