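#' Define a layered feedforward architecture
#'
#' An architecture is the list of layer widths from input to output, e.g.
#' `c(8, 4, 4, 4, 4, 4, 1)` for eight descriptors, five 4-node hidden layers
#' and one regression output. Hidden nodes are sigmoid; the output node is
#' linear by default (a single regression output in eV), with a sigmoid
#' option for targets rescaled to (0, 1).
#'
#' @param layers Integer vector of layer sizes, input first, output last; at
#'   least three entries, all positive.
#' @param output Output-node activation, `"linear"` or `"sigmoid"`.
#' @return A `network_arch` object.
#' @examples
#' network_arch()                 # the default 8-4-4-4-4-4-1 QSPR net
#' network_arch(c(2, 3, 1))
#' @export
network_arch <- function(layers = c(8L, 4L, 4L, 4L, 4L, 4L, 1L),
                         output = c("linear", "sigmoid")) {
  output <- match.arg(output)
  layers <- as.integer(layers)
  if (length(layers) < 3L || any(is.na(layers)) || any(layers < 1L)) {
    abort("`layers` needs at least 3 positive sizes (input, hidden..., output).",
          class = "capsonet_config_error")
  }
  structure(list(layers = layers, output = output), class = "network_arch")
}

#' @export
print.network_arch <- function(x, ...) {
  cat(sprintf("<network_arch: %s, %s output, %d parameters>\n",
              paste(x$layers, collapse = "-"), x$output, parameter_count(x)))
  invisible(x)
}

arch_layers <- function(arch) {
  if (inherits(arch, "network_arch")) arch$layers else as.integer(arch)
}

arch_output <- function(arch) {
  if (inherits(arch, "network_arch")) arch$output else "linear"
}

#' Number of free parameters of an architecture
#'
#' Each layer transition from width `n` to width `k` contributes `n * k`
#' weights plus `k` biases, so the total is `sum(n_l * n_{l+1} + n_{l+1})`.
#' The default 8-4-4-4-4-4-1 network has 121 parameters.
#'
#' @param arch A [network_arch()] or a bare vector of layer sizes.
#' @return Integer parameter count.
#' @examples
#' parameter_count(c(2, 3, 1))  # 13
#' parameter_count(network_arch())  # 121
#' @export
parameter_count <- function(arch) {
  n <- arch_layers(arch)
  sum(n[-length(n)] * n[-1] + n[-1])
}

# Precomputed flat-vector index ranges for each layer's weights and biases.
param_indices <- function(layers) {
  L <- length(layers)
  out <- vector("list", L - 1L)
  off <- 0L
  for (l in seq_len(L - 1L)) {
    nw <- layers[l] * layers[l + 1L]
    out[[l]] <- list(w = off + seq_len(nw), b = off + nw + seq_len(layers[l + 1L]))
    off <- off + nw + layers[l + 1L]
  }
  out
}

#' Flatten network parameters into a particle vector, and back
#'
#' A particle encodes a complete network as one flat vector: layer by layer,
#' the weight matrix first (column-major over an `n_l x n_{l+1}` matrix whose
#' column `j` feeds destination node `j`), then that layer's biases. The
#' codec is bijective: `decode_params(encode_params(w, b), arch)` restores
#' the matrices exactly, and the forward pass is invariant under the round
#' trip.
#'
#' @param weights List of weight matrices, one per layer transition, each
#'   `n_l x n_{l+1}`.
#' @param biases List of bias vectors, each of length `n_{l+1}`.
#' @return `encode_params()`: a numeric vector of length
#'   [parameter_count()]. `decode_params()`: a list with elements `weights`
#'   and `biases`.
#' @examples
#' w <- list(matrix(1:6, 2, 3), matrix(7:9, 3, 1))
#' b <- list(c(0, 0, 0), 0)
#' theta <- encode_params(w, b)
#' identical(decode_params(theta, c(2, 3, 1))$weights, w)
#' @export
encode_params <- function(weights, biases) {
  if (length(weights) != length(biases)) {
    abort("`weights` and `biases` must have one entry per layer transition.",
          class = "capsonet_shape_error")
  }
  unlist(purrr::map2(weights, biases, function(W, b) {
    if (ncol(W) != length(b)) {
      abort("Bias length must equal the number of destination nodes.",
            class = "capsonet_shape_error")
    }
    c(as.numeric(W), as.numeric(b))
  }), use.names = FALSE)
}

#' @rdname encode_params
#' @param theta Flat parameter vector.
#' @param arch A [network_arch()] or vector of layer sizes.
#' @export
decode_params <- function(theta, arch) {
  layers <- arch_layers(arch)
  want <- parameter_count(layers)
  if (length(theta) != want) {
    abort(
      sprintf("Parameter vector has length %d but architecture %s needs %d.",
              length(theta), paste(layers, collapse = "-"), want),
      class = "capsonet_shape_error"
    )
  }
  idx <- param_indices(layers)
  list(
    weights = purrr::imap(idx, function(ix, l) {
      matrix(theta[ix$w], layers[l], layers[l + 1L])
    }),
    biases = purrr::map(idx, function(ix) theta[ix$b])
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass through the network
#'
#' Hidden layers apply the sigmoid `1 / (1 + exp(-z))`; the output node is
#' linear or sigmoid per the architecture. Saturation is safe: for large
#' `|z|` the activation is numerically exactly 0 or 1 with no overflow.
#'
#' @param arch A [network_arch()] or vector of layer sizes.
#' @param theta Flat parameter vector of length [parameter_count()].
#' @param input Numeric descriptor vector of length `layers[1]`.
#' @return A list with `prediction` (scalar), `activations` (list of layer
#'   outputs `h^l`, the output layer last) and `preactivations` (the `z^l`).
#' @examples
#' arch <- network_arch(c(1, 1, 1))
#' nn_forward(arch, c(1, 0, 1, 0), 0)$prediction  # sigmoid(0) = 0.5 hidden
#' @export
nn_forward <- function(arch, theta, input) {
  layers <- arch_layers(arch)
  if (any(!is.finite(input))) {
    abort("Network input must be finite.", class = "capsonet_input_error")
  }
  if (length(input) != layers[1]) {
    abort(sprintf("Input has length %d but the input layer has %d nodes.",
                  length(input), layers[1]),
          class = "capsonet_shape_error")
  }
  par <- decode_params(theta, layers)
  L <- length(layers)
  h <- as.numeric(input)
  activations <- vector("list", L - 1L)
  preactivations <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    z <- drop(crossprod(par$weights[[l]], h)) + par$biases[[l]]
    preactivations[[l]] <- z
    h <- if (l < L - 1L || arch_output(arch) == "sigmoid") sigmoid(z) else z
    activations[[l]] <- h
  }
  list(prediction = h[1], activations = activations,
       preactivations = preactivations)
}

# Fast batched forward: returns a closure over a fixed input matrix so the
# per-evaluation cost inside the swarm objective is just the matrix products.
make_batch_forward <- function(X, layers, output = "linear") {
  X <- as.matrix(X)
  n <- nrow(X)
  idx <- param_indices(layers)
  L <- length(layers)
  force(output)
  function(theta) {
    H <- X
    for (l in seq_len(L - 1L)) {
      Z <- H %*% matrix(theta[idx[[l]]$w], layers[l], layers[l + 1L]) +
        rep(theta[idx[[l]]$b], each = n)
      H <- if (l < L - 1L || output == "sigmoid") 1 / (1 + exp(-Z)) else Z
    }
    H[, 1]
  }
}

#' Predict a batch of rows with a raw parameter vector
#'
#' Row-wise forward pass over a descriptor matrix; order preserved.
#'
#' @inheritParams nn_forward
#' @param x Numeric matrix (or data frame of numeric columns) with
#'   `layers[1]` columns.
#' @return Numeric vector of predictions, one per row.
#' @export
predict_batch <- function(arch, theta, x) {
  layers <- arch_layers(arch)
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(numeric(0))
  if (ncol(x) != layers[1]) {
    abort(sprintf("Input matrix has %d columns but the input layer has %d nodes.",
                  ncol(x), layers[1]),
          class = "capsonet_shape_error")
  }
  decode_params(theta, layers)  # length check with informative error
  make_batch_forward(x, layers, arch_output(arch))(theta)
}
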