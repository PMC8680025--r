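#' Encoder architecture and training hyperparameters
#'
#' Describes one fully connected encoder: rectified-linear hidden layers, a
#' hyperbolic-tangent output head over the disease labels, bias units in
#' every layer, inverted dropout on the hidden layers during training, and
#' Adam mini-batch optimisation. The per-dataset compression network
#' ("Encoder 1") uses hidden widths 64/32/32/16 with dropout 0.5; the fusion
#' network over concatenated bottlenecks ("Encoder 2") uses 32/24/16 without
#' dropout. Published training setting: Adam, learning rate 1e-4, 150
#' epochs, batch sizes 2048 (Encoder 1) and 3072 (Encoder 2).
#'
#' @param layer_sizes Hidden-layer widths, e.g. `c(64, 32, 32, 16)`.
#' @param input_dim,output_dim Optional; usually filled at fit time from the
#'   data.
#' @param dropout_rate Hidden-layer dropout fraction in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (>= 1).
#' @param seed Optional default seed.
#' @return An `encoder_spec`.
#' @export
encoder_spec <- function(layer_sizes = c(64, 32, 32, 16),
                         input_dim = NULL, output_dim = NULL,
                         dropout_rate = 0.5, learning_rate = 1e-4,
                         batch_size = 2048, epochs = 150, seed = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 1L, all(layer_sizes >= 1L),
            dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(layer_sizes = layer_sizes,
                 input_dim = if (!is.null(input_dim)) as.integer(input_dim),
                 output_dim = if (!is.null(output_dim)) as.integer(output_dim),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 optimizer = "adam",
                 seed = seed),
            class = "encoder_spec")
}

#' Parameter count of an encoder, printed-formula convention
#'
#' Counts trainable parameters layer by layer as
#' `fan_in x (fan_out + 1)` for consecutive hidden layers (the +1 accounting
#' for the bias unit) plus `last_hidden x output_dim` for the output head —
#' e.g. an 800-input Encoder 1 over 27 labels gives
#' 800x65 + 64x33 + 32x33 + 32x17 + 16x27 = 56,144.
#'
#' @param spec An [encoder_spec()] with `input_dim` and `output_dim` set, or
#'   supply them here.
#' @param input_dim,output_dim Overrides for the spec's fields.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, input_dim = spec$input_dim,
                             output_dim = spec$output_dim) {
  stopifnot(inherits(spec, "encoder_spec"),
            !is.null(input_dim), !is.null(output_dim))
  dims <- c(input_dim, spec$layer_sizes)
  hidden <- sum(dims[-length(dims)] * (dims[-1] + 1))
  as.integer(hidden + dims[length(dims)] * output_dim)
}

relu <- function(x) (x + abs(x)) / 2

init_layers <- function(dims) {
  # symmetric uniform fan-in scaling; biases start at zero
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    lim <- 1 / sqrt(max(1, fan_in))
    list(W = matrix(stats::runif(fan_in * dims[l + 1L], -lim, lim),
                    fan_in, dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

# forward pass; returns hidden activations (post-ReLU) and probabilities.
# dropout_masks NULL at inference.
encoder_forward <- function(layers, X, dropout_masks = NULL) {
  H <- list()
  A <- X
  n_hidden <- length(layers) - 1L
  for (l in seq_len(n_hidden)) {
    A <- relu(sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, "+"))
    if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]])) {
      A <- A * dropout_masks[[l]]
    }
    H[[l]] <- A
  }
  out <- layers[[n_hidden + 1L]]
  Z <- sweep(A %*% out$W, 2L, out$b, "+")
  P <- (tanh(Z) + 1) / 2
  list(hidden = H, probs = P)
}

bce_loss <- function(P, Y, clip = 1e-7) {
  P <- pmin(pmax(P, clip), 1 - clip)
  -mean(Y * log(P) + (1 - Y) * log(1 - P))
}

#' Train one encoder
#'
#' Mini-batch Adam training of a fully connected encoder against the binary
#' label matrix: ReLU hidden layers (with inverted dropout while training),
#' tanh output rescaled to `[0, 1]` via `(o + 1) / 2`, and mean per-label
#' binary cross-entropy (probabilities clipped at 1e-7) as the loss. The
#' rescaling makes the tanh head a probability-like score and gives the
#' numerically convenient gradient `2 (p - y)` at the output. Training is
#' deterministic given `seed`.
#'
#' @param features A [feature_dataset()] or numeric matrix (genes x inputs).
#' @param labels A [label_matrix()] or numeric 0/1 matrix aligned by row.
#' @param spec An [encoder_spec()].
#' @param seed Integer seed (falls back to `spec$seed`, then 1).
#' @return A `trained_encoder`: layer weights, the spec (with dimensions
#'   filled in), and `training_log` of per-epoch losses.
#' @export
train_encoder <- function(features, labels, spec, seed = NULL) {
  stopifnot(inherits(spec, "encoder_spec"))
  X <- if (inherits(features, "feature_dataset")) features$matrix else features
  Y <- if (inherits(labels, "label_matrix")) labels$matrix else labels
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  stopifnot(is.matrix(X), nrow(X) >= 1L, ncol(X) >= 1L,
            nrow(X) == nrow(Y))
  seed <- as.integer(seed %||% spec$seed %||% 1L)
  spec$input_dim <- ncol(X)
  spec$output_dim <- ncol(Y)
  dims <- c(ncol(X), spec$layer_sizes, ncol(Y))
  n_hidden <- length(spec$layer_sizes)
  set.seed(seed)
  layers <- init_layers(dims)
  adam <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                          mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  log_loss <- numeric(spec$epochs)
  keep <- 1 - spec$dropout_rate
  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    epoch_loss <- 0
    for (idx in batches) {
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      masks <- NULL
      if (spec$dropout_rate > 0) {
        masks <- lapply(spec$layer_sizes, function(w) {
          matrix(stats::rbinom(length(idx) * w, 1L, keep) / keep, length(idx), w)
        })
      }
      fw <- encoder_forward(layers, Xb, masks)
      P <- pmin(pmax(fw$probs, 1e-7), 1 - 1e-7)
      loss <- -mean(Yb * log(P) + (1 - Yb) * log(1 - P))
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
      epoch_loss <- epoch_loss + loss * length(idx)
      # backward: d(loss)/d(logit) = 2 (p - y) / N for the tanh-BCE head
      N <- length(Yb)
      delta <- 2 * (fw$probs - Yb) / N
      grads <- vector("list", length(layers))
      for (l in rev(seq_along(layers))) {
        A_prev <- if (l == 1L) Xb else fw$hidden[[l - 1L]]
        grads[[l]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
        if (l > 1L) {
          delta <- delta %*% t(layers[[l]]$W)
          if (!is.null(masks)) delta <- delta * masks[[l - 1L]]
          delta <- delta * (fw$hidden[[l - 1L]] > 0)
        }
      }
      step <- step + 1L
      corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
      for (l in seq_along(layers)) {
        a <- adam[[l]]; g <- grads[[l]]
        a$mW <- b1 * a$mW + (1 - b1) * g$W
        a$vW <- b2 * a$vW + (1 - b2) * g$W^2
        a$mb <- b1 * a$mb + (1 - b1) * g$b
        a$vb <- b2 * a$vb + (1 - b2) * g$b^2
        layers[[l]]$W <- layers[[l]]$W -
          spec$learning_rate * (a$mW / corr1) / (sqrt(a$vW / corr2) + eps)
        layers[[l]]$b <- layers[[l]]$b -
          spec$learning_rate * (a$mb / corr1) / (sqrt(a$vb / corr2) + eps)
        adam[[l]] <- a
      }
    }
    log_loss[epoch] <- epoch_loss / n
  }
  structure(list(spec = spec, layers = layers, training_log = log_loss,
                 seed = seed,
                 source = if (inherits(features, "feature_dataset")) features$name),
            class = "trained_encoder")
}

#' @export
print.trained_encoder <- function(x, ...) {
  cat(sprintf("Trained encoder (%s): %d -> %s -> %d labels; final loss %.5f\n",
              x$source %||% "matrix", x$spec$input_dim,
              paste(x$spec$layer_sizes, collapse = "/"), x$spec$output_dim,
              utils::tail(x$training_log, 1)))
  invisible(x)
}

encoder_input <- function(model, features) {
  X <- if (inherits(features, "feature_dataset")) features$matrix else features
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$spec$input_dim) {
    stop("feature width ", ncol(X), " does not match model input ",
         model$spec$input_dim)
  }
  X
}

#' Bottleneck activations of a trained encoder
#'
#' Forward pass with dropout disabled, returning the activations of the last
#' hidden layer — the encoder's learned low-dimensional representation of
#' its dataset (width 16 under the default architecture), kept after
#' training for fusion by the second-stage network.
#'
#' @param model A `trained_encoder`.
#' @param features Matrix or [feature_dataset()] with matching width.
#' @return A `bottleneck_features` object: activation matrix plus source name.
#' @export
extract_bottleneck <- function(model, features) {
  stopifnot(inherits(model, "trained_encoder"))
  X <- encoder_input(model, features)
  fw <- encoder_forward(model$layers, X)
  M <- fw$hidden[[length(fw$hidden)]]
  rownames(M) <- rownames(X)
  structure(list(matrix = M, source = model$source %||% "matrix"),
            class = "bottleneck_features")
}

#' Concatenate per-dataset bottlenecks
#'
#' Column-wise concatenation, in the given order, of each dataset's
#' bottleneck activations — the input of the fusion encoder (width
#' 16 x number of datasets under the defaults).
#'
#' @param parts List of `bottleneck_features` with identical gene ordering.
#' @return Numeric matrix.
#' @export
concatenate_bottlenecks <- function(parts) {
  stopifnot(length(parts) >= 1L)
  rows <- lapply(parts, function(p) rownames(p$matrix))
  if (!all(vapply(rows, identical, logical(1), rows[[1]]))) {
    stop("bottlenecks have mismatched gene ordering")
  }
  out <- do.call(cbind, lapply(parts, `[[`, "matrix"))
  colnames(out) <- unlist(lapply(parts, function(p) {
    paste0(p$source, ".", seq_len(ncol(p$matrix)))
  }))
  out
}

#' Label scores from a trained encoder
#'
#' Deterministic forward pass (dropout off); the tanh outputs are rescaled
#' to `[0, 1]` by `(o + 1) / 2`.
#'
#' @param model A `trained_encoder`.
#' @param features Matrix or [feature_dataset()] with matching width.
#' @return Numeric score matrix (genes x labels), entries in `[0, 1]`.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "trained_encoder"))
  X <- encoder_input(model, features)
  P <- encoder_forward(model$layers, X)$probs
  rownames(P) <- rownames(X)
  P
}
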