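#' Fit the two-stage modular model
#'
#' Stage one trains a separate Encoder 1 on every feature dataset (each
#' against the full multi-label target), then keeps each encoder's
#' 16-dimensional bottleneck. Stage two trains the fusion network Encoder 2
#' on the column-wise concatenation of all bottlenecks, producing the final
#' per-label scores. Modular encoding lets datasets of very different
#' dimensionality (an 800-dimensional network embedding next to a
#' 300-column pathway table) contribute on an equal footing.
#'
#' @param datasets List of [feature_dataset()] objects or matrices with
#'   aligned rows (training genes).
#' @param labels A [label_matrix()] or 0/1 matrix aligned with the datasets.
#' @param config A [pipeline_config()]; its `encoder1` / `encoder2` specs
#'   are used as templates.
#' @param seed Integer seed; per-encoder seeds are derived from it.
#' @return An `mdl_model` with the per-dataset encoders and the fusion
#'   encoder; score new genes with [predict()] on a list of matching
#'   feature matrices.
#' @export
fit_mdl <- function(datasets, labels, config = pipeline_config(), seed = 1L) {
  stopifnot(length(datasets) >= 1L)
  seed <- as.integer(seed)
  encoders <- vector("list", length(datasets))
  parts <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    encoders[[k]] <- train_encoder(datasets[[k]], labels, config$encoder1,
                                   seed = derive_seed(seed, k))
    parts[[k]] <- extract_bottleneck(encoders[[k]], datasets[[k]])
  }
  fused <- concatenate_bottlenecks(parts)
  fusion <- train_encoder(fused, labels, config$encoder2,
                          seed = derive_seed(seed, length(datasets) + 1L))
  structure(list(encoders = encoders, fusion = fusion,
                 n_datasets = length(datasets), seed = seed,
                 label_names = if (inherits(labels, "label_matrix")) labels$label_names),
            class = "mdl_model")
}

#' @export
print.mdl_model <- function(x, ...) {
  cat(sprintf("MDL model: %d dataset encoders + fusion encoder (seed %d)\n",
              x$n_datasets, x$seed))
  invisible(x)
}

#' @param object An `mdl_model`.
#' @param newdata List of feature matrices / datasets, same order and widths
#'   as at fit time.
#' @param ... Unused.
#' @rdname fit_mdl
#' @export
predict.mdl_model <- function(object, newdata, ...) {
  stopifnot(length(newdata) == object$n_datasets)
  parts <- lapply(seq_along(newdata), function(k) {
    extract_bottleneck(object$encoders[[k]], newdata[[k]])
  })
  scores <- predict_scores(object$fusion, concatenate_bottlenecks(parts))
  if (!is.null(object$label_names)) colnames(scores) <- object$label_names
  scores
}

# small deterministic seed mixer kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
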