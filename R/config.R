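#' Pipeline configuration
#'
#' Bundles every tunable of the prediction pipeline. Defaults follow the
#' published setting for real-scale data: 800-dimensional network embedding,
#' restart probability 0.5, encoder hidden widths 64/32/32/16 (per-dataset
#' Encoder 1, dropout 0.5) and 32/24/16 (fusion Encoder 2, no dropout), Adam
#' with learning rate 1e-4 for 150 epochs at batch sizes 2048 / 3072, 10-fold
#' cross-validation, and consensus recommendation of the top 30 negatives
#' required in at least 20 of the repeated runs.
#'
#' @param embedding_dim Embedding dimension d (>= 1).
#' @param restart_prob RWR restart probability in (0, 1].
#' @param embedding_method `"svd"` (deterministic, default) or `"softmax"`.
#' @param encoder1,encoder2 [encoder_spec()] templates (output_dim and
#'   input_dim are filled per dataset at fit time).
#' @param n_folds Cross-validation folds (>= 2).
#' @param seeds Integer vector of run seeds.
#' @param top_k Recommendation list length per disease.
#' @param min_frequency Minimum number of runs a gene must reach the per-run
#'   top_k to be recommended (<= number of seeds).
#' @param strategy Unknown-gene strategy, `"include"` or `"exclude"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(embedding_dim = 800,
                            restart_prob = 0.5,
                            embedding_method = c("svd", "softmax"),
                            encoder1 = encoder_spec(layer_sizes = c(64, 32, 32, 16),
                                                    dropout_rate = 0.5,
                                                    learning_rate = 1e-4,
                                                    batch_size = 2048, epochs = 150),
                            encoder2 = encoder_spec(layer_sizes = c(32, 24, 16),
                                                    dropout_rate = 0,
                                                    learning_rate = 1e-4,
                                                    batch_size = 3072, epochs = 150),
                            n_folds = 10,
                            seeds = 1:30,
                            top_k = 30,
                            min_frequency = 20,
                            strategy = c("include", "exclude")) {
  embedding_method <- match.arg(embedding_method)
  strategy <- match.arg(strategy)
  stopifnot(embedding_dim >= 1, restart_prob > 0, restart_prob <= 1,
            n_folds >= 2, top_k >= 1, length(seeds) >= 1,
            min_frequency >= 1, min_frequency <= length(seeds))
  structure(list(embedding_dim = as.integer(embedding_dim),
                 restart_prob = restart_prob,
                 embedding_method = embedding_method,
                 encoder1 = encoder1, encoder2 = encoder2,
                 n_folds = as.integer(n_folds),
                 seeds = as.integer(seeds),
                 top_k = as.integer(top_k),
                 min_frequency = as.integer(min_frequency),
                 strategy = strategy),
            class = "pipeline_config")
}

#' A reduced configuration for desk-scale synthetic benchmarks
#'
#' Same architecture as [pipeline_config()] but with a small embedding, a
#' larger learning rate, a small batch and fewer epochs so that the full
#' pipeline trains in seconds on networks of a few hundred genes. These are
#' the settings used throughout the package's synthetic benchmark suite.
#'
#' @param seeds Run seeds (default `1:3`).
#' @param n_folds CV folds (default 5).
#' @param embedding_dim Embedding dimension (default 32).
#' @param epochs Training epochs for both encoders (default 150).
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
benchmark_config <- function(seeds = 1:3, n_folds = 5, embedding_dim = 32,
                             epochs = 150, ...) {
  args <- utils::modifyList(list(
    embedding_dim = embedding_dim,
    encoder1 = encoder_spec(layer_sizes = c(64, 32, 32, 16), dropout_rate = 0.5,
                            learning_rate = 1e-3, batch_size = 64, epochs = epochs),
    encoder2 = encoder_spec(layer_sizes = c(32, 24, 16), dropout_rate = 0,
                            learning_rate = 1e-3, batch_size = 64, epochs = epochs),
    seeds = seeds, n_folds = n_folds,
    min_frequency = max(1L, ceiling(2 / 3 * length(seeds)))
  ), list(...))
  do.call(pipeline_config, args)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  enc <- function(x, default) {
    if (is.null(x)) return(default)
    do.call(encoder_spec, x[intersect(names(x), names(formals(encoder_spec)))])
  }
  defaults <- pipeline_config()
  pipeline_config(
    embedding_dim = y$embedding_dim %||% defaults$embedding_dim,
    restart_prob = y$restart_prob %||% defaults$restart_prob,
    embedding_method = y$embedding_method %||% defaults$embedding_method,
    encoder1 = enc(y$encoder1, defaults$encoder1),
    encoder2 = enc(y$encoder2, defaults$encoder2),
    n_folds = y$n_folds %||% defaults$n_folds,
    seeds = y$seeds %||% defaults$seeds,
    top_k = y$top_k %||% defaults$top_k,
    min_frequency = y$min_frequency %||% defaults$min_frequency,
    strategy = y$strategy %||% defaults$strategy
  )
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config` to write.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- unclass(config)
  y$encoder1 <- unclass(y$encoder1)
  y$encoder2 <- unclass(y$encoder2)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
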