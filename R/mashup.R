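#' Mashup-style multi-network embedding
#'
#' Compresses the diffusion states of one or more networks over a shared
#' gene universe into a single d-dimensional vector per gene. Each network's
#' diffusion-state matrix S^(k) is log-transformed with pseudo-count
#' `eps = 1/n`; the matrices are stacked row-wise and factorised so that one
#' latent gene vector x_i, shared across all networks, approximates every
#' network's diffusion profile of that gene.
#'
#' Two factorisations are available. `"svd"` (default, deterministic): a
#' rank-d truncated singular value decomposition of the stacked matrix
#' `L = W X^T`, with gene vectors `X = V_d diag(sqrt(sigma_d))` and context
#' vectors `W = U_d diag(sqrt(sigma_d))`. `"softmax"`: the multinomial
#' logistic model of the original diffusion columns,
#' `s_hat_i(j) proportional to exp(x_i . w_j^(k))`, fitted by gradient
#' descent on the summed KL divergence with equal weight per network, shared
#' x and per-network w.
#'
#' @param networks A [weighted_network()] or list of them (one universe).
#' @param d Embedding dimension (>= 1); capped at the feasible rank with a
#'   warning. Real-scale published setting: d = 800.
#' @param restart_prob RWR restart probability (default 0.5).
#' @param method `"svd"` or `"softmax"`.
#' @param seed Seed for the softmax initialisation.
#' @param learning_rate,n_iter Softmax gradient-descent controls.
#' @param diffusion Optional precomputed list of `diffusion_states` matching
#'   `networks` (skips the RWR step).
#' @return A `mashup_embedding`: `X` (n x d gene vectors), `contexts`
#'   (per-network context matrices), `d`, `method`, `singular_values`
#'   (svd method only).
#' @export
mashup_embed <- function(networks, d, restart_prob = 0.5,
                         method = c("svd", "softmax"), seed = 1L,
                         learning_rate = 0.1, n_iter = 500,
                         diffusion = NULL) {
  method <- match.arg(method)
  if (inherits(networks, "weighted_network")) networks <- list(networks)
  stopifnot(length(networks) >= 1L, d >= 1)
  uni <- networks[[1]]$universe
  for (nt in networks) {
    if (!same_universe(nt$universe, uni)) stop("all networks must share one universe")
  }
  n <- length(uni)
  if (is.null(diffusion)) {
    diffusion <- lapply(networks, compute_diffusion_states, restart_prob = restart_prob)
  }
  if (method == "svd") {
    eps <- 1 / n
    L <- do.call(rbind, lapply(diffusion, function(ds) log(ds$S + eps)))
    # column i of L: gene i's log diffusion profile in every network, stacked;
    # right singular vectors therefore give one shared latent vector per gene.
    r <- min(d, n, nrow(L))
    if (r < d) warning("embedding dimension reduced to feasible rank ", r)
    sv <- svd(L, nu = r, nv = r)
    scale <- sqrt(sv$d[seq_len(r)])
    X <- sv$v[, seq_len(r), drop = FALSE] %*% diag(scale, r)
    W <- sv$u[, seq_len(r), drop = FALSE] %*% diag(scale, r)
    contexts <- lapply(seq_along(diffusion), function(k) {
      W[(k - 1) * n + seq_len(n), , drop = FALSE]
    })
    rownames(X) <- uni$ids
    return(structure(list(X = X, contexts = contexts, d = r, method = "svd",
                          singular_values = sv$d[seq_len(r)],
                          restart_prob = restart_prob, universe = uni),
                     class = "mashup_embedding"))
  }
  # softmax method: minimise sum_k sum_i KL(s_i^(k) || softmax(W^(k) x_i))
  r <- min(d, n)
  if (r < d) warning("embedding dimension reduced to feasible rank ", r)
  set.seed(seed)
  X <- matrix(stats::rnorm(n * r, sd = 0.1), n, r)
  Ws <- lapply(seq_along(diffusion), function(k) matrix(stats::rnorm(n * r, sd = 0.1), n, r))
  Ss <- lapply(diffusion, `[[`, "S")
  for (it in seq_len(n_iter)) {
    gX <- matrix(0, n, r)
    for (k in seq_along(Ss)) {
      Z <- Ws[[k]] %*% t(X)                  # n x n: logits for column i
      Z <- sweep(Z, 2L, apply(Z, 2L, max), "-")
      P <- exp(Z)
      P <- sweep(P, 2L, colSums(P), "/")
      D <- P - Ss[[k]]                       # gradient of KL wrt logits
      gX <- gX + t(D) %*% Ws[[k]] / n
      gW <- D %*% X / n
      Ws[[k]] <- Ws[[k]] - learning_rate * gW
    }
    X <- X - learning_rate * gX
  }
  rownames(X) <- uni$ids
  structure(list(X = X, contexts = Ws, d = r, method = "softmax",
                 restart_prob = restart_prob, universe = uni),
            class = "mashup_embedding")
}

#' @export
print.mashup_embedding <- function(x, ...) {
  cat(sprintf("Mashup embedding: %d genes x %d dimensions (%s, %d network%s)\n",
              nrow(x$X), x$d, x$method, length(x$contexts),
              if (length(x$contexts) == 1) "" else "s"))
  invisible(x)
}

#' Convert an embedding into a feature dataset
#'
#' @param embedding A `mashup_embedding`.
#' @param name Dataset name (default "Mashup").
#' @return A continuous [feature_dataset()] over the embedding's universe.
#' @export
embedding_as_dataset <- function(embedding, name = "Mashup") {
  stopifnot(inherits(embedding, "mashup_embedding"))
  X <- embedding$X
  colnames(X) <- paste0("dim", seq_len(ncol(X)))
  feature_dataset(name, X, embedding$universe, kind = "continuous")
}

#' Write an embedding as a TSV (gene id + d columns)
#'
#' @param embedding A `mashup_embedding`.
#' @param path Output path.
#' @export
write_embedding <- function(embedding, path) {
  write_feature_table(embedding_as_dataset(embedding), path)
}

#' Dimensionality-reduction percentage
#'
#' `(1 - embedded_dim / original_dim) * 100`: how much smaller an embedding
#' is than the raw representation. Embedding 15,000-dimensional network
#' profiles into 800 dimensions, for instance, is a reduction of about 95%.
#'
#' @param original_dim Original dimension (> 0).
#' @param embedded_dim Embedded dimension.
#' @return Percentage reduced; negative (with a warning) if the embedding is
#'   larger than the original.
#' @export
reduction_percentage <- function(original_dim, embedded_dim) {
  stopifnot(original_dim > 0)
  out <- (1 - embedded_dim / original_dim) * 100
  if (out < 0) warning("embedded dimension exceeds the original dimension")
  out
}
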