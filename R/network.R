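#' Weighted gene-gene network
#'
#' A nonnegative, symmetric adjacency matrix over a gene universe — the
#' object random-walk diffusion operates on. Directed inputs are symmetrised
#' by summation at load time; self-loops are permitted.
#'
#' @param A Square numeric nonnegative matrix.
#' @param universe A [gene_universe()] with one gene per row/column.
#' @param name Optional network name.
#' @return A `weighted_network` object.
#' @export
weighted_network <- function(A, universe, name = "network") {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), inherits(universe, "gene_universe"),
            nrow(A) == length(universe))
  if (anyNA(A) || any(!is.finite(A))) stop("adjacency must be finite")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  if (max(abs(A - t(A))) > 1e-12 * max(1, max(abs(A)))) {
    A <- (A + t(A)) / 2
  }
  dimnames(A) <- list(universe$ids, universe$ids)
  structure(list(A = A, universe = universe, name = name),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  nz <- sum(x$A[upper.tri(x$A, diag = TRUE)] != 0)
  cat(sprintf("Weighted network '%s': %d genes, %d edges\n",
              x$name, nrow(x$A), nz))
  invisible(x)
}

#' Turn a boolean annotation matrix into a similarity network
#'
#' Gene-gene edge weights are the cosine similarities of the genes'
#' annotation rows; weights below `threshold` and the diagonal are zeroed.
#' This provides a diffusible network view of term-membership data (GO-style
#' annotations, pathway memberships) so that it can enter the multi-network
#' embedding alongside interaction networks.
#'
#' @param features A boolean [feature_dataset()].
#' @param similarity_threshold Minimum cosine similarity kept, in `[0, 1]`.
#' @return A [weighted_network()] over the same universe.
#' @export
annotation_to_network <- function(features, similarity_threshold = 0) {
  stopifnot(inherits(features, "feature_dataset"),
            similarity_threshold >= 0, similarity_threshold <= 1)
  if (features$kind != "boolean") stop("annotation_to_network expects a boolean dataset")
  M <- features$matrix
  if (all(M == 0)) warning("all-zero annotation matrix: resulting network is empty")
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm == 0] <- 1 # all-zero rows keep zero similarity
  S <- tcrossprod(M / nrm)
  S[S < similarity_threshold] <- 0
  diag(S) <- 0
  # clip numerical overshoot above 1
  S[S > 1] <- 1
  weighted_network(S, features$universe, name = paste0(features$name, "_cosine"))
}
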