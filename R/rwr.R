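#' Column-stochastic transition matrix of a network
#'
#' Normalises each adjacency column to sum to one, `B[i, j] = A[i, j] /
#' sum_i A[i, j]`, so that column j holds the probabilities of stepping from
#' node j to each neighbour. Zero-degree columns first receive a unit
#' self-loop, keeping the matrix stochastic while letting isolated genes
#' diffuse to themselves.
#'
#' @param net A [weighted_network()].
#' @return A `transition_matrix` object wrapping the column-stochastic `B`.
#' @export
build_transition_matrix <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  A <- net$A
  deg <- colSums(A)
  zero <- deg == 0
  if (any(zero)) {
    diag(A)[zero] <- 1
    deg[zero] <- 1
  }
  B <- sweep(A, 2L, deg, "/")
  structure(list(B = B, universe = net$universe),
            class = "transition_matrix")
}

#' Random walk with restart from one node
#'
#' Iterates `s <- (1 - p_r) * B %*% s + p_r * e_i` to its fixed point: at
#' each step the walker either follows the network (probability `1 - p_r`)
#' or restarts at node i (probability `p_r`). The stationary distribution is
#' the node's *diffusion state*, a network-proximity profile. The same fixed
#' point solves the linear system `(I - (1 - p_r) B) s = p_r e_i`, available
#' via `method = "solve"` as an exact cross-check.
#'
#' @param B A `transition_matrix` from [build_transition_matrix()].
#' @param i Node index (1-based) or gene id.
#' @param restart_prob Restart probability in (0, 1].
#' @param tol L1 convergence tolerance for power iteration.
#' @param max_iter Iteration cap.
#' @param method `"power"` (default) or `"solve"` (closed form).
#' @return Numeric stationary distribution over all nodes (sums to 1).
#' @export
rwr <- function(B, i, restart_prob = 0.5, tol = 1e-9, max_iter = 1000,
                method = c("power", "solve")) {
  method <- match.arg(method)
  stopifnot(inherits(B, "transition_matrix"),
            restart_prob > 0, restart_prob <= 1)
  if (is.character(i)) i <- gene_index(B$universe, i)
  n <- nrow(B$B)
  stopifnot(i >= 1, i <= n)
  e <- numeric(n); e[i] <- 1
  if (restart_prob == 1) return(stats::setNames(e, B$universe$ids))
  if (method == "solve") {
    s <- solve(diag(n) - (1 - restart_prob) * B$B, restart_prob * e)
    return(stats::setNames(as.numeric(s), B$universe$ids))
  }
  s <- e
  for (it in seq_len(max_iter)) {
    s_new <- (1 - restart_prob) * as.numeric(B$B %*% s) + restart_prob * e
    if (sum(abs(s_new - s)) < tol) return(stats::setNames(s_new, B$universe$ids))
    s <- s_new
  }
  stop(sprintf("rwr did not converge within %d iterations (L1 residual %.3e)",
               max_iter, sum(abs((1 - restart_prob) * as.numeric(B$B %*% s) +
                                 restart_prob * e - s))))
}

#' Diffusion-state matrix of a network
#'
#' Column i is the random-walk-with-restart stationary distribution from
#' node i. For moderate networks (n <= `solve_limit`) all columns are
#' obtained at once from a single dense factorisation of
#' `(I - (1 - p_r) B)`; larger networks fall back to per-column power
#' iteration.
#'
#' @param net A [weighted_network()].
#' @param restart_prob Restart probability in (0, 1].
#' @param tol,max_iter Power-iteration controls (see [rwr()]).
#' @param solve_limit Largest n for the dense closed-form path.
#' @return A `diffusion_states` object with matrix `S` (n x n, columns are
#'   probability distributions) and the restart probability used.
#' @export
compute_diffusion_states <- function(net, restart_prob = 0.5, tol = 1e-9,
                                     max_iter = 1000, solve_limit = 2000) {
  stopifnot(inherits(net, "weighted_network"))
  tm <- build_transition_matrix(net)
  n <- nrow(tm$B)
  if (restart_prob == 1) {
    S <- diag(n)
  } else if (n <= solve_limit) {
    S <- solve(diag(n) - (1 - restart_prob) * tm$B) * restart_prob
  } else {
    S <- vapply(seq_len(n), function(i) {
      rwr(tm, i, restart_prob, tol = tol, max_iter = max_iter)
    }, numeric(n))
  }
  dimnames(S) <- list(net$universe$ids, net$universe$ids)
  structure(list(S = S, restart_prob = restart_prob, universe = net$universe,
                 name = net$name),
            class = "diffusion_states")
}

#' @export
print.diffusion_states <- function(x, ...) {
  cat(sprintf("Diffusion states of '%s': %d x %d, restart probability %.3g\n",
              x$name, nrow(x$S), ncol(x$S), x$restart_prob))
  invisible(x)
}
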