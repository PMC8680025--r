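#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples with three p-value routes:
#' the exact null distribution (`stats::pwilcox`) when both samples have
#' fewer than 20 values and no ties; complete enumeration of group
#' assignments when ties are present but the number of assignments is small
#' (so fully tied toy samples still get exact p-values); and otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (each >= 1 value; >= 2 for meaningful tests).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param enumeration_limit Largest number of group assignments enumerated
#'   exactly when ties are present.
#' @return List with `statistic` (U of x over y), `p.value`, and `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater", "less"),
                           enumeration_limit = 2e4) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  n_x <- length(x); n_y <- length(y)
  stopifnot(n_x >= 1, n_y >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  mu <- n_x * n_y / 2
  if (!ties && n_x < 20 && n_y < 20) {
    p <- switch(alternative,
      greater = stats::pwilcox(U - 1, n_x, n_y, lower.tail = FALSE),
      less = stats::pwilcox(U, n_x, n_y),
      two.sided = {
        if (U > mu) {
          min(1, 2 * stats::pwilcox(U - 1, n_x, n_y, lower.tail = FALSE))
        } else if (U < mu) {
          min(1, 2 * stats::pwilcox(U, n_x, n_y))
        } else 1
      })
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  if (ties && choose(n_x + n_y, n_x) <= enumeration_limit) {
    combos <- utils::combn(n_x + n_y, n_x)
    U_all <- apply(combos, 2L, function(idx) {
      sum(r[idx]) - n_x * (n_x + 1) / 2
    })
    eps <- 1e-9
    p <- switch(alternative,
      greater = mean(U_all >= U - eps),
      less = mean(U_all <= U + eps),
      two.sided = mean(abs(U_all - mu) >= abs(U - mu) - eps))
    return(list(statistic = U, p.value = p, method = "enumeration"))
  }
  # normal approximation with tie correction and continuity correction
  N <- n_x + n_y
  tie_tab <- table(pooled)
  sigma <- sqrt((n_x * n_y / 12) *
                ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1))))
  if (sigma == 0) {
    p <- if (alternative == "two.sided") 1 else 1 # all values identical
    return(list(statistic = U, p.value = p, method = "normal"))
  }
  z <- switch(alternative,
    greater = (U - mu - 0.5) / sigma,
    less = (U - mu + 0.5) / sigma,
    two.sided = (U - mu - sign(U - mu) * 0.5) / sigma)
  p <- switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two.sided = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)))
  list(statistic = U, p.value = p, method = "normal")
}

#' Seed-replicated statistical comparison of two methods
#'
#' Compares two collections of fold-level AUROC values (typically 30 seeds x
#' 10 folds per method) with a Welch two-sample t-test on the means and
#' Mann-Whitney rank tests under the three alternatives "Greater",
#' "Two-side" and "Less": the respective null hypotheses are that method b
#' is better than, the same as, or worse than method a. A small "Greater"
#' p-value therefore rejects "b is at least as good as a" in favour of a.
#'
#' @param a Fold-level AUROCs of the reference method (ours).
#' @param b Fold-level AUROCs of the comparison method.
#' @return A `method_comparison`: sample means, `t_p` (two-sided Welch),
#'   `u_p_greater`, `u_p_two_side`, `u_p_less`.
#' @export
compare_methods <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2)
  t_p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
  } else {
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b),
                 t_p = t_p,
                 u_p_greater = mann_whitney_u(a, b, "greater")$p.value,
                 u_p_two_side = mann_whitney_u(a, b, "two.sided")$p.value,
                 u_p_less = mann_whitney_u(a, b, "less")$p.value),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison: mean AUROC %.4f (ours, n=%d) vs %.4f (other, n=%d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  cat(sprintf("  T-test p = %.4g; U test Greater %.4g / Two-side %.4g / Less %.4g\n",
              x$t_p, x$u_p_greater, x$u_p_two_side, x$u_p_less))
  invisible(x)
}
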