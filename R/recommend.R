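#' Rank negative-labeled genes for one disease
#'
#' Genes without an annotation for a disease are negatives by default, but
#' absence of evidence is not evidence of absence: the most confidently
#' scored negatives are candidate associations. Negatives are ordered by
#' descending predicted score, ties broken lexicographically by gene id for
#' reproducibility.
#'
#' @param scores Score matrix (genes x labels) with gene-id rownames.
#' @param labels A [label_matrix()] (or 0/1 matrix with the same dimnames).
#' @param disease Label name (or column index).
#' @return A data.frame `gene`, `score`, in rank order; zero rows (with a
#'   warning) if every gene is positive.
#' @export
rank_negative_genes <- function(scores, labels, disease) {
  Y <- if (inherits(labels, "label_matrix")) labels$matrix else labels
  stopifnot(is.matrix(scores), nrow(scores) == nrow(Y))
  if (is.character(disease) && !disease %in% colnames(Y)) {
    stop("unknown disease label '", disease, "'")
  }
  gene_ids <- rownames(scores) %||% as.character(seq_len(nrow(scores)))
  neg <- which(Y[, disease] == 0)
  if (length(neg) == 0L) {
    warning("no negative genes for '", disease, "'")
    return(data.frame(gene = character(), score = numeric()))
  }
  s <- scores[neg, disease]
  ord <- order(-s, gene_ids[neg], method = "radix")
  data.frame(gene = gene_ids[neg][ord], score = unname(s[ord]),
             stringsAsFactors = FALSE)
}

#' Per-run recommendation rankings
#'
#' Applies [rank_negative_genes()] to every disease label for one run's
#' score matrix.
#'
#' @param scores Score matrix of one run (genes x labels).
#' @param labels A [label_matrix()].
#' @param seed The run's seed (bookkeeping only).
#' @return A `recommendation_run`: named list of per-disease rankings.
#' @export
recommendation_run <- function(scores, labels, seed = NA_integer_) {
  Y <- if (inherits(labels, "label_matrix")) labels$matrix else labels
  diseases <- colnames(Y)
  rankings <- lapply(diseases, function(d) rank_negative_genes(scores, labels, d))
  names(rankings) <- diseases
  structure(list(rankings = rankings, seed = seed), class = "recommendation_run")
}

#' Consensus recommendation across repeated runs
#'
#' Training a stochastic model repeatedly changes each run's top list; a
#' gene is only recommended when it reaches the per-run top `top_k` in at
#' least `min_freq` of the runs (published setting: top 30 in at least 20 of
#' 30 runs). For every qualifying gene the mean (Ave. P), maximum (Hig. P)
#' and minimum (Low. P) of its scores over the runs where it made the top
#' list are reported, along with the average score of all other negative
#' genes over all runs.
#'
#' @param runs List of `recommendation_run` objects.
#' @param top_k Per-run list length (default 30, the size of the smallest
#'   annotated disease label in the published setting).
#' @param min_freq Minimum number of qualifying runs (default 20).
#' @return A `consensus_recommendation`: per-disease data.frames with
#'   `gene`, `frequency`, `ave_p`, `hig_p`, `low_p`, plus `rest_mean` per
#'   disease and the settings used.
#' @export
consensus_recommend <- function(runs, top_k = 30, min_freq = 20) {
  stopifnot(length(runs) >= 1L, min_freq <= length(runs), min_freq >= 1,
            top_k >= 1)
  diseases <- names(runs[[1]]$rankings)
  per_disease <- lapply(diseases, function(d) {
    tops <- lapply(runs, function(r) utils::head(r$rankings[[d]], top_k))
    all_top_genes <- unlist(lapply(tops, `[[`, "gene"))
    freq <- table(all_top_genes)
    qualified <- names(freq)[freq >= min_freq]
    summaries <- lapply(qualified, function(g) {
      s <- unlist(lapply(tops, function(tt) tt$score[tt$gene == g]))
      data.frame(gene = g, frequency = as.integer(freq[[g]]),
                 ave_p = mean(s), hig_p = max(s), low_p = min(s),
                 stringsAsFactors = FALSE)
    })
    tab <- if (length(summaries)) do.call(rbind, summaries) else {
      data.frame(gene = character(), frequency = integer(), ave_p = numeric(),
                 hig_p = numeric(), low_p = numeric())
    }
    tab <- tab[order(-tab$frequency, -tab$ave_p, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    # rest-gene average: all negatives outside the recommended list, over runs
    rest <- unlist(lapply(runs, function(r) {
      rk <- r$rankings[[d]]
      rk$score[!rk$gene %in% tab$gene]
    }))
    list(table = tab, rest_mean = if (length(rest)) mean(rest) else NA_real_)
  })
  names(per_disease) <- diseases
  structure(list(diseases = lapply(per_disease, `[[`, "table"),
                 rest_mean = vapply(per_disease, `[[`, numeric(1), "rest_mean"),
                 n_runs = length(runs), top_k = as.integer(top_k),
                 min_freq = as.integer(min_freq)),
            class = "consensus_recommendation")
}

#' @export
print.consensus_recommendation <- function(x, ...) {
  cat(sprintf("Consensus recommendation: %d diseases, top %d in >= %d of %d runs\n",
              length(x$diseases), x$top_k, x$min_freq, x$n_runs))
  n_rec <- vapply(x$diseases, nrow, integer(1))
  cat(sprintf("  recommended genes per disease: min %d / median %s / max %d\n",
              min(n_rec), format(stats::median(n_rec)), max(n_rec)))
  invisible(x)
}

#' One-sided rank comparison of two score blocks
#'
#' The core test behind the neighbour comparison: are the scores of one
#' pre-specified block of genes stochastically larger than another's? The
#' default is the one-sided Mann-Whitney rank-sum test (`"rank"`); a Welch
#' t-test alternative is available (`"mean"`).
#'
#' @param top,rest Numeric score blocks.
#' @param test `"rank"` (default) or `"mean"`.
#' @return p-value for the alternative that `top` scores are larger.
#' @export
block_score_test <- function(top, rest, test = c("rank", "mean")) {
  test <- match.arg(test)
  if (test == "rank") {
    mann_whitney_u(top, rest, "greater")$p.value
  } else {
    stats::t.test(top, rest, alternative = "greater", var.equal = FALSE)$p.value
  }
}

#' Neighbour hypothesis test for recommended genes
#'
#' Checks that the top `top_k` recommended negatives genuinely stand apart
#' from the genes ranked just below them (ranks `top_k + 1` to `2 top_k`)
#' rather than sitting on a smooth continuum. Per-gene mean scores across
#' runs define the ranking; the per-run scores of the two adjacent blocks
#' (top_k genes x runs values each) are then compared with the one-sided
#' test of [block_score_test()] under the null hypothesis that recommended
#' genes score the same as their neighbours. Pooling per-run scores rather
#' than per-gene means keeps the run-to-run variability of a stochastic
#' model in the test, so the p-value reflects how consistently the two
#' blocks separate across repetitions.
#'
#' @param runs List of `recommendation_run` objects.
#' @param disease Label name; or `NULL` to test every disease.
#' @param top_k Block size (default 30).
#' @param test Passed to [block_score_test()].
#' @return Data.frame `disease`, `p_value` (`NA`, with a warning, where
#'   fewer than `2 * top_k` negatives exist).
#' @export
neighbor_hypothesis_test <- function(runs, disease = NULL, top_k = 30,
                                     test = c("rank", "mean")) {
  test <- match.arg(test)
  stopifnot(length(runs) >= 1L)
  diseases <- disease %||% names(runs[[1]]$rankings)
  res <- vapply(diseases, function(d) {
    score_lists <- lapply(runs, function(r) {
      rk <- r$rankings[[d]]
      stats::setNames(rk$score, rk$gene)
    })
    genes <- names(score_lists[[1]])
    if (length(genes) < 2 * top_k) {
      warning("disease '", d, "': fewer than ", 2 * top_k,
              " negative genes, test skipped")
      return(NA_real_)
    }
    per_run <- do.call(cbind, lapply(score_lists, `[`, genes))
    mean_scores <- rowMeans(per_run)
    ord <- order(-mean_scores, genes, method = "radix")
    top <- as.vector(per_run[ord[seq_len(top_k)], ])
    nbr <- as.vector(per_run[ord[top_k + seq_len(top_k)], ])
    block_score_test(top, nbr, test)
  }, numeric(1))
  data.frame(disease = diseases, p_value = unname(res), stringsAsFactors = FALSE)
}

#' Recommendation-confidence percentage
#'
#' With `top_k` genes recommended out of `n_genes` candidates, a recommended
#' gene sits above `(1 - top_k / n_genes) * 100` percent of the candidate
#' pool — e.g. 30 of 19,188 genes is a confidence above 99.8%.
#'
#' @param top_k Recommended list length.
#' @param n_genes Candidate pool size.
#' @return Percentage in `[0, 100)`.
#' @export
recommendation_confidence <- function(top_k, n_genes) {
  stopifnot(n_genes > 0, top_k >= 0, top_k <= n_genes)
  (1 - top_k / n_genes) * 100
}
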