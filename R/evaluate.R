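#' Area under the ROC curve
#'
#' Rank-based AUROC equal to the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive gene scores higher, with
#' ties counted one half. Equivalently the area under the curve of true
#' positive rate `TP / (TP + FN)` against false positive rate
#' `FP / (FP + TN)` as the score threshold sweeps.
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 vector of the same length.
#' @return AUROC in `[0, 1]`, or `NA` when only one class is present (such
#'   folds are excluded from averages).
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Random fold assignment
#'
#' Uniform random, near-equal-sized folds (sizes differ by at most one);
#' not label-stratified.
#'
#' @param n Number of genes.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector in `1..n_folds`, one entry per gene.
#' @export
make_folds <- function(n, n_folds = 10, seed = 1L) {
  stopifnot(n >= n_folds, n_folds >= 2)
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(n_folds), n))
}

# package a row subset of aligned datasets for a scorer
subset_split <- function(datasets, labels, rows) {
  list(datasets = lapply(datasets, function(d) {
         if (inherits(d, "feature_dataset")) {
           list(matrix = d$matrix[rows, , drop = FALSE], kind = d$kind,
                known = d$known_mask[rows], name = d$name)
         } else {
           list(matrix = d[rows, , drop = FALSE], kind = "continuous",
                known = rep(TRUE, length(rows)), name = "matrix")
         }
       }),
       labels = if (inherits(labels, "label_matrix")) {
         labels$matrix[rows, , drop = FALSE]
       } else labels[rows, , drop = FALSE],
       rows = rows)
}

#' k-fold cross-validated per-label AUROC
#'
#' For each fold the scorer is fitted on the other folds and scores the held
#' -out genes; AUROC is computed per label within each test fold and then
#' averaged over folds (labels whose test fold lacks positives or negatives
#' are skipped for that fold and logged). Every gene is scored exactly once
#' out-of-fold, and the full out-of-fold score matrix is returned for
#' downstream ranking.
#'
#' @param scorer Function `f(train, test, seed)` where `train`/`test` carry
#'   `$datasets` (list of `matrix`/`kind`/`known`/`name`) and `$labels`;
#'   must return a score matrix for the test genes. See [mdl_scorer()],
#'   [naive_scorer()], [lr_scorer()].
#' @param datasets List of [feature_dataset()]s (or matrices) with aligned
#'   rows.
#' @param labels A [label_matrix()] or 0/1 matrix.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and training.
#' @return An `auroc_result`: `fold_label` (folds x labels AUROC matrix,
#'   `NA` where skipped), `label_mean`, `macro` (mean of label means),
#'   `scores` (out-of-fold score matrix), `folds`, `skipped` log.
#' @export
cross_validate <- function(scorer, datasets, labels, n_folds = 10, seed = 1L) {
  if (inherits(datasets, "feature_dataset") || is.matrix(datasets)) {
    datasets <- list(datasets)
  }
  Y <- if (inherits(labels, "label_matrix")) labels$matrix else labels
  n <- nrow(Y)
  label_names <- colnames(Y) %||% paste0("label", seq_len(ncol(Y)))
  folds <- make_folds(n, n_folds, seed)
  fold_label <- matrix(NA_real_, n_folds, ncol(Y),
                       dimnames = list(NULL, label_names))
  oof <- matrix(NA_real_, n, ncol(Y), dimnames = list(rownames(Y), label_names))
  skipped <- character()
  for (f in seq_len(n_folds)) {
    test_rows <- which(folds == f)
    train <- subset_split(datasets, labels, which(folds != f))
    test <- subset_split(datasets, labels, test_rows)
    S <- scorer(train, test, derive_seed(as.integer(seed), f))
    stopifnot(nrow(S) == length(test_rows), ncol(S) == ncol(Y))
    oof[test_rows, ] <- S
    for (l in seq_len(ncol(Y))) {
      a <- auroc(S[, l], test$labels[, l])
      if (is.na(a)) {
        skipped <- c(skipped, sprintf("fold %d: label '%s' single-class, skipped",
                                      f, label_names[l]))
      }
      fold_label[f, l] <- a
    }
  }
  label_mean <- colMeans(fold_label, na.rm = TRUE)
  label_mean[is.nan(label_mean)] <- NA_real_
  structure(list(fold_label = fold_label, label_mean = label_mean,
                 macro = mean(label_mean, na.rm = TRUE),
                 scores = oof, folds = folds, seed = seed,
                 skipped = skipped),
            class = "auroc_result")
}

#' @export
print.auroc_result <- function(x, ...) {
  cat(sprintf("Cross-validated AUROC over %d folds, %d labels: macro %.4f\n",
              nrow(x$fold_label), ncol(x$fold_label), x$macro))
  if (length(x$skipped)) cat(" ", length(x$skipped), "single-class fold/label pairs skipped\n")
  invisible(x)
}

#' Scorer wrapping the full two-stage model
#'
#' @param config A [pipeline_config()].
#' @return A scorer function for [cross_validate()].
#' @export
mdl_scorer <- function(config = pipeline_config()) {
  function(train, test, seed) {
    model <- fit_mdl(lapply(train$datasets, `[[`, "matrix"), train$labels,
                     config, seed = seed)
    predict(model, lapply(test$datasets, `[[`, "matrix"))
  }
}

#' Research-level naive score
#'
#' Scores each gene by how much it has been studied: the sum over boolean
#' datasets of the gene's number of terms (annotation / interaction /
#' pathway counts, 0 when the gene is unknown to the source) plus, for each
#' continuous dataset, 1 if the gene is present in the source and 0
#' otherwise. The single score is reused for every label — a baseline
#' testing whether a classifier merely favours well-studied genes.
#'
#' @param datasets List of [feature_dataset()]s.
#' @return Named numeric vector of per-gene scores.
#' @export
naive_score <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  parts <- lapply(datasets, function(d) {
    stopifnot(inherits(d, "feature_dataset"))
    if (d$kind == "boolean") rowSums(d$matrix) else as.numeric(d$known_mask)
  })
  out <- Reduce(`+`, parts)
  names(out) <- datasets[[1]]$universe$ids
  out
}

naive_score_raw <- function(parts) {
  Reduce(`+`, lapply(parts, function(d) {
    if (d$kind == "boolean") rowSums(d$matrix) else as.numeric(d$known)
  }))
}

#' @rdname naive_score
#' @return `naive_scorer()` returns a scorer for [cross_validate()] (the
#'   naive score needs no training).
#' @export
naive_scorer <- function() {
  function(train, test, seed) {
    s <- naive_score_raw(test$datasets)
    matrix(s, nrow = length(s), ncol = ncol(test$labels))
  }
}

#' Ridge-penalised logistic-regression baseline
#'
#' Independent one-vs-rest L2-regularised logistic models per label; scores
#' are predicted positive-class probabilities. The default penalty
#' `lambda = 1/n` matches the conventional unit-strength L2 default of
#' common implementations. Labels with a single class in training yield a
#' constant 0.5 score (logged via attribute `degenerate`).
#'
#' @param features Numeric matrix (genes x features), at least one column.
#' @param labels A [label_matrix()] or 0/1 matrix.
#' @param lambda Ridge penalty; default `1/nrow(features)`.
#' @param newdata Optional matrix to score (defaults to `features`).
#' @return Score matrix (rows of `newdata` x labels), entries in `[0, 1]`.
#' @export
lr_baseline <- function(features, labels, lambda = NULL, newdata = features) {
  Y <- if (inherits(labels, "label_matrix")) labels$matrix else labels
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  stopifnot(is.matrix(features), nrow(features) == nrow(Y))
  if (ncol(features) == 0L) stop("feature matrix has zero columns")
  lambda <- lambda %||% 1 / nrow(features)
  # glmnet requires >= 2 columns; pad constant-free with a zero column
  X <- features
  if (ncol(X) == 1L) X <- cbind(X, 0)
  NX <- newdata
  if (ncol(NX) == 1L) NX <- cbind(NX, 0)
  out <- matrix(0.5, nrow(NX), ncol(Y), dimnames = list(rownames(NX), colnames(Y)))
  degenerate <- character()
  for (l in seq_len(ncol(Y))) {
    y <- Y[, l]
    if (length(unique(y)) < 2L) {
      degenerate <- c(degenerate, colnames(Y)[l] %||% as.character(l))
      next
    }
    # warm-start path down to the target penalty stabilises the fit
    path <- sort(unique(c(1, 0.3, 0.1, 0.03, 0.01, lambda)), decreasing = TRUE)
    path <- path[path >= lambda]
    fit <- withCallingHandlers(
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = path, standardize = TRUE),
      # expected on very small or very unbalanced folds; the baseline result
      # (a near-constant score) is still well defined
      warning = function(w) {
        if (grepl("fewer than 8|Convergence for", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    out[, l] <- as.numeric(stats::predict(fit, NX, type = "response",
                                          s = lambda))
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' @rdname lr_baseline
#' @param concat Whether the scorer concatenates all datasets column-wise
#'   (default) before fitting.
#' @return `lr_scorer()` returns a scorer for [cross_validate()].
#' @export
lr_scorer <- function(lambda = NULL, concat = TRUE) {
  function(train, test, seed) {
    Xtr <- do.call(cbind, lapply(train$datasets, `[[`, "matrix"))
    Xte <- do.call(cbind, lapply(test$datasets, `[[`, "matrix"))
    lr_baseline(Xtr, train$labels, lambda = lambda, newdata = Xte)
  }
}

#' Gradient-boosted-tree baseline (optional)
#'
#' Thin per-label wrapper around the xgboost library (one-vs-rest binary
#' logistic boosting); available only when xgboost is installed.
#'
#' @param nrounds Boosting rounds.
#' @param ... Passed to `xgboost::xgboost()`.
#' @return A scorer for [cross_validate()].
#' @export
gbt_scorer <- function(nrounds = 50, ...) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("the GBT baseline needs the xgboost package")
  }
  function(train, test, seed) {
    Xtr <- do.call(cbind, lapply(train$datasets, `[[`, "matrix"))
    Xte <- do.call(cbind, lapply(test$datasets, `[[`, "matrix"))
    Y <- train$labels
    out <- matrix(0.5, nrow(Xte), ncol(Y))
    for (l in seq_len(ncol(Y))) {
      if (length(unique(Y[, l])) < 2L) next
      dtr <- xgboost::xgb.DMatrix(Xtr, label = Y[, l], nthread = 1)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              nthread = 1, ...),
                                data = dtr, nrounds = nrounds, verbose = 0)
      out[, l] <- stats::predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1))
    }
    out
  }
}
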