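#' Feature dataset
#'
#' One named gene-by-feature matrix over a universe, either boolean (0/1
#' pathway / annotation / interaction memberships) or continuous (e.g.
#' expression values), together with a per-gene mask marking genes actually
#' present in the source. Genes absent from the source ("unknown" genes) carry
#' all-zero rows and `known_mask = FALSE`; how they enter training is decided
#' later by [align_datasets()].
#'
#' @param name Dataset name (e.g. "KEGG", "GTEx", "Mashup").
#' @param matrix Numeric matrix, rows = genes in universe order.
#' @param universe A [gene_universe()].
#' @param kind `"boolean"` or `"continuous"`.
#' @param known_mask Logical per-gene vector; defaults to all `TRUE`.
#' @return A `feature_dataset` object.
#' @export
feature_dataset <- function(name, matrix, universe, kind = c("boolean", "continuous"),
                            known_mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(universe, "gene_universe"), is.matrix(matrix))
  matrix <- structure(matrix + 0, dimnames = dimnames(matrix)) # force numeric
  if (nrow(matrix) != length(universe)) {
    stop("dataset '", name, "': ", nrow(matrix), " rows but universe has ",
         length(universe), " genes")
  }
  if (is.null(known_mask)) known_mask <- rep(TRUE, nrow(matrix))
  known_mask <- as.logical(known_mask)
  stopifnot(length(known_mask) == nrow(matrix), !anyNA(known_mask))
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("dataset '", name, "' contains missing or non-finite values")
  }
  if (kind == "boolean" && !all(matrix %in% c(0, 1))) {
    stop("dataset '", name, "' is boolean but has entries outside {0, 1}")
  }
  matrix[!known_mask, ] <- 0
  rownames(matrix) <- universe$ids
  structure(
    list(name = name, matrix = matrix, kind = kind,
         known_mask = known_mask, universe = universe),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("Feature dataset '%s' (%s): %d genes x %d features, %.1f%% unknown\n",
              x$name, x$kind, nrow(x$matrix), ncol(x$matrix),
              100 * mean(!x$known_mask)))
  invisible(x)
}

#' Proportion of genes missing from a feature source
#'
#' The fraction of universe genes not covered by the dataset's source, the
#' per-dataset "unknown proportion" statistic.
#'
#' @param dataset A `feature_dataset`.
#' @return Fraction in `[0, 1]`.
#' @export
unknown_proportion <- function(dataset) {
  stopifnot(inherits(dataset, "feature_dataset"))
  mean(!dataset$known_mask)
}

#' Label matrix with a primary / secondary / tertiary hierarchy
#'
#' Binary gene-by-label annotations plus a child-to-parent map organising the
#' labels as a forest rooted at a single primary label. In the default
#' aging-disease setting there are 27 labels: one primary (`Class_Disease`),
#' seven secondary organ-system groups, and nineteen tertiary diseases; the
#' label count is never hard-coded and any consistent hierarchy is accepted.
#'
#' @param matrix Numeric 0/1 matrix, rows = genes in universe order,
#'   columns = labels.
#' @param universe A [gene_universe()].
#' @param label_names Character vector naming the columns.
#' @param hierarchy Named character vector mapping child label -> parent
#'   label; may be empty for flat label sets.
#' @return A `label_matrix` object.
#' @export
label_matrix <- function(matrix, universe, label_names = colnames(matrix),
                         hierarchy = character()) {
  stopifnot(inherits(universe, "gene_universe"), is.matrix(matrix))
  matrix <- matrix + 0
  if (nrow(matrix) != length(universe)) stop("label rows must match universe size")
  if (is.null(label_names)) stop("label names are required")
  label_names <- as.character(label_names)
  if (length(label_names) != ncol(matrix) || anyDuplicated(label_names)) {
    stop("label names must be unique and match the number of columns")
  }
  if (!all(matrix %in% c(0, 1))) stop("label entries must be 0 or 1")
  hierarchy <- validate_hierarchy(hierarchy, label_names)
  dimnames(matrix) <- list(universe$ids, label_names)
  structure(
    list(matrix = matrix, label_names = label_names,
         hierarchy = hierarchy, universe = universe),
    class = "label_matrix"
  )
}

# hierarchy: named chr vector child -> parent over known labels, acyclic,
# and (when nonempty) a forest with exactly one root label.
validate_hierarchy <- function(hierarchy, label_names) {
  if (length(hierarchy) == 0L) return(stats::setNames(character(), character()))
  hierarchy <- vapply(hierarchy, as.character, character(1))
  children <- names(hierarchy)
  if (is.null(children) || any(!nzchar(children))) stop("hierarchy must be a named child -> parent vector")
  bad <- setdiff(union(children, hierarchy), label_names)
  if (length(bad)) stop("hierarchy mentions unknown labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(children)) stop("a label may have at most one parent")
  # cycle check by walking each chain upward
  for (ch in children) {
    seen <- character()
    cur <- ch
    while (cur %in% children) {
      if (cur %in% seen) stop("cycle in label hierarchy at '", cur, "'")
      seen <- c(seen, cur)
      cur <- unname(hierarchy[cur])
    }
  }
  roots <- setdiff(unique(unname(hierarchy)), children)
  # labels that appear nowhere in the hierarchy are tolerated only if they
  # chain to the root set; a single root is required for nonempty hierarchies
  if (length(roots) != 1L) {
    stop("hierarchy must have exactly one root label, found: ",
         paste(roots, collapse = ", "))
  }
  hierarchy
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("Label matrix: %d genes x %d labels (%d hierarchy edges)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$hierarchy)))
  invisible(x)
}

#' Propagate positive labels up the hierarchy
#'
#' If a gene is annotated with any label, every ancestor label (secondary
#' group, then the primary root) is set positive as well: a gene associated
#' with a specific disease is by definition associated with the disease class
#' it belongs to. The operation is idempotent.
#'
#' @param labels A [label_matrix()].
#' @return A `label_matrix` with ancestor-closed annotations.
#' @export
propagate_hierarchy <- function(labels) {
  stopifnot(inherits(labels, "label_matrix"))
  m <- labels$matrix
  h <- labels$hierarchy
  if (length(h)) {
    # process children bottom-up: repeatedly OR child columns into parents
    remaining <- names(h)
    # topological order: a child whose own children are all done can fire
    depth <- vapply(names(h), function(ch) {
      d <- 0L; cur <- ch
      while (cur %in% names(h)) { d <- d + 1L; cur <- unname(h[cur]) }
      d
    }, integer(1))
    for (ch in names(h)[order(-depth)]) {
      parent <- unname(h[ch])
      m[, parent] <- pmax(m[, parent], m[, ch])
    }
  }
  labels$matrix <- m
  labels
}

#' The default 27-label aging-disease hierarchy
#'
#' One primary label (`Class_Disease`), seven secondary organ-system labels,
#' and nineteen tertiary disease labels. Eighteen tertiary names follow the
#' published aging-disease label set; the nineteenth leaf is the placeholder
#' `Neoplasm.Other`, as only eighteen distinct tertiary names are available
#' from that source.
#'
#' @return A list with `label_names` (length 27) and `hierarchy`
#'   (child -> parent map), suitable for [label_matrix()].
#' @export
default_label_hierarchy <- function() {
  secondaries <- c("Disease.Brain", "Disease.Heart", "Disease.Immune",
                   "Disease.Muscle", "Disease.Neoplasm", "Disease.Nutrition",
                   "Disease.Respiratory.Asthma")
  tert <- c(
    Brain.Alzheimer = "Disease.Brain",
    Brain.Multiple.Sclerosis = "Disease.Brain",
    Brain.Parkinson = "Disease.Brain",
    Heart.Arteriosclerosis = "Disease.Heart",
    Heart.Coronary.Disease = "Disease.Heart",
    Heart.Hypertension = "Disease.Heart",
    Immune.Hypersensitivity = "Disease.Immune",
    Muscle.Arthritis = "Disease.Muscle",
    Muscle.Osteoporosis = "Disease.Muscle",
    Neoplasm.Adenocarcinoma = "Disease.Neoplasm",
    Neoplasm.Breast = "Disease.Neoplasm",
    Neoplasm.Colorectal = "Disease.Neoplasm",
    Neoplasm.Lung = "Disease.Neoplasm",
    Neoplasm.Prostatic = "Disease.Neoplasm",
    Neoplasm.Stomach = "Disease.Neoplasm",
    Neoplasm.Other = "Disease.Neoplasm",
    Nutritional.Diabetes.Type1 = "Disease.Nutrition",
    Nutritional.Diabetes.Type2 = "Disease.Nutrition",
    Nutritional.Obesity = "Disease.Nutrition"
  )
  hierarchy <- c(stats::setNames(rep("Class_Disease", length(secondaries)), secondaries), tert)
  list(label_names = c("Class_Disease", secondaries, names(tert)),
       hierarchy = hierarchy)
}

#' Align heterogeneous datasets on a common gene set
#'
#' Feature sources cover different subsets of the gene universe. Two
#' strategies reconcile them before training: `"include"` keeps every gene
#' and leaves unknown rows zero-imputed (the natural reading of boolean
#' membership coding, where absence scores 0), while `"exclude"` restricts
#' every dataset and the label matrix to genes known in *all* datasets.
#'
#' @param datasets List of [feature_dataset()] objects over one universe.
#' @param labels A [label_matrix()] over the same universe.
#' @param strategy `"include"` or `"exclude"`.
#' @return List with `datasets`, `labels`, and `universe` (restricted under
#'   `"exclude"`).
#' @export
align_datasets <- function(datasets, labels, strategy = c("include", "exclude")) {
  strategy <- match.arg(strategy)
  stopifnot(length(datasets) >= 1L, inherits(labels, "label_matrix"))
  for (d in datasets) {
    stopifnot(inherits(d, "feature_dataset"))
    if (!same_universe(d$universe, labels$universe)) {
      stop("dataset '", d$name, "' is indexed by a different universe")
    }
  }
  if (strategy == "include") {
    return(list(datasets = datasets, labels = labels, universe = labels$universe))
  }
  keep <- Reduce(`&`, lapply(datasets, `[[`, "known_mask"))
  if (!any(keep)) stop("exclude strategy removes every gene: no gene is known in all datasets")
  uni <- gene_universe(labels$universe$ids[keep])
  datasets <- lapply(datasets, function(d) {
    feature_dataset(d$name, d$matrix[keep, , drop = FALSE], uni, d$kind,
                    known_mask = d$known_mask[keep])
  })
  labels <- label_matrix(labels$matrix[keep, , drop = FALSE], uni,
                         labels$label_names, labels$hierarchy)
  list(datasets = datasets, labels = labels, universe = uni)
}
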