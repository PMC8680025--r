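#' Read a weighted edge list
#'
#' Reads a 2-3 column TSV (`gene_a`, `gene_b`, optional `weight`; comment
#' lines start with `#`, no header) into a symmetric weighted adjacency over
#' a gene universe. Duplicate edges are summed, as are the two directions of
#' a directed listing; self-loops are allowed.
#'
#' @param path TSV file path.
#' @param universe Optional [gene_universe()]; when absent the union of
#'   listed genes (in order of first appearance) is used.
#' @return A [weighted_network()].
#' @export
load_edge_list <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  df <- if (length(lines)) {
    utils::read.delim(text = lines, header = FALSE, colClasses = "character")
  } else data.frame()
  if (nrow(df) == 0L) {
    if (is.null(universe)) stop("empty edge list and no universe supplied")
    n <- length(universe)
    return(weighted_network(matrix(0, n, n), universe))
  }
  if (!ncol(df) %in% c(2L, 3L)) stop("edge list must have 2 or 3 columns")
  w <- if (ncol(df) == 3L) suppressWarnings(as.numeric(df[[3]])) else rep(1, nrow(df))
  if (anyNA(w)) stop("non-numeric weight at row ", which(is.na(w))[1])
  if (any(w < 0)) stop("negative weight at row ", which(w < 0)[1])
  if (is.null(universe)) {
    ids <- unique(c(rbind(df[[1]], df[[2]])))
    universe <- gene_universe(ids)
  }
  i <- gene_index(universe, df[[1]])
  j <- gene_index(universe, df[[2]])
  n <- length(universe)
  A <- matrix(0, n, n, dimnames = list(universe$ids, universe$ids))
  for (k in seq_along(w)) {
    A[i[k], j[k]] <- A[i[k], j[k]] + w[k]
    if (i[k] != j[k]) A[j[k], i[k]] <- A[j[k], i[k]] + w[k]
  }
  weighted_network(A, universe)
}

#' Write a network as an edge list TSV
#'
#' Upper-triangle (including diagonal) nonzero entries of the adjacency.
#'
#' @param net A [weighted_network()].
#' @param path Output TSV path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  idx <- which(upper.tri(net$A, diag = TRUE) & net$A != 0, arr.ind = TRUE)
  df <- data.frame(a = net$universe$ids[idx[, 1]],
                   b = net$universe$ids[idx[, 2]],
                   w = net$A[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a feature table
#'
#' Feature tables are TSVs with a header row: first column `gene`, then one
#' column per feature; a `.known` sidecar column (0/1) records source
#' coverage and is written/read automatically. Rows may appear in any order;
#' genes of the universe missing from the file are treated as unknown.
#'
#' @param path TSV path.
#' @param universe A [gene_universe()]; for reading, defaults to the file's
#'   genes in order.
#' @param name Dataset name; defaults to the file name.
#' @param kind `"boolean"` or `"continuous"`.
#' @return [read_feature_table()] returns a [feature_dataset()].
#' @export
read_feature_table <- function(path, universe = NULL, name = NULL,
                               kind = c("boolean", "continuous")) {
  kind <- match.arg(kind)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = NA, comment.char = "#")
  stopifnot(ncol(df) >= 2L, names(df)[1] == "gene")
  genes <- as.character(df[[1]])
  known_col <- names(df) == ".known"
  known <- if (any(known_col)) as.logical(df[[which(known_col)]] != 0) else rep(TRUE, nrow(df))
  feat <- as.matrix(df[, !known_col & seq_len(ncol(df)) > 1L, drop = FALSE])
  storage.mode(feat) <- "double"
  if (is.null(universe)) universe <- gene_universe(genes)
  m <- matrix(0, length(universe), ncol(feat),
              dimnames = list(universe$ids, colnames(feat)))
  mask <- rep(FALSE, length(universe))
  pos <- gene_index(universe, genes)
  m[pos, ] <- feat
  mask[pos] <- known
  feature_dataset(name, m, universe, kind, known_mask = mask)
}

#' @rdname read_feature_table
#' @param dataset A [feature_dataset()] to write.
#' @export
write_feature_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "feature_dataset"))
  df <- data.frame(gene = dataset$universe$ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(dataset$matrix, check.names = FALSE))
  df$.known <- as.integer(dataset$known_mask)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a label table and its hierarchy
#'
#' Label tables are TSVs: first column `gene`, one 0/1 column per label.
#' The hierarchy is a separate 2-column TSV (`child`, `parent`) with header.
#'
#' @param path Label TSV path.
#' @param universe A [gene_universe()]; defaults to the file's genes.
#' @param hierarchy_path Optional hierarchy TSV path.
#' @return [read_label_table()] returns a [label_matrix()].
#' @export
read_label_table <- function(path, universe = NULL, hierarchy_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE, comment.char = "#")
  stopifnot(ncol(df) >= 2L, names(df)[1] == "gene")
  genes <- as.character(df[[1]])
  m0 <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m0) <- "double"
  if (is.null(universe)) universe <- gene_universe(genes)
  m <- matrix(0, length(universe), ncol(m0), dimnames = list(universe$ids, colnames(m0)))
  m[gene_index(universe, genes), ] <- m0
  hierarchy <- character()
  if (!is.null(hierarchy_path)) {
    h <- utils::read.delim(hierarchy_path, header = TRUE, colClasses = "character")
    hierarchy <- stats::setNames(h[[2]], h[[1]])
  }
  label_matrix(m, universe, colnames(m0), hierarchy)
}

#' @rdname read_label_table
#' @param labels A [label_matrix()] to write.
#' @export
write_label_table <- function(labels, path, hierarchy_path = NULL) {
  stopifnot(inherits(labels, "label_matrix"))
  df <- data.frame(gene = labels$universe$ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(labels$matrix, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hierarchy_path)) {
    h <- data.frame(child = names(labels$hierarchy),
                    parent = unname(labels$hierarchy))
    utils::write.table(h, hierarchy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
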