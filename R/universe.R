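#' Gene universe
#'
#' An ordered set of unique gene identifiers shared by every network, feature
#' dataset and label matrix in an analysis. Gene identifiers are opaque
#' strings; numeric (Entrez-style) identifiers are kept as character and never
#' parsed as integers.
#'
#' @param ids Character vector of gene identifiers.
#' @return A `gene_universe` object: the ordered identifiers plus an
#'   id-to-position lookup (positions are 1-based internally and never appear
#'   in files, which always carry explicit gene-ID columns).
#' @export
gene_universe <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) < 1L) stop("a gene universe needs at least one gene")
  if (anyNA(ids) || any(!nzchar(ids))) stop("gene ids must be non-missing, non-empty strings")
  if (anyDuplicated(ids)) stop("duplicate gene ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(
    list(ids = ids, index = stats::setNames(seq_along(ids), ids)),
    class = "gene_universe"
  )
}

#' @export
length.gene_universe <- function(x) length(x$ids)

#' @export
print.gene_universe <- function(x, ...) {
  cat("Gene universe with", length(x$ids), "genes\n")
  show <- utils::head(x$ids, 5L)
  cat(" ", paste(show, collapse = ", "), if (length(x$ids) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Positions of gene ids in a universe
#'
#' @param universe A `gene_universe`.
#' @param ids Character vector of gene identifiers.
#' @return Integer positions; unknown ids raise an error.
#' @export
gene_index <- function(universe, ids) {
  stopifnot(inherits(universe, "gene_universe"))
  pos <- universe$index[as.character(ids)]
  if (anyNA(pos)) {
    stop("gene ids not in universe: ",
         paste(utils::head(ids[is.na(pos)], 5L), collapse = ", "))
  }
  unname(pos)
}

same_universe <- function(a, b) identical(a$ids, b$ids)
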