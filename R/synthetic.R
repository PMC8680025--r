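#' Configuration of the synthetic benchmark generator
#'
#' Describes a synthetic study in which a planted community partition drives
#' every data modality, emulating the statistical shape of real gene-disease
#' studies: dense-within / sparse-between gene networks, boolean annotation
#' matrices enriched in the communities their features belong to, continuous
#' expression-like matrices with community-level means, hierarchical
#' multi-label disease annotations tied to communities, per-dataset
#' unknown-gene masks, and "hidden positives" — truly associated genes
#' released with a negative label, which is exactly the situation the
#' recommendation machinery is meant to detect.
#'
#' @param n_genes Number of genes.
#' @param n_communities Number of planted communities (<= n_genes).
#' @param n_networks Independent planted-partition networks sharing the one
#'   community structure (default 2, exercising multi-network integration).
#' @param p_within,p_between Edge probabilities inside / between communities.
#' @param n_boolean_datasets,n_boolean_features Boolean annotation datasets
#'   and features per dataset.
#' @param feature_background Background probability of a boolean feature.
#' @param enrichment_odds Odds multiplier of a boolean feature inside its
#'   community (1 = no feature signal).
#' @param n_continuous_datasets,n_continuous_features Continuous datasets
#'   and features per dataset.
#' @param community_effect SD of per-community means of continuous features
#'   (0 = no continuous signal).
#' @param noise_scale SD of per-gene continuous noise.
#' @param label_names,hierarchy Label set; defaults to
#'   [default_label_hierarchy()]'s 27-label aging-disease structure.
#' @param positive_rate Probability that a gene of a label's linked
#'   community is annotated positive.
#' @param background_rate Positive probability for all other genes (equal to
#'   `positive_rate` means no planted label signal).
#' @param hidden_fraction Fraction of true positives per leaf label released
#'   as negatives (hidden positives).
#' @param unknown_fraction Per-dataset fraction of genes masked unknown.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500,
                             n_communities = 8,
                             n_networks = 2,
                             p_within = 0.3, p_between = 0.02,
                             n_boolean_datasets = 2, n_boolean_features = 40,
                             feature_background = 0.1, enrichment_odds = 4,
                             n_continuous_datasets = 1, n_continuous_features = 20,
                             community_effect = 0.5, noise_scale = 1,
                             label_names = NULL, hierarchy = NULL,
                             positive_rate = 0.8, background_rate = 0.01,
                             hidden_fraction = 0.1,
                             unknown_fraction = 0.05,
                             seed = 1L) {
  if (is.null(label_names)) {
    lh <- default_label_hierarchy()
    label_names <- lh$label_names
    hierarchy <- lh$hierarchy
  }
  stopifnot(n_genes >= 2, n_communities >= 1, n_communities <= n_genes,
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            enrichment_odds > 0, positive_rate >= 0, positive_rate <= 1,
            background_rate >= 0, background_rate <= 1,
            hidden_fraction >= 0, hidden_fraction < 1,
            unknown_fraction >= 0, unknown_fraction < 1,
            n_networks >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_communities = as.integer(n_communities),
                 n_networks = as.integer(n_networks),
                 p_within = p_within, p_between = p_between,
                 n_boolean_datasets = as.integer(n_boolean_datasets),
                 n_boolean_features = as.integer(n_boolean_features),
                 feature_background = feature_background,
                 enrichment_odds = enrichment_odds,
                 n_continuous_datasets = as.integer(n_continuous_datasets),
                 n_continuous_features = as.integer(n_continuous_features),
                 community_effect = community_effect,
                 noise_scale = noise_scale,
                 label_names = label_names, hierarchy = hierarchy,
                 positive_rate = positive_rate,
                 background_rate = background_rate,
                 hidden_fraction = hidden_fraction,
                 unknown_fraction = unknown_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic study
#'
#' Draws one complete dataset collection from a [synthetic_config()]:
#' networks, boolean and continuous feature datasets, the released label
#' matrix (ancestor-closed), and the ground truth (community assignment,
#' full true label matrix, and the hidden-positive list) kept alongside for
#' evaluation. Identical seeds give identical output.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset`: `universe`, `networks` (list of
#'   [weighted_network()]), `datasets` (list of [feature_dataset()]),
#'   `labels` ([label_matrix()], released), and `truth` (communities,
#'   `true_labels`, `hidden` data.frame of gene/label pairs).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(config$seed))
  n <- config$n_genes
  ids <- sprintf("g%04d", seq_len(n))
  uni <- gene_universe(ids)
  communities <- sort(rep_len(seq_len(config$n_communities), n))

  networks <- lapply(seq_len(config$n_networks), function(k) {
    A <- matrix(0, n, n)
    same <- outer(communities, communities, "==")
    p <- ifelse(same, config$p_within, config$p_between)
    up <- upper.tri(A)
    edge <- up & (matrix(stats::runif(n * n), n, n) < p)
    A[edge] <- stats::runif(sum(edge), 0.5, 1.5)
    A <- A + t(A)
    weighted_network(A, uni, name = paste0("net", k))
  })

  datasets <- list()
  for (b in seq_len(config$n_boolean_datasets)) {
    pfeat <- config$n_boolean_features
    feat_comm <- rep_len(seq_len(config$n_communities), pfeat)
    base <- config$feature_background
    p_in <- (base * config$enrichment_odds) /
      (1 - base + base * config$enrichment_odds)
    P <- matrix(base, n, pfeat)
    for (j in seq_len(pfeat)) P[communities == feat_comm[j], j] <- p_in
    M <- matrix(as.numeric(stats::runif(n * pfeat) < P), n, pfeat)
    colnames(M) <- sprintf("term%03d", seq_len(pfeat))
    datasets[[length(datasets) + 1L]] <-
      feature_dataset(paste0("bool", b), M, uni, "boolean")
  }
  for (cdx in seq_len(config$n_continuous_datasets)) {
    pfeat <- config$n_continuous_features
    mu <- matrix(stats::rnorm(config$n_communities * pfeat,
                              sd = config$community_effect),
                 config$n_communities, pfeat)
    M <- mu[communities, , drop = FALSE] +
      matrix(stats::rnorm(n * pfeat, sd = config$noise_scale), n, pfeat)
    colnames(M) <- sprintf("expr%03d", seq_len(pfeat))
    datasets[[length(datasets) + 1L]] <-
      feature_dataset(paste0("cont", cdx), M, uni, "continuous")
  }

  # unknown-gene masks, independently per dataset
  if (config$unknown_fraction > 0) {
    for (k in seq_along(datasets)) {
      n_unknown <- floor(config$unknown_fraction * n)
      if (n_unknown > 0) {
        hide <- sample.int(n, n_unknown)
        mask <- rep(TRUE, n); mask[hide] <- FALSE
        datasets[[k]] <- feature_dataset(datasets[[k]]$name,
                                         datasets[[k]]$matrix, uni,
                                         datasets[[k]]$kind, known_mask = mask)
      }
    }
  }

  # labels: leaves of the hierarchy (and childless non-root labels) carry
  # direct annotations tied to communities; ancestors follow by propagation
  labs <- config$label_names
  h <- config$hierarchy %||% character()
  parents <- unique(unname(h))
  base_labels <- if (length(h)) setdiff(labs, parents) else labs
  base_comm <- rep_len(seq_len(config$n_communities), length(base_labels))
  true_m <- matrix(0, n, length(labs), dimnames = list(ids, labs))
  for (bl in seq_along(base_labels)) {
    p <- ifelse(communities == base_comm[bl],
                config$positive_rate, config$background_rate)
    true_m[, base_labels[bl]] <- as.numeric(stats::runif(n) < p)
  }
  released_m <- true_m
  hidden <- data.frame(gene = character(), label = character(),
                       stringsAsFactors = FALSE)
  if (config$hidden_fraction > 0) {
    for (bl in base_labels) {
      pos <- which(true_m[, bl] == 1)
      n_hide <- floor(config$hidden_fraction * length(pos))
      if (n_hide > 0) {
        hide <- sample(pos, n_hide)
        released_m[hide, bl] <- 0
        hidden <- rbind(hidden, data.frame(gene = ids[hide], label = bl,
                                           stringsAsFactors = FALSE))
      }
    }
  }
  true_labels <- propagate_hierarchy(label_matrix(true_m, uni, labs, h))
  labels <- propagate_hierarchy(label_matrix(released_m, uni, labs, h))

  structure(list(universe = uni, networks = networks, datasets = datasets,
                 labels = labels,
                 truth = list(communities = stats::setNames(communities, ids),
                              true_labels = true_labels, hidden = hidden),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("Synthetic dataset: %d genes, %d communities, %d network%s, ",
                     "%d feature datasets, %d labels, %d hidden positives\n"),
              x$config$n_genes, x$config$n_communities, length(x$networks),
              if (length(x$networks) == 1) "" else "s", length(x$datasets),
              ncol(x$labels$matrix), nrow(x$truth$hidden)))
  invisible(x)
}

# compact 6-label hierarchy for exact small-scale tests
tiny_label_hierarchy <- function() {
  list(label_names = c("Class_Disease", "Disease.A", "Disease.B",
                       "A.One", "A.Two", "B.One"),
       hierarchy = c(Disease.A = "Class_Disease", Disease.B = "Class_Disease",
                     A.One = "Disease.A", A.Two = "Disease.A",
                     B.One = "Disease.B"))
}

#' Fixed-seed benchmark suite
#'
#' Three reference scales generated with fixed seeds: `tiny` (60 genes, 3
#' communities, 6 labels) for exact unit-level checks, `small` (500 genes, 8
#' communities, the full 27-label 1+7+19 hierarchy) for pipeline-level
#' benchmarks, and `medium` (2000 genes) for end-to-end timing.
#'
#' @param scale `"tiny"`, `"small"` or `"medium"`.
#' @param ... Overrides forwarded to [synthetic_config()] (e.g.
#'   `enrichment_odds`, `seed`).
#' @return A `synthetic_dataset`.
#' @export
generate_benchmark_suite <- function(scale = c("tiny", "small", "medium"), ...) {
  scale <- match.arg(scale)
  overrides <- list(...)
  base <- switch(scale,
    tiny = {
      lh <- tiny_label_hierarchy()
      list(n_genes = 60, n_communities = 3, n_networks = 1,
           n_boolean_datasets = 1, n_boolean_features = 12,
           n_continuous_datasets = 1, n_continuous_features = 6,
           label_names = lh$label_names, hierarchy = lh$hierarchy,
           seed = 101L)
    },
    small = list(n_genes = 500, n_communities = 8, seed = 202L),
    medium = list(n_genes = 2000, n_communities = 10, seed = 303L))
  generate_synthetic(do.call(synthetic_config, utils::modifyList(base, overrides)))
}

#' Write a synthetic dataset to TSV files
#'
#' Emits every object in the package's file formats: one edge list per
#' network, one feature table per dataset, the label table with its
#' hierarchy, and the ground truth (communities, hidden positives) for
#' reference.
#'
#' @param data A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  stopifnot(inherits(data, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(data$networks)) {
    write_edge_list(data$networks[[k]],
                    file.path(dir, paste0("network_", data$networks[[k]]$name, ".tsv")))
  }
  for (d in data$datasets) {
    write_feature_table(d, file.path(dir, paste0("features_", d$name, ".tsv")))
  }
  write_label_table(data$labels, file.path(dir, "labels.tsv"),
                    file.path(dir, "hierarchy.tsv"))
  utils::write.table(data.frame(gene = names(data$truth$communities),
                                community = unname(data$truth$communities)),
                     file.path(dir, "truth_communities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data$truth$hidden, file.path(dir, "truth_hidden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
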