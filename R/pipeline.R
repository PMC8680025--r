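#' Load a study directory
#'
#' Reads every input of a pipeline run from one directory in the package's
#' TSV formats: `network_*.tsv` edge lists, `features_*.tsv` feature tables
#' (a table whose values are all 0/1 is taken as boolean), and `labels.tsv`
#' with `hierarchy.tsv`. The gene universe is taken from the label table.
#'
#' @param dir Directory path.
#' @return A list with `universe`, `networks`, `datasets`, `labels` —
#'   structurally identical to a [generate_synthetic()] result (minus truth).
#' @export
load_study <- function(dir) {
  lab_path <- file.path(dir, "labels.tsv")
  if (!file.exists(lab_path)) stop("no labels.tsv in ", dir)
  hier_path <- file.path(dir, "hierarchy.tsv")
  labels <- read_label_table(lab_path, hierarchy_path =
                               if (file.exists(hier_path)) hier_path)
  uni <- labels$universe
  net_files <- sort(list.files(dir, "^network_.*\\.tsv$", full.names = TRUE))
  networks <- lapply(net_files, load_edge_list, universe = uni)
  feat_files <- sort(list.files(dir, "^features_.*\\.tsv$", full.names = TRUE))
  datasets <- lapply(feat_files, function(f) {
    d <- read_feature_table(f, universe = uni,
                            name = sub("^features_(.*)\\.tsv$", "\\1", basename(f)),
                            kind = "continuous")
    if (all(d$matrix %in% c(0, 1))) {
      d <- feature_dataset(d$name, d$matrix, uni, "boolean", d$known_mask)
    }
    d
  })
  list(universe = uni, networks = networks, datasets = datasets, labels = labels)
}

pipeline_stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(force(expr), error = function(e) {
    manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e),
                                     seconds = proc.time()[["elapsed"]] - t0)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  manifest$stages[[name]] <- list(status = "complete",
                                  seconds = round(proc.time()[["elapsed"]] - t0, 3))
  list(manifest = manifest, value = value)
}

#' Run the full prediction pipeline
#'
#' One-command orchestration: align datasets under the configured
#' unknown-gene strategy, embed all networks (Mashup), train and
#' cross-validate the two-stage model once per seed alongside the naive and
#' logistic-regression baselines on the same folds, compare the methods
#' statistically, and produce consensus recommendations with the neighbour
#' test. All randomness flows from the configured seeds; rerunning with the
#' same config and data reproduces every output.
#'
#' @param data A `synthetic_dataset`, a [load_study()] result, or a study
#'   directory path.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, summary TSVs and the run
#'   manifest (YAML) are written there.
#' @param verbose Print per-stage progress.
#' @return An `mdl_pipeline_result`: `evaluation` (per seed/fold/label AUROC
#'   long table), `macro` per method, `comparisons`, `consensus`,
#'   `neighbor_test`, `embedding`, and `manifest` (config snapshot, stage
#'   status and timings).
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(data)) data <- load_study(data)
  stopifnot(length(data$networks) >= 1L, inherits(data$labels, "label_matrix"))
  manifest <- list(config = unclass(config),
                   seeds = config$seeds,
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   stages = list())
  say <- function(...) if (verbose) message(...)

  st <- pipeline_stage(manifest, "align", {
    align_datasets(data$datasets, data$labels, config$strategy)
  })
  manifest <- st$manifest; aligned <- st$value
  say("aligned: ", length(aligned$universe), " genes")

  st <- pipeline_stage(manifest, "embed", {
    networks <- data$networks
    if (config$strategy == "exclude") {
      keep <- gene_index(data$labels$universe, aligned$universe$ids)
      networks <- lapply(networks, function(nt) {
        weighted_network(nt$A[keep, keep, drop = FALSE], aligned$universe, nt$name)
      })
    }
    mashup_embed(networks, d = min(config$embedding_dim, length(aligned$universe)),
                 restart_prob = config$restart_prob,
                 method = config$embedding_method)
  })
  manifest <- st$manifest; embedding <- st$value
  say("embedded ", length(data$networks), " network(s) into ", embedding$d, " dims")

  datasets <- c(list(embedding_as_dataset(embedding)), aligned$datasets)
  labels <- aligned$labels

  st <- pipeline_stage(manifest, "evaluate", {
    scorers <- list(MDL = mdl_scorer(config), Naive = naive_scorer(),
                    LR = lr_scorer())
    rows <- list(); runs <- list(); fold_macro <- list()
    for (m in names(scorers)) fold_macro[[m]] <- numeric()
    for (seed in config$seeds) {
      for (m in names(scorers)) {
        cv <- cross_validate(scorers[[m]], datasets, labels,
                             n_folds = config$n_folds, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, seed = seed,
          fold = rep(seq_len(config$n_folds), ncol(cv$fold_label)),
          label = rep(colnames(cv$fold_label), each = config$n_folds),
          auroc = as.vector(cv$fold_label))
        fold_macro[[m]] <- c(fold_macro[[m]],
                             rowMeans(cv$fold_label, na.rm = TRUE))
        if (m == "MDL") {
          runs[[as.character(seed)]] <- recommendation_run(cv$scores, labels,
                                                           seed = seed)
        }
        say(sprintf("seed %d %s macro %.4f", seed, m, cv$macro))
      }
    }
    list(table = do.call(rbind, rows), fold_macro = fold_macro, runs = runs)
  })
  manifest <- st$manifest; ev <- st$value

  st <- pipeline_stage(manifest, "compare", {
    lapply(setdiff(names(ev$fold_macro), "MDL"), function(m) {
      c(list(other = m), unclass(compare_methods(ev$fold_macro$MDL,
                                                 ev$fold_macro[[m]])))
    })
  })
  manifest <- st$manifest; comparisons <- st$value

  st <- pipeline_stage(manifest, "recommend", {
    consensus_recommend(ev$runs, top_k = config$top_k,
                        min_freq = config$min_frequency)
  })
  manifest <- st$manifest; consensus <- st$value

  st <- pipeline_stage(manifest, "neighbor_test", {
    suppressWarnings(neighbor_hypothesis_test(ev$runs, top_k = config$top_k))
  })
  manifest <- st$manifest; nbr <- st$value

  macro <- vapply(ev$fold_macro, mean, numeric(1), na.rm = TRUE)
  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  result <- structure(list(evaluation = ev$table, macro = macro,
                           fold_macro = ev$fold_macro,
                           runs = ev$runs,
                           comparisons = comparisons, consensus = consensus,
                           neighbor_test = nbr, embedding = embedding,
                           labels = labels, datasets = datasets,
                           manifest = manifest),
                      class = "mdl_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.mdl_pipeline_result <- function(x, ...) {
  cat("Pipeline result over", length(x$manifest$seeds), "seed(s)\n")
  cat("  mean per-fold macro AUROC by method:\n")
  for (m in names(x$macro)) cat(sprintf("    %-6s %.4f\n", m, x$macro[[m]]))
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$evaluation, file.path(out_dir, "evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- do.call(rbind, lapply(result$comparisons, function(cp) {
    data.frame(other = cp$other, mean_ours = cp$mean_a, mean_other = cp$mean_b,
               t_p = cp$t_p, u_greater = cp$u_p_greater,
               u_two_side = cp$u_p_two_side, u_less = cp$u_p_less)
  }))
  utils::write.table(comp, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- do.call(rbind, lapply(names(result$consensus$diseases), function(d) {
    tab <- result$consensus$diseases[[d]]
    if (nrow(tab) == 0) return(NULL)
    cbind(disease = d, tab, rest_mean = result$consensus$rest_mean[[d]])
  }))
  if (!is.null(rec)) {
    utils::write.table(rec, file.path(out_dir, "recommendations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(result$neighbor_test, file.path(out_dir, "neighbor_test.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_embedding(result$embedding, file.path(out_dir, "mashup.tsv"))
  yaml::write_yaml(result$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
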