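# End-to-end plumbing: prediction tables on disk, metric reports, and the
# one-command synthetic pipeline (synth -> features -> train -> predict ->
# evaluate) with per-stage error attribution.

#' Write / read a prediction table
#'
#' TSV of (`enzyme`, `residue_number`, `propensity`, `predicted`, `label`),
#' the on-disk interface between prediction and evaluation.
#'
#' @param preds Prediction tibble from [predict.catsite_model()].
#' @param path Output TSV.
#' @return `path` (write) or the tibble (read).
#' @export
write_predictions <- function(preds, path) {
  write.table(preds, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Metric report for a prediction table
#'
#' Fixed-threshold metrics (default 0.5), Best-F1 with its threshold, and
#' ranking metrics, in one flat list suitable for JSON serialization.
#'
#' @param preds Prediction tibble with `propensity` and `label`.
#' @param threshold Fixed decision threshold.
#' @return Named list of metric values (micro aggregation, labelled).
#' @export
evaluate_predictions <- function(preds, threshold = 0.5) {
  tm <- threshold_metrics(preds, threshold)
  bf <- best_f1(preds)
  rm_ <- rank_metrics(preds)
  list(threshold = threshold, precision = tm$precision, recall = tm$recall,
       f1 = tm$f1, best_f1 = bf$best_f1, best_f1_threshold = bf$threshold,
       auc = rm_$auc, aupr = rm_$aupr, aggregate = "micro",
       n_residues = nrow(preds), prevalence = mean(preds$label))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e))))
}

#' Run the synthetic pipeline end to end
#'
#' Generates the benchmark, builds graphs, trains, predicts the held-out
#' split, evaluates, and writes predictions, metrics, history and a
#' resolved-config snapshot into `out_dir`. Deterministic for a fixed
#' config; stage failures are reported with the stage name.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory.
#' @param train_config A [catsite_train_config()].
#' @param model_dims Named list overriding model dimensions
#'   (`gcn_dims`, `branch_dim`, `fusion_dim`).
#' @param cutoff Contact cutoff in Angstrom.
#' @param threshold Prediction threshold.
#' @return List with `metrics`, `predictions`, `fit`, invisibly.
#' @export
end_to_end <- function(config = synth_config(), out_dir = tempfile(),
                       train_config = catsite_train_config(),
                       model_dims = list(gcn_dims = c(64, 64, 64),
                                         branch_dim = 128,
                                         fusion_dim = 128),
                       cutoff = 10, threshold = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bench <- stage("synth", synth_benchmark(config))
  graphs_train <- stage("features", bundle_graphs(bench$train, cutoff))
  graphs_test <- stage("features", bundle_graphs(bench$test, cutoff))
  model <- catsite_model(gcn_dims = model_dims$gcn_dims,
                         branch_dim = model_dims$branch_dim,
                         fusion_dim = model_dims$fusion_dim,
                         seed = train_config$seed)
  fit <- stage("train", train_catsite(graphs_train, train_config, model))
  preds <- stage("predict", predict(fit, graphs_test, threshold = threshold))
  metrics <- stage("evaluate", evaluate_predictions(preds, threshold))
  write_predictions(preds, file.path(out_dir, "predictions.tsv"))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(fit$history, file.path(out_dir, "history.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(synth = unclass(config), train = unclass(train_config),
         model_dims = model_dims, cutoff = cutoff, threshold = threshold),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(metrics = metrics, predictions = preds, fit = fit))
}

#' Class-separation silhouette of enzyme representations
#'
#' Mean silhouette width of the pooled per-enzyme representations grouped
#' by enzyme class; positive values mean the contrastive phase separated
#' the classes.
#'
#' @param model A `catsite_model` or `catsite_fit`.
#' @param dataset List of `residue_graph` objects with `ec_class` set.
#' @return Scalar mean silhouette width.
#' @export
class_silhouette <- function(model, dataset) {
  zs <- enzyme_representations(model, dataset)
  cl <- attr(zs, "class_labels")
  if (length(unique(cl)) < 2)
    abort("silhouette needs at least two enzyme classes")
  sil <- cluster::silhouette(as.integer(factor(cl)), stats::dist(zs))
  mean(sil[, "sil_width"])
}
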