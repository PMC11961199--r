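# Residue-level evaluation: threshold metrics, Best-F1, ranking metrics
# (AUC via the Mann-Whitney pairwise formulation with tie correction, AUPR
# via step-wise precision-recall integration), and the spatial
# distance-to-nearest-catalytic analysis.

check_pred_tbl <- function(preds) {
  preds <- tibble::as_tibble(preds)
  if (!all(c("propensity", "label") %in% names(preds)))
    abort("predictions need columns 'propensity' and 'label'")
  if (any(preds$propensity < 0 | preds$propensity > 1))
    abort("propensities must lie in [0, 1]")
  if (!all(preds$label %in% c(0, 1))) abort("labels must be binary")
  preds
}

confusion_f1 <- function(scores, labels, t) {
  pred <- as.integer(scores >= t)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  tibble::tibble(threshold = t, precision = precision, recall = recall,
                 f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn,
                 precision_defined = tp + fp > 0,
                 recall_defined = tp + fn > 0)
}

#' Precision, recall and F1 at a fixed threshold
#'
#' Residue-level confusion counts pooled across enzymes (micro
#' aggregation) or averaged per enzyme (macro). Undefined ratios (empty
#' denominators) are reported as 0 and flagged via the
#' `precision_defined` / `recall_defined` columns.
#'
#' @param preds Tibble with columns `propensity`, `label` (and `enzyme`
#'   for macro aggregation).
#' @param threshold Decision threshold in `[0, 1]`; a residue is called
#'   catalytic when `propensity >= threshold`.
#' @param aggregate `"micro"` (pooled counts, default) or `"macro"`.
#' @return One-row tibble (micro) or per-enzyme rows plus means (macro),
#'   with an `aggregate` column labelling the convention used.
#' @export
threshold_metrics <- function(preds, threshold = 0.5,
                              aggregate = c("micro", "macro")) {
  aggregate <- match.arg(aggregate)
  preds <- check_pred_tbl(preds)
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  if (aggregate == "micro") {
    out <- confusion_f1(preds$propensity, preds$label, threshold)
    out$aggregate <- "micro"
    return(out)
  }
  if (!("enzyme" %in% names(preds)))
    abort("macro aggregation needs an 'enzyme' column")
  per <- preds |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::group_modify(~confusion_f1(.x$propensity, .x$label, threshold)) |>
    dplyr::ungroup()
  per$aggregate <- "macro"
  per
}

#' Best F1 over all thresholds
#'
#' Maximizes F1 over the set of unique propensity values plus the 0/1
#' endpoints; ties are broken toward the lower threshold.
#'
#' @param preds Tibble with `propensity`, `label`; both classes must be
#'   present.
#' @return One-row tibble with `best_f1` and `threshold`.
#' @export
best_f1 <- function(preds) {
  preds <- check_pred_tbl(preds)
  if (length(unique(preds$label)) < 2)
    abort("best_f1 requires both positive and negative labels")
  ts <- sort(unique(c(0, preds$propensity, 1)))
  f1s <- vapply(ts, function(t)
    confusion_f1(preds$propensity, preds$label, t)$f1, numeric(1))
  best <- which.max(f1s)  # which.max takes the first (lowest threshold) tie
  tibble::tibble(best_f1 = f1s[best], threshold = ts[best])
}

auc_mannwhitney <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg))  # midranks handle ties (each tie counts 0.5)
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

aupr_step <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate only at distinct-score boundaries so ties share a threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / sum(labels)
  # step-wise integration: sum precision * increment in recall
  sum(precision * diff(c(0, recall)))
}

#' Ranking metrics: AUC and AUPR
#'
#' AUC uses the Mann-Whitney pairwise formulation with midrank tie
#' correction (a tied positive/negative pair counts 0.5). AUPR uses
#' step-wise integration of the precision-recall curve at distinct-score
#' thresholds (precision times recall increment).
#'
#' @param preds Tibble with `propensity`, `label`; both classes present.
#' @return One-row tibble with `auc` and `aupr`.
#' @export
rank_metrics <- function(preds) {
  preds <- check_pred_tbl(preds)
  if (length(unique(preds$label)) < 2)
    abort("rank metrics require both positive and negative labels")
  tibble::tibble(auc = auc_mannwhitney(preds$propensity, preds$label),
                 aupr = aupr_step(preds$propensity, preds$label))
}

#' Euclidean distance to the nearest catalytic residue
#'
#' For each residue in `subset`, the minimum Calpha-Calpha distance to a
#' catalytic residue. Catalytic residues report the distance to the
#' nearest *other* catalytic residue (self excluded) so the spatial
#' cohesion of an active site is measurable; with a single catalytic
#' residue in the mask, that residue yields no row.
#'
#' @param coords `n x 3` Calpha coordinate matrix.
#' @param mask Binary catalytic mask with at least one positive.
#' @param subset Optional binary/logical/index subset of residues to
#'   report (default: all residues).
#' @return Tibble with `index`, `is_catalytic`, `distance` (Angstrom).
#' @export
distance_to_nearest_catalytic <- function(coords, mask, subset = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  mask <- as.integer(mask)
  if (length(mask) != n) abort("mask length must match coordinate rows")
  cat_idx <- which(mask == 1)
  if (length(cat_idx) == 0) abort("no catalytic residues in mask")
  idx <- if (is.null(subset)) seq_len(n)
         else if (is.logical(subset) || all(subset %in% c(0, 1)) &&
                  length(subset) == n) which(as.logical(subset))
         else as.integer(subset)
  d <- as.matrix(stats::dist(coords))
  rows <- lapply(idx, function(i) {
    targets <- setdiff(cat_idx, i)
    if (length(targets) == 0) return(NULL)
    tibble::tibble(index = i, is_catalytic = mask[i] == 1,
                   distance = min(d[i, targets]))
  })
  dplyr::bind_rows(rows)
}

#' Summarize nearest-catalytic distance distributions
#'
#' Pooled median and quartiles (linear-interpolation convention,
#' `stats::quantile` type 7) of per-residue distances, optionally grouped.
#'
#' @param distances Tibble from [distance_to_nearest_catalytic()] (or any
#'   tibble with a `distance` column), or a bare numeric vector.
#' @param by Optional column name to group by (e.g. `"is_catalytic"`).
#' @return Tibble with `n`, `q1`, `median`, `q3`.
#' @export
summarize_distances <- function(distances, by = NULL) {
  if (is.numeric(distances))
    distances <- tibble::tibble(distance = distances)
  if (nrow(distances) == 0) abort("no distances to summarize")
  summar <- function(d) tibble::tibble(
    n = length(d),
    q1 = unname(stats::quantile(d, 0.25, type = 7)),
    median = stats::median(d),
    q3 = unname(stats::quantile(d, 0.75, type = 7)))
  if (is.null(by)) return(summar(distances$distance))
  distances |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(~summar(.x$distance)) |>
    dplyr::ungroup()
}

#' Spatial-cohesion rank test
#'
#' One-sided Wilcoxon rank-sum test that catalytic residues'
#' nearest-other-catalytic distances are stochastically smaller than
#' non-catalytic residues' distances to the nearest catalytic residue.
#'
#' @param distances Tibble from [distance_to_nearest_catalytic()] with
#'   both residue kinds present.
#' @return `htest` object from [stats::wilcox.test()].
#' @export
cohesion_test <- function(distances) {
  a <- distances$distance[distances$is_catalytic]
  b <- distances$distance[!distances$is_catalytic]
  if (length(a) == 0 || length(b) == 0)
    abort("cohesion test needs both catalytic and non-catalytic distances")
  stats::wilcox.test(a, b, alternative = "less", exact = FALSE)
}

#' Distance distributions by residue kind
#'
#' Boxplot of nearest-catalytic distances for catalytic vs non-catalytic
#' residues, the spatial-cohesion picture of an active site.
#'
#' @param distances Tibble from [distance_to_nearest_catalytic()].
#' @return A ggplot object.
#' @export
plot_distance_cohesion <- function(distances) {
  ggplot2::ggplot(distances,
                  ggplot2::aes(x = ifelse(.data$is_catalytic,
                                          "catalytic", "non-catalytic"),
                               y = .data$distance)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "distance to nearest catalytic residue (Å)")
}
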