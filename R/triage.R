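# MAVE-based mutation-tolerance triage: binarize variant functional scores
# at the intersection of the first and last components of a 3-Gaussian
# mixture, then classify residues as wild type-like (WTL) or functional
# loss (FL) from distance-to-predicted-catalytic-residue and solvent
# accessibility with a depth-limited decision tree.

#' Classification cutoff from a three-Gaussian mixture
#'
#' Fits a univariate three-component Gaussian mixture (unequal variances)
#' to the variant scores and returns the point between the first and last
#' components' means where their weighted densities are equal — the
#' functional/non-functional classification cutoff.
#'
#' @param scores Numeric vector of at least 50 finite variant scores.
#' @param seed Seed for the (deterministic, hierarchically initialized)
#'   mixture fit; kept for interface stability.
#' @return Scalar cutoff, with the fitted mixture parameters attached as
#'   attribute `"mixture"` (tibble of `mean`, `sd`, `weight` ordered by
#'   mean).
#' @export
gaussian_cutoff <- function(scores, seed = 1) {
  if (length(scores) < 50)
    abort("gaussian_cutoff needs at least 50 scores")
  if (!all(is.finite(scores))) abort("scores must be finite")
  if (stats::sd(scores) < 1e-10)
    abort("degenerate score distribution (zero variance)")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  fit <- tryCatch(
    mclust::densityMclust(scores, G = 3, modelNames = "V",
                          verbose = FALSE, plot = FALSE),
    error = function(e) NULL)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  if (is.null(fit) || is.null(fit$parameters))
    abort("three-component mixture fit failed to converge")
  mu <- fit$parameters$mean
  sigma <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  w <- fit$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]; w <- w[ord]
  cut <- mixture_intersection(mu[1], sigma[1], w[1], mu[3], sigma[3], w[3])
  attr(cut, "mixture") <- tibble::tibble(mean = mu, sd = sigma, weight = w)
  cut
}

# equal-weighted-density point of two Gaussians on (m1, m2)
mixture_intersection <- function(m1, s1, w1, m2, s2, w2) {
  if (m2 <= m1) abort("component means must be ordered")
  f <- function(x) w1 * stats::dnorm(x, m1, s1) - w2 * stats::dnorm(x, m2, s2)
  lo <- m1; hi <- m2
  if (f(lo) * f(hi) > 0) {
    # scan for a sign change inside the interval
    xs <- seq(lo, hi, length.out = 512)
    fs <- f(xs)
    k <- which(fs[-1] * fs[-length(fs)] <= 0)[1]
    if (is.na(k))
      abort("no density intersection between the first and last components")
    lo <- xs[k]; hi <- xs[k + 1]
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Build a variant table
#'
#' @param data Tibble/data frame with columns `residue_number`, `wildtype`,
#'   `substitution`, `score`.
#' @param orientation `"high_active"` (higher score = more active, the
#'   usual MAVE convention) or `"low_active"`.
#' @param provenance Optional provenance tag.
#' @return Tibble of class `variant_table` with orientation metadata.
#' @export
variant_table <- function(data, orientation = c("high_active", "low_active"),
                          provenance = NULL) {
  orientation <- match.arg(orientation)
  data <- tibble::as_tibble(data)
  need <- c("residue_number", "wildtype", "substitution", "score")
  if (!all(need %in% names(data)))
    abort(paste0("variant table needs columns: ",
                 paste(need, collapse = ", ")))
  if (!all(is.finite(data$score))) abort("variant scores must be finite")
  attr(data, "orientation") <- orientation
  attr(data, "provenance") <- provenance
  class(data) <- c("variant_table", class(data))
  data
}

#' Classify variants and residues as WTL or FL
#'
#' A variant is wild type-like (WTL) when its orientation-normalized score
#' is at or above the cutoff, otherwise functional loss (FL). A residue's
#' class is the majority vote over its variants; ties go to FL
#' (conservative toward flagging functional loss).
#'
#' @param table A [variant_table()] (orientation metadata required unless
#'   `orientation` is given explicitly).
#' @param cutoff Finite classification cutoff on the score scale.
#' @param orientation Optional override of the table's orientation.
#' @return List with `variants` (per-variant tibble, added `call` column)
#'   and `residues` (per-residue tibble with `residue_number`, `n_wtl`,
#'   `n_fl`, `call`).
#' @export
classify_variants <- function(table, cutoff, orientation = NULL) {
  if (!is.finite(cutoff)) abort("cutoff must be finite")
  orientation <- orientation %||% attr(table, "orientation")
  if (is.null(orientation) ||
      !orientation %in% c("high_active", "low_active"))
    abort("unknown score orientation; declare 'high_active' or 'low_active'")
  s <- if (orientation == "high_active") table$score else -table$score
  cut <- if (orientation == "high_active") cutoff else -cutoff
  variants <- tibble::as_tibble(table)
  variants$call <- ifelse(s >= cut, "WTL", "FL")
  residues <- variants |>
    dplyr::group_by(.data$residue_number) |>
    dplyr::summarise(n_wtl = sum(.data$call == "WTL"),
                     n_fl = sum(.data$call == "FL"), .groups = "drop") |>
    dplyr::mutate(call = ifelse(.data$n_wtl > .data$n_fl, "WTL", "FL"))
  list(variants = variants, residues = residues)
}

#' Triage features: distance to predicted catalytic residues + accessibility
#'
#' Pairs each residue's Euclidean distance to the nearest predicted
#' catalytic residue (a residue that is itself predicted catalytic scores
#' 0) with its relative solvent accessibility — the two inputs of the
#' tree-structured mutation-tolerance model.
#'
#' @param record An [enzyme_record()] (or `n x 3` coordinate matrix).
#' @param predicted_catalytic Binary mask of predicted catalytic residues,
#'   at least one positive.
#' @param sasa Per-residue relative accessibility (numeric vector), or a
#'   tibble with a `rel_sasa` column; computed from the record when `NULL`.
#' @return Tibble with `residue_number` (when available), `distance`,
#'   `accessibility`.
#' @export
triage_features <- function(record, predicted_catalytic, sasa = NULL) {
  coords <- if (inherits(record, "enzyme_record")) record$ca_coords
            else as.matrix(record)
  n <- nrow(coords)
  mask <- as.integer(predicted_catalytic)
  if (length(mask) != n) abort("predicted mask length must match residues")
  if (sum(mask) == 0) abort("empty prediction mask: no predicted catalytic residues")
  if (is.null(sasa)) {
    if (!inherits(record, "enzyme_record"))
      abort("sasa must be supplied when record is a bare coordinate matrix")
    sasa <- compute_sasa(record)$rel_sasa
  } else if (is.data.frame(sasa)) {
    sasa <- sasa$rel_sasa
  }
  if (length(sasa) != n) abort("sasa length must match residues")
  d <- as.matrix(stats::dist(coords))
  cat_idx <- which(mask == 1)
  dist_pred <- vapply(seq_len(n), function(i) {
    if (mask[i] == 1) 0 else min(d[i, cat_idx])
  }, numeric(1))
  tibble::tibble(
    residue_number = if (inherits(record, "enzyme_record"))
      record$residue_numbers else as.character(seq_len(n)),
    distance = dist_pred, accessibility = sasa)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit the tree-structured mutation-tolerance model
#'
#' Depth-limited axis-aligned decision tree on the two triage features
#' (distance to nearest predicted catalytic residue, relative solvent
#' accessibility) predicting WTL vs FL, with seeded stratified k-fold
#' cross-validation. Precision is reported for the FL class (the class
#' being flagged).
#'
#' @param features Tibble with columns `distance` and `accessibility`.
#' @param residue_classes Character/factor vector of `"WTL"`/`"FL"` labels.
#' @param depth Maximum tree depth (default 3).
#' @param folds Cross-validation folds (default 5).
#' @param seed Fold-assignment seed.
#' @return Object of class `triage_fit`: `tree` (rpart), `cv` tibble
#'   (per-fold accuracy/precision), `cv_accuracy`, `cv_precision`,
#'   `train_accuracy`, `train_precision`.
#' @export
fit_triage_tree <- function(features, residue_classes, depth = 3,
                            folds = 5, seed = 1) {
  features <- tibble::as_tibble(features)
  if (!all(c("distance", "accessibility") %in% names(features)))
    abort("features need columns 'distance' and 'accessibility'")
  y <- factor(as.character(residue_classes), levels = c("FL", "WTL"))
  if (any(is.na(y))) abort("residue classes must be 'WTL' or 'FL'")
  if (length(unique(y)) < 2)
    abort("both WTL and FL classes must be present")
  dat <- data.frame(class = y, distance = features$distance,
                    accessibility = features$accessibility)
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = 5,
                               xval = 0)
  metrics <- function(fit, newdata) {
    pred <- predict(fit, newdata, type = "class")
    acc <- mean(pred == newdata$class)
    tp <- sum(pred == "FL" & newdata$class == "FL")
    fp <- sum(pred == "FL" & newdata$class != "FL")
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    c(accuracy = acc, precision = prec)
  }
  fold <- stratified_folds(y, folds, seed)
  cv <- purrr::map_dfr(seq_len(folds), function(k) {
    tr <- dat[fold != k, , drop = FALSE]
    te <- dat[fold == k, , drop = FALSE]
    fit_k <- rpart::rpart(class ~ distance + accessibility, data = tr,
                          method = "class", control = ctrl)
    m <- metrics(fit_k, te)
    tibble::tibble(fold = k, accuracy = m["accuracy"],
                   precision = m["precision"])
  })
  tree <- rpart::rpart(class ~ distance + accessibility, data = dat,
                       method = "class", control = ctrl)
  m_full <- metrics(tree, dat)
  structure(list(tree = tree, cv = cv,
                 cv_accuracy = mean(cv$accuracy),
                 cv_precision = mean(cv$precision),
                 train_accuracy = unname(m_full["accuracy"]),
                 train_precision = unname(m_full["precision"]),
                 depth = depth, folds = folds, seed = seed),
            class = "triage_fit")
}

#' @export
print.triage_fit <- function(x, ...) {
  cat("<triage_fit> depth<=", x$depth, ", ", x$folds,
      "-fold CV accuracy ", signif(x$cv_accuracy, 3),
      " (precision ", signif(x$cv_precision, 3), "); full-set accuracy ",
      signif(x$train_accuracy, 3), "\n", sep = "")
  invisible(x)
}
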