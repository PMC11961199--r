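# independent pairwise AUC oracle: ties count one half
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# independent step-integration AUPR oracle over distinct thresholds
aupr_oracle <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in ts) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    r <- tp / sum(labels)
    p <- tp / (tp + fp)
    area <- area + p * (r - prev_r)
    prev_r <- r
  }
  area
}

rand_preds <- function(n, seed, ties = FALSE) {
  set.seed(seed)
  s <- if (ties) sample(seq(0, 1, 0.1), n, replace = TRUE) else runif(n)
  tibble::tibble(propensity = s,
                 label = rbinom(n, 1, 0.3))
}

test_that("threshold metrics match hand-tallied confusion counts", {
  # perfect predictor
  p <- tibble::tibble(propensity = c(1, 1, 0, 0), label = c(1, 1, 0, 0))
  m <- threshold_metrics(p, 0.5)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  # all-negative predictions: recall 0, precision flagged 0
  p2 <- tibble::tibble(propensity = rep(0, 4), label = c(1, 0, 1, 0))
  m2 <- threshold_metrics(p2, 0.5)
  expect_equal(m2$recall, 0)
  expect_equal(m2$precision, 0)
  expect_false(m2$precision_defined)
  # 20-residue fixture tallied by hand
  s <- c(.9, .8, .8, .7, .6, .55, .5, .45, .4, .35,
         .3, .3, .25, .2, .15, .1, .1, .05, .02, .01)
  y <- c(1, 1, 0, 1, 0, 1, 1, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0)
  m3 <- threshold_metrics(tibble::tibble(propensity = s, label = y), 0.5)
  # scores >= 0.5: positions 1..7 -> labels 1,1,0,1,0,1,1 -> TP=5, FP=2
  expect_equal(m3$tp, 5); expect_equal(m3$fp, 2)
  expect_equal(m3$fn, sum(y) - 5); expect_equal(m3$tn, 13 - 2)
  expect_equal(m3$precision, 5 / 7)
  expect_equal(m3$recall, 5 / 7)
})

test_that("macro aggregation reports per-enzyme rows labelled macro", {
  p <- dplyr::bind_rows(
    tibble::tibble(enzyme = "a", propensity = c(1, 0), label = c(1, 0)),
    tibble::tibble(enzyme = "b", propensity = c(1, 0), label = c(0, 1)))
  m <- threshold_metrics(p, 0.5, aggregate = "macro")
  expect_equal(nrow(m), 2)
  expect_true(all(m$aggregate == "macro"))
  expect_equal(sort(m$f1), c(0, 1))
})

test_that("best F1 dominates fixed thresholds and matches a dense grid", {
  p <- tibble::tibble(propensity = c(.9, .8, .3, .2), label = c(1, 1, 0, 0))
  bf <- best_f1(p)
  expect_equal(bf$best_f1, 1)
  set.seed(51)
  p2 <- rand_preds(50, 52, ties = TRUE)
  bf2 <- best_f1(p2)
  for (t in seq(0, 1, 0.05))
    expect_gte(bf2$best_f1, threshold_metrics(p2, t)$f1)
  grid <- max(vapply(seq(0, 1, 0.001), function(t)
    threshold_metrics(p2, t)$f1, numeric(1)))
  expect_equal(bf2$best_f1, grid, tolerance = 1e-12)
  expect_error(best_f1(tibble::tibble(propensity = .5, label = 1)),
               "both")
})

test_that("AUC and AUPR match brute-force oracles including ties", {
  perfect <- tibble::tibble(propensity = c(.9, .8, .2, .1),
                            label = c(1, 1, 0, 0))
  expect_equal(rank_metrics(perfect)$auc, 1)
  expect_equal(rank_metrics(perfect)$aupr, 1)
  allsame <- tibble::tibble(propensity = rep(.5, 10),
                            label = rep(c(0, 1), 5))
  expect_equal(rank_metrics(allsame)$auc, 0.5)
  for (seed in c(53, 54, 55)) {
    p <- rand_preds(30, seed, ties = TRUE)
    rm_ <- rank_metrics(p)
    expect_equal(rm_$auc, auc_pairwise_oracle(p$propensity, p$label),
                 tolerance = 1e-12)
    expect_equal(rm_$aupr, aupr_oracle(p$propensity, p$label),
                 tolerance = 1e-12)
  }
})

test_that("pairwise AUC agrees with trapezoidal ROC integration", {
  roc_trapezoid <- function(scores, labels) {
    ts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
    fpr <- vapply(ts, function(t) mean(scores[labels == 0] >= t),
                  numeric(1))
    tpr <- vapply(ts, function(t) mean(scores[labels == 1] >= t),
                  numeric(1))
    sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  }
  set.seed(56)
  for (k in 1:200) {
    n <- sample(10:40, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_pairwise_oracle(s, y), roc_trapezoid(s, y),
                 tolerance = 1e-9)
    p <- tibble::tibble(propensity = s, label = y)
    expect_equal(rank_metrics(p)$auc, roc_trapezoid(s, y),
                 tolerance = 1e-9)
  }
})

test_that("nearest-catalytic distances follow the self-exclusion rule", {
  ca <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0))
  # single catalytic residue: no other catalytic residue to report
  d1 <- distance_to_nearest_catalytic(ca, c(1, 0, 0), subset = 1)
  expect_equal(nrow(d1), 0)
  # catalytic at both ends, query the middle
  d2 <- distance_to_nearest_catalytic(ca, c(1, 0, 1))
  expect_equal(d2$distance[d2$index == 2], 6)
  expect_equal(d2$distance[d2$index == 1], 12)  # other catalytic
  expect_error(distance_to_nearest_catalytic(ca, c(0, 0, 0)), "no catalytic")
})

test_that("distances match the nested-loop oracle on a synthetic enzyme", {
  set.seed(57)
  xyz <- generate_backbone(100)
  mask <- integer(100); mask[sample(100, 6)] <- 1L
  got <- distance_to_nearest_catalytic(xyz, mask)
  for (row in sample(nrow(got), 20)) {
    i <- got$index[row]
    best <- Inf
    for (j in which(mask == 1)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij < best) best <- dij
    }
    expect_equal(got$distance[row], best, tolerance = 1e-9)
  }
})

test_that("distance summaries use the linear-interpolation convention", {
  expect_equal(summarize_distances(rep(4, 7)),
               tibble::tibble(n = 7, q1 = 4, median = 4, q3 = 4))
  s <- summarize_distances(c(2, 4, 6, 8, 10))
  expect_equal(s$median, 6)
  expect_equal(s$q1, 4)   # type-7 quantile
  expect_equal(s$q3, 8)
})

test_that("planted catalytic sites are spatially cohesive", {
  b <- small_dataset()
  dists <- dplyr::bind_rows(lapply(b, function(x)
    distance_to_nearest_catalytic(x$record$ca_coords,
                                  x$record$catalytic_mask)))
  s <- summarize_distances(dists, by = "is_catalytic")
  med_cat <- s$median[s$is_catalytic]
  med_non <- s$median[!s$is_catalytic]
  expect_lt(med_cat, med_non)
  ht <- cohesion_test(dists)
  expect_lt(ht$p.value, 0.01)
  expect_s3_class(plot_distance_cohesion(dists), "ggplot")
})
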