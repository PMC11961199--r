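test_that("triplet margin loss matches its closed forms and oracle", {
  z <- rnorm(8)
  zn <- z + rnorm(8)
  zn <- z + (zn - z) / sqrt(sum((zn - z)^2))  # ||z - zn|| = 1
  expect_equal(triplet_margin_loss(z, z, zn, alpha = 1), 0)
  # identical positive and negative: distances cancel, loss = margin = 1
  zp <- rnorm(8)
  expect_equal(triplet_margin_loss(z, zp, zp), 1)
  set.seed(41)
  for (k in 1:10) {
    a <- rnorm(10); p <- rnorm(10); n <- rnorm(10)
    oracle <- max(0, sqrt(sum((a - p)^2)) - sqrt(sum((a - n)^2)) + 1)
    expect_equal(triplet_margin_loss(a, p, n), oracle)
    expect_gte(triplet_margin_loss(a, p, n), 0)
  }
  expect_error(triplet_margin_loss(rnorm(3), rnorm(4), rnorm(3)),
               "dimensions")
})

test_that("triplet loss is zero whenever the negative is margin-far", {
  set.seed(42)
  for (k in 1:20) {
    a <- rnorm(6); p <- rnorm(6); n <- rnorm(6)
    dp <- sqrt(sum((a - p)^2)); dn <- sqrt(sum((a - n)^2))
    if (dn >= dp + 1) expect_equal(triplet_margin_loss(a, p, n), 0)
  }
  # unhinged variant can go negative
  a <- c(0, 0); p <- c(0, 0); n <- c(10, 0)
  expect_equal(triplet_margin_loss(a, p, n, hinge = FALSE), -9)
})

test_that("cluster centers are group means", {
  v <- rnorm(5)
  c1 <- update_cluster_centers(rbind(v), classes = 2)
  expect_equal(unname(c1[1, ]), v)
  c2 <- update_cluster_centers(rbind(v, -v), classes = c(1, 1))
  expect_equal(unname(c2[1, ]), rep(0, 5))
  set.seed(43)
  emb <- matrix(rnorm(15 * 6), 15, 6)
  cls <- rep(1:3, each = 5)
  centers <- update_cluster_centers(emb, cls)
  for (k in 1:3) {
    oracle <- colMeans(emb[cls == k, ])
    expect_equal(unname(centers[as.character(k), ]), oracle)
  }
  expect_error(update_cluster_centers(matrix(0, 0, 3), integer(0)),
               "no enzymes")
})

test_that("triplet sampling is forced with 2 classes, seeded, and uniform", {
  centers <- update_cluster_centers(matrix(rnorm(12), 3, 4), 1:3)
  set.seed(44)
  s <- sample_triplet(1, centers)
  expect_equal(s$zp, centers["1", ])
  expect_true(s$negative_class %in% c("2", "3"))
  two <- centers[1:2, ]
  expect_equal(sample_triplet(1, two)$negative_class, "2")
  # seeded reproducibility
  set.seed(7); seq1 <- replicate(20, sample_triplet(2, centers)$negative_class)
  set.seed(7); seq2 <- replicate(20, sample_triplet(2, centers)$negative_class)
  expect_identical(seq1, seq2)
  expect_error(sample_triplet(1, centers[1, , drop = FALSE]), "2 enzyme")
})

test_that("negative sampling over 3 classes is empirically uniform", {
  centers <- update_cluster_centers(matrix(rnorm(16), 4, 4), 1:4)
  set.seed(45)
  draws <- replicate(10000, sample_triplet(1, centers)$negative_class)
  counts <- table(factor(draws, levels = c("2", "3", "4")))
  # 3 sigma of Binomial(10000, 1/3)
  expect_true(all(abs(counts - 10000 / 3) <
                    3 * sqrt(10000 * (1 / 3) * (2 / 3))))
})

test_that("the mixing schedule hits its endpoints and decreases", {
  expect_equal(lambda_schedule(0, 30), 1)
  expect_equal(lambda_schedule(9, 30), 0)   # boundary at ceil(0.3*30)
  expect_equal(lambda_schedule(20, 30), 0)
  lams <- vapply(0:29, lambda_schedule, numeric(1), n_epochs = 30)
  expect_true(all(diff(lams) <= 0))
  expect_equal(lambda_schedule(0, 10, frac = 0), 0)
})

test_that("training learns the planted signal on a tiny set", {
  graphs <- small_graphs()
  model <- catsite_model(gcn_dims = c(16, 16, 16), branch_dim = 32,
                         fusion_dim = 32, seed = 2)
  cfg <- catsite_train_config(epochs = 20, seed = 2)
  fit <- train_catsite(graphs, cfg, model)
  h <- fit$history
  expect_equal(nrow(h), 20)
  expect_equal(h$lambda[1], 1)
  expect_equal(h$lambda[20], 0)
  boundary <- which(h$lambda == 0)[1]
  # supervised loss at the end is below the loss at the phase boundary
  expect_lt(h$supervised_loss[20], h$supervised_loss[boundary])
  expect_true(all(is.finite(h$supervised_loss)))
})

test_that("contrastive phase separates class representations", {
  graphs <- small_graphs()
  model <- catsite_model(gcn_dims = c(8, 8, 8), branch_dim = 16,
                         fusion_dim = 16, seed = 3)
  # pure contrastive training
  cfg <- catsite_train_config(epochs = 6, contrastive_frac = 1, seed = 3)
  fit <- train_catsite(graphs, cfg, model)
  zs <- enzyme_representations(fit, graphs)
  cls <- attr(zs, "class_labels")
  d <- as.matrix(dist(zs))
  same <- d[outer(cls, cls, "==") & upper.tri(d)]
  diff_ <- d[outer(cls, cls, "!=") & upper.tri(d)]
  expect_lt(mean(same), mean(diff_))
})

test_that("training is bit-reproducible under a fixed seed", {
  graphs <- small_graphs()[1:4]
  run <- function() {
    model <- catsite_model(gcn_dims = c(4, 4, 4), branch_dim = 8,
                           fusion_dim = 8, seed = 5)
    train_catsite(graphs, catsite_train_config(epochs = 3, seed = 5),
                  model)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
})

test_that("single-class data is rejected in the contrastive phase", {
  graphs <- small_graphs()
  graphs <- lapply(graphs, function(g) { g$ec_class <- 1L; g })
  model <- catsite_model(gcn_dims = c(4, 4, 4), branch_dim = 4,
                         fusion_dim = 4, seed = 1)
  expect_error(
    train_catsite(graphs, catsite_train_config(epochs = 2, seed = 1),
                  model),
    "contrastive")
  # and accepted once the contrastive phase is disabled
  fit <- train_catsite(graphs,
                       catsite_train_config(epochs = 2, seed = 1,
                                            contrastive_frac = 0), model)
  expect_s3_class(fit, "catsite_fit")
})

test_that("fit tidiers expose history and summary", {
  graphs <- small_graphs()[1:3]
  model <- catsite_model(gcn_dims = c(4, 4, 4), branch_dim = 4,
                         fusion_dim = 4, seed = 6)
  fit <- train_catsite(graphs, catsite_train_config(epochs = 2, seed = 6),
                       model)
  td <- tidy(fit)
  expect_true(all(c("epoch", "lambda", "contrastive_loss",
                    "supervised_loss") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$epochs, 2)
  expect_gt(gl$n_parameters, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})
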