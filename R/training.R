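#' Triplet margin loss
#'
#' Hinged contrastive loss over pooled enzyme representations:
#' \eqn{L = \max(0, \lVert z_a - z_p\rVert_2 - \lVert z_a - z_n\rVert_2
#' + \alpha)}. The unhinged variant (no clamp at zero) is available behind
#' `hinge = FALSE`.
#'
#' @param za,zp,zn Anchor, positive and negative vectors of equal length.
#' @param alpha Margin, `>= 0` (default 1).
#' @param hinge Clamp at zero (default `TRUE`).
#' @return Scalar loss (non-negative when hinged).
#' @export
triplet_margin_loss <- function(za, zp, zn, alpha = 1, hinge = TRUE) {
  if (length(za) != length(zp) || length(za) != length(zn))
    abort("triplet_margin_loss: vectors must have equal dimensions")
  if (alpha < 0) abort("margin alpha must be non-negative")
  val <- sqrt(sum((za - zp)^2)) - sqrt(sum((za - zn)^2)) + alpha
  if (hinge) max(0, val) else val
}

#' Per-class cluster centers of enzyme representations
#'
#' Arithmetic mean of the pooled representations of each enzyme class,
#' recomputed every epoch during the contrastive phase.
#'
#' @param embeddings Numeric matrix, one row per enzyme.
#' @param classes Integer/character class label per row.
#' @return Matrix with one row per class (rownames are the class labels).
#' @export
update_cluster_centers <- function(embeddings, classes) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) == 0) abort("no enzymes to compute centers from")
  if (length(classes) != nrow(embeddings))
    abort("classes length must match embedding rows")
  cl <- sort(unique(classes))
  centers <- t(vapply(cl, function(k) {
    colMeans(embeddings[classes == k, , drop = FALSE])
  }, numeric(ncol(embeddings))))
  rownames(centers) <- as.character(cl)
  centers
}

#' Sample a contrastive triplet's positive and negative
#'
#' The positive is the anchor class's cluster center; the negative is
#' drawn uniformly among the remaining class centers using the current
#' RNG state (seed upstream for reproducibility).
#'
#' @param anchor_class Class label of the anchor enzyme.
#' @param centers Center matrix from [update_cluster_centers()].
#' @return List with `zp`, `zn`, `negative_class`.
#' @export
sample_triplet <- function(anchor_class, centers) {
  cls <- rownames(centers)
  if (length(cls) < 2)
    abort(paste0("contrastive sampling needs >= 2 enzyme classes; ",
                 "disable the contrastive phase (contrastive_frac = 0) ",
                 "for single-class data"))
  key <- as.character(anchor_class)
  if (!(key %in% cls)) abort(paste0("unknown anchor class: ", key))
  others <- setdiff(cls, key)
  neg <- if (length(others) == 1) others else sample(others, 1)
  list(zp = centers[key, ], zn = centers[neg, ], negative_class = neg)
}

#' Contrastive-to-supervised mixing schedule
#'
#' The mixing weight `lambda` decays linearly from 1 at epoch 0 to 0 at
#' the phase boundary `ceiling(frac * n_epochs)` and stays 0 afterwards;
#' the per-epoch loss is `lambda * L_contrastive + (1 - lambda) * L_sup`.
#'
#' @param epoch Zero-based epoch index.
#' @param n_epochs Total epochs.
#' @param frac Fraction of epochs forming the contrastive phase.
#' @return `lambda` in `[0, 1]`.
#' @export
lambda_schedule <- function(epoch, n_epochs, frac = 0.3) {
  boundary <- ceiling(frac * n_epochs)
  if (boundary <= 0) return(0)
  max(0, 1 - epoch / boundary)
}

#' Training configuration
#'
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param seed RNG seed covering initialization order, shuffling and
#'   negative sampling.
#' @param contrastive_frac Fraction of epochs in the contrastive phase.
#' @param alpha Triplet margin.
#' @param hinge Hinged triplet loss.
#' @param pos_weight Positive-class weight of the supervised
#'   cross-entropy; `NULL` uses the inverse catalytic prevalence of the
#'   training set.
#' @param verbose Print per-epoch losses.
#' @return List of class `catsite_train_config`.
#' @export
catsite_train_config <- function(epochs = 30, lr = 1e-3, beta1 = 0.9,
                                 beta2 = 0.999, eps = 1e-8, seed = 1,
                                 contrastive_frac = 0.3, alpha = 1,
                                 hinge = TRUE, pos_weight = NULL,
                                 verbose = FALSE) {
  structure(list(epochs = epochs, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = seed,
                 contrastive_frac = contrastive_frac, alpha = alpha,
                 hinge = hinge, pos_weight = pos_weight, verbose = verbose),
            class = "catsite_train_config")
}

# weighted softmax cross-entropy over the n x 2 logits; returns loss and
# gradient w.r.t. logits
supervised_loss <- function(logits, labels, pos_weight) {
  prob <- softmax2(logits)
  w <- ifelse(labels == 1, pos_weight, 1)
  eps <- 1e-12
  p_true <- ifelse(labels == 1, prob[, 2], prob[, 1])
  loss <- sum(w * -log(pmax(p_true, eps))) / sum(w)
  y1 <- cbind(1 - labels, labels)
  dlogits <- (prob - y1) * (w / sum(w))
  list(loss = loss, dlogits = dlogits)
}

# gradient of the hinged triplet loss w.r.t. the pooled vector z
triplet_grad_z <- function(z, zp, zn, alpha, hinge) {
  dp <- sqrt(sum((z - zp)^2)); dn <- sqrt(sum((z - zn)^2))
  val <- dp - dn + alpha
  if (hinge && val <= 0) return(list(loss = 0, dz = NULL))
  dz <- (z - zp) / max(dp, 1e-12) - (z - zn) / max(dn, 1e-12)
  list(loss = if (hinge) max(0, val) else val, dz = dz)
}

# full analytic backward pass for one enzyme; dxe is the upstream gradient
# on X_E (already mixing supervised head and contrastive pooling terms),
# dlogits the gradient on the logits (NULL during a pure contrastive step)
catsite_backward <- function(model, graph, cache, dlogits, dxe_extra) {
  p <- model$params
  grads <- list()
  dxe <- matrix(0, nrow(cache$Zf), ncol(cache$Zf))
  if (!is.null(dlogits)) {
    grads$Wh <- crossprod(relu(cache$Zf), dlogits)   # t(X_E) %*% dlogits
    grads$bh <- matrix(colSums(dlogits), 1)
    dxe <- dxe + dlogits %*% t(p$Wh)
  } else {
    grads$Wh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
    grads$bh <- matrix(0, 1, ncol(p$bh))
  }
  if (!is.null(dxe_extra)) dxe <- dxe + dxe_extra
  dzf <- dxe * (cache$Zf > 0)
  grads$Wf <- crossprod(cache$Cc, dzf)
  grads$bf <- matrix(colSums(dzf), 1)
  dcc <- dzf %*% t(p$Wf)
  nb <- ncol(cache$Bg)
  dbg <- dcc[, seq_len(nb), drop = FALSE]
  dbe <- dcc[, nb + seq_len(ncol(cache$Be)), drop = FALSE]
  dzg <- dbg * (cache$Zg > 0)
  grads$Wg <- crossprod(cache$Hc, dzg)
  grads$bg <- matrix(colSums(dzg), 1)
  dhc <- dzg %*% t(p$Wg)
  dze <- dbe * (cache$Ze > 0)
  grads$We <- crossprod(graph$x_g, dze)
  grads$be <- matrix(colSums(dze), 1)
  d1 <- ncol(cache$H1); d2 <- ncol(cache$H2); d3 <- ncol(cache$H3)
  dh1 <- dhc[, seq_len(d1), drop = FALSE]
  dh2 <- dhc[, d1 + seq_len(d2), drop = FALSE]
  dh3 <- dhc[, d1 + d2 + seq_len(d3), drop = FALSE]
  s <- cache$S
  # layer 3
  dz3 <- dh3 * (cache$Z3 > 0)
  grads$W3 <- crossprod(s %*% cache$H2, dz3)
  dh2 <- dh2 + s %*% (dz3 %*% t(p$W3))
  # layer 2
  dz2 <- dh2 * (cache$Z2 > 0)
  grads$W2 <- crossprod(s %*% cache$H1, dz2)
  dh1 <- dh1 + s %*% (dz2 %*% t(p$W2))
  # layer 1
  dz1 <- dh1 * (cache$Z1 > 0)
  grads$W1 <- crossprod(s %*% cache$H0, dz1)
  grads
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      cfg$lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$eps)
  }
  list(params = params, state = state)
}

#' Train the catalytic-residue model
#'
#' Contrastive pre-training with the enzyme-class triplet margin loss
#' blends into class-weighted supervised training under the linear
#' [lambda_schedule()]: per epoch the optimized loss is
#' `lambda * L_triplet + (1 - lambda) * L_supervised`. Class cluster
#' centers are recomputed at the start of every contrastive-phase epoch
#' from the current model. Optimization is per-enzyme Adam.
#'
#' @param dataset Non-empty list of `residue_graph` objects.
#' @param config A [catsite_train_config()].
#' @param model Optional pre-built [catsite_model()]; by default one is
#'   initialized from the config seed with package-default dimensions.
#' @return Object of class `catsite_fit`: the trained `model`, a per-epoch
#'   `history` tibble (both loss components), final `centers`, `config`.
#' @export
train_catsite <- function(dataset, config = catsite_train_config(),
                          model = NULL) {
  if (length(dataset) == 0) abort("dataset must be non-empty")
  set.seed(config$seed)
  if (is.null(model)) model <- catsite_model(seed = config$seed)
  # per-channel standardization of the atomic block from the training set
  xa_all <- do.call(rbind, lapply(dataset, `[[`, "x_a"))
  ctr <- colMeans(xa_all)
  scl <- apply(xa_all, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  model$config$xa_center <- ctr
  model$config$xa_scale <- scl

  labels_all <- unlist(lapply(dataset, `[[`, "labels"))
  prevalence <- mean(labels_all)
  pos_weight <- config$pos_weight %||%
    (if (prevalence > 0) (1 - prevalence) / prevalence else 1)

  classes <- vapply(dataset, function(g) as.integer(g$ec_class), integer(1))
  state <- list(t = 0,
                m = lapply(model$params, function(p) p * 0),
                v = lapply(model$params, function(p) p * 0))
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lam <- lambda_schedule(epoch - 1, config$epochs, config$contrastive_frac)
    centers <- NULL
    if (lam > 0) {
      if (length(unique(classes[!is.na(classes)])) < 2)
        abort(paste0("contrastive phase requires >= 2 enzyme classes; ",
                     "set contrastive_frac = 0 for single-class data"))
      zs <- t(vapply(dataset, function(g) {
        pool_sequence(catsite_forward(model, g)$xe)
      }, numeric(model$config$fusion_dim)))
      centers <- update_cluster_centers(zs, classes)
    }
    con_losses <- numeric(0)
    sup_losses <- numeric(0)
    for (i in sample(length(dataset))) {
      g <- dataset[[i]]
      fw <- catsite_forward(model, g, cache = TRUE)
      sup <- supervised_loss(fw$logits, g$labels, pos_weight)
      sup_losses <- c(sup_losses, sup$loss)
      dlogits <- if (lam < 1) (1 - lam) * sup$dlogits else NULL
      dxe_extra <- NULL
      if (lam > 0) {
        z <- pool_sequence(fw$xe)
        trip <- sample_triplet(classes[i], centers)
        tg <- triplet_grad_z(z, trip$zp, trip$zn, config$alpha, config$hinge)
        con_losses <- c(con_losses, tg$loss)
        if (!is.null(tg$dz)) {
          n <- nrow(fw$xe)
          dxe_extra <- lam *
            matrix(tg$dz, n, length(tg$dz), byrow = TRUE) / n
        }
      }
      grads <- catsite_backward(model, g, fw$cache, dlogits, dxe_extra)
      if (any(!vapply(grads, function(x) all(is.finite(x)), logical(1))) ||
          !is.finite(sup$loss))
        abort(paste0("training diverged (non-finite loss/gradient) at ",
                     "epoch ", epoch, ", enzyme ", g$id))
      upd <- adam_step(model$params, grads, state, config)
      model$params <- upd$params
      state <- upd$state
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lambda = lam,
      contrastive_loss = if (length(con_losses)) mean(con_losses) else NA_real_,
      supervised_loss = mean(sup_losses))
    if (config$verbose)
      message(sprintf("epoch %d  lambda %.2f  L_con %.4f  L_sup %.4f",
                      epoch, lam,
                      if (length(con_losses)) mean(con_losses) else NA,
                      mean(sup_losses)))
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 centers = centers, config = config,
                 pos_weight = pos_weight, prevalence = prevalence),
            class = "catsite_fit")
}

#' @export
print.catsite_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("<catsite_fit> ", nrow(x$history), " epochs; final supervised loss ",
      signif(h$supervised_loss, 4), "; positive-class weight ",
      signif(x$pos_weight, 4), "\n", sep = "")
  invisible(x)
}

#' Pooled class representations of a dataset under a model
#'
#' Forward-passes every enzyme and mean-pools `X_E`, giving the per-enzyme
#' representation vectors used by the contrastive objective and by
#' class-separation diagnostics.
#'
#' @param model A `catsite_model` or `catsite_fit`.
#' @param dataset List of `residue_graph` objects.
#' @return Matrix, one row per enzyme, with `class` attribute vector.
#' @export
enzyme_representations <- function(model, dataset) {
  if (inherits(model, "catsite_fit")) model <- model$model
  zs <- t(vapply(dataset, function(g) {
    pool_sequence(catsite_forward(model, g)$xe)
  }, numeric(model$config$fusion_dim)))
  attr(zs, "class_labels") <-
    vapply(dataset, function(g) as.integer(g$ec_class), integer(1))
  zs
}
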