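#' Construct the catalytic-residue prediction model
#'
#' A three-layer graph convolutional network over the contact graph,
#' fused with the language-model embedding branch by a multilayer
#' perceptron, ending in a two-channel residue head:
#' \deqn{H^{(i)} = \mathrm{ReLU}(\tilde D^{-1/2}(A+I_n)\tilde D^{-1/2}
#'   H^{(i-1)} W^{(i)}),\quad H^{(0)} = [X_L, X_A]}
#' The three layer outputs are concatenated, passed through a
#' fully-connected graph branch, joined with the embedding branch
#' \eqn{\mathrm{ReLU}(X_G W_e + b_e)}, fused to the representation
#' \eqn{X_E \in R^{n \times d}}, and reduced to logits
#' \eqn{Y \in R^{n \times 2}}; a 2-way softmax turns channel 2 into the
#' catalytic propensity.
#'
#' @param theta Width of the graph-convolution input block `[X_L, X_A]`
#'   (50 evolutionary + 14 atomic = 64).
#' @param gcn_dims Integer vector of the three graph-layer widths.
#' @param branch_dim Width of the graph and embedding branches.
#' @param fusion_dim Width `d` of the fused representation `X_E`.
#' @param embed_dim Embedding block width `h1` (1024).
#' @param seed Initialization seed.
#' @param init `"glorot"` (uniform fan-based) or `"zero"`.
#' @return An object of class `catsite_model`.
#' @export
catsite_model <- function(theta = 64, gcn_dims = c(256, 256, 256),
                          branch_dim = 512, fusion_dim = 512,
                          embed_dim = 1024, seed = 1,
                          init = c("glorot", "zero")) {
  init <- match.arg(init)
  stopifnot(length(gcn_dims) == 3, all(gcn_dims >= 1))
  dims <- list(
    W1 = c(theta, gcn_dims[1]), W2 = c(gcn_dims[1], gcn_dims[2]),
    W3 = c(gcn_dims[2], gcn_dims[3]),
    Wg = c(sum(gcn_dims), branch_dim), bg = c(1, branch_dim),
    We = c(embed_dim, branch_dim), be = c(1, branch_dim),
    Wf = c(2 * branch_dim, fusion_dim), bf = c(1, fusion_dim),
    Wh = c(fusion_dim, 2), bh = c(1, 2))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  params <- lapply(dims, function(d) {
    if (init == "zero" || d[1] == 1) {
      matrix(0, d[1], d[2])
    } else {
      lim <- sqrt(6 / (d[1] + d[2]))
      matrix(runif(prod(d), -lim, lim), d[1], d[2])
    }
  })
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  structure(
    list(params = params,
         config = list(theta = theta, gcn_dims = gcn_dims,
                       branch_dim = branch_dim, fusion_dim = fusion_dim,
                       embed_dim = embed_dim, seed = seed, init = init,
                       xa_center = rep(0, 14), xa_scale = rep(1, 14))),
    class = "catsite_model")
}

#' @export
print.catsite_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<catsite_model> GCN ", paste(x$config$gcn_dims, collapse = "/"),
      ", branches ", x$config$branch_dim, ", fusion ", x$config$fusion_dim,
      ", ", format(np, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Returns \eqn{S = \tilde D^{-1/2}(A + I_n)\tilde D^{-1/2}} with
#' \eqn{\tilde D_{ii} = \sum_j (A + I_n)_{ij}}, the propagation operator
#' of each graph-convolution layer.
#'
#' @param a Symmetric binary `n x n` adjacency with zero diagonal.
#' @return Symmetric `n x n` matrix.
#' @export
normalized_adjacency <- function(a) {
  a <- as.matrix(a)
  if (!isTRUE(all.equal(a, t(a), check.attributes = FALSE)))
    abort("adjacency must be symmetric")
  at <- a + diag(nrow(a))
  dm <- 1 / sqrt(rowSums(at))
  at * tcrossprod(dm)
}

# standardize the atomic block with the model's stored training statistics
scale_xa <- function(model, x_a) {
  sweep(sweep(x_a, 2, model$config$xa_center, "-"), 2,
        model$config$xa_scale, "/")
}

relu <- function(x) (x > 0) * x

#' Graph-convolution forward pass
#'
#' Propagates `H0 = [x_l, x_a]` (atomic block standardized by the model's
#' stored training statistics) through the three graph layers
#' `H_i = ReLU(S H_{i-1} W_i)` and returns all three layer outputs for
#' concatenation.
#'
#' @param model A [catsite_model()].
#' @param graph A `residue_graph`.
#' @return List with elements `H1`, `H2`, `H3` (and pre-activations
#'   `Z1..Z3`, `S`, `H0` for internal use).
#' @export
gcn_forward <- function(model, graph) {
  h0 <- cbind(graph$x_l, scale_xa(model, graph$x_a))
  if (ncol(h0) != nrow(model$params$W1))
    abort(paste0("feature width ", ncol(h0),
                 " does not match W1 input width ", nrow(model$params$W1)))
  s <- normalized_adjacency(graph$adjacency)
  z1 <- s %*% (h0 %*% model$params$W1); h1 <- relu(z1)
  z2 <- s %*% (h1 %*% model$params$W2); h2 <- relu(z2)
  z3 <- s %*% (h2 %*% model$params$W3); h3 <- relu(z3)
  list(H1 = h1, H2 = h2, H3 = h3, Z1 = z1, Z2 = z2, Z3 = z3,
       S = s, H0 = h0)
}

softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  cbind(e1, e2) / (e1 + e2)
}

#' Fuse graph layers with the embedding branch and score residues
#'
#' Concatenates `[H1, H2, H3]`, applies the graph-branch layer, joins the
#' ReLU embedding branch of `x_g`, fuses to `X_E` (`n x d`) and reduces to
#' two logits per residue; a softmax over the two channels yields the
#' catalytic propensity.
#'
#' @param model A [catsite_model()].
#' @param h1,h2,h3 Graph-layer outputs from [gcn_forward()].
#' @param x_g `n x 1024` embedding block.
#' @return List with `logits` (`n x 2`), `propensity` (length `n`, channel
#'   2 softmax), `xe` (`n x d`) and cached pre-activations.
#' @export
fuse_and_score <- function(model, h1, h2, h3, x_g) {
  n <- nrow(h1)
  if (nrow(h2) != n || nrow(h3) != n || nrow(x_g) != n)
    abort("row counts of H1, H2, H3 and x_g must agree")
  p <- model$params
  hc <- cbind(h1, h2, h3)
  zg <- sweep(hc %*% p$Wg, 2, p$bg, "+"); bg <- relu(zg)
  ze <- sweep(x_g %*% p$We, 2, p$be, "+"); be <- relu(ze)
  cc <- cbind(bg, be)
  zf <- sweep(cc %*% p$Wf, 2, p$bf, "+"); xe <- relu(zf)
  logits <- sweep(xe %*% p$Wh, 2, p$bh, "+")
  prob <- softmax2(logits)
  list(logits = logits, propensity = prob[, 2], xe = xe,
       Hc = hc, Zg = zg, Bg = bg, Ze = ze, Be = be, Cc = cc, Zf = zf,
       prob = prob)
}

#' Mean-pool a residue representation into a sequence vector
#'
#' Column-wise mean of `X_E`, the fixed-size enzyme representation used as
#' the anchor/positive/negative vectors of the contrastive objective.
#'
#' @param xe `n x d` matrix, `n >= 1`.
#' @return Numeric vector of length `d`.
#' @export
pool_sequence <- function(xe) {
  xe <- as.matrix(xe)
  if (nrow(xe) == 0) abort("pool_sequence: empty representation (n = 0)")
  colMeans(xe)
}

# Full forward pass; cache = TRUE retains intermediates for backprop.
catsite_forward <- function(model, graph, cache = FALSE) {
  g <- gcn_forward(model, graph)
  f <- fuse_and_score(model, g$H1, g$H2, g$H3, graph$x_g)
  out <- list(propensity = f$propensity, logits = f$logits, xe = f$xe)
  if (cache) out$cache <- c(g, f)
  out
}

#' Predict catalytic propensities for residue graphs
#'
#' @param object A `catsite_model` or `catsite_fit`.
#' @param graphs A `residue_graph` or list of them.
#' @param threshold Propensity threshold for the hard call.
#' @param ... Unused.
#' @return Tibble with columns `enzyme`, `residue_number`, `propensity`,
#'   `predicted`, `label`.
#' @export
predict.catsite_model <- function(object, graphs, threshold = 0.5, ...) {
  if (inherits(graphs, "residue_graph")) graphs <- list(graphs)
  purrr::map_dfr(graphs, function(g) {
    fw <- catsite_forward(object, g)
    tibble::tibble(
      enzyme = g$id,
      residue_number = g$residue_numbers %||% as.character(seq_along(fw$propensity)),
      propensity = as.numeric(fw$propensity),
      predicted = as.integer(fw$propensity >= threshold),
      label = as.integer(g$labels))
  })
}

#' @rdname predict.catsite_model
#' @export
predict.catsite_fit <- function(object, graphs, threshold = 0.5, ...) {
  predict.catsite_model(object$model, graphs, threshold = threshold, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load model checkpoints as text
#'
#' Parameters are written as one whitespace-separated numeric file per
#' tensor plus a JSON sidecar recording dimensions and configuration.
#'
#' @param model A `catsite_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir` (save) or the model (load).
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(model$params)) {
    write.table(model$params[[nm]], file.path(dir, paste0(nm, ".txt")),
                row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(model$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  model <- catsite_model(theta = cfg$theta, gcn_dims = cfg$gcn_dims,
                         branch_dim = cfg$branch_dim,
                         fusion_dim = cfg$fusion_dim,
                         embed_dim = cfg$embed_dim, seed = cfg$seed,
                         init = "zero")
  model$config$xa_center <- cfg$xa_center
  model$config$xa_scale <- cfg$xa_scale
  for (nm in names(model$params)) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".txt"))))
    dimnames(m) <- NULL
    stopifnot(all(dim(m) == dim(model$params[[nm]])))
    model$params[[nm]] <- m
  }
  model
}
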