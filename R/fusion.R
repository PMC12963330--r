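# Gated fusion of the two node views: the Node2Vec structural embedding z_i
# and the projected raw-feature vector h_i = phi(W_x x_i + b_x). A learnable
# sigmoid gate g_i = sigma(W_g [z_i || h_i] + b_g) interpolates the views
# elementwise: f_i = g_i * z_i + (1 - g_i) * h_i, so each fused coordinate is
# a convex combination of the corresponding coordinates of the two views.
# Fusion parameters are trained jointly with the GNN.

#' Initialize fusion parameters
#'
#' @param p raw-feature dimension.
#' @param d latent (embedding) dimension.
#' @param seed integer seed for Glorot-uniform initialization.
#' @return list with `W_x` (p x d), `b_x` (d), `W_g` (2d x d), `b_g` (d).
#' @export
init_fusion_params <- function(p, d, seed = 42L) {
  with_seed(seed, list(
    W_x = glorot(p, d), b_x = numeric(d),
    W_g = glorot(2 * d, d), b_g = numeric(d)))
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Project raw features into the latent space
#'
#' `h_i = phi(W_x x_i + b_x)` with phi = ReLU.
#'
#' @param X n x p matrix of (standardized) raw features, or a length-p vector.
#' @param params fusion parameter list (see [init_fusion_params()]).
#' @return n x d matrix of projected features.
#' @export
project_features <- function(X, params) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(params$W_x))
    stop("project_features: feature length ", ncol(X),
         " does not match W_x rows ", nrow(params$W_x), call. = FALSE)
  relu(sweep(X %*% params$W_x, 2, params$b_x, "+"))
}

#' Compute the fusion gate
#'
#' `g_i = sigmoid(W_g [z_i || h_i] + b_g)`; entries lie strictly in (0, 1).
#'
#' @param Z n x d structural embeddings (or length-d vector).
#' @param H n x d projected features.
#' @param params fusion parameter list.
#' @return n x d gate matrix.
#' @export
compute_gate <- function(Z, H, params) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  if (!all(dim(Z) == dim(H)))
    stop("compute_gate: z and h dimensions differ", call. = FALSE)
  if (2 * ncol(Z) != nrow(params$W_g))
    stop("compute_gate: latent dimension does not match W_g", call. = FALSE)
  sigmoid(sweep(cbind(Z, H) %*% params$W_g, 2, params$b_g, "+"))
}

#' Fuse the two views by gated elementwise interpolation
#'
#' `f_i = g_i * z_i + (1 - g_i) * h_i`.
#'
#' @param Z,H,G equal-dimension matrices (or vectors): structural view,
#'   feature view, gate.
#' @return fused matrix of the same shape.
#' @export
fuse <- function(Z, H, G) {
  if (is.null(dim(Z))) {
    Z <- matrix(Z, nrow = 1); H <- matrix(H, nrow = 1)
    G <- matrix(G, nrow = 1)
  }
  if (!all(dim(Z) == dim(H)) || !all(dim(Z) == dim(G)))
    stop("fuse: shape mismatch", call. = FALSE)
  G * Z + (1 - G) * H
}

# forward with cache for joint training
fusion_forward <- function(Z, X, params) {
  pre_x <- sweep(X %*% params$W_x, 2, params$b_x, "+")
  H <- relu(pre_x)
  ZH <- cbind(Z, H)
  Ag <- sweep(ZH %*% params$W_g, 2, params$b_g, "+")
  G <- sigmoid(Ag)
  Fm <- G * Z + (1 - G) * H
  list(f = Fm, cache = list(Z = Z, X = X, H = H, G = G, pre_x = pre_x,
                            ZH = ZH))
}

fusion_backward <- function(dF, cache, params) {
  d <- ncol(cache$Z)
  dG <- dF * (cache$Z - cache$H)
  dH <- dF * (1 - cache$G)
  dAg <- dG * cache$G * (1 - cache$G)
  dW_g <- crossprod(cache$ZH, dAg)
  db_g <- colSums(dAg)
  dZH <- dAg %*% t(params$W_g)
  dH <- dH + dZH[, d + seq_len(d), drop = FALSE]
  dpre <- dH * (cache$pre_x > 0)
  list(grads = list(W_x = crossprod(cache$X, dpre), b_x = colSums(dpre),
                    W_g = dW_g, b_g = db_g))
}
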