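# Minimal dense NN primitives with hand-written gradients: activations,
# batch normalization, inverted dropout, Adam, and the class-weighted
# cross-entropy head. No autodiff framework is used; every layer's backward
# pass is derived and implemented explicitly (and verified against finite
# differences in the test suite).

relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# inverted dropout mask (train-time only); uses the session RNG
dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# --- batch normalization (over nodes, per feature) -------------------------

batchnorm_forward <- function(X, gamma, beta, train, run_mean, run_var,
                              momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)                   # biased, as is conventional
    ivar <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, ivar, "*")
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
    cache <- list(xhat = xhat, ivar = ivar, xc = xc, gamma = gamma)
  } else {
    xhat <- sweep(sweep(X, 2, run_mean), 2, 1 / sqrt(run_var + eps), "*")
    cache <- NULL
  }
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, cache = cache, run_mean = run_mean, run_var = run_var)
}

batchnorm_backward <- function(dOut, cache) {
  n <- nrow(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, cache$gamma, "*")
  # dX = ivar/n * (n*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  t1 <- n * dxhat
  t2 <- matrix(colSums(dxhat), n, ncol(dOut), byrow = TRUE)
  t3 <- cache$xhat * matrix(colSums(dxhat * cache$xhat), n, ncol(dOut),
                            byrow = TRUE)
  dX <- sweep(t1 - t2 - t3, 2, cache$ivar / n, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# classic Adam with L2-style weight decay folded into the gradient
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# --- weighted cross-entropy head -------------------------------------------

#' Class-weighted cross-entropy loss
#'
#' `loss = -sum_{i in mask} w[y_i] * log p_i[y_i] / sum_{i in mask} w[y_i]`,
#' with probabilities clamped at 1e-12.
#'
#' @param probs n x K matrix of class probabilities (rows sum to 1).
#' @param y integer class labels in 1..K.
#' @param weights length-K class weights.
#' @param mask logical or integer subset of rows entering the loss.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, y, weights, mask = NULL) {
  if (is.null(mask)) mask <- seq_len(nrow(probs))
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("weighted_cross_entropy: empty mask",
                              call. = FALSE)
  w <- weights[y[mask]]
  p <- pmax(probs[cbind(mask, y[mask])], 1e-12)
  -sum(w * log(p)) / sum(w)
}

# gradient of the weighted CE w.r.t. the pre-softmax logits (full n x K,
# zero outside the mask)
ce_logit_grad <- function(probs, y, weights, mask) {
  if (is.logical(mask)) mask <- which(mask)
  n <- nrow(probs); K <- ncol(probs)
  w <- weights[y[mask]]
  G <- matrix(0, n, K)
  P <- probs[mask, , drop = FALSE]
  P[cbind(seq_along(mask), y[mask])] <-
    P[cbind(seq_along(mask), y[mask])] - 1
  G[mask, ] <- (w / sum(w)) * P
  G
}
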