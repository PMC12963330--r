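# IK-BRNet and baselines.
#
# IK-BRNet is a lightweight relation-aware graph attention network: a single
# linear/attention machinery (W_l, a_l) is *shared* across all edge types,
# and relation identity enters only through a small learned relation
# embedding r_k concatenated into the attention logit:
#
#   e_ij = LeakyReLU(a_l^T [W_l f_i || W_l f_j || r_k])
#
# so edge types modulate attention scores without per-relation weight
# matrices. Self-loops are virtual edges with their own relation embedding
# r_self in the logit and a learned scalar weight s_l on the self message.
# The GAT baseline is the identical architecture with the relation block
# removed (all edges treated uniformly); the GCN baseline uses the
# symmetrically normalized adjacency D^(-1/2)(A + I)D^(-1/2).

#' Symmetrically normalized adjacency with self-loops
#'
#' `A_hat = D~^(-1/2) (A + I) D~^(-1/2)` where `D~` is the degree matrix of
#' `A + I`. An isolated node keeps `A_hat[i, i] = 1`.
#'
#' @param A square binary adjacency matrix.
#' @return normalized adjacency matrix of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A))
    stop("normalize_adjacency: matrix must be square", call. = FALSE)
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  dinv * At * rep(dinv, each = nrow(A))
}

#' Build message-passing tensors from a knowledge graph
#'
#' Directed relations (INFECTS, ENRICHED_AT, IS_A) are mirrored with reverse
#' edges carrying the same relation id; CO_OCCURS is stored in both
#' directions already. A virtual self-loop edge with relation id
#' `n_rel + 1` is appended for every node. Also precomputes the normalized
#' adjacency used by the GCN baseline.
#'
#' @param graph a `knowledge_graph`.
#' @param self_loops append virtual self-loop edges (default TRUE).
#' @return list with `src`, `dst`, `rel` (integer vectors), `is_self`,
#'   `idx_by_dst` (edge indices grouped by destination), `n`, `n_rel`,
#'   `A_hat`.
#' @export
make_graph_tensors <- function(graph, self_loops = TRUE) {
  n <- nrow(graph$nodes)
  vocab <- graph$relation_vocabulary
  e <- graph$edges
  rel <- match(e$relation, vocab)
  if (anyNA(rel))
    stop("make_graph_tensors: unknown relation id in edge list", call. = FALSE)
  mirror <- e$relation != "CO_OCCURS" & e$src != e$dst
  src <- c(e$src, e$dst[mirror])
  dst <- c(e$dst, e$src[mirror])
  relv <- c(rel, rel[mirror])
  is_self <- rep(FALSE, length(src))
  if (self_loops) {
    src <- c(src, seq_len(n))
    dst <- c(dst, seq_len(n))
    relv <- c(relv, rep(length(vocab) + 1L, n))
    is_self <- c(is_self, rep(TRUE, n))
  }
  idx_by_dst <- split(seq_along(dst), dst)
  A <- matrix(0, n, n)
  und <- e$src != e$dst
  A[cbind(e$src[und], e$dst[und])] <- 1
  A[cbind(e$dst[und], e$src[und])] <- 1
  list(src = src, dst = dst, rel = relv, is_self = is_self,
       idx_by_dst = idx_by_dst,
       dst_groups = as.integer(names(idx_by_dst)),
       n = n, n_rel = length(vocab), A_hat = normalize_adjacency(A))
}

#' Shuffle edge relation labels (ablation helper)
#'
#' Permutes the relation ids of all non-self edges (seeded). Used to test
#' that IK-BRNet actually exploits relation identity while the GAT baseline,
#' which ignores relations, is unaffected.
#'
#' @param tensors output of [make_graph_tensors()].
#' @param seed integer seed.
#' @return tensors with permuted relation ids.
#' @export
shuffle_relations <- function(tensors, seed = 0L) {
  with_seed(seed, {
    i <- which(!tensors$is_self)
    tensors$rel[i] <- tensors$rel[sample(i)]
    tensors
  })
}

# --- parameter initialization ----------------------------------------------

#' Initialize a model
#'
#' @param type one of "ikbrnet", "gat", "gcn".
#' @param p_in raw-feature dimension (input to the fusion projection, and to
#'   the first GCN layer).
#' @param d latent dimension of the fused representation (= Node2Vec dim);
#'   ignored by the GCN baseline.
#' @param relations relation vocabulary (character).
#' @param hidden hidden width of the graph layers (default 32).
#' @param r_dim relation-embedding dimension (default 8; IK-BRNet only).
#' @param dropout dropout probability applied to layer inputs during
#'   training (default 0.3).
#' @param seed integer seed for parameter initialization.
#' @return object of class `ikb_model` with `params` (flat named list) and
#'   batch-norm `buffers`.
#' @export
init_model <- function(type = c("ikbrnet", "gat", "gcn"), p_in, d = 32L,
                       relations = RELATIONS, hidden = 32L, r_dim = 8L,
                       dropout = 0.3, seed = 42L) {
  type <- match.arg(type)
  n_rel <- length(relations)
  params <- with_seed(seed, {
    pr <- list()
    if (type %in% c("ikbrnet", "gat")) {
      pr$W_x <- glorot(p_in, d); pr$b_x <- numeric(d)
      pr$W_g <- glorot(2 * d, d); pr$b_g <- numeric(d)
      pr$W_p <- glorot(d, hidden); pr$b_p <- numeric(hidden)
      for (l in 1:2) {
        pr[[paste0("W", l)]] <- glorot(hidden, hidden)
        pr[[paste0("a", l, "_dst")]] <- runif(hidden, -0.1, 0.1)
        pr[[paste0("a", l, "_src")]] <- runif(hidden, -0.1, 0.1)
        if (type == "ikbrnet")
          pr[[paste0("a", l, "_rel")]] <- runif(r_dim, -0.1, 0.1)
        pr[[paste0("s", l)]] <- 1.0
        pr[[paste0("gamma", l)]] <- rep(1, hidden)
        pr[[paste0("beta", l)]] <- numeric(hidden)
      }
      if (type == "ikbrnet")
        pr$r_emb <- matrix(rnorm((n_rel + 1) * r_dim, sd = 0.1),
                           n_rel + 1, r_dim)
    } else {
      pr$W_c1 <- glorot(p_in, hidden); pr$b_c1 <- numeric(hidden)
      pr$W_c2 <- glorot(hidden, hidden); pr$b_c2 <- numeric(hidden)
    }
    pr$W_h <- glorot(hidden, 2L); pr$b_h <- numeric(2L)
    pr
  })
  structure(list(
    type = type, params = params,
    dims = list(p_in = p_in, d = d, hidden = hidden, r_dim = r_dim,
                n_rel = n_rel),
    relations = relations, dropout = dropout,
    buffers = list(bn1_mean = numeric(hidden), bn1_var = rep(1, hidden),
                   bn2_mean = numeric(hidden), bn2_var = rep(1, hidden))),
    class = "ikb_model")
}

#' Count model parameters
#'
#' @param model an `ikb_model` (or a flat parameter list).
#' @return total scalar parameter count, with a named per-block breakdown in
#'   attribute `"breakdown"`.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "ikb_model")) model$params else model
  sizes <- vapply(params, length, integer(1))
  structure(sum(sizes), breakdown = sizes)
}

# --- relation-aware attention layer ----------------------------------------

attn_fwd <- function(Fin, W, a_dst, a_src, s, gamma, beta, tensors,
                     r_emb = NULL, a_rel = NULL, train = FALSE, dropout = 0,
                     run_mean = NULL, run_var = NULL, slope = 0.2) {
  N <- tensors$n
  h <- ncol(W)
  if (is.null(run_mean)) run_mean <- numeric(h)
  if (is.null(run_var)) run_var <- rep(1, h)
  mask <- if (train) dropout_mask(nrow(Fin), ncol(Fin), dropout) else NULL
  Fd <- if (is.null(mask)) Fin else Fin * mask
  M <- Fd %*% W
  src <- tensors$src; dst <- tensors$dst
  Msrc <- M[src, , drop = FALSE]
  Mdst <- M[dst, , drop = FALSE]
  u <- drop(Mdst %*% a_dst) + drop(Msrc %*% a_src)
  if (!is.null(r_emb)) {
    if (max(tensors$rel) > nrow(r_emb))
      stop("attention layer: relation id outside vocabulary", call. = FALSE)
    Rk <- r_emb[tensors$rel, , drop = FALSE]
    u <- u + drop(Rk %*% a_rel)
  } else Rk <- NULL
  lg <- leaky_relu(u, slope)
  segmax <- numeric(N)
  segmax[tensors$dst_groups] <-
    vapply(tensors$idx_by_dst, function(ii) max(lg[ii]), numeric(1))
  ex <- exp(lg - segmax[dst])
  denom <- segment_sum(ex, dst, N)
  alpha <- ex / denom[dst]
  coef <- ifelse(tensors$is_self, s, 1)
  w_e <- alpha * coef
  out_pre <- scatter_add(w_e * Msrc, dst, N)
  H <- relu(out_pre)
  bn <- batchnorm_forward(H, gamma, beta, train, run_mean, run_var)
  list(out = bn$out, run_mean = bn$run_mean, run_var = bn$run_var,
       alpha = alpha,
       cache = list(Fd = Fd, mask = mask, M = M, Msrc = Msrc, Mdst = Mdst,
                    u = u, alpha = alpha, coef = coef, w_e = w_e,
                    out_pre = out_pre, Rk = Rk, bn = bn$cache, slope = slope))
}

attn_bwd <- function(dOut, cache, W, a_dst, a_src, tensors, a_rel = NULL) {
  N <- tensors$n
  src <- tensors$src; dst <- tensors$dst
  bnb <- batchnorm_backward(dOut, cache$bn)
  dpre <- bnb$dX * (cache$out_pre > 0)
  dpre_dst <- dpre[dst, , drop = FALSE]
  d_we <- rowSums(cache$Msrc * dpre_dst)
  dMsrc_agg <- cache$w_e * dpre_dst
  d_alpha <- cache$coef * d_we
  d_s <- sum(d_we[tensors$is_self] * cache$alpha[tensors$is_self])
  t1 <- cache$alpha * d_alpha
  seg <- segment_sum(t1, dst, N)
  d_lg <- t1 - cache$alpha * seg[dst]
  d_u <- d_lg * ifelse(cache$u > 0, 1, cache$slope)
  da_dst <- colSums(cache$Mdst * d_u)
  da_src <- colSums(cache$Msrc * d_u)
  extra <- list()
  if (!is.null(cache$Rk)) {
    extra$a_rel <- colSums(cache$Rk * d_u)
    dr_by_rel <- segment_sum(d_u, tensors$rel, tensors$n_rel + 1L)
    extra$r_emb <- outer(dr_by_rel, a_rel)
  }
  dM <- scatter_add(dMsrc_agg + outer(d_u, a_src), src, N) +
    scatter_add(outer(d_u, a_dst), dst, N)
  dW <- crossprod(cache$Fd, dM)
  dFd <- dM %*% t(W)
  dFin <- if (is.null(cache$mask)) dFd else dFd * cache$mask
  list(dFin = dFin, W = dW, a_dst = da_dst, a_src = da_src, s = d_s,
       gamma = bnb$dgamma, beta = bnb$dbeta, extra = extra)
}

#' Apply one relation-aware attention layer
#'
#' Functional form (eval-mode by default): messages `W f_j` are aggregated
#' with softmax attention over each node's in-neighborhood (plus a virtual
#' self-loop weighted by the scalar `s`), with logits
#' `LeakyReLU(a^T [W f_i || W f_j || r_k])`; omitting `relation_embeddings`
#' gives the relation-blind (GAT) layer.
#'
#' @param inputs n x d_in input matrix.
#' @param tensors output of [make_graph_tensors()].
#' @param W,a_dst,a_src,s,gamma,beta layer parameters.
#' @param relation_embeddings optional (n_rel + 1) x r_dim matrix.
#' @param a_rel optional length-r_dim attention sub-vector for the relation
#'   block.
#' @param train training mode (batch statistics + dropout).
#' @param dropout dropout probability in training mode.
#' @return n x d_out output matrix with attention coefficients in attribute
#'   `"alpha"`.
#' @export
relation_attention_layer <- function(inputs, tensors, W, a_dst, a_src,
                                     s = 1, gamma = rep(1, ncol(W)),
                                     beta = numeric(ncol(W)),
                                     relation_embeddings = NULL, a_rel = NULL,
                                     train = FALSE, dropout = 0) {
  r <- attn_fwd(inputs, W, a_dst, a_src, s, gamma, beta, tensors,
                r_emb = relation_embeddings, a_rel = a_rel, train = train,
                dropout = dropout)
  structure(r$out, alpha = r$alpha)
}

# --- full model forward / backward -----------------------------------------

model_forward <- function(model, tensors, Z = NULL, X, train = FALSE,
                          keep_cache = FALSE) {
  p <- model$params
  drp <- if (train) model$dropout else 0
  if (model$type %in% c("ikbrnet", "gat")) {
    fus <- fusion_forward(Z, X, p)
    P0 <- sweep(fus$f %*% p$W_p, 2, p$b_p, "+")
    F0 <- relu(P0)
    use_rel <- model$type == "ikbrnet"
    l1 <- attn_fwd(F0, p$W1, p$a1_dst, p$a1_src, p$s1, p$gamma1, p$beta1,
                   tensors, r_emb = if (use_rel) p$r_emb,
                   a_rel = if (use_rel) p$a1_rel, train = train,
                   dropout = drp, run_mean = model$buffers$bn1_mean,
                   run_var = model$buffers$bn1_var)
    l2 <- attn_fwd(l1$out, p$W2, p$a2_dst, p$a2_src, p$s2, p$gamma2, p$beta2,
                   tensors, r_emb = if (use_rel) p$r_emb,
                   a_rel = if (use_rel) p$a2_rel, train = train,
                   dropout = drp, run_mean = model$buffers$bn2_mean,
                   run_var = model$buffers$bn2_var)
    logits <- sweep(l2$out %*% p$W_h, 2, p$b_h, "+")
    probs <- softmax_rows(logits)
    buffers <- list(bn1_mean = l1$run_mean, bn1_var = l1$run_var,
                    bn2_mean = l2$run_mean, bn2_var = l2$run_var)
    cache <- if (keep_cache)
      list(fus = fus$cache, P0 = P0, F0 = F0, l1 = l1$cache, l2 = l2$cache,
           O1 = l1$out, O2 = l2$out, probs = probs)
    list(probs = probs, hidden = l2$out, buffers = buffers, cache = cache)
  } else {
    A <- tensors$A_hat
    AX <- A %*% X
    H1pre <- sweep(AX %*% p$W_c1, 2, p$b_c1, "+")
    H1 <- relu(H1pre)
    mask <- if (train) dropout_mask(nrow(H1), ncol(H1), drp) else NULL
    H1d <- if (is.null(mask)) H1 else H1 * mask
    AH <- A %*% H1d
    H2pre <- sweep(AH %*% p$W_c2, 2, p$b_c2, "+")
    H2 <- relu(H2pre)
    logits <- sweep(H2 %*% p$W_h, 2, p$b_h, "+")
    probs <- softmax_rows(logits)
    cache <- if (keep_cache)
      list(AX = AX, H1pre = H1pre, H1 = H1, mask = mask, H1d = H1d, AH = AH,
           H2pre = H2pre, H2 = H2, probs = probs)
    list(probs = probs, hidden = H2, buffers = model$buffers, cache = cache)
  }
}

model_backward <- function(model, tensors, dlogits, cache) {
  p <- model$params
  g <- list()
  if (model$type %in% c("ikbrnet", "gat")) {
    g$W_h <- crossprod(cache$O2, dlogits)
    g$b_h <- colSums(dlogits)
    dO2 <- dlogits %*% t(p$W_h)
    use_rel <- model$type == "ikbrnet"
    b2 <- attn_bwd(dO2, cache$l2, p$W2, p$a2_dst, p$a2_src, tensors,
                   a_rel = if (use_rel) p$a2_rel)
    g$W2 <- b2$W; g$a2_dst <- b2$a_dst; g$a2_src <- b2$a_src; g$s2 <- b2$s
    g$gamma2 <- b2$gamma; g$beta2 <- b2$beta
    b1 <- attn_bwd(b2$dFin, cache$l1, p$W1, p$a1_dst, p$a1_src, tensors,
                   a_rel = if (use_rel) p$a1_rel)
    g$W1 <- b1$W; g$a1_dst <- b1$a_dst; g$a1_src <- b1$a_src; g$s1 <- b1$s
    g$gamma1 <- b1$gamma; g$beta1 <- b1$beta
    if (use_rel) {
      g$a1_rel <- b1$extra$a_rel
      g$a2_rel <- b2$extra$a_rel
      g$r_emb <- b1$extra$r_emb + b2$extra$r_emb
    }
    dF0 <- b1$dFin
    dP0 <- dF0 * (cache$P0 > 0)
    # fused input reconstructed from the cache: f = g*z + (1-g)*h
    fmat <- cache$fus$G * cache$fus$Z + (1 - cache$fus$G) * cache$fus$H
    g$W_p <- crossprod(fmat, dP0)
    g$b_p <- colSums(dP0)
    dfused <- dP0 %*% t(p$W_p)
    fb <- fusion_backward(dfused, cache$fus, p)
    g <- c(g, fb$grads)
  } else {
    g$W_h <- crossprod(cache$H2, dlogits)
    g$b_h <- colSums(dlogits)
    dH2 <- dlogits %*% t(p$W_h)
    dH2pre <- dH2 * (cache$H2pre > 0)
    g$W_c2 <- crossprod(cache$AH, dH2pre)
    g$b_c2 <- colSums(dH2pre)
    dH1d <- tensors$A_hat %*% (dH2pre %*% t(p$W_c2))
    dH1 <- if (is.null(cache$mask)) dH1d else dH1d * cache$mask
    dH1pre <- dH1 * (cache$H1pre > 0)
    g$W_c1 <- crossprod(cache$AX, dH1pre)
    g$b_c1 <- colSums(dH1pre)
  }
  g
}

# one training-mode forward + backward pass; returns loss, grads, updated
# batch-norm buffers and the train-mode probabilities
loss_and_grads <- function(model, tensors, Z, X, y, class_w, mask,
                           train = TRUE) {
  fw <- model_forward(model, tensors, Z, X, train = train, keep_cache = TRUE)
  loss <- weighted_cross_entropy(fw$probs, y, class_w, mask)
  dlogits <- ce_logit_grad(fw$probs, y, class_w, mask)
  grads <- model_backward(model, tensors, dlogits, fw$cache)
  list(loss = loss, grads = grads, buffers = fw$buffers, probs = fw$probs)
}

#' IK-BRNet forward pass
#'
#' Feature projection of the fused inputs to the hidden space, two
#' relation-aware attention layers, and a softmax classification head. Eval
#' mode disables dropout and uses running batch-norm statistics, so outputs
#' are deterministic.
#'
#' @param model an `ikb_model` of type "ikbrnet".
#' @param tensors output of [make_graph_tensors()].
#' @param Z Node2Vec embedding matrix (n x d).
#' @param X standardized raw-feature matrix (n x p).
#' @param mode "eval" or "train".
#' @return list with `probs` (n x 2, rows sum to 1; columns health, disease)
#'   and `hidden` (final 32-d representations).
#' @export
ikbrnet_forward <- function(model, tensors, Z, X, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (model$type != "ikbrnet")
    stop("ikbrnet_forward: model type is ", model$type, call. = FALSE)
  fw <- model_forward(model, tensors, Z, X, train = mode == "train")
  list(probs = fw$probs, hidden = fw$hidden)
}

#' GAT baseline forward pass
#'
#' Identical to [ikbrnet_forward()] with the relation-embedding block removed
#' from the attention logits (all edges treated uniformly).
#'
#' @inheritParams ikbrnet_forward
#' @export
gat_baseline_forward <- function(model, tensors, Z, X,
                                 mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (model$type != "gat")
    stop("gat_baseline_forward: model type is ", model$type, call. = FALSE)
  fw <- model_forward(model, tensors, Z, X, train = mode == "train")
  list(probs = fw$probs, hidden = fw$hidden)
}

#' GCN baseline forward pass
#'
#' Two layers of `A_hat X W` with ReLU and dropout between, then a softmax
#' head.
#'
#' @param model an `ikb_model` of type "gcn".
#' @param tensors output of [make_graph_tensors()] (uses `A_hat`).
#' @param X input feature matrix.
#' @param mode "eval" or "train".
#' @export
gcn_baseline_forward <- function(model, tensors, X,
                                 mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (model$type != "gcn")
    stop("gcn_baseline_forward: model type is ", model$type, call. = FALSE)
  fw <- model_forward(model, tensors, Z = NULL, X = X,
                      train = mode == "train")
  list(probs = fw$probs, hidden = fw$hidden)
}
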