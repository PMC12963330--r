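test_that("normalize_adjacency matches hand computations", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(A2), matrix(0.5, 2, 2))
  expect_error(normalize_adjacency(matrix(0, 2, 3)), "square")
  # permutation equivariance
  withr::local_seed(1)
  A <- matrix(rbinom(36, 1, 0.4), 6, 6)
  A <- 1 * ((A + t(A)) > 0); diag(A) <- 0
  P <- diag(6)[sample(6), ]
  expect_equal(P %*% normalize_adjacency(A) %*% t(P),
               normalize_adjacency(P %*% A %*% t(P)), tolerance = 1e-12)
  # self-loops present: strictly positive diagonal
  expect_true(all(diag(normalize_adjacency(A)) > 0))
})

test_that("a singleton in-neighborhood gets attention weight 1", {
  g <- make_bare_graph(2, rbind(c(1, 2)))
  tensors <- make_graph_tensors(g, self_loops = FALSE)
  withr::local_seed(2)
  W <- matrix(rnorm(12), 3, 4)
  Fin <- matrix(rnorm(6), 2, 3)
  out <- relation_attention_layer(Fin, tensors, W, a_dst = rnorm(4),
                                  a_src = rnorm(4))
  alpha <- attr(out, "alpha")
  expect_equal(unname(alpha), c(1, 1))  # both directed edges are singletons
  # output equals eval-mode BN of the ReLU'd transformed message
  msg <- pmax(Fin[1, , drop = FALSE] %*% W, 0)
  expect_equal(unclass(out)[2, ], drop(msg / sqrt(1 + 1e-5)),
               tolerance = 1e-12)
})

test_that("attention weights sum to 1 over every in-neighborhood", {
  g <- toy_knowledge_graph(seed = 5)
  tensors <- make_graph_tensors(g)
  withr::local_seed(3)
  h <- 6
  out <- relation_attention_layer(matrix(rnorm(nrow(g$nodes) * h),
                                         ncol = h),
                                  tensors, W = matrix(rnorm(h * h), h, h),
                                  a_dst = rnorm(h), a_src = rnorm(h),
                                  relation_embeddings =
                                    matrix(rnorm(5 * 3), 5, 3),
                                  a_rel = rnorm(3))
  sums <- tapply(attr(out, "alpha"), tensors$dst, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("relation-tied IK-BRNet layer equals the relation-blind layer", {
  withr::local_seed(7)
  n <- 12; h <- 5
  edges <- t(combn(n, 2))
  edges <- edges[runif(nrow(edges)) < 0.3, , drop = FALSE]
  g <- make_bare_graph(n, edges)
  # assign random relation labels to the stored edges
  g$edges$relation <- sample(c("INFECTS", "ENRICHED_AT", "IS_A"),
                             nrow(g$edges), replace = TRUE)
  tensors <- make_graph_tensors(g)
  Fin <- matrix(rnorm(n * h), n, h)
  W <- matrix(rnorm(h * h), h, h)
  a_dst <- rnorm(h); a_src <- rnorm(h); s <- 0.7
  blind <- relation_attention_layer(Fin, tensors, W, a_dst, a_src, s = s)
  tied <- relation_attention_layer(Fin, tensors, W, a_dst, a_src, s = s,
                                   relation_embeddings = matrix(0, 5, 3),
                                   a_rel = rnorm(3))
  expect_equal(unclass(tied), unclass(blind), tolerance = 1e-6)
  # unknown relation id is rejected
  bad <- tensors; bad$rel[1] <- 99L
  expect_error(relation_attention_layer(Fin, bad, W, a_dst, a_src,
                                        relation_embeddings =
                                          matrix(0, 5, 3),
                                        a_rel = rnorm(3)),
               "vocabulary")
})

make_model_inputs <- function(g, d = 6, seed = 4) {
  withr::local_seed(seed)
  n <- nrow(g$nodes)
  list(Z = matrix(rnorm(n * d), n, d),
       X = suppressWarnings(zscore_features(g, rep(TRUE, n))))
}

test_that("forward passes are row-stochastic and eval-deterministic", {
  g <- toy_knowledge_graph(seed = 6)
  tensors <- make_graph_tensors(g)
  inp <- make_model_inputs(g)
  for (type in c("ikbrnet", "gat", "gcn")) {
    model <- init_model(type, p_in = ncol(inp$X), d = 6,
                        relations = g$relation_vocabulary, hidden = 8,
                        seed = 3)
    fw <- switch(type,
      ikbrnet = ikbrnet_forward(model, tensors, inp$Z, inp$X),
      gat = gat_baseline_forward(model, tensors, inp$Z, inp$X),
      gcn = gcn_baseline_forward(model, tensors, inp$X))
    expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-6))
    expect_true(all(fw$probs >= 0))
    fw2 <- switch(type,
      ikbrnet = ikbrnet_forward(model, tensors, inp$Z, inp$X),
      gat = gat_baseline_forward(model, tensors, inp$Z, inp$X),
      gcn = gcn_baseline_forward(model, tensors, inp$X))
    expect_identical(fw$probs, fw2$probs)
  }
})

test_that("GCN on an edgeless graph reduces to an MLP on features", {
  g <- make_bare_graph(5, matrix(numeric(0), 0, 2))
  g$features <- matrix(rnorm(5 * 3), 5, 3)
  tensors <- make_graph_tensors(g)
  expect_equal(tensors$A_hat, diag(5))
  model <- init_model("gcn", p_in = 3, relations = g$relation_vocabulary,
                      hidden = 4, seed = 9)
  fw <- gcn_baseline_forward(model, tensors, g$features)
  p <- model$params
  H1 <- pmax(sweep(g$features %*% p$W_c1, 2, p$b_c1, "+"), 0)
  H2 <- pmax(sweep(H1 %*% p$W_c2, 2, p$b_c2, "+"), 0)
  logits <- sweep(H2 %*% p$W_h, 2, p$b_h, "+")
  expect_equal(fw$probs, exp(logits) / rowSums(exp(logits)),
               tolerance = 1e-12)
})

test_that("2-node GCN with hand-set weights gives hand-computed logits", {
  g <- make_bare_graph(2, rbind(c(1, 2)))
  tensors <- make_graph_tensors(g)
  X <- rbind(c(1, 0), c(0, 2))
  model <- init_model("gcn", p_in = 2, relations = g$relation_vocabulary,
                      hidden = 2, seed = 1)
  model$params$W_c1 <- diag(2); model$params$b_c1 <- c(0, 0)
  model$params$W_c2 <- diag(2); model$params$b_c2 <- c(0, 0)
  model$params$W_h <- diag(2); model$params$b_h <- c(0, 0)
  # A_hat = [[.5,.5],[.5,.5]]; layer1 = relu(A X) = [[.5,1],[.5,1]];
  # layer2 = relu(A H1) = [[.5,1],[.5,1]]; logits = H2
  fw <- gcn_baseline_forward(model, tensors, X)
  l <- c(0.5, 1)
  expect_equal(fw$probs[1, ], setNames(exp(l) / sum(exp(l)), NULL),
               tolerance = 1e-12)
  expect_equal(fw$probs[1, ], fw$probs[2, ], tolerance = 1e-12)
})

test_that("count_parameters does exact bookkeeping", {
  expect_equal(as.integer(count_parameters(list(W = matrix(0, 3, 2),
                                                b = numeric(2)))), 8L)
  g <- toy_knowledge_graph(seed = 2)
  ik <- init_model("ikbrnet", p_in = ncol(g$features), d = 8,
                   relations = g$relation_vocabulary, hidden = 8, r_dim = 4)
  ga <- init_model("gat", p_in = ncol(g$features), d = 8,
                   relations = g$relation_vocabulary, hidden = 8)
  expect_gt(count_parameters(ik), count_parameters(ga))
  # doubling r_dim grows the count by (n_rel + 1) * r_dim for the embedding
  # table plus 2 * r_dim for the two per-layer attention sub-vectors
  ik2 <- init_model("ikbrnet", p_in = ncol(g$features), d = 8,
                    relations = g$relation_vocabulary, hidden = 8, r_dim = 8)
  n_rel <- length(g$relation_vocabulary)
  expect_equal(as.integer(count_parameters(ik2) - count_parameters(ik)),
               (n_rel + 1L + 2L) * 4L)
  bd <- attr(count_parameters(ik), "breakdown")
  expect_equal(as.integer(sum(bd)), as.integer(count_parameters(ik)))
})

test_that("models are permutation-equivariant in eval mode", {
  g <- toy_knowledge_graph(seed = 8)
  n <- nrow(g$nodes)
  inp <- make_model_inputs(g, seed = 5)
  withr::local_seed(6)
  perm <- sample(n)
  gp <- g
  gp$nodes <- g$nodes[perm, ]
  gp$features <- g$features[perm, , drop = FALSE]
  inv <- order(perm)
  gp$edges$src <- inv[g$edges$src]
  gp$edges$dst <- inv[g$edges$dst]
  gp$labels <- g$labels[perm]
  tensors <- make_graph_tensors(g)
  tensors_p <- make_graph_tensors(gp)
  for (type in c("ikbrnet", "gat", "gcn")) {
    model <- init_model(type, p_in = ncol(inp$X), d = 6,
                        relations = g$relation_vocabulary, hidden = 8,
                        seed = 7)
    fw <- ikbrnet:::model_forward(model, tensors, inp$Z, inp$X,
                                  train = FALSE)
    fwp <- ikbrnet:::model_forward(model, tensors_p, inp$Z[perm, ],
                                   inp$X[perm, ], train = FALSE)
    expect_equal(fwp$probs, fw$probs[perm, ], tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  g <- toy_knowledge_graph(seed = 1, nv = 4, nb = 2, n_phage = 2)
  tensors <- make_graph_tensors(g)
  n <- nrow(g$nodes)
  inp <- make_model_inputs(g, d = 5, seed = 1)
  y <- ifelse(is.na(g$labels) | g$labels == "health", 1L, 2L)
  mask <- g$nodes$type %in% c("Virus", "Phage")
  w <- c(1, 2)
  withr::local_seed(99)
  for (type in c("ikbrnet", "gat", "gcn")) {
    model <- init_model(type, p_in = ncol(inp$X), d = 5,
                        relations = g$relation_vocabulary, hidden = 7,
                        r_dim = 3, dropout = 0, seed = 1)
    lg <- ikbrnet:::loss_and_grads(model, tensors, inp$Z, inp$X, y, w, mask)
    for (rep in 1:10) {
      nm <- sample(names(model$params), 1)
      i <- sample(length(model$params[[nm]]), 1)
      h <- 1e-5
      bump <- function(delta) {
        m2 <- model
        m2$params[[nm]][i] <- m2$params[[nm]][i] + delta
        ikbrnet:::loss_and_grads(m2, tensors, inp$Z, inp$X, y, w, mask)$loss
      }
      fd <- (bump(h) - bump(-h)) / (2 * h)
      an <- lg$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
    }
  }
})
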