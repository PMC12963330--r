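test_that("zscore_features standardizes on the training mask only", {
  g <- make_bare_graph(3, matrix(numeric(0), 0, 2))
  g$features <- cbind(v = c(1, 2, 3), onehot = c(1, 0, 1))
  g$numeric_feature_cols <- 1L
  X <- zscore_features(g, rep(TRUE, 3))
  expect_equal(X[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(X[, 2], c(1, 0, 1))  # one-hot untouched

  # constant column -> zeros with a warning
  g$features[, 1] <- 5
  expect_warning(Xc <- zscore_features(g, rep(TRUE, 3)), "zero-variance")
  expect_equal(Xc[, 1], c(0, 0, 0))

  # leakage guard: a held-out outlier does not change the transform
  g2 <- make_bare_graph(4, matrix(numeric(0), 0, 2))
  g2$features <- cbind(v = c(1, 2, 3, 1000), o = rep(1, 4))
  g2$numeric_feature_cols <- 1L
  tr <- c(TRUE, TRUE, TRUE, FALSE)
  A <- zscore_features(g2, tr)
  g2$features[4, 1] <- -999
  B <- zscore_features(g2, tr)
  expect_equal(A[1:3, 1], B[1:3, 1])
  expect_error(zscore_features(g2, rep(FALSE, 4)), "empty")
})

test_that("stratified_split reproduces the 60/20/20 protocol", {
  labels <- c(rep("disease", 81), rep("health", 419))
  sp <- stratified_split(labels, seed = 42)
  expect_equal(sum(sp$test), 100)
  expect_equal(sum(sp$test & labels == "disease"), 16)
  expect_equal(sum(sp$val), 100)
  expect_equal(sum(sp$train), 300)
  expect_equal(sum(sp$train & labels == "disease"), 49)
  # masks partition the labeled universe
  expect_true(all(sp$train + sp$val + sp$test == 1))

  # exact small case: 10 labels, 5/5 -> (6, 2, 2) with (3, 1, 1) positives
  lab10 <- rep(c("a", "b"), each = 5)
  sp10 <- stratified_split(lab10, seed = 1)
  expect_equal(c(sum(sp10$train), sum(sp10$val), sum(sp10$test)),
               c(6, 2, 2))
  expect_equal(sum(sp10$train & lab10 == "a"), 3)

  expect_identical(stratified_split(labels, seed = 9),
                   stratified_split(labels, seed = 9))
  expect_false(identical(stratified_split(labels, seed = 9),
                         stratified_split(labels, seed = 10)))
  expect_error(stratified_split(rep("x", 10)), "2 classes")
})

test_that("NA labels are excluded and tiny classes warned into train", {
  labels <- c(rep("a", 10), rep("b", 2), NA, NA)
  expect_warning(sp <- stratified_split(labels, seed = 3), "< 3 members")
  expect_true(all(sp$train[11:12]))
  expect_false(any(sp$train[13:14] | sp$val[13:14] | sp$test[13:14]))
})

test_that("split masks never overlap across 200 random seeds", {
  labels <- c(rep("disease", 13), rep("health", 37))
  for (s in 1:200) {
    sp <- stratified_split(labels, seed = s)
    expect_true(all(sp$train + sp$val + sp$test == 1))
  }
})

test_that("class_weights implements normalized inverse frequency", {
  expect_equal(unname(class_weights(c(50, 50))), c(1, 1))
  w <- class_weights(c(disease = 81, health = 419))
  expect_equal(unname(w), c(500 / (2 * 81), 500 / (2 * 419)),
               tolerance = 1e-12)
  expect_equal(round(unname(w), 4), c(3.0864, 0.5967))
  # frequency-weighted mean is 1 for any counts
  for (counts in list(c(3, 7), c(10, 20, 30), c(1, 999))) {
    w <- class_weights(counts)
    expect_equal(sum(w * counts) / sum(counts), 1, tolerance = 1e-12)
  }
  expect_error(class_weights(c(5, 0)), "zero-count")
})

test_that("weighted cross-entropy matches closed forms", {
  # perfect one-hot predictions -> ~0 loss
  P <- rbind(c(1, 0), c(0, 1))
  expect_lt(weighted_cross_entropy(P, c(1L, 2L), c(1, 1)), 1e-10)
  # uniform predictions -> ln 2 regardless of weights
  U <- matrix(0.5, 2, 2)
  expect_equal(weighted_cross_entropy(U, c(1L, 2L), c(1, 1)), log(2))
  expect_equal(weighted_cross_entropy(U, c(1L, 2L), c(2, 1)), log(2))
  # masked version only sees masked rows
  P2 <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(weighted_cross_entropy(P2, c(1L, 1L), c(1, 1), mask = 1),
               -log(0.9))
  expect_error(weighted_cross_entropy(P2, c(1L, 1L), c(1, 1),
                                      mask = logical(2)), "empty mask")
})

test_that("plain gradient descent decreases the convex softmax toy", {
  withr::local_seed(21)
  X <- cbind(1, matrix(rnorm(40), 20, 2))
  y <- ifelse(X[, 2] + 0.5 * rnorm(20) > 0, 2L, 1L)
  W <- matrix(0, 3, 2)
  w_cls <- c(1, 1)
  losses <- numeric(50)
  for (it in 1:50) {
    probs <- exp(X %*% W); probs <- probs / rowSums(probs)
    losses[it] <- weighted_cross_entropy(probs, y, w_cls)
    G <- ikbrnet:::ce_logit_grad(probs, y, w_cls, seq_len(20))
    W <- W - 0.1 * crossprod(X, G)
  }
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("early-stopping rule follows the strikes > patience convention", {
  es <- ikbrnet:::es_init()
  # epoch 1 improves; epochs 2+ are flat
  es <- ikbrnet:::es_update(es, 1.0, 1L, 1e-5, patience = 1L)
  expect_true(es$improved); expect_false(es$stop)
  es <- ikbrnet:::es_update(es, 1.0, 2L, 1e-5, patience = 1L)
  expect_false(es$improved); expect_false(es$stop)
  es <- ikbrnet:::es_update(es, 1.0, 3L, 1e-5, patience = 1L)
  expect_true(es$stop)
  expect_equal(es$best_epoch, 1L)
  # sub-min_delta improvement does not reset the clock
  es2 <- ikbrnet:::es_init()
  es2 <- ikbrnet:::es_update(es2, 1.0, 1L, 1e-2, 5L)
  es2 <- ikbrnet:::es_update(es2, 0.999, 2L, 1e-2, 5L)
  expect_false(es2$improved)
})

make_separable_fit <- function(seed = 0) {
  # 20-node two-cluster toy: features linearly separable by construction
  withr::local_seed(seed)
  n <- 20
  edges <- cbind(seq_len(n - 1), 2:n)
  g <- make_bare_graph(n, edges)
  lab <- rep(c("health", "disease"), each = n / 2)
  g$features <- cbind(sig = ifelse(lab == "disease", 1, -1) + 0.1 * rnorm(n),
                      noise = rnorm(n))
  g$numeric_feature_cols <- 1:2
  g$labels <- setNames(lab, g$nodes$id)
  tensors <- make_graph_tensors(g)
  masks <- list(train = rep(c(TRUE, FALSE), 10),
                val = rep(c(FALSE, TRUE), 10))
  X <- zscore_features(g, masks$train)
  Z <- matrix(rnorm(n * 4), n, 4)
  y <- ifelse(lab == "disease", 2L, 1L)
  model <- init_model("ikbrnet", p_in = 2, d = 4,
                      relations = g$relation_vocabulary, hidden = 8,
                      r_dim = 3, dropout = 0, seed = seed)
  cfg <- train_config(max_epochs = 40, patience = 40, dropout = 0,
                      hidden = 8, seed = seed)
  list(fit = train_model(model, tensors, Z, X, y, masks, cfg),
       tensors = tensors, Z = Z, X = X, y = y, masks = masks)
}

test_that("training learns a separable toy and is seed-deterministic", {
  r <- make_separable_fit(0)
  h <- r$fit$history
  expect_true(all(diff(h$train_loss[1:5]) < 0))
  expect_equal(h$train_acc[nrow(h)], 1.0)
  r2 <- make_separable_fit(0)
  expect_equal(r2$fit$history, r$fit$history, tolerance = 1e-12)
  expect_equal(r2$fit$model$params, r$fit$model$params, tolerance = 1e-12)
})

test_that("restored parameters reproduce the recorded best validation loss", {
  r <- make_separable_fit(1)
  fw <- ikbrnet:::model_forward(r$fit$model, r$tensors, r$Z, r$X,
                                train = FALSE)
  cw <- class_weights(base::table(r$y[r$masks$train | r$masks$val]))
  val_loss <- weighted_cross_entropy(fw$probs, r$y, cw, r$masks$val)
  expect_equal(val_loss, attr(r$fit$history, "best_val_loss"),
               tolerance = 1e-12)
  expect_lte(attr(r$fit$history, "best_epoch"),
             attr(r$fit$history, "stopped_epoch"))
})
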