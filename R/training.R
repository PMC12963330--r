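# Training: stratified 60/20/20 splitting, z-score feature standardization
# fitted on the training mask only, inverse-frequency class weights, and the
# full-batch Adam loop with validation-loss early stopping.

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.01).
#' @param weight_decay L2 weight decay (default 5e-4).
#' @param max_epochs maximum number of full-batch epochs (default 100).
#' @param patience early-stopping patience in epochs (default 20); training
#'   stops once the validation loss has failed to improve (by at least
#'   `min_delta`) for more than `patience` consecutive epochs.
#' @param min_delta minimum improvement of the validation loss to count as
#'   progress (default 1e-5).
#' @param dropout dropout probability (default 0.3).
#' @param hidden hidden width (default 32).
#' @param seed integer seed covering parameter initialization and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, weight_decay = 5e-4, max_epochs = 100L,
                         patience = 20L, min_delta = 1e-5, dropout = 0.3,
                         hidden = 32L, seed = 42L) {
  stopifnot(lr > 0, weight_decay >= 0, max_epochs > 0, patience > 0,
            patience <= max_epochs, hidden > 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 dropout = dropout, hidden = as.integer(hidden),
                 seed = as.integer(seed)), class = "train_config")
}

#' Standardize numeric node features on the training mask
#'
#' Each numeric feature column is transformed to `(x - mu) / sigma` with
#' `mu`, `sigma` (population SD) computed on training-mask nodes only, so no
#' information leaks from validation or test nodes. Zero-variance columns are
#' set to 0 with a warning. One-hot columns are untouched.
#'
#' @param graph a `knowledge_graph` (uses `features` and
#'   `numeric_feature_cols`).
#' @param train_mask logical or integer subset of nodes used to fit the
#'   transform.
#' @return standardized feature matrix.
#' @export
zscore_features <- function(graph, train_mask) {
  X <- graph$features
  if (is.logical(train_mask)) train_mask <- which(train_mask)
  if (length(train_mask) == 0)
    stop("zscore_features: empty training mask", call. = FALSE)
  num <- graph$numeric_feature_cols %||% seq_len(ncol(X))
  warned <- character(0)
  for (j in num) {
    v <- X[train_mask, j]
    mu <- mean(v)
    sg <- sqrt(mean((v - mu)^2))
    if (sg == 0) {
      X[, j] <- 0
      warned <- c(warned, colnames(X)[j] %||% as.character(j))
    } else X[, j] <- (X[, j] - mu) / sg
  }
  if (length(warned) > 0)
    warning("zscore_features: zero-variance column(s) set to 0: ",
            paste(warned, collapse = ", "), call. = FALSE)
  X
}

#' Stratified train/validation/test split
#'
#' Two-stage split matching the 60/20/20 protocol: 20\% of labeled nodes are
#' held out for testing, and the remaining 80\% is split 75/25 into training
#' and validation, per class, with largest-remainder rounding so per-class
#' proportions are within one node of exact. Shuffling within class is
#' seeded.
#'
#' @param labels character or factor vector of class labels (`NA` entries are
#'   excluded from all masks).
#' @param fractions length-3 numeric (train, val, test), default
#'   `c(0.6, 0.2, 0.2)`.
#' @param seed integer seed (default 42).
#' @return list of logical masks `train`, `val`, `test` over `labels`.
#' @export
stratified_split <- function(labels, fractions = c(0.6, 0.2, 0.2),
                             seed = 42L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  lab <- as.character(labels)
  idx_lab <- which(!is.na(lab))
  classes <- sort(unique(lab[idx_lab]))
  if (length(classes) < 2)
    stop("stratified_split: need >= 2 classes", call. = FALSE)
  n <- length(idx_lab)
  test_frac <- fractions[3]
  val_frac_of_rest <- fractions[2] / (fractions[1] + fractions[2])

  largest_remainder <- function(counts, frac, total) {
    raw <- counts * frac
    base <- floor(raw)
    extra <- total - sum(base)
    if (extra > 0) {
      o <- order(raw - base, decreasing = TRUE)
      base[o[seq_len(extra)]] <- base[o[seq_len(extra)]] + 1
    }
    base
  }

  counts <- vapply(classes, function(cl) sum(lab[idx_lab] == cl), numeric(1))
  n_test_by_class <- largest_remainder(counts, test_frac,
                                       round(test_frac * n))
  rest <- counts - n_test_by_class
  n_val_by_class <- largest_remainder(rest, val_frac_of_rest,
                                      round(val_frac_of_rest * sum(rest)))

  train <- val <- test <- rep(FALSE, length(lab))
  with_seed(seed, {
    for (k in seq_along(classes)) {
      members <- idx_lab[lab[idx_lab] == classes[k]]
      if (length(members) < 3) {
        warning("stratified_split: class '", classes[k],
                "' has < 3 members; all assigned to train", call. = FALSE)
        train[members] <- TRUE
        next
      }
      members <- members[sample.int(length(members))]
      nt <- n_test_by_class[k]; nv <- n_val_by_class[k]
      test[members[seq_len(nt)]] <- TRUE
      val[members[nt + seq_len(nv)]] <- TRUE
      train[members[-(seq_len(nt + nv))]] <- TRUE
    }
  })
  list(train = train, val = val, test = test)
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` for `N` total labeled nodes and `K` classes; the
#' class-frequency-weighted mean of the weights is 1 by construction
#' (`sum_c n_c w_c = N`).
#'
#' @param label_counts named vector of per-class counts (all positive).
#' @return named weight vector in the same order.
#' @export
class_weights <- function(label_counts) {
  if (any(label_counts <= 0))
    stop("class_weights: zero-count class", call. = FALSE)
  N <- sum(label_counts)
  K <- length(label_counts)
  setNames(as.numeric(N / (K * label_counts)), names(label_counts))
}

# Early-stopping bookkeeping: an epoch "improves" when the validation loss
# drops below the best by at least min_delta; training stops once the number
# of consecutive non-improving epochs exceeds `patience`.
es_init <- function() list(best_loss = Inf, best_epoch = 0L, strikes = 0L,
                           improved = FALSE, stop = FALSE)

es_update <- function(st, val_loss, epoch, min_delta, patience) {
  if (val_loss < st$best_loss - min_delta) {
    st$best_loss <- val_loss
    st$best_epoch <- epoch
    st$strikes <- 0L
    st$improved <- TRUE
  } else {
    st$strikes <- st$strikes + 1L
    st$improved <- FALSE
    st$stop <- st$strikes > patience
  }
  st
}

#' Train a model full-batch with early stopping
#'
#' Runs Adam (learning rate and weight decay from `config`) on full-batch
#' forward/backward passes, tracking the eval-mode validation loss. Training
#' stops when the validation loss has not improved by at least
#' `config$min_delta` for more than `config$patience` consecutive epochs, or
#' at `config$max_epochs`; parameters (and batch-norm buffers) are restored
#' from the best epoch.
#'
#' @param model an initialized `ikb_model`.
#' @param tensors output of [make_graph_tensors()].
#' @param Z Node2Vec embedding matrix (ignored for the GCN baseline).
#' @param X standardized feature matrix.
#' @param y integer labels in 1..2 (1 = health, 2 = disease; `NA` for
#'   unlabeled nodes).
#' @param masks list of logical masks `train`, `val` from
#'   [stratified_split()].
#' @param config a [train_config()].
#' @return list with `model` (trained, best-epoch state) and `history`
#'   (data.frame: epoch, train_loss, train_acc, val_loss, val_acc; plus
#'   `best_epoch`, `stopped_epoch`, `best_val_loss` attributes).
#' @export
train_model <- function(model, tensors, Z, X, y, masks,
                        config = train_config()) {
  class_w <- class_weights(base::table(y[masks$train | masks$val]))
  y_int <- y
  model$dropout <- config$dropout
  with_seed(config$seed, {
    state <- adam_init(model$params)
    es <- es_init()
    best <- list(params = model$params, buffers = model$buffers)
    hist <- vector("list", config$max_epochs)
    stopped <- config$max_epochs
    for (ep in seq_len(config$max_epochs)) {
      lg <- loss_and_grads(model, tensors, Z, X, y_int, class_w, masks$train,
                           train = TRUE)
      if (!is.finite(lg$loss))
        stop("train_model: training loss diverged (non-finite) at epoch ", ep,
             call. = FALSE)
      model$buffers <- lg$buffers
      st <- adam_step(model$params, lg$grads, state, config$lr,
                      config$weight_decay)
      model$params <- st$params
      state <- st$state

      ev <- model_forward(model, tensors, Z, X, train = FALSE)
      val_loss <- weighted_cross_entropy(ev$probs, y_int, class_w, masks$val)
      pred <- max.col(ev$probs)
      hist[[ep]] <- data.frame(
        epoch = ep, train_loss = lg$loss,
        train_acc = mean((max.col(lg$probs) == y_int)[masks$train]),
        val_loss = val_loss,
        val_acc = mean((pred == y_int)[masks$val]))

      es <- es_update(es, val_loss, ep, config$min_delta, config$patience)
      if (es$improved)
        best <- list(params = model$params, buffers = model$buffers)
      if (es$stop) { stopped <- ep; break }
    }
    model$params <- best$params
    model$buffers <- best$buffers
    history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    attr(history, "best_epoch") <- es$best_epoch
    attr(history, "stopped_epoch") <- stopped
    attr(history, "best_val_loss") <- es$best_loss
    list(model = model, history = history)
  })
}

#' End-to-end fit on a knowledge graph
#'
#' Convenience wrapper: stratified split over the labeled virus universe,
#' train-mask z-scoring, class weights, model initialization and training.
#' Supervision is restricted to Virus/Phage nodes (bacteria, lineage and site
#' nodes participate in message passing only).
#'
#' @param graph a `knowledge_graph` with labels.
#' @param Z Node2Vec embedding matrix aligned to `graph$nodes`.
#' @param model_type "ikbrnet", "gat" or "gcn".
#' @param config a [train_config()].
#' @param split_seed seed of the stratified split (default 42, independent of
#'   the training seed).
#' @param label_universe node types carrying supervision (default
#'   `c("Virus", "Phage")`).
#' @return list with `model`, `history`, `masks`, `X` (standardized
#'   features), `y`, `tensors`.
#' @export
fit_model <- function(graph, Z, model_type = "ikbrnet",
                      config = train_config(), split_seed = 42L,
                      label_universe = c("Virus", "Phage")) {
  lab <- graph$labels
  lab[!(graph$nodes$type %in% label_universe)] <- NA
  masks <- stratified_split(lab, seed = split_seed)
  X <- zscore_features(graph, masks$train)
  y <- match(graph$labels, c("health", "disease"))
  tensors <- make_graph_tensors(graph)
  d <- if (is.null(Z)) ncol(X) else ncol(Z)
  model <- init_model(model_type, p_in = ncol(X), d = d,
                      relations = graph$relation_vocabulary,
                      hidden = config$hidden, dropout = config$dropout,
                      seed = config$seed)
  fit <- train_model(model, tensors, Z, X, y, masks, config)
  c(fit, list(masks = masks, X = X, y = y, tensors = tensors))
}
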