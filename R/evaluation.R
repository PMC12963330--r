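# Evaluation: confusion-matrix metric bundle (positive class = disease),
# ROC-AUC (Mann-Whitney, half credit for ties), PR-AUC (step curve),
# link-prediction protocol (sampled negatives for ROC/PR; filtered ranking
# against all type-valid candidates for Hits@K and MRR), and site-level mean
# disease scores.

#' Classification metrics from confusion counts
#'
#' Positive class = disease. Per-class precision/recall/F1 are combined by
#' support-weighted averaging, which makes `weighted_recall == accuracy` an
#' identity. MCC factors of zero yield MCC = 0.
#'
#' @param tp,fn,tn,fp non-negative confusion counts.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `mcc`,
#'   `weighted_precision`, `weighted_recall`, `weighted_f1`, and the counts.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  n <- tp + fn + tn + fp
  if (n == 0) stop("confusion_metrics: empty confusion matrix", call. = FALSE)
  pos <- tp + fn; neg <- tn + fp
  if (pos == 0 || neg == 0)
    stop("confusion_metrics: need at least one positive and one negative",
         call. = FALSE)
  sens <- tp / pos
  spec <- tn / neg
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  prec_pos <- if (tp + fp == 0) 0 else tp / (tp + fp)
  prec_neg <- if (tn + fn == 0) 0 else tn / (tn + fn)
  f1_pos <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  f1_neg <- if (2 * tn + fn + fp == 0) 0 else 2 * tn / (2 * tn + fn + fp)
  wp <- pos / n; wn <- neg / n
  list(accuracy = (tp + tn) / n, sensitivity = sens, specificity = spec,
       mcc = mcc,
       weighted_precision = wp * prec_pos + wn * prec_neg,
       weighted_recall = wp * sens + wn * spec,
       weighted_f1 = wp * f1_pos + wn * f1_neg,
       counts = c(tp = tp, fn = fn, tn = tn, fp = fp))
}

#' ROC-AUC (Mann-Whitney)
#'
#' `AUC = P(score_pos > score_neg) + 0.5 * P(tie)`, computed exactly over all
#' positive-negative pairs via midranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 (or logical) labels; both classes must be present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_auc: both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks give half credit for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' PR-AUC (area under the precision-recall step curve)
#'
#' Thresholds are traversed at distinct score values (ties grouped); the area
#' is accumulated as `sum (R_t - R_{t-1}) * P_t` over the step curve.
#'
#' @inheritParams roc_auc
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("pr_auc: no positives", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index within each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Ranking metrics from a vector of ranks
#' @param ranks integer (or numeric) ranks of the true candidates.
#' @param k cutoff for Hits@K.
#' @return list with `mrr` and `hits_at_k`.
#' @export
ranking_metrics <- function(ranks, k = 10L) {
  list(mrr = mean(1 / ranks), hits_at_k = mean(ranks <= k))
}

#' Link-prediction evaluation for INFECTS edges
#'
#' Edge score = `sigmoid(<hidden[phage], hidden[bacterium]>)` on the model's
#' final hidden representations. ROC-AUC and PR-AUC use one uniformly sampled
#' type-valid non-edge negative per positive (seeded). Hits@K and MRR rank
#' each test positive against all type-valid candidate bacteria for that
#' phage under the filtered protocol (other known positives removed);
#' tied scores receive average ranks.
#'
#' @param hidden n x h matrix of final hidden node representations (rows
#'   aligned to `graph$nodes`).
#' @param graph a `knowledge_graph`.
#' @param test_pairs data.frame (`phage`, `bacterium` taxon ids) of held-out
#'   positives (must be absent from the training graph's INFECTS edges).
#' @param known_pairs data.frame of all known positives (train + test) used
#'   for negative sampling and rank filtering; defaults to `test_pairs` plus
#'   the graph's INFECTS edges.
#' @param k Hits@K cutoff (default 10).
#' @param seed seed for negative sampling.
#' @param filtered remove known positives from the candidate ranking
#'   (default TRUE).
#' @return list with `roc_auc`, `pr_auc`, `hits_at_k`, `mrr`, `n_pos`.
#' @export
link_prediction_eval <- function(hidden, graph, test_pairs,
                                 known_pairs = NULL, k = 10L, seed = 42L,
                                 filtered = TRUE) {
  ids <- graph$nodes$id
  bact <- which(graph$nodes$type == "Bacteria")
  if (is.null(known_pairs)) {
    tr <- graph$edges[graph$edges$relation == "INFECTS", , drop = FALSE]
    known_pairs <- rbind(
      data.frame(phage = ids[tr$src], bacterium = ids[tr$dst],
                 stringsAsFactors = FALSE),
      test_pairs[, c("phage", "bacterium")])
  }
  pi_ <- match(test_pairs$phage, ids)
  bi <- match(test_pairs$bacterium, ids)
  if (anyNA(pi_) || anyNA(bi))
    stop("link_prediction_eval: test pair references unknown node",
         call. = FALSE)
  known_key <- paste(known_pairs$phage, known_pairs$bacterium)

  score <- function(p, b) sigmoid(rowSums(hidden[p, , drop = FALSE] *
                                            hidden[b, , drop = FALSE]))
  pos_scores <- score(pi_, bi)

  # one uniformly sampled type-valid non-edge negative per positive
  phage <- which(graph$nodes$type == "Phage")
  if (length(phage) == 0 || length(bact) == 0)
    stop("link_prediction_eval: graph has no phage or no bacteria nodes",
         call. = FALSE)
  neg_scores <- with_seed(seed, {
    vapply(seq_along(pi_), function(i) {
      for (try_ in 1:1000) {
        p2 <- phage[sample.int(length(phage), 1L)]
        b2 <- bact[sample.int(length(bact), 1L)]
        if (!paste(ids[p2], ids[b2]) %in% known_key)
          return(score(p2, b2))
      }
      NA_real_
    }, numeric(1))
  })
  keep <- !is.na(neg_scores)
  if (any(!keep))
    warning("link_prediction_eval: ", sum(!keep),
            " negative draws failed (graph nearly complete); skipped",
            call. = FALSE)
  sc <- c(pos_scores[keep], neg_scores[keep])
  lb <- c(rep(1L, sum(keep)), rep(0L, sum(keep)))

  # filtered ranking against all type-valid candidates per phage
  ranks <- vapply(seq_along(pi_), function(i) {
    cand <- bact
    if (filtered) {
      drop_ <- paste(ids[pi_[i]], ids[cand]) %in% known_key &
        cand != bi[i]
      cand <- cand[!drop_]
    }
    if (length(cand) <= 1) return(NA_real_)
    s <- score(rep(pi_[i], length(cand)), cand)
    rank(-s, ties.method = "average")[match(bi[i], cand)]
  }, numeric(1))
  if (anyNA(ranks))
    warning("link_prediction_eval: ", sum(is.na(ranks)),
            " phage(s) had no candidate negatives for ranking; skipped",
            call. = FALSE)
  ranks <- ranks[!is.na(ranks)]

  c(list(roc_auc = roc_auc(sc, lb), pr_auc = pr_auc(sc, lb)),
    ranking_metrics(ranks, k = k), list(n_pos = length(pi_)))
}

#' Site-level mean disease scores
#'
#' For each site, the mean predicted disease probability over viral taxa
#' (Virus and Phage nodes) enriched at that site. Sites with no enriched
#' viruses are omitted with a warning.
#'
#' @param probs n x 2 probability matrix (columns health, disease) aligned to
#'   `graph$nodes`.
#' @param graph a `knowledge_graph`.
#' @return named numeric vector, one mean disease probability per site.
#' @export
site_disease_scores <- function(probs, graph) {
  viral <- graph$nodes$type %in% c("Virus", "Phage")
  en <- graph$edges[graph$edges$relation == "ENRICHED_AT", , drop = FALSE]
  out <- numeric(0)
  for (s in graph$sites) {
    sn <- match(paste0("SITE:", s), graph$nodes$id)
    members <- unique(en$src[en$dst == sn])
    members <- members[viral[members]]
    if (length(members) == 0) {
      warning("site_disease_scores: no enriched viruses at site '", s, "'",
              call. = FALSE)
      next
    }
    out[s] <- mean(probs[members, 2])
  }
  out
}

#' Classification metric bundle from scores on a mask
#'
#' Applies argmax classification and assembles [confusion_metrics()] plus
#' ROC-AUC of the disease probability.
#'
#' @param probs n x 2 probability matrix (columns health, disease).
#' @param y integer labels (1 = health, 2 = disease).
#' @param mask logical or integer node subset.
#' @return `confusion_metrics()` list with an additional `auc_roc` element.
#' @export
classification_metrics <- function(probs, y, mask) {
  if (is.logical(mask)) mask <- which(mask)
  pred <- max.col(probs[mask, , drop = FALSE])
  truth <- y[mask]
  m <- confusion_metrics(tp = sum(pred == 2 & truth == 2),
                         fn = sum(pred == 1 & truth == 2),
                         tn = sum(pred == 1 & truth == 1),
                         fp = sum(pred == 2 & truth == 1))
  m$auc_roc <- roc_auc(probs[mask, 2], truth == 2)
  m
}
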