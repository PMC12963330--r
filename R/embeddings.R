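# Node2Vec structural embeddings: second-order biased random walks over the
# untyped, undirected graph topology, followed by skip-gram with negative
# sampling. Relation semantics deliberately do not enter this view; they are
# handled by the relation-aware GNN.

#' Node2Vec walk and skip-gram configuration
#'
#' @param p return parameter (unnormalized weight 1/p of stepping back to the
#'   previous node).
#' @param q in-out parameter (weight 1/q of stepping to a node not adjacent
#'   to the previous one; common neighbors get weight 1).
#' @param walks_per_node number of walks started at every node.
#' @param walk_length maximum number of nodes per walk.
#' @param window skip-gram context window half-width.
#' @param dim embedding dimension d.
#' @param epochs skip-gram epochs over the corpus.
#' @param negatives negative samples per positive pair.
#' @param lr initial skip-gram learning rate (linearly decayed).
#' @param seed integer seed.
#' @return an object of class `walk_config`.
#' @export
walk_config <- function(p = 1.0, q = 1.0, walks_per_node = 10L,
                        walk_length = 80L, window = 5L, dim = 32L,
                        epochs = 5L, negatives = 5L, lr = 0.025, seed = 42L) {
  if (p <= 0 || q <= 0) stop("walk_config: p and q must be > 0", call. = FALSE)
  if (dim < 2) stop("walk_config: dim must be >= 2", call. = FALSE)
  if (walk_length < 2) stop("walk_config: walk_length must be >= 2",
                            call. = FALSE)
  structure(list(p = p, q = q, walks_per_node = as.integer(walks_per_node),
                 walk_length = as.integer(walk_length),
                 window = as.integer(window), dim = as.integer(dim),
                 epochs = as.integer(epochs), negatives = as.integer(negatives),
                 lr = lr, seed = as.integer(seed)),
            class = "walk_config")
}

# undirected, untyped, deduplicated adjacency in CSR form (0-based, sorted)
graph_csr <- function(graph) {
  n <- nrow(graph$nodes)
  e <- graph$edges
  if (nrow(e) > 0) {
    a <- pmin(e$src, e$dst); b <- pmax(e$src, e$dst)
    keep <- a != b
    key <- unique((a[keep] - 1) * n + (b[keep] - 1))
    a <- key %/% n + 1; b <- key %% n + 1
    src <- c(a, b); dst <- c(b, a)
    o <- order(src, dst)
    src <- src[o]; dst <- dst[o]
  } else src <- dst <- integer(0)
  ptr <- c(0L, cumsum(tabulate(src, nbins = n)))
  list(idx = as.integer(dst - 1L), ptr = as.integer(ptr), n = n)
}

#' Generate second-order biased random walks
#'
#' Edges are treated as undirected and untyped; transition weights follow the
#' Node2Vec scheme (1/p back to the previous node, 1 to a common neighbor of
#' previous and current, 1/q otherwise). Isolated nodes yield length-1 walks.
#'
#' @param graph a `knowledge_graph`.
#' @param cfg a [walk_config()].
#' @return list of integer vectors of node indices (attribute `n_nodes`).
#' @export
generate_walks <- function(graph, cfg = walk_config()) {
  csr <- graph_csr(graph)
  walks <- cpp_node2vec_walks(csr$idx, csr$ptr, cfg$p, cfg$q,
                              cfg$walks_per_node, cfg$walk_length, cfg$seed)
  attr(walks, "n_nodes") <- csr$n
  walks
}

#' Train skip-gram embeddings over a walk corpus
#'
#' Skip-gram with negative sampling (unigram^0.75 negative distribution,
#' linearly decayed learning rate). Deterministic given the config seed.
#'
#' @param walks walk corpus from [generate_walks()].
#' @param cfg a [walk_config()].
#' @param n_nodes number of nodes (defaults to the corpus attribute).
#' @param node_ids optional row names for the returned matrix.
#' @return numeric matrix `n_nodes x dim`, one embedding row per node.
#' @export
train_skipgram <- function(walks, cfg = walk_config(),
                           n_nodes = attr(walks, "n_nodes"),
                           node_ids = NULL) {
  if (cfg$dim < 1) stop("train_skipgram: dim must be >= 1", call. = FALSE)
  if (length(walks) == 0) stop("train_skipgram: empty walk corpus",
                               call. = FALSE)
  Z <- cpp_sgns_train(walks, as.integer(n_nodes), cfg$dim, cfg$window,
                      cfg$negatives, cfg$epochs, cfg$lr, cfg$seed)
  if (!is.null(node_ids)) rownames(Z) <- node_ids
  Z
}

#' Compute Node2Vec embeddings for all graph nodes
#'
#' Convenience wrapper: [generate_walks()] + [train_skipgram()].
#'
#' @param graph a `knowledge_graph`.
#' @param cfg a [walk_config()].
#' @return embedding matrix with one row per node (row names = node ids).
#' @export
node2vec_embeddings <- function(graph, cfg = walk_config()) {
  walks <- generate_walks(graph, cfg)
  train_skipgram(walks, cfg, node_ids = graph$nodes$id)
}

#' Write embeddings as TSV (node_id + d floats)
#' @param Z embedding matrix with row names.
#' @param path output TSV path.
#' @param cfg optional `walk_config` recorded in the header comment.
#' @export
write_embeddings <- function(Z, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg))
    writeLines(sprintf("# dim=%d config_hash=%s", ncol(Z), config_hash(cfg)),
               con)
  df <- data.frame(node_id = rownames(Z), Z, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# stable short hash of a config list (no external digest dependency);
# output-path fields are excluded so identical settings hash identically
# regardless of where artifacts land
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out <- NULL
  s <- paste(deparse(cfg), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}
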