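# Shared fixtures, built in code.

# Minimal microbe table: nv viruses (first n_phage of them phages hosted on
# bacterium 1), nb bacteria, deterministic under `seed`.
make_toy_table <- function(nv = 3, nb = 3, n_phage = 1, n_samples = 8,
                           sites = c("Dental Plaque", "Tongue"),
                           seed = 1) {
  withr::local_seed(seed)
  n <- nv + nb
  taxon <- c(sprintf("V%d", seq_len(nv)), sprintf("B%d", seq_len(nb)))
  name <- c(sprintf("virus%d", seq_len(nv)), sprintf("bact%d", seq_len(nb)))
  kingdom <- c(rep("Virus", nv), rep("Bacteria", nb))
  is_phage <- c(rep(1L, n_phage), rep(0L, nv - n_phage), rep(0L, nb))
  host <- rep(NA_character_, n)
  if (n_phage > 0) host[seq_len(n_phage)] <- name[nv + 1]
  rec <- data.frame(
    Taxon = taxon, Name = name, Kingdom = kingdom, Is_Phage = is_phage,
    Predicted_host = host,
    Lineage = c(paste("Viruses", "Fam1", name[seq_len(nv)], sep = ";"),
                paste("Bacteria", "Phy1", name[nv + seq_len(nb)], sep = ";")),
    Genome_Size_bp = c(rep(5e4, nv), rep(2e6, nb)),
    GC_Content = runif(n, 0.3, 0.7),
    Mean_Abundance = runif(n), stringsAsFactors = FALSE)
  for (s in sites) {
    rec[[paste0("Abund_", gsub(" ", "_", s))]] <- runif(n)
    rec[[paste0("Enriched_", gsub(" ", "_", s))]] <- 0L
  }
  rec$Enriched_Dental_Plaque[1] <- 1L
  rec[[paste0("Enriched_", gsub(" ", "_", sites[2]))]][2:n] <- 1L
  m <- matrix(runif(n * n_samples), n, n_samples,
              dimnames = list(taxon, sprintf("S%d", seq_len(n_samples))))
  structure(list(records = rec, sample_matrix = m, sites = sites),
            class = "microbe_table")
}

# Bare knowledge graph from an explicit undirected edge list (all CO_OCCURS),
# for walk/embedding tests.
make_bare_graph <- function(n, edge_mat) {
  edges <- if (length(edge_mat) > 0)
    data.frame(src = c(edge_mat[, 1], edge_mat[, 2]),
               dst = c(edge_mat[, 2], edge_mat[, 1]),
               relation = "CO_OCCURS", stringsAsFactors = FALSE)
  else data.frame(src = integer(0), dst = integer(0),
                  relation = character(0))
  structure(list(
    nodes = data.frame(id = sprintf("n%02d", seq_len(n)), type = "Bacteria",
                       stringsAsFactors = FALSE),
    features = matrix(0, n, 2), numeric_feature_cols = 1:2,
    edges = edges, labels = rep(NA_character_, n),
    relation_vocabulary = c("INFECTS", "ENRICHED_AT", "IS_A", "CO_OCCURS"),
    sites = character(0), report = list()), class = "knowledge_graph")
}

# Two k-cliques joined by a single bridge edge.
two_clique_graph <- function(k = 6) {
  c1 <- t(combn(seq_len(k), 2))
  c2 <- t(combn(k + seq_len(k), 2))
  make_bare_graph(2 * k, rbind(c1, c2, c(1, k + 1)))
}

# Small built knowledge graph with all relation types, via the real builder.
toy_knowledge_graph <- function(seed = 1, nv = 6, nb = 4, n_phage = 3) {
  tb <- make_toy_table(nv = nv, nb = nb, n_phage = n_phage, seed = seed)
  co <- suppressWarnings(spearman_cooccurrence(tb$sample_matrix,
                                               rho_threshold = 0.2,
                                               alpha = 0.9))
  build_graph(tb, co)
}

# independent brute-force ROC-AUC oracle: all positive-negative pairs
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# independent Spearman oracle: explicit rank vectors + textbook Pearson
brute_force_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
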