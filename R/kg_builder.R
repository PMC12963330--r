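# Knowledge-graph construction: parse microbiome tables, infer co-occurrence
# edges by thresholded Spearman correlation, and assemble a typed graph of
# Bacteria / Virus / Phage / Site nodes with INFECTS / ENRICHED_AT / IS_A /
# CO_OCCURS edges, per-node feature vectors and disease labels.

RELATIONS <- c("INFECTS", "ENRICHED_AT", "IS_A", "CO_OCCURS")

#' Parse a microbiome taxon table and its sample matrix
#'
#' Reads the CSV contract of [write_microbe_table()]: one row per taxon with
#' `Taxon`, `Kingdom`, `Is_Phage`, `Predicted_host`, `Lineage`
#' (semicolon-delimited ranks), `Genome_Size_bp`, `GC_Content`,
#' `Mean_Abundance`, one `Abund_<site>` and one `Enriched_<site>` column per
#' site (spaces in site names encoded as underscores), plus a companion
#' samples CSV keyed by `Taxon`.
#'
#' @param table_path taxon table CSV.
#' @param samples_path taxa x samples CSV.
#' @return a `microbe_table` (records + aligned sample matrix + site names).
#' @export
parse_microbe_table <- function(table_path, samples_path) {
  rec <- as.data.frame(data.table::fread(table_path))
  for (col in c("Taxon", "Kingdom"))
    if (!col %in% names(rec))
      stop(sprintf("parse_microbe_table: missing required column '%s'", col),
           call. = FALSE)
  if (anyDuplicated(rec$Taxon))
    stop("parse_microbe_table: duplicate taxon_id in 'Taxon' column",
         call. = FALSE)
  ab_cols <- grep("^Abund_", names(rec), value = TRUE)
  sites <- gsub("_", " ", sub("^Abund_", "", ab_cols))
  num_cols <- c("Genome_Size_bp", "GC_Content", "Mean_Abundance", ab_cols)
  num_cols <- intersect(num_cols, names(rec))
  if (any(unlist(rec[ab_cols]) < 0, na.rm = TRUE) ||
      any(rec$Mean_Abundance < 0, na.rm = TRUE))
    stop("parse_microbe_table: negative abundance", call. = FALSE)
  if (!is.null(rec$GC_Content) &&
      any(rec$GC_Content < 0 | rec$GC_Content > 1, na.rm = TRUE))
    stop("parse_microbe_table: GC_Content outside [0, 1]", call. = FALSE)
  if (is.null(rec$Is_Phage)) rec$Is_Phage <- 0L
  if (any(rec$Is_Phage == 1L & rec$Kingdom != "Virus"))
    stop("parse_microbe_table: Is_Phage set on a non-Virus record",
         call. = FALSE)
  if (!is.null(rec$Predicted_host)) {
    rec$Predicted_host[rec$Predicted_host %in% c("", "NA")] <- NA_character_
    if (any(!is.na(rec$Predicted_host) & rec$Is_Phage != 1L))
      stop("parse_microbe_table: Predicted_host on a non-phage record",
           call. = FALSE)
  } else rec$Predicted_host <- NA_character_

  sm <- as.data.frame(data.table::fread(samples_path))
  if (!"Taxon" %in% names(sm))
    stop("parse_microbe_table: missing required column 'Taxon' in samples file",
         call. = FALSE)
  m <- as.matrix(sm[, setdiff(names(sm), "Taxon"), drop = FALSE])
  rownames(m) <- sm$Taxon
  missing <- setdiff(rec$Taxon, rownames(m))
  if (length(missing) > 0)
    stop("parse_microbe_table: taxa absent from samples file: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  m <- m[rec$Taxon, , drop = FALSE]
  if (any(m < 0)) stop("parse_microbe_table: negative abundance in samples",
                       call. = FALSE)
  structure(list(records = rec, sample_matrix = m, sites = sites),
            class = "microbe_table")
}

#' Significant co-occurrence pairs by Spearman correlation
#'
#' For every unordered taxon pair computes Spearman's rho (average ranks for
#' ties) across samples and a two-sided p-value via the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (`|rho| = 1` is assigned p = 0). A pair is emitted iff `|rho| >
#' rho_threshold` and `p < alpha`. Constant rows (zero rank variance) are
#' excluded with one summary warning.
#'
#' @param sample_matrix taxa x samples numeric matrix (>= 4 samples).
#' @param rho_threshold correlation magnitude threshold (default 0.5).
#' @param alpha significance threshold on the two-sided p-value (default 0.01).
#' @return data.frame with columns `taxon_a`, `taxon_b` (lexicographic order),
#'   `rho`, `p_value`; one row per significant unordered pair.
#' @export
spearman_cooccurrence <- function(sample_matrix, rho_threshold = 0.5,
                                  alpha = 0.01) {
  m <- as.matrix(sample_matrix)
  ns <- ncol(m)
  if (ns < 4) stop("spearman_cooccurrence: need >= 4 samples", call. = FALSE)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  rk <- t(apply(m, 1L, rank))          # average ranks for ties
  const <- apply(rk, 1L, function(r) all(r == r[1]))
  if (any(const))
    warning("spearman_cooccurrence: skipping ", sum(const),
            " constant row(s): ", paste(head(ids[const], 5), collapse = ", "),
            call. = FALSE)
  keep <- which(!const)
  if (length(keep) < 2)
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      rho = numeric(0), p_value = numeric(0)))
  R <- stats::cor(t(rk[keep, , drop = FALSE]))    # Pearson on ranks
  R[R > 1] <- 1; R[R < -1] <- -1
  ut <- which(upper.tri(R), arr.ind = TRUE)
  rho <- R[ut]
  tstat <- rho * sqrt((ns - 2) / pmax(1 - rho^2, 0))
  p <- ifelse(abs(rho) >= 1, 0, 2 * stats::pt(-abs(tstat), df = ns - 2))
  sel <- abs(rho) > rho_threshold & p < alpha
  a <- ids[keep][ut[sel, 1]]; b <- ids[keep][ut[sel, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(taxon_a = a, taxon_b = b, rho = rho[sel],
                    p_value = p[sel], stringsAsFactors = FALSE)
  out[order(out$taxon_a, out$taxon_b), , drop = FALSE]
}

#' Assemble the heterogeneous knowledge graph
#'
#' Creates one node per taxon (type `Phage` if the phage flag is set, else
#' `Virus`/`Bacteria` by kingdom), auxiliary lineage nodes for every lineage
#' prefix above the taxon, and one `Site` node per site. Edges:
#' `INFECTS` (phage -> resolvable bacterial host; unresolvable hosts are
#' dropped and counted in the build report), `ENRICHED_AT` (microbe -> site),
#' `IS_A` (taxon -> parent lineage node -> ... chain), and `CO_OCCURS`
#' (both directions per significant pair). Microbe features are
#' `[genome_size, gc_content, mean_abundance, per-site abundances]` plus a
#' one-hot block over top-level lineage ranks and the Site marker; lineage and
#' site nodes carry zero numeric features and their one-hot marker.
#'
#' @param table a `microbe_table`.
#' @param cooccurrence data.frame from [spearman_cooccurrence()] (may be
#'   empty).
#' @param infects_pairs optional data.frame (`phage`, `bacterium` taxon ids)
#'   overriding the table's `Predicted_host` column; used to exclude held-out
#'   test pairs from the training graph.
#' @return an object of class `knowledge_graph` with elements `nodes`
#'   (data.frame: id, type), `features` (matrix), `edges` (data.frame: src,
#'   dst, relation, as node indices + relation name), `labels`,
#'   `relation_vocabulary`, `sites`, and `report`.
#' @export
build_graph <- function(table, cooccurrence = NULL, infects_pairs = NULL) {
  rec <- table$records
  sites <- table$sites
  n_tax <- nrow(rec)
  node_type <- ifelse(rec$Is_Phage == 1L, "Phage",
                      ifelse(rec$Kingdom == "Virus", "Virus", "Bacteria"))

  # lineage nodes: every strict prefix of each taxon lineage
  lin <- strsplit(rec$Lineage %||% rec$Kingdom, ";", fixed = TRUE)
  lin_ids <- character(0)
  for (l in lin) {
    k <- length(l)
    if (k >= 2)
      lin_ids <- c(lin_ids,
                   vapply(seq_len(k - 1),
                          function(j) paste(l[seq_len(j)], collapse = ";"),
                          character(1)))
  }
  lin_ids <- unique(lin_ids)
  site_ids <- paste0("SITE:", sites)

  ids <- c(rec$Taxon, paste0("LIN:", lin_ids), site_ids)
  types <- c(node_type, rep("Lineage", length(lin_ids)),
             rep("Site", length(sites)))
  idx <- setNames(seq_along(ids), ids)
  n <- length(ids)

  # features ---------------------------------------------------------------
  ab_cols <- paste0("Abund_", gsub(" ", "_", sites))
  num_names <- c("genome_size", "gc_content", "mean_abundance",
                 paste0("abund_", gsub(" ", "_", sites)))
  toplevel <- vapply(lin, `[`, character(1), 1L)
  onehot_levels <- c(sort(unique(toplevel)), "Lineage", "Site")
  p_num <- length(num_names)
  X <- matrix(0, n, p_num + length(onehot_levels),
              dimnames = list(ids, c(num_names, paste0("is_", onehot_levels))))
  X[seq_len(n_tax), 1] <- rec$Genome_Size_bp
  X[seq_len(n_tax), 2] <- rec$GC_Content
  X[seq_len(n_tax), 3] <- rec$Mean_Abundance
  for (j in seq_along(sites))
    X[seq_len(n_tax), 3 + j] <- rec[[ab_cols[j]]]
  X[cbind(seq_len(n_tax), p_num + match(toplevel, onehot_levels))] <- 1
  lin_top <- vapply(strsplit(lin_ids, ";", fixed = TRUE), `[`, character(1), 1L)
  if (length(lin_ids) > 0) {
    lin_rows <- n_tax + seq_along(lin_ids)
    X[cbind(lin_rows, p_num + match(lin_top, onehot_levels))] <- 1
    X[lin_rows, p_num + match("Lineage", onehot_levels)] <- 1
  }
  X[n_tax + length(lin_ids) + seq_along(sites),
    p_num + match("Site", onehot_levels)] <- 1

  # edges ------------------------------------------------------------------
  src <- integer(0); dst <- integer(0); rel <- character(0)
  add_edges <- function(s, d, r) {
    src <<- c(src, s); dst <<- c(dst, d); rel <<- c(rel, rep(r, length(s)))
  }

  dropped_hosts <- 0L
  if (is.null(infects_pairs)) {
    ph <- which(rec$Is_Phage == 1L & !is.na(rec$Predicted_host))
    if (length(ph) > 0) {
      # Predicted_host holds a taxon *name*; resolve to a Bacteria node
      host_key <- if ("Name" %in% names(rec)) rec$Name else rec$Taxon
      hm <- match(rec$Predicted_host[ph], host_key)
      ok <- !is.na(hm) & node_type[pmax(hm, 1L)] == "Bacteria"
      ok[is.na(ok)] <- FALSE
      dropped_hosts <- sum(!ok)
      add_edges(ph[ok], hm[ok], "INFECTS")
    }
  } else {
    pi_ <- match(infects_pairs$phage, rec$Taxon)
    bi <- match(infects_pairs$bacterium, rec$Taxon)
    ok <- !is.na(pi_) & !is.na(bi) & node_type[pmax(bi, 1L)] == "Bacteria" &
      node_type[pmax(pi_, 1L)] == "Phage"
    ok[is.na(ok)] <- FALSE
    dropped_hosts <- sum(!ok)
    add_edges(pi_[ok], bi[ok], "INFECTS")
  }

  en_cols <- paste0("Enriched_", gsub(" ", "_", sites))
  for (j in seq_along(sites)) {
    if (!en_cols[j] %in% names(rec)) next
    who <- which(rec[[en_cols[j]]] == 1L)
    if (length(who) > 0)
      add_edges(who, rep(idx[site_ids[j]], length(who)), "ENRICHED_AT")
  }

  # IS_A chains: taxon -> immediate parent prefix; prefix -> its parent
  for (i in seq_len(n_tax)) {
    l <- lin[[i]]
    if (length(l) >= 2) {
      parent <- paste0("LIN:", paste(l[-length(l)], collapse = ";"))
      add_edges(i, idx[[parent]], "IS_A")
    }
  }
  if (length(lin_ids) > 0) {
    parts <- strsplit(lin_ids, ";", fixed = TRUE)
    for (j in seq_along(lin_ids)) {
      l <- parts[[j]]
      if (length(l) >= 2) {
        parent <- paste0("LIN:", paste(l[-length(l)], collapse = ";"))
        add_edges(idx[[paste0("LIN:", lin_ids[j])]], idx[[parent]], "IS_A")
      }
    }
  }

  if (!is.null(cooccurrence) && nrow(cooccurrence) > 0) {
    a <- idx[cooccurrence$taxon_a]; b <- idx[cooccurrence$taxon_b]
    ok <- !is.na(a) & !is.na(b)
    if (any(!ok))
      stop("build_graph: co-occurrence edges reference unknown taxa",
           call. = FALSE)
    add_edges(c(a, b), c(b, a), "CO_OCCURS")  # both directions
  }

  edges <- data.frame(src = src, dst = dst, relation = rel,
                      stringsAsFactors = FALSE)
  report <- list(
    n_nodes = n, n_taxa = n_tax, dropped_hosts = dropped_hosts,
    edge_counts = as.list(base::table(factor(edges$relation,
                                             levels = RELATIONS))))

  g <- structure(list(
    nodes = data.frame(id = ids, type = types, stringsAsFactors = FALSE),
    features = X, numeric_feature_cols = seq_len(p_num),
    edges = edges, labels = NULL,
    relation_vocabulary = RELATIONS, sites = sites, report = report),
    class = "knowledge_graph")
  g$labels <- assign_disease_labels(g)
  g
}

#' Assign disease/health labels from dental-plaque enrichment
#'
#' A microbe node is labeled `disease` iff it has an `ENRICHED_AT` edge to the
#' Dental Plaque site node (regardless of other enrichments); all other
#' microbe nodes are `health`. Site and lineage nodes are unlabeled (`NA`).
#'
#' @param graph a `knowledge_graph`.
#' @return named character vector over all nodes (`NA` for non-microbes).
#' @export
assign_disease_labels <- function(graph) {
  plaque <- match("SITE:Dental Plaque", graph$nodes$id)
  if (is.na(plaque))
    stop("assign_disease_labels: no 'Dental Plaque' site node in graph",
         call. = FALSE)
  microbe <- graph$nodes$type %in% c("Bacteria", "Virus", "Phage")
  lab <- rep(NA_character_, nrow(graph$nodes))
  lab[microbe] <- "health"
  en <- graph$edges[graph$edges$relation == "ENRICHED_AT" &
                      graph$edges$dst == plaque, ]
  lab[unique(en$src)] <- "disease"
  setNames(lab, graph$nodes$id)
}

#' Write a knowledge graph as TSV + JSON report
#'
#' @param graph a `knowledge_graph`.
#' @param nodes_path nodes TSV (id, type, label, then feature columns).
#' @param edges_path edges TSV (src id, relation, dst id).
#' @param report_path optional JSON build report.
#' @export
write_graph <- function(graph, nodes_path, edges_path, report_path = NULL) {
  nd <- data.frame(id = graph$nodes$id, type = graph$nodes$type,
                   label = graph$labels, graph$features, check.names = FALSE)
  data.table::fwrite(nd, nodes_path, sep = "\t")
  ed <- data.frame(src = graph$nodes$id[graph$edges$src],
                   relation = graph$edges$relation,
                   dst = graph$nodes$id[graph$edges$dst])
  data.table::fwrite(ed, edges_path, sep = "\t")
  if (!is.null(report_path))
    jsonlite::write_json(graph$report, report_path, auto_unbox = TRUE)
  invisible(nodes_path)
}
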