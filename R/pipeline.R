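# Pipeline driver: one flat run configuration shared by all stages, staged
# commands (simulate -> build-graph -> embed -> train -> evaluate -> report)
# with file artifacts between stages, and a small CLI wrapper.

#' Default run configuration
#'
#' One flat key-value configuration for the whole pipeline; sections of it
#' feed [synth_config()], [walk_config()] and [train_config()]. Any field can
#' be overridden by a config file (`key: value` lines) or CLI flags.
#'
#' @param out output directory (default "ikb_run").
#' @param model "ikbrnet", "gat" or "gcn".
#' @param seed master seed; stage seeds default to it.
#' @param ... overrides for any field of the underlying configs, plus
#'   `link_test_fraction` (INFECTS hold-out, default 0.2) and `hits_k`
#'   (default 10).
#' @return named list of class `run_config`.
#' @export
run_config <- function(out = "ikb_run", model = "ikbrnet", seed = 42L, ...) {
  cfg <- list(
    out = out, model = model, seed = as.integer(seed),
    # synthetic data
    n_virus = 500L, n_disease_virus = 81L, n_bacteria = 150L,
    n_phage_fraction = 0.7, sites = c("Dental Plaque", "Tongue",
                                      "Buccal Mucosa", "Saliva"),
    n_samples = 60L, n_latent_factors = 8L, hub_exponent = 1.5,
    noise_sd = 0.8, enrichment_multiplier = 8,
    # co-occurrence
    rho_threshold = 0.5, alpha = 0.01,
    # node2vec
    p = 1.0, q = 1.0, walks_per_node = 10L, walk_length = 80L, window = 5L,
    dim = 32L, epochs = 5L, negatives = 5L, lr_sgns = 0.025,
    # training
    lr = 0.01, weight_decay = 5e-4, max_epochs = 100L, patience = 20L,
    dropout = 0.3, hidden = 32L, split_seed = 42L,
    # evaluation
    link_test_fraction = 0.2, hits_k = 10L)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0)
    stop("run_config: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(ov)] <- ov
  class(cfg) <- "run_config"
  cfg
}

#' Parse a flat key-value config file
#'
#' Lines of the form `key: value`; `#` starts a comment; comma-separated
#' values become vectors; numbers and TRUE/FALSE are auto-typed.
#'
#' @param path config file path.
#' @return named list of parsed values.
#' @export
parse_config_file <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  out <- list()
  for (l in ln) {
    m <- regmatches(l, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", l))[[1]]
    if (length(m) != 3)
      stop("parse_config_file: cannot parse line: ", l, call. = FALSE)
    vals <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    typed <- suppressWarnings(as.numeric(vals))
    v <- if (!anyNA(typed)) typed
    else if (all(vals %in% c("TRUE", "FALSE"))) as.logical(vals)
    else vals
    out[[m[2]]] <- v
  }
  out
}

run_paths <- function(cfg) {
  o <- cfg$out
  list(dataset = file.path(o, "dataset.csv"),
       samples = file.path(o, "samples.csv"),
       truth = file.path(o, "truth.json"),
       nodes = file.path(o, "nodes.tsv"),
       edges = file.path(o, "edges.tsv"),
       build_report = file.path(o, "build_report.json"),
       link_test = file.path(o, "link_test_pairs.json"),
       embeddings = file.path(o, "embeddings.tsv"),
       checkpoint = function(m) file.path(o, sprintf("checkpoint_%s.json", m)),
       history = function(m) file.path(o, sprintf("history_%s.csv", m)),
       metrics = function(m) file.path(o, sprintf("metrics_%s.json", m)),
       report = file.path(o, "report.txt"))
}

need_artifact <- function(path, producer) {
  p <- if (is.function(path)) stop("internal") else path
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s'; run the `%s` command first",
                 p, producer), call. = FALSE)
  p
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

#' Read a knowledge graph back from its TSV artifacts
#' @param nodes_path,edges_path files written by [write_graph()].
#' @return a `knowledge_graph`.
#' @export
read_graph <- function(nodes_path, edges_path) {
  nd <- as.data.frame(data.table::fread(nodes_path, sep = "\t"))
  ed <- as.data.frame(data.table::fread(edges_path, sep = "\t"))
  feat_cols <- setdiff(names(nd), c("id", "type", "label"))
  X <- as.matrix(nd[, feat_cols, drop = FALSE])
  rownames(X) <- nd$id
  idx <- setNames(seq_len(nrow(nd)), nd$id)
  edges <- data.frame(src = unname(idx[ed$src]), dst = unname(idx[ed$dst]),
                      relation = ed$relation, stringsAsFactors = FALSE)
  sites <- sub("^SITE:", "", nd$id[nd$type == "Site"])
  structure(list(
    nodes = data.frame(id = nd$id, type = nd$type, stringsAsFactors = FALSE),
    features = X,
    numeric_feature_cols = which(!startsWith(feat_cols, "is_")),
    edges = edges,
    labels = setNames(ifelse(nd$label == "", NA_character_, nd$label), nd$id),
    relation_vocabulary = RELATIONS, sites = sites,
    report = list(n_nodes = nrow(nd))), class = "knowledge_graph")
}

#' Read embeddings written by [write_embeddings()]
#' @param path TSV path.
#' @return embedding matrix with node ids as row names.
#' @export
read_embeddings <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!startsWith(ln, "#")]
  df <- as.data.frame(data.table::fread(text = ln, sep = "\t",
                                        header = TRUE))
  Z <- as.matrix(df[, -1, drop = FALSE])
  dimnames(Z) <- list(df$node_id, NULL)
  Z
}

save_model <- function(fit, path, cfg) {
  params <- lapply(fit$model$params, function(p)
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = NULL, data = as.numeric(p)))
  obj <- list(type = fit$model$type, dims = fit$model$dims,
              relations = fit$model$relations, dropout = fit$model$dropout,
              params = params, buffers = fit$model$buffers,
              best_epoch = attr(fit$history, "best_epoch"),
              stopped_epoch = attr(fit$history, "stopped_epoch"),
              parameter_count = as.integer(count_parameters(fit$model)),
              parameter_breakdown =
                as.list(attr(count_parameters(fit$model), "breakdown")),
              config_hash = config_hash(cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2)
      matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(type = obj$type, params = params, dims = as.list(obj$dims),
                 relations = obj$relations, dropout = obj$dropout,
                 buffers = lapply(obj$buffers, as.numeric)),
            class = "ikb_model")
}

#' Run one pipeline command
#'
#' Stages: `simulate` (dataset CSVs + ground-truth JSON), `build-graph`
#' (nodes/edges TSV + build report + held-out INFECTS test pairs), `embed`
#' (Node2Vec embeddings TSV), `train` (checkpoint + history CSV), `evaluate`
#' (metrics JSON: classification + link prediction + site scores), `report`
#' (text summary comparing ikbrnet vs gat). Every JSON artifact embeds the
#' config hash; all stages are deterministic given the config.
#'
#' @param command one of "simulate", "build-graph", "embed", "train",
#'   "evaluate", "report".
#' @param cfg a [run_config()].
#' @return invisibly, the paths of the artifacts written.
#' @export
run_command <- function(command = c("simulate", "build-graph", "embed",
                                    "train", "evaluate", "report"),
                        cfg = run_config()) {
  command <- match.arg(command)
  pt <- run_paths(cfg)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  if (command == "simulate") {
    log_msg("INFO", "simulating dataset (seed ", cfg$seed, ")")
    sc <- synth_config(
      n_virus = cfg$n_virus, n_disease_virus = cfg$n_disease_virus,
      n_bacteria = cfg$n_bacteria, n_phage_fraction = cfg$n_phage_fraction,
      sites = cfg$sites, n_samples = cfg$n_samples,
      n_latent_factors = cfg$n_latent_factors,
      hub_exponent = cfg$hub_exponent, noise_sd = cfg$noise_sd,
      enrichment_multiplier = cfg$enrichment_multiplier, seed = cfg$seed)
    ds <- generate_dataset(sc)
    write_microbe_table(ds$table, pt$dataset, pt$samples)
    write_ground_truth(ds$truth, pt$truth)
    return(invisible(c(pt$dataset, pt$samples, pt$truth)))
  }

  if (command == "build-graph") {
    need_artifact(pt$dataset, "simulate")
    need_artifact(pt$truth, "simulate")
    tb <- parse_microbe_table(pt$dataset, pt$samples)
    log_msg("INFO", "computing co-occurrence edges")
    co <- spearman_cooccurrence(tb$sample_matrix, cfg$rho_threshold,
                                cfg$alpha)
    truth <- read_ground_truth(pt$truth)
    ho <- hold_out_infects(truth, cfg$link_test_fraction, seed = cfg$seed)
    g <- build_graph(tb, co, infects_pairs = ho$train)
    write_graph(g, pt$nodes, pt$edges, pt$build_report)
    jsonlite::write_json(list(test_pairs = ho$test,
                              config_hash = config_hash(cfg)),
                         pt$link_test, auto_unbox = TRUE)
    log_msg("INFO", "graph: ", nrow(g$nodes), " nodes, ", nrow(g$edges),
            " stored edges")
    return(invisible(c(pt$nodes, pt$edges, pt$build_report, pt$link_test)))
  }

  if (command == "embed") {
    need_artifact(pt$nodes, "build-graph")
    g <- read_graph(pt$nodes, pt$edges)
    wc <- walk_config(p = cfg$p, q = cfg$q,
                      walks_per_node = cfg$walks_per_node,
                      walk_length = cfg$walk_length, window = cfg$window,
                      dim = cfg$dim, epochs = cfg$epochs,
                      negatives = cfg$negatives, lr = cfg$lr_sgns,
                      seed = cfg$seed)
    log_msg("INFO", "training Node2Vec embeddings (d=", cfg$dim, ")")
    Z <- node2vec_embeddings(g, wc)
    write_embeddings(Z, pt$embeddings, wc)
    return(invisible(pt$embeddings))
  }

  if (command == "train") {
    need_artifact(pt$nodes, "build-graph")
    need_artifact(pt$embeddings, "embed")
    g <- read_graph(pt$nodes, pt$edges)
    Z <- read_embeddings(pt$embeddings)
    tc <- train_config(lr = cfg$lr, weight_decay = cfg$weight_decay,
                       max_epochs = cfg$max_epochs, patience = cfg$patience,
                       dropout = cfg$dropout, hidden = cfg$hidden,
                       seed = cfg$seed)
    log_msg("INFO", "training ", cfg$model)
    fit <- fit_model(g, if (cfg$model == "gcn") NULL else Z, cfg$model,
                     config = tc, split_seed = cfg$split_seed)
    save_model(fit, pt$checkpoint(cfg$model), cfg)
    data.table::fwrite(as.data.frame(fit$history), pt$history(cfg$model))
    log_msg("INFO", "best epoch ", attr(fit$history, "best_epoch"),
            ", stopped at ", attr(fit$history, "stopped_epoch"))
    return(invisible(c(pt$checkpoint(cfg$model), pt$history(cfg$model))))
  }

  if (command == "evaluate") {
    need_artifact(pt$nodes, "build-graph")
    need_artifact(pt$embeddings, "embed")
    need_artifact(pt$checkpoint(cfg$model), "train")
    g <- read_graph(pt$nodes, pt$edges)
    Z <- read_embeddings(pt$embeddings)
    model <- load_model(pt$checkpoint(cfg$model))
    tensors <- make_graph_tensors(g)
    lab <- g$labels
    lab[!(g$nodes$type %in% c("Virus", "Phage"))] <- NA
    masks <- stratified_split(lab, seed = cfg$split_seed)
    X <- zscore_features(g, masks$train)
    y <- match(g$labels, c("health", "disease"))
    fw <- model_forward(model, tensors, Z = if (model$type == "gcn") NULL
                        else Z, X = X, train = FALSE)
    cls <- classification_metrics(fw$probs, y, masks$test)
    site <- site_disease_scores(fw$probs, g)
    need_artifact(pt$link_test, "build-graph")
    lt <- jsonlite::read_json(pt$link_test, simplifyVector = TRUE)
    lp <- link_prediction_eval(fw$hidden, g,
                               as.data.frame(lt$test_pairs),
                               k = cfg$hits_k, seed = cfg$seed)
    metrics <- list(model = cfg$model, classification = cls,
                    site_disease_scores = as.list(site),
                    link_prediction = lp, config_hash = config_hash(cfg))
    jsonlite::write_json(metrics, pt$metrics(cfg$model), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(pt$metrics(cfg$model)))
  }

  # report
  for (m in c("ikbrnet", "gat"))
    need_artifact(pt$metrics(m), "evaluate")
  mk <- jsonlite::read_json(pt$metrics("ikbrnet"), simplifyVector = TRUE)
  mg <- jsonlite::read_json(pt$metrics("gat"), simplifyVector = TRUE)
  fmt <- function(m) with(m$classification, sprintf(
    "  accuracy %.3f  sensitivity %.3f  specificity %.3f  mcc %.3f  auc %.3f",
    accuracy, sensitivity, specificity, mcc, auc_roc))
  lines <- c(
    "Model comparison on identical splits",
    sprintf("config_hash: %s", config_hash(cfg)),
    "", "IK-BRNet (relation-aware):", fmt(mk),
    sprintf("  link prediction: roc %.3f  pr %.3f  hits@%d %.3f  mrr %.3f",
            mk$link_prediction$roc_auc, mk$link_prediction$pr_auc,
            cfg$hits_k, mk$link_prediction$hits_at_k,
            mk$link_prediction$mrr),
    "", "GAT baseline (relation-blind):", fmt(mg),
    sprintf("  link prediction: roc %.3f  pr %.3f  hits@%d %.3f  mrr %.3f",
            mg$link_prediction$roc_auc, mg$link_prediction$pr_auc,
            cfg$hits_k, mg$link_prediction$hits_at_k,
            mg$link_prediction$mrr),
    "", "Site disease scores (IK-BRNet):",
    paste(sprintf("  %s: %.3f", names(mk$site_disease_scores),
                  unlist(mk$site_disease_scores)), collapse = "\n"))
  writeLines(lines, pt$report)
  invisible(pt$report)
}

#' Command-line entry point
#'
#' Usage: `ikbrnet <command> [--config PATH] [--seed INT] [--model NAME]
#' [--out DIR]`. Flags override config-file values, which override defaults.
#'
#' @param args character vector of CLI arguments.
#' @return exit status (0 on success), invisibly.
#' @export
ikb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: ikbrnet <simulate|build-graph|embed|train|evaluate|",
            "report> [--config PATH] [--seed INT] [--model NAME] [--out DIR]")
    return(invisible(1L))
  }
  command <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args))
      stop("ikb_cli: flag --", key, " needs a value", call. = FALSE)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  base_cfg <- if (!is.null(opts$config)) parse_config_file(opts$config)
  else list()
  for (f in intersect(c("seed", "model", "out"), names(opts)))
    base_cfg[[f]] <- if (f == "seed") as.integer(opts[[f]]) else opts[[f]]
  cfg <- do.call(run_config, base_cfg)
  run_command(command, cfg)
  invisible(0L)
}
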