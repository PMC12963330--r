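test_that("parse_microbe_table reads the CSV contract faithfully", {
  tb0 <- make_toy_table(nv = 2, nb = 1, n_phage = 1, seed = 4)
  d <- withr::local_tempdir()
  write_microbe_table(tb0, file.path(d, "t.csv"), file.path(d, "s.csv"))
  tb <- parse_microbe_table(file.path(d, "t.csv"), file.path(d, "s.csv"))
  expect_equal(nrow(tb$records), 3)
  expect_equal(sum(!is.na(tb$records$Predicted_host)), 1)
  expect_equal(length(strsplit(tb$records$Lineage[1], ";")[[1]]), 3)
  expect_equal(rownames(tb$sample_matrix), tb$records$Taxon)
})

test_that("parse_microbe_table enforces the record invariants", {
  tb0 <- make_toy_table(seed = 4)
  d <- withr::local_tempdir()
  p <- file.path(d, "t.csv"); s <- file.path(d, "s.csv")

  bad <- tb0; bad$records$GC_Content[1] <- 1.2
  write_microbe_table(bad, p, s)
  expect_error(parse_microbe_table(p, s), "GC_Content")

  bad <- tb0; bad$records$Taxon[2] <- bad$records$Taxon[1]
  write_microbe_table(bad, p, s)
  expect_error(parse_microbe_table(p, s), "duplicate")

  bad <- tb0; bad$records$Mean_Abundance[1] <- -1
  write_microbe_table(bad, p, s)
  expect_error(parse_microbe_table(p, s), "negative")

  bad <- tb0; names(bad$records)[names(bad$records) == "Kingdom"] <- "King"
  write_microbe_table(bad, p, s)
  expect_error(parse_microbe_table(p, s), "Kingdom")

  bad <- tb0; bad$records$Predicted_host[3] <- "bact1"  # non-phage host
  write_microbe_table(bad, p, s)
  expect_error(parse_microbe_table(p, s), "non-phage")
})

test_that("spearman_cooccurrence handles exact, anti- and weak correlation", {
  m <- rbind(x = c(1, 2, 3, 4, 5),
             y = c(2, 4, 6, 8, 10),    # rho = +1
             z = c(5, 4, 3, 2, 1))     # rho = -1 with x and y
  co <- spearman_cooccurrence(m)
  key <- paste(co$taxon_a, co$taxon_b)
  expect_true("x y" %in% key)
  expect_true("x z" %in% key)
  expect_equal(co$rho[key == "x y"], 1)
  expect_equal(co$rho[key == "x z"], -1)
  expect_equal(co$p_value[key == "x y"], 0)

  # rho = 0.8 on n = 4 fails p < 0.01 under the t approximation (p ~ 0.2)
  m2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  expect_equal(nrow(spearman_cooccurrence(m2)), 0)
  rho <- brute_force_spearman(m2[1, ], m2[2, ])
  expect_equal(rho, 0.8)
  p <- 2 * pt(-abs(rho * sqrt(2 / (1 - rho^2))), df = 2)
  expect_gt(p, 0.19)

  expect_error(spearman_cooccurrence(m2[, 1:3]), "4 samples")
})

test_that("spearman_cooccurrence matches the brute-force oracle to 1e-12", {
  withr::local_seed(8)
  for (rep in 1:5) {
    m <- matrix(sample(1:40, 80, replace = TRUE), 8, 10,
                dimnames = list(letters[1:8], NULL))
    co <- suppressWarnings(
      spearman_cooccurrence(m, rho_threshold = 0, alpha = 1.1))
    for (i in seq_len(nrow(co))) {
      a <- co$taxon_a[i]; b <- co$taxon_b[i]
      expect_equal(co$rho[i], brute_force_spearman(m[a, ], m[b, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("constant rows are skipped with a warning, not an error", {
  m <- rbind(a = c(1, 1, 1, 1, 1), b = c(1, 2, 3, 4, 5),
             c = c(2, 4, 6, 8, 10))
  expect_warning(co <- spearman_cooccurrence(m), "constant")
  expect_equal(nrow(co), 1)
  expect_setequal(c(co$taxon_a, co$taxon_b), c("b", "c"))
})

test_that("build_graph maps table rows to the typed graph", {
  tb <- make_toy_table(nv = 2, nb = 2, n_phage = 1, seed = 6)
  g <- build_graph(tb, NULL)
  inf <- g$edges[g$edges$relation == "INFECTS", ]
  expect_equal(nrow(inf), 1)
  expect_equal(g$nodes$type[inf$src], "Phage")
  expect_equal(g$nodes$type[inf$dst], "Bacteria")
  # microbe enriched at 2 sites -> 2 ENRICHED_AT edges
  tb2 <- make_toy_table(nv = 2, nb = 2, n_phage = 0, seed = 6)
  tb2$records$Enriched_Dental_Plaque[2] <- 1L  # V2 now enriched at both
  g2 <- build_graph(tb2, NULL)
  en <- g2$edges[g2$edges$relation == "ENRICHED_AT", ]
  v2 <- match("V2", g2$nodes$id)
  expect_equal(sum(en$src == v2), 2)
  # unresolvable host is dropped and counted, not fatal
  tb3 <- make_toy_table(nv = 2, nb = 2, n_phage = 1, seed = 6)
  tb3$records$Predicted_host[1] <- "no_such_bacterium"
  g3 <- build_graph(tb3, NULL)
  expect_equal(sum(g3$edges$relation == "INFECTS"), 0)
  expect_equal(g3$report$dropped_hosts, 1)
})

test_that("default synthetic dataset builds the expected graph", {
  ds <- generate_dataset(synth_config(seed = 42))
  g <- build_graph(ds$table, NULL)
  expect_equal(g$report$n_taxa, 650)
  expect_equal(sum(g$edges$relation == "INFECTS"),
               nrow(ds$truth$infects_pairs))
  lab <- g$labels[ds$table$records$Taxon[ds$table$records$Kingdom == "Virus"]]
  expect_equal(as.vector(base::table(lab)[c("disease", "health")]),
               c(81L, 419L))
  # feature block geometry: numeric + one-hot, identical length for all nodes
  expect_true(all(rowSums(is.na(g$features)) == 0))
  site_rows <- which(g$nodes$type == "Site")
  expect_true(all(g$features[site_rows, g$numeric_feature_cols] == 0))
})

test_that("graph build is idempotent and label counts permutation-invariant", {
  tb <- make_toy_table(nv = 5, nb = 3, n_phage = 2, seed = 9)
  co <- suppressWarnings(spearman_cooccurrence(tb$sample_matrix, 0.2, 0.9))
  g1 <- build_graph(tb, co)
  g2 <- build_graph(tb, co)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$labels, g2$labels)

  perm <- c(4, 2, 7, 1, 8, 3, 6, 5)
  tbp <- tb
  tbp$records <- tb$records[perm, ]
  tbp$sample_matrix <- tb$sample_matrix[perm, ]
  gp <- build_graph(tbp, co)
  expect_equal(base::table(gp$labels), base::table(g1$labels))
  expect_equal(gp$labels[sort(names(gp$labels))],
               g1$labels[sort(names(g1$labels))])
})

test_that("every INFECTS edge is Phage -> Bacteria", {
  g <- toy_knowledge_graph(seed = 10)
  inf <- g$edges[g$edges$relation == "INFECTS", ]
  expect_true(all(g$nodes$type[inf$src] == "Phage"))
  expect_true(all(g$nodes$type[inf$dst] == "Bacteria"))
})

test_that("assign_disease_labels follows plaque enrichment exactly", {
  tb <- make_toy_table(nv = 3, nb = 2, n_phage = 0, seed = 2)
  # V1: plaque only; V2: plaque + tongue; V3: tongue only
  tb$records$Enriched_Dental_Plaque <- c(1L, 1L, 0L, 0L, 0L)
  tb$records$Enriched_Tongue <- c(0L, 1L, 1L, 1L, 1L)
  g <- build_graph(tb, NULL)
  expect_equal(unname(g$labels[c("V1", "V2", "V3")]),
               c("disease", "disease", "health"))
  expect_true(all(is.na(g$labels[g$nodes$type %in% c("Site", "Lineage")])))

  # no Dental Plaque site -> labeling error
  tb2 <- make_toy_table(nv = 2, nb = 1, n_phage = 0,
                        sites = c("Dental Plaque", "Tongue"), seed = 2)
  g2 <- build_graph(tb2, NULL)
  g2$nodes$id[g2$nodes$id == "SITE:Dental Plaque"] <- "SITE:Elsewhere"
  expect_error(assign_disease_labels(g2), "Dental Plaque")
})

test_that("graph TSV artifacts round-trip", {
  g <- toy_knowledge_graph(seed = 12)
  d <- withr::local_tempdir()
  write_graph(g, file.path(d, "n.tsv"), file.path(d, "e.tsv"),
              file.path(d, "r.json"))
  g2 <- read_graph(file.path(d, "n.tsv"), file.path(d, "e.tsv"))
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$features, g$features, tolerance = 1e-12)
  expect_equal(g2$labels, g$labels)
  o <- order(g$edges$src, g$edges$dst, g$edges$relation)
  o2 <- order(g2$edges$src, g2$edges$dst, g2$edges$relation)
  expect_equal(g2$edges[o2, ], g$edges[o, ], ignore_attr = TRUE)
})
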