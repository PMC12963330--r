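# Synthetic multi-kingdom oral-microbiome generator.
#
# Real oral virome surveys of this shape (hundreds of viral taxa across four
# oral niches, dense co-occurrence structure, phage-host edges concentrated on
# hub genera) are not publicly deposited, so every downstream stage is
# exercised against a seeded generator that emulates the statistical shape of
# such a survey: a log-linear latent-factor abundance model (which plants
# tunable Spearman co-occurrence), site-enrichment effects (which define the
# disease label), and preferential-attachment host assignment (which creates
# keystone-style bacterial hubs).

.bact_genera <- c(
  "Porphyromonas", "Fusobacterium", "Streptococcus", "Veillonella",
  "Prevotella", "Actinomyces", "Neisseria", "Lactobacillus", "Rothia",
  "Capnocytophaga", "Treponema", "Tannerella", "Aggregatibacter",
  "Haemophilus", "Gemella", "Granulicatella", "Leptotrichia", "Selenomonas",
  "Corynebacterium", "Campylobacter")

.bact_phyla <- c(
  Porphyromonas = "Bacteroidota", Fusobacterium = "Fusobacteriota",
  Streptococcus = "Bacillota", Veillonella = "Bacillota",
  Prevotella = "Bacteroidota", Actinomyces = "Actinomycetota",
  Neisseria = "Pseudomonadota", Lactobacillus = "Bacillota",
  Rothia = "Actinomycetota", Capnocytophaga = "Bacteroidota",
  Treponema = "Spirochaetota", Tannerella = "Bacteroidota",
  Aggregatibacter = "Pseudomonadota", Haemophilus = "Pseudomonadota",
  Gemella = "Bacillota", Granulicatella = "Bacillota",
  Leptotrichia = "Fusobacteriota", Selenomonas = "Bacillota",
  Corynebacterium = "Actinomycetota", Campylobacter = "Campylobacterota")

.virus_families <- c(
  "Siphoviridae", "Myoviridae", "Podoviridae", "Microviridae",
  "Inoviridae", "Herpesviridae", "Anelloviridae", "Papillomaviridae")

#' Configuration for the synthetic oral-microbiome generator
#'
#' Defaults encode the stated shape of the emulated survey: 500 viral taxa
#' across four oral sites, 81 of them (16.2\%) enriched in dental plaque (the
#' disease-defining niche), dense co-occurrence structure on the order of
#' 20,000 significant pairs, and phage-host edges concentrated on a few hub
#' bacteria.
#'
#' @param n_virus number of viral taxa (default 500).
#' @param n_disease_virus number of viruses enriched at Dental Plaque, i.e.
#'   carrying the disease label (default 81).
#' @param n_bacteria number of bacterial taxa (default 150).
#' @param n_phage_fraction fraction of viruses flagged as phages (default 0.7).
#' @param sites ordered character vector of oral sites; must contain
#'   "Dental Plaque".
#' @param n_samples number of abundance samples used for co-occurrence
#'   inference (default 60).
#' @param n_latent_factors number of latent co-abundance factors (default 8).
#' @param hub_exponent preferential-attachment exponent for host assignment;
#'   values > 1 concentrate INFECTS edges on hub bacteria (default 1.5).
#' @param noise_sd standard deviation of log-abundance noise (default 0.8).
#' @param enrichment_multiplier fold-increase of abundance at an enriched
#'   site; must exceed 1 (default 8).
#' @param seed integer seed; the single source of randomness for a
#'   [generate_dataset()] call.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_virus = 500L, n_disease_virus = 81L,
                         n_bacteria = 150L, n_phage_fraction = 0.7,
                         sites = c("Dental Plaque", "Tongue",
                                   "Buccal Mucosa", "Saliva"),
                         n_samples = 60L, n_latent_factors = 8L,
                         hub_exponent = 1.5, noise_sd = 0.8,
                         enrichment_multiplier = 8, seed = 42L) {
  cfg <- list(n_virus = as.integer(n_virus),
              n_disease_virus = as.integer(n_disease_virus),
              n_bacteria = as.integer(n_bacteria),
              n_phage_fraction = n_phage_fraction, sites = as.character(sites),
              n_samples = as.integer(n_samples),
              n_latent_factors = as.integer(n_latent_factors),
              hub_exponent = hub_exponent, noise_sd = noise_sd,
              enrichment_multiplier = enrichment_multiplier,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (length(cfg$sites) == 0L)
    stop("synth_config: `sites` must be non-empty", call. = FALSE)
  if (!"Dental Plaque" %in% cfg$sites)
    stop("synth_config: `sites` must contain \"Dental Plaque\"", call. = FALSE)
  counts <- c(n_virus = cfg$n_virus, n_bacteria = cfg$n_bacteria,
              n_samples = cfg$n_samples,
              n_latent_factors = cfg$n_latent_factors)
  if (any(counts <= 0L))
    stop("synth_config: counts must be positive: ",
         paste(names(counts)[counts <= 0L], collapse = ", "), call. = FALSE)
  if (cfg$n_disease_virus < 0L || cfg$n_disease_virus > cfg$n_virus)
    stop("synth_config: n_disease_virus must lie in [0, n_virus]",
         call. = FALSE)
  if (cfg$enrichment_multiplier <= 1)
    stop("synth_config: enrichment_multiplier must be > 1", call. = FALSE)
  if (cfg$n_phage_fraction < 0 || cfg$n_phage_fraction > 1)
    stop("synth_config: n_phage_fraction must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic multi-kingdom oral-microbiome dataset
#'
#' Produces a taxon table (bacteria + viruses with lineage, genomic traits,
#' per-site abundances and enrichment flags) together with a taxa x samples
#' relative-abundance matrix and the generating ground truth.
#'
#' The abundance model is log-linear: each taxon loads on one latent
#' co-abundance factor, and `log A[i, t] = mu_i + lambda_i * F[k(i), t] +
#' log(enrichment_multiplier) * enriched(i, site(t)) + noise`; sample columns
#' are then closed to relative abundances. Taxa sharing a factor therefore
#' have elevated Spearman correlation across samples, which is what the
#' downstream co-occurrence threshold detects. Exactly `n_disease_virus`
#' viruses are enriched at Dental Plaque; every other microbe is enriched at
#' one (occasionally two) non-plaque site. Each phage is assigned a bacterial
#' host with probability proportional to `(current host degree + 1)^hub_exponent`,
#' so hosts accumulate preferentially on a few hub genera, and each phage
#' shares its host's latent factor (phage populations track their host
#' populations, which is what makes co-abundance informative about host
#' specificity).
#'
#' @param config a [synth_config()].
#' @return a list with components `table` (a `microbe_table`: `records`
#'   data.frame + `sample_matrix`) and `truth` (a `ground_truth`:
#'   `infects_pairs`, `disease_labels`, `latent_loadings`, `config`).
#' @export
generate_dataset <- function(config = synth_config()) {
  validate_synth_config(config)
  with_seed(config$seed, {
    nv <- config$n_virus; nb <- config$n_bacteria
    n <- nv + nb
    sites <- config$sites
    nonplaque <- setdiff(sites, "Dental Plaque")

    bact_id <- sprintf("B%03d", seq_len(nb))
    vir_id  <- sprintf("V%03d", seq_len(nv))
    genus <- sample(.bact_genera, nb, replace = TRUE)
    bact_name <- paste0(genus, "_sp", seq_len(nb))
    fam <- sample(.virus_families, nv, replace = TRUE)
    n_phage <- round_half_up(config$n_phage_fraction * nv)
    is_phage_v <- rep(FALSE, nv)
    if (n_phage > 0) is_phage_v[sample.int(nv, n_phage)] <- TRUE
    vir_name <- ifelse(is_phage_v, paste0("phage_ctg", seq_len(nv)),
                       paste0("virus_ctg", seq_len(nv)))

    taxon_id <- c(vir_id, bact_id)
    name <- c(vir_name, bact_name)
    kingdom <- c(rep("Virus", nv), rep("Bacteria", nb))
    is_phage <- c(is_phage_v, rep(FALSE, nb))
    lineage <- c(paste("Viruses", fam, vir_name, sep = ";"),
                 paste("Bacteria", .bact_phyla[genus], genus, bact_name,
                       sep = ";"))

    genome <- numeric(n)
    genome[seq_len(nv)][is_phage_v] <-
      round(rlnorm(sum(is_phage_v), log(4.5e4), 0.4))
    genome[seq_len(nv)][!is_phage_v] <-
      round(rlnorm(sum(!is_phage_v), log(1.5e5), 0.6))
    genome[nv + seq_len(nb)] <- round(rlnorm(nb, log(2.2e6), 0.3))
    gc <- runif(n, 0.25, 0.75)

    # enrichment: disease viruses at Dental Plaque, everyone else at 1 (with
    # prob 0.15, 2) non-plaque sites
    enrich <- matrix(0L, n, length(sites), dimnames = list(taxon_id, sites))
    disease_idx <- if (config$n_disease_virus > 0)
      sample.int(nv, config$n_disease_virus) else integer(0)
    enrich[disease_idx, "Dental Plaque"] <- 1L
    others <- setdiff(seq_len(n), disease_idx)
    if (length(nonplaque) > 0L) {
      primary <- sample(nonplaque, length(others), replace = TRUE)
      enrich[cbind(others, match(primary, sites))] <- 1L
      second <- runif(length(others)) < 0.15
      for (j in which(second)) {
        alt <- setdiff(nonplaque, primary[j])
        if (length(alt) > 0)
          enrich[others[j], sample(alt, 1L)] <- 1L
      }
    }

    # preferential-attachment host assignment: one bacterial host per phage
    phage_rows <- which(is_phage)
    host_deg <- rep(0, nb)
    host_of <- integer(length(phage_rows))
    for (j in seq_along(phage_rows)) {
      w <- (host_deg + 1)^config$hub_exponent
      h <- sample.int(nb, 1L, prob = w)
      host_of[j] <- h
      host_deg[h] <- host_deg[h] + 1
    }
    predicted_host <- rep(NA_character_, n)
    predicted_host[phage_rows] <- bact_name[host_of]

    # latent co-abundance structure; a phage shares its host's factor (phage
    # populations track their bacterial host populations, which is what makes
    # co-abundance informative about host specificity)
    K <- config$n_latent_factors
    factor_of <- sample.int(K, n, replace = TRUE)
    factor_of[phage_rows] <- factor_of[nv + host_of]
    lambda <- abs(rnorm(n, mean = 1, sd = 0.15))
    L <- matrix(0, n, K, dimnames = list(taxon_id, NULL))
    L[cbind(seq_len(n), factor_of)] <- lambda

    mu <- rnorm(n, mean = -9, sd = 1)
    # per-taxon enrichment strength: log-fold is Gamma-distributed with mean
    # log(enrichment_multiplier) (shape 4 => CV 0.5), so some enriched taxa
    # barely stand out of the noise while others are strongly enriched --
    # mirroring real surveys, where site enrichment is not a clean step
    logfold <- log(config$enrichment_multiplier) * rgamma(n, shape = 4,
                                                          rate = 4)
    sample_site <- rep(sites, length.out = config$n_samples)
    Fs <- matrix(rnorm(K * config$n_samples), K, config$n_samples)
    logA <- outer(mu, rep(1, config$n_samples)) + L %*% Fs +
      logfold * enrich[, sample_site, drop = FALSE] +
      matrix(rnorm(n * config$n_samples, sd = config$noise_sd),
             n, config$n_samples)
    S <- exp(logA)
    dimnames(S) <- list(taxon_id, sprintf("S%03d", seq_len(config$n_samples)))

    # per-site abundances are empirical means over that site's samples, so
    # the feature columns inherit the sampling noise of the survey they
    # summarize instead of restating the enrichment flags noiselessly
    site_ab <- vapply(sites,
                      function(s) rowMeans(S[, sample_site == s, drop = FALSE]),
                      numeric(n))
    colnames(site_ab) <- sites

    records <- data.frame(
      Taxon = taxon_id, Name = name, Kingdom = kingdom,
      Is_Phage = as.integer(is_phage), Predicted_host = predicted_host,
      Lineage = lineage, Genome_Size_bp = genome, GC_Content = gc,
      Mean_Abundance = rowMeans(site_ab),
      stringsAsFactors = FALSE, check.names = FALSE)
    for (s in sites)
      records[[paste0("Abund_", gsub(" ", "_", s))]] <- site_ab[, s]
    for (s in sites)
      records[[paste0("Enriched_", gsub(" ", "_", s))]] <- enrich[, s]

    table <- structure(list(records = records, sample_matrix = S,
                            sites = sites),
                       class = "microbe_table")

    labels <- setNames(ifelse(enrich[, "Dental Plaque"] == 1L,
                              "disease", "health"), taxon_id)
    truth <- structure(list(
      infects_pairs = data.frame(phage = taxon_id[phage_rows],
                                 bacterium = bact_id[host_of],
                                 stringsAsFactors = FALSE),
      disease_labels = labels,
      latent_loadings = L,
      config = config), class = "ground_truth")
    list(table = table, truth = truth)
  })
}

#' Split ground-truth INFECTS pairs into train and test sets
#'
#' @param truth a `ground_truth` object (or any list with an `infects_pairs`
#'   data.frame).
#' @param fraction test fraction, strictly between 0 and 1; the test share is
#'   `round_half_up(fraction * n_pairs)`.
#' @param seed integer seed for the partition.
#' @return list with `train` and `test` data.frames, a disjoint partition of
#'   the input pairs.
#' @export
hold_out_infects <- function(truth, fraction, seed = 42L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("hold_out_infects: `fraction` must lie strictly in (0, 1)",
         call. = FALSE)
  pairs <- truth$infects_pairs
  n <- nrow(pairs)
  n_test <- round_half_up(fraction * n)
  with_seed(seed, {
    test_idx <- sort(sample.int(n, n_test))
    list(train = pairs[setdiff(seq_len(n), test_idx), , drop = FALSE],
         test = pairs[test_idx, , drop = FALSE])
  })
}

#' Write a microbe table to CSV files
#'
#' @param table a `microbe_table`.
#' @param path output CSV path for the taxon table.
#' @param samples_path output CSV path for the taxa x samples matrix (first
#'   column `Taxon`).
#' @return invisibly, the two paths.
#' @export
write_microbe_table <- function(table, path, samples_path) {
  data.table::fwrite(table$records, path)
  sm <- data.frame(Taxon = rownames(table$sample_matrix),
                   table$sample_matrix, check.names = FALSE)
  data.table::fwrite(sm, samples_path)
  invisible(c(path, samples_path))
}

#' Write generator ground truth as JSON
#'
#' Records the INFECTS pairs, disease labels and a config echo (the latent
#' loadings are omitted: they are reproducible from the seed).
#'
#' @param truth a `ground_truth`.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    infects_pairs = truth$infects_pairs,
    disease_labels = as.list(truth$disease_labels),
    config = unclass(truth$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read generator ground truth from JSON
#' @param path JSON path written by [write_ground_truth()].
#' @return a `ground_truth` (without latent loadings).
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(infects_pairs = as.data.frame(x$infects_pairs),
                 disease_labels = unlist(x$disease_labels),
                 latent_loadings = NULL,
                 config = x$config), class = "ground_truth")
}
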