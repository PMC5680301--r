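#' Configuration for the paired synthetic panel generator
#'
#' Defines the study conditions emulated by the generator: two noisy
#' replicate expression panels over the same cell lines with partially
#' overlapping gene panels, planted co-expression gene modules matching
#' planted network communities, planted cell-line clusters, cluster-shifted
#' drug responses with missing IC50s, and cluster-enriched mutations.
#'
#' @param n_genes number of module (signal) genes, split evenly across
#'   modules.
#' @param n_decoy_genes number of pure-noise decoy genes.
#' @param n_samples number of cell lines (shared by both panels).
#' @param n_modules number of planted gene modules / network communities.
#' @param n_clusters number of planted cell-line clusters.
#' @param module_shift SD-unit scale of the per-(module, cluster) mean
#'   shifts driving module expression (default 3).
#' @param noise_sd within-dataset measurement noise SD (default 1,
#'   log2-expression units).
#' @param batch_shift_sd SD of the per-gene additive batch offset of the
#'   second panel (default 0.5).
#' @param panel_overlap fraction of genes present on the second panel
#'   (default 0.9; the first panel carries all genes).
#' @param missing_fraction_a,missing_fraction_b fractions of drug-response
#'   entries masked as missing in each panel (defaults 0.25 and 0.45, the
#'   typical non-extractable-IC50 rates of large public panels).
#' @param n_drugs number of drugs (default 15).
#' @param drug_effect_size SD-unit sensitivity shift of each drug's
#'   affected cluster (default 2).
#' @param n_mutation_genes number of recurrently mutated genes (default 8).
#' @param mutation_base_rate background mutation probability (default 0.1).
#' @param mutation_odds odds multiplier of the enriched (gene, cluster)
#'   pairs (>= 1; default 8).
#' @param n_tissues number of tissue-of-origin labels, assigned
#'   independently of the planted clusters (default 24).
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return validated list of class `"GeneratorConfig"`.
#' @export
generator_config <- function(n_genes = 2000L, n_decoy_genes = 500L,
                             n_samples = 300L, n_modules = 5L,
                             n_clusters = 8L, module_shift = 3,
                             noise_sd = 1, batch_shift_sd = 0.5,
                             panel_overlap = 0.9,
                             missing_fraction_a = 0.25,
                             missing_fraction_b = 0.45,
                             n_drugs = 15L, drug_effect_size = 2,
                             n_mutation_genes = 8L,
                             mutation_base_rate = 0.1, mutation_odds = 8,
                             n_tissues = 24L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_decoy_genes = as.integer(n_decoy_genes),
              n_samples = as.integer(n_samples),
              n_modules = as.integer(n_modules),
              n_clusters = as.integer(n_clusters),
              module_shift = module_shift, noise_sd = noise_sd,
              batch_shift_sd = batch_shift_sd,
              panel_overlap = panel_overlap,
              missing_fraction_a = missing_fraction_a,
              missing_fraction_b = missing_fraction_b,
              n_drugs = as.integer(n_drugs),
              drug_effect_size = drug_effect_size,
              n_mutation_genes = as.integer(n_mutation_genes),
              mutation_base_rate = mutation_base_rate,
              mutation_odds = mutation_odds,
              n_tissues = as.integer(n_tissues), seed = as.integer(seed))
  counts <- c("n_genes", "n_samples", "n_modules", "n_clusters", "n_drugs",
              "n_tissues")
  for (f in counts) if (cfg[[f]] < 1L) stop(f, " must be positive",
                                            call. = FALSE)
  if (cfg$n_decoy_genes < 0L) stop("n_decoy_genes must be >= 0",
                                   call. = FALSE)
  if (cfg$n_modules > cfg$n_genes)
    stop("n_modules cannot exceed n_genes", call. = FALSE)
  if (cfg$n_clusters > cfg$n_samples)
    stop("n_clusters cannot exceed n_samples", call. = FALSE)
  for (f in c("panel_overlap", "missing_fraction_a", "missing_fraction_b",
              "mutation_base_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0,1]", call. = FALSE)
  }
  if (cfg$mutation_odds < 1)
    stop("mutation_odds must be >= 1 (enrichment only)", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  class(cfg) <- "GeneratorConfig"
  cfg
}

#' Generate a pair of pseudo-panel expression matrices with known truth
#'
#' Plants `n_modules` gene modules and `n_clusters` cell-line clusters:
#' every (module, cluster) pair receives a mean shift drawn from
#' `N(0, module_shift^2)`, shared by all genes of the module, so module
#' genes are strongly co-expressed and clusters are separated in module
#' space. Decoy genes carry noise only. Panel B shares the signal of panel
#' A but has independent noise, a per-gene additive batch offset, and a
#' restricted gene panel (`panel_overlap`). The returned truth bundle also
#' fixes the drug-effect map, the mutation-enrichment map and the tissue
#' labels used by the downstream generators.
#'
#' @param config `GeneratorConfig`.
#' @return list: `expr_a`, `expr_b` (genes x samples matrices) and `truth`
#'   (class `"TruthBundle"`: `modules`, `clusters`, `tissues`,
#'   `drug_effects`, `mutation_effects`, `config`, `seed`).
#' @export
generate_paired_expression <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  cfg <- config
  .with_seed(cfg$seed, function() {
    gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
    decoy_ids <- if (cfg$n_decoy_genes > 0L)
      sprintf("decoy_%05d", seq_len(cfg$n_decoy_genes)) else character(0L)
    all_ids <- c(gene_ids, decoy_ids)
    sample_ids <- sprintf("cl_%04d", seq_len(cfg$n_samples))

    module_of <- sort(rep_len(seq_len(cfg$n_modules), cfg$n_genes))
    modules <- split(gene_ids, paste0("module_", module_of))
    cluster_of <- sample(rep_len(seq_len(cfg$n_clusters), cfg$n_samples))
    clusters <- setNames(paste0("cluster_", cluster_of), sample_ids)
    tissues <- setNames(
      paste0("tissue_", sample(rep_len(seq_len(cfg$n_tissues),
                                       cfg$n_samples))),
      sample_ids)

    baseline <- rnorm(length(all_ids), mean = 7, sd = 1)
    # per-(module, cluster) mean shifts: each module's profile across the
    # clusters is standardized so its spread is exactly module_shift noise-SD
    # units - the parameter's definition - rather than a random draw of it
    mu <- matrix(rnorm(cfg$n_modules * cfg$n_clusters),
                 cfg$n_modules, cfg$n_clusters)
    if (cfg$n_clusters > 1L) {
      mu <- (mu - rowMeans(mu)) / apply(mu, 1L, sd) *
        cfg$module_shift * cfg$noise_sd
    } else {
      mu[] <- 0
    }
    signal <- matrix(baseline, length(all_ids), cfg$n_samples)
    signal[seq_len(cfg$n_genes), ] <- signal[seq_len(cfg$n_genes), ] +
      mu[cbind(rep(module_of, cfg$n_samples),
               rep(cluster_of, each = cfg$n_genes))]
    dimnames(signal) <- list(all_ids, sample_ids)

    noise <- function() matrix(rnorm(length(signal), sd = cfg$noise_sd),
                               nrow(signal), ncol(signal))
    expr_a <- signal + noise()
    batch <- rnorm(length(all_ids), sd = cfg$batch_shift_sd)
    expr_b <- signal + noise() + batch
    n_keep <- max(2L, round(cfg$panel_overlap * length(all_ids)))
    panel_b <- sort(sample.int(length(all_ids), n_keep))
    expr_b <- expr_b[panel_b, , drop = FALSE]

    drug_ids <- sprintf("drug_%02d", seq_len(cfg$n_drugs))
    drug_effects <- data.frame(
      drug_id = drug_ids,
      cluster = paste0("cluster_",
                       ((seq_len(cfg$n_drugs) - 1L) %% cfg$n_clusters) + 1L),
      shift = cfg$drug_effect_size,
      sign = ifelse(seq_len(cfg$n_drugs) %% 2L == 1L, "sensitive",
                    "resistant"),
      stringsAsFactors = FALSE)
    mut_ids <- if (cfg$n_mutation_genes > 0L)
      sprintf("mutgene_%02d", seq_len(cfg$n_mutation_genes)) else character(0L)
    mutation_effects <- data.frame(
      gene_id = mut_ids,
      cluster = if (length(mut_ids) > 0L)
        paste0("cluster_",
               ((seq_along(mut_ids) - 1L) %% cfg$n_clusters) + 1L)
        else character(0L),
      odds_multiplier = rep(cfg$mutation_odds, length(mut_ids)),
      stringsAsFactors = FALSE)

    truth <- structure(list(modules = modules, clusters = clusters,
                            tissues = tissues, decoy_ids = decoy_ids,
                            module_means = mu, drug_effects = drug_effects,
                            mutation_effects = mutation_effects,
                            config = cfg, seed = cfg$seed),
                       class = "TruthBundle")
    list(expr_a = expr_a, expr_b = expr_b, truth = truth)
  })
}

#' Generate a scored interaction graph matching the planted modules
#'
#' Planted modules double as network communities: within-module gene pairs
#' receive high-confidence edges (score `within_score`) at density
#' `within_density`; all other pairs (including decoys) receive sparse
#' low-confidence edges (scores uniform in \[0.1, 0.5\]) at rate
#' `cross_rate`, so decoys stay weakly connected.
#'
#' @param truth `TruthBundle` with planted modules.
#' @param within_score combined score put on within-module edges (default
#'   0.9).
#' @param within_density probability of an edge between two genes of the
#'   same module (default 0.3).
#' @param cross_rate probability of a low-score edge between any other gene
#'   pair (default 0.01).
#' @param seed integer seed (defaults to the truth seed + 1).
#' @return `InteractionGraph`.
#' @export
generate_interaction_graph <- function(truth, within_score = 0.9,
                                       within_density = 0.3,
                                       cross_rate = 0.01,
                                       seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "TruthBundle"))
  if (length(truth$modules) == 0L) stop("truth has no modules", call. = FALSE)
  ids <- c(unlist(truth$modules, use.names = FALSE), truth$decoy_ids)
  mod_idx <- integer(length(ids))
  names(mod_idx) <- ids
  for (m in seq_along(truth$modules)) mod_idx[truth$modules[[m]]] <- m
  n <- length(ids)
  pr <- which(upper.tri(matrix(nrow = n, ncol = n)), arr.ind = TRUE)
  within <- mod_idx[pr[, 1L]] > 0L & mod_idx[pr[, 1L]] == mod_idx[pr[, 2L]]
  .with_seed(seed, function() {
    keep <- runif(nrow(pr)) < ifelse(within, within_density, cross_rate)
    a <- ids[pr[keep, 1L]]
    b <- ids[pr[keep, 2L]]
    w <- within[keep]
    score <- numeric(length(a))
    score[w] <- within_score
    score[!w] <- runif(sum(!w), 0.1, 0.5)
    interaction_graph(a, b, score)
  })
}

#' Generate paired drug-response tables with cluster-shifted effects
#'
#' Each drug's sensitivity is Gaussian on the -log10(molar IC50) scale
#' around a drug-specific baseline (mean 6, i.e. about 1 uM, SD 1); the
#' affected cluster of the truth's drug-effect map is shifted by the effect
#' size, upward for a "sensitive" phenotype and downward for "resistant".
#' Sensitivities are converted back to micromolar IC50 (`10^(6 - s)`), so
#' the tables exercise the IC50 scale conversion. Both panels share the
#' baselines and effects but have independent noise and independent
#' missingness masks at the configured fractions.
#'
#' @param truth `TruthBundle` with planted clusters.
#' @param config `GeneratorConfig` (defaults to the one in `truth`).
#' @param seed integer seed (defaults to the truth seed + 2).
#' @return list of two `DrugResponseTable`s (`drugs_a`, `drugs_b`), metric
#'   `"ic50_uM"`.
#' @export
generate_drug_responses <- function(truth, config = truth$config,
                                    seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "TruthBundle"))
  eff <- truth$drug_effects
  unknown <- setdiff(eff$cluster, unique(truth$clusters))
  if (length(unknown) > 0L)
    stop("drug effect references unknown cluster(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  samples <- names(truth$clusters)
  n <- length(samples)
  .with_seed(seed, function() {
    base <- rnorm(nrow(eff), mean = 6, sd = 1)
    shift_sign <- ifelse(eff$sign == "sensitive", 1, -1)
    make_panel <- function(missing_fraction) {
      s <- matrix(rnorm(nrow(eff) * n, sd = 1), nrow(eff), n) + base
      for (i in seq_len(nrow(eff))) {
        inc <- truth$clusters[samples] == eff$cluster[i]
        s[i, inc] <- s[i, inc] + shift_sign[i] * eff$shift[i]
      }
      miss <- matrix(runif(length(s)) < missing_fraction, nrow(s), ncol(s))
      ic50 <- 10^(6 - s)
      ic50[miss] <- NA
      dimnames(ic50) <- list(eff$drug_id, samples)
      drug_response_table(ic50, metric = "ic50_uM",
                          orientation = "high_is_resistant")
    }
    list(drugs_a = make_panel(config$missing_fraction_a),
         drugs_b = make_panel(config$missing_fraction_b))
  })
}

#' Generate a binary mutation matrix with cluster-enriched genes
#'
#' Mutations arise as independent Bernoulli draws at the background rate;
#' for each (gene, cluster) pair of the truth's mutation-effect map, the
#' odds of mutation inside that cluster are multiplied by the configured
#' factor (>= 1, so only enrichment is planted, matching the one-tailed
#' enrichment test downstream).
#'
#' @param truth `TruthBundle` with planted clusters.
#' @param config `GeneratorConfig` (defaults to the one in `truth`).
#' @param seed integer seed (defaults to the truth seed + 3).
#' @return binary mutation matrix (genes x samples).
#' @export
generate_mutations <- function(truth, config = truth$config,
                               seed = truth$seed + 3L) {
  stopifnot(inherits(truth, "TruthBundle"))
  eff <- truth$mutation_effects
  if (any(eff$odds_multiplier < 1))
    stop("mutation odds multipliers must be >= 1 (enrichment only)",
         call. = FALSE)
  samples <- names(truth$clusters)
  n <- length(samples)
  base <- config$mutation_base_rate
  .with_seed(seed, function() {
    rate <- matrix(base, nrow(eff), n,
                   dimnames = list(eff$gene_id, samples))
    for (i in seq_len(nrow(eff))) {
      inc <- truth$clusters[samples] == eff$cluster[i]
      odds <- base / (1 - base) * eff$odds_multiplier[i]
      rate[i, inc] <- odds / (1 + odds)
    }
    m <- matrix(as.numeric(runif(length(rate)) < rate), nrow(rate),
                ncol(rate), dimnames = dimnames(rate))
    validate_mutation_matrix(m)
    m
  })
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates paired expression panels, the interaction graph, paired drug
#' responses, mutations and tissue labels, and writes them in the TSV
#' formats the pipeline reads, plus a JSON truth sidecar so downstream
#' validation never has to re-derive the ground truth.
#'
#' @param config `GeneratorConfig`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, list with `paths` (named file paths) and the
#'   in-memory objects (`expr_a`, `expr_b`, `graph`, `drugs_a`, `drugs_b`,
#'   `mutations`, `truth`).
#' @export
write_synthetic_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "GeneratorConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_paired_expression(config)
  graph <- generate_interaction_graph(gen$truth)
  drugs <- generate_drug_responses(gen$truth)
  muts <- generate_mutations(gen$truth)
  p <- function(f) file.path(out_dir, f)
  paths <- c(expr_a = p("expression_a.tsv"), expr_b = p("expression_b.tsv"),
             graph = p("interaction_graph.tsv"),
             drugs_a = p("drug_response_a.tsv"),
             drugs_b = p("drug_response_b.tsv"),
             mutations = p("mutations.tsv"), tissues = p("tissues.tsv"),
             truth = p("truth.json"))
  write_expression_matrix(gen$expr_a, paths[["expr_a"]])
  write_expression_matrix(gen$expr_b, paths[["expr_b"]])
  write_interaction_graph(graph, paths[["graph"]])
  write_drug_response(drugs$drugs_a, paths[["drugs_a"]])
  write_drug_response(drugs$drugs_b, paths[["drugs_b"]])
  write_mutation_matrix(muts, paths[["mutations"]])
  write.table(data.frame(sample_id = names(gen$truth$tissues),
                         tissue = unname(gen$truth$tissues)),
              paths[["tissues"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_json <- list(modules = gen$truth$modules,
                     clusters = as.list(gen$truth$clusters),
                     tissues = as.list(gen$truth$tissues),
                     decoy_ids = gen$truth$decoy_ids,
                     drug_effects = gen$truth$drug_effects,
                     mutation_effects = gen$truth$mutation_effects,
                     config = unclass(gen$truth$config),
                     seed = gen$truth$seed)
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths, expr_a = gen$expr_a, expr_b = gen$expr_b,
                 graph = graph, drugs_a = drugs$drugs_a,
                 drugs_b = drugs$drugs_b, mutations = muts,
                 truth = gen$truth))
}
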