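#' Analysis configuration
#'
#' Bundles and validates the tunable parameters of the full pipeline.
#' Defaults follow the method's reference settings: strong-edge threshold
#' 0.7, within-network correlation threshold 0.5, FDR level 0.05, 1000
#' consensus iterations at subsample fraction 0.8 under Pearson distance
#' and Ward linkage (analyses at reduced scale typically lower
#' `n_iterations` to 100).
#'
#' @param edge_score_min minimum interaction combined score (default 0.7).
#' @param correlation_min minimum within-network expression correlation
#'   (default 0.5).
#' @param fdr_alpha significance level on FDR-adjusted p-values (default
#'   0.05).
#' @param n_iterations consensus iterations (default 1000).
#' @param subsample_fraction feature subsample fraction in (0,1\] (default
#'   0.8).
#' @param gene_k_range,sample_k_range candidate cluster numbers for gene
#'   modules and cell-line clusters.
#' @param k_override_genes,k_override_samples optional explicit k imposed
#'   instead of the delta-area criterion.
#' @param k_select_tolerance delta-area tolerance of [select_k()] (default
#'   0.02).
#' @param gsea_permutations gene-label permutations per enrichment test
#'   (default 1000).
#' @param distance,linkage recorded clustering conventions; only
#'   `"pearson"`/`"ward"` are implemented.
#' @param seed integer master seed, recorded in all outputs.
#' @return validated list of class `"AnalysisConfig"`.
#' @export
analysis_config <- function(edge_score_min = 0.7, correlation_min = 0.5,
                            fdr_alpha = 0.05, n_iterations = 1000L,
                            subsample_fraction = 0.8,
                            gene_k_range = 2:10, sample_k_range = 2:12,
                            k_override_genes = NULL,
                            k_override_samples = NULL,
                            k_select_tolerance = 0.02,
                            gsea_permutations = 1000L,
                            distance = "pearson", linkage = "ward",
                            seed = 1L) {
  for (f in c("edge_score_min", "correlation_min", "fdr_alpha")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop(f, " must be a single value in [0,1]", call. = FALSE)
  }
  if (!identical(distance, "pearson") || !identical(linkage, "ward"))
    stop("only distance = 'pearson' with linkage = 'ward' is implemented",
         call. = FALSE)
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("n_iterations must be >= 1", call. = FALSE)
  if (!is.numeric(subsample_fraction) || subsample_fraction <= 0 ||
      subsample_fraction > 1)
    stop("subsample_fraction must lie in (0,1]", call. = FALSE)
  if (length(gene_k_range) < 1L || length(sample_k_range) < 1L)
    stop("k ranges must be non-empty", call. = FALSE)
  structure(list(edge_score_min = edge_score_min,
                 correlation_min = correlation_min, fdr_alpha = fdr_alpha,
                 n_iterations = n_iterations,
                 subsample_fraction = subsample_fraction,
                 gene_k_range = as.integer(gene_k_range),
                 sample_k_range = as.integer(sample_k_range),
                 k_override_genes = k_override_genes,
                 k_override_samples = k_override_samples,
                 k_select_tolerance = k_select_tolerance,
                 gsea_permutations = as.integer(gsea_permutations),
                 distance = distance, linkage = linkage,
                 seed = as.integer(seed)),
            class = "AnalysisConfig")
}

.stage <- function(name, log_file, expr) {
  .log(log_file, "stage '", name, "' started")
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  .log(log_file, "stage '", name, "' done")
  res
}

.log <- function(log_file, ...) {
  msg <- paste0(...)
  if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
  if (!isTRUE(getOption("pharmclust.quiet", FALSE))) message(msg)
  invisible(NULL)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

# run one dataset through gene selection -> modules -> network filter ->
# cell-line consensus -> clustering
.cluster_one_dataset <- function(expr, graph, config, tag, log_file) {
  sel <- .stage(paste0(tag, ":gene_selection"), log_file,
                select_variant_genes(expr))
  if (length(sel) < 3L)
    stop("stage '", tag, ":gene_selection' failed: fewer than 3 variant ",
         "genes selected", call. = FALSE)
  .log(log_file, tag, ": ", length(sel), " variant genes selected")

  gk <- config$gene_k_range[config$gene_k_range <= length(sel)]
  cons_genes <- .stage(paste0(tag, ":gene_consensus"), log_file,
    consensus_cluster(expr[sel, , drop = FALSE], axis = "rows",
                      k_range = gk, n_iterations = config$n_iterations,
                      subsample_fraction = config$subsample_fraction,
                      seed = config$seed + 11L,
                      k_select_tolerance = config$k_select_tolerance))
  k_genes <- if (!is.null(config$k_override_genes))
    select_k(cons_genes, override = config$k_override_genes)$k
  else cons_genes$chosen_k
  modules <- modules_from_gene_clusters(cons_genes, k_genes,
                                        dataset_tag = tag)
  .log(log_file, tag, ": ", length(modules), " gene modules at k = ",
       k_genes)

  reports <- .stage(paste0(tag, ":network_filter"), log_file,
    lapply(modules, filter_by_network, graph = graph, expr = expr,
           score_min = config$edge_score_min,
           corr_min = config$correlation_min))
  kept <- sort(unique(unlist(lapply(reports, `[[`, "kept_gene_ids"),
                             use.names = FALSE)))
  if (length(kept) < 3L)
    stop("stage '", tag, ":network_filter' failed: fewer than 3 genes ",
         "survive the network filter", call. = FALSE)
  .log(log_file, tag, ": ", length(kept), " genes kept by network filter")

  sk <- config$sample_k_range[config$sample_k_range <= ncol(expr)]
  cons_samples <- .stage(paste0(tag, ":cell_line_consensus"), log_file,
    consensus_cluster(expr[kept, , drop = FALSE], axis = "columns",
                      k_range = sk, n_iterations = config$n_iterations,
                      subsample_fraction = config$subsample_fraction,
                      seed = config$seed + 12L,
                      k_select_tolerance = config$k_select_tolerance))
  k_samples <- if (!is.null(config$k_override_samples))
    select_k(cons_samples, override = config$k_override_samples)$k
  else cons_samples$chosen_k
  labels <- cons_samples$assignments_per_k[, as.character(k_samples)]
  clustering <- cell_line_clustering(setNames(paste0("cluster_", labels),
                                              names(labels)))
  .log(log_file, tag, ": ", clustering$k, " cell-line clusters at k = ",
       k_samples)

  list(selected_genes = sel, gene_consensus = cons_genes,
       modules = modules, filter_reports = reports, kept_genes = kept,
       sample_consensus = cons_samples, clustering = clustering)
}

#' Run the full pipeline on a paired pair of datasets
#'
#' End-to-end orchestration: harmonizes the two expression panels, then per
#' panel selects variant genes, builds consensus gene modules, prunes them
#' against the interaction network, consensus-clusters the cell lines on
#' the surviving genes, and characterizes the clusters (differential
#' expression, module enrichment, mutation enrichment); across panels it
#' quantifies clustering concordance and matches cluster labels; when drug
#' responses are supplied it computes per-drug pseudo-F partition
#' comparisons (if tissue labels are given), cluster-drug associations per
#' panel and their robust cross-panel intersection. All result tables are
#' written as TSV under `out_dir` together with a provenance record
#' (configuration, seed, input checksums). With identical inputs and seed
#' the written tables are byte-identical across runs.
#'
#' @param config `AnalysisConfig`.
#' @param expr_a,expr_b expression matrices or TSV paths.
#' @param graph `InteractionGraph` or TSV path.
#' @param drugs_a,drugs_b optional `DrugResponseTable`s or TSV paths (then
#'   `drug_metric` applies).
#' @param mutations optional mutation matrix or TSV path.
#' @param tissue_labels optional named tissue vector or two-column TSV path.
#' @param out_dir output directory.
#' @param drug_metric metric declared when drug tables are read from file.
#' @return invisibly, a list with all intermediate and final objects
#'   (`harmonized`, `dataset_a`, `dataset_b`, `similarity`, `accuracy`,
#'   `match`, `de`, `gsea`, `mutation_enrichment`, `pseudo_f`,
#'   `associations`, `robust`, `paths`).
#' @export
run_pipeline <- function(config, expr_a, expr_b, graph, drugs_a = NULL,
                         drugs_b = NULL, mutations = NULL,
                         tissue_labels = NULL, out_dir,
                         drug_metric = "ic50_uM") {
  stopifnot(inherits(config, "AnalysisConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "pipeline.log")
  if (file.exists(log_file)) file.remove(log_file)

  checksums <- list()
  take <- function(x, reader, label) {
    if (is.character(x) && length(x) == 1L) {
      checksums[[label]] <<- unname(tools::md5sum(x))
      reader(x)
    } else x
  }
  expr_a <- take(expr_a, read_expression_matrix, "expr_a")
  expr_b <- take(expr_b, read_expression_matrix, "expr_b")
  graph <- take(graph, read_interaction_graph, "graph")
  drugs_a <- take(drugs_a, function(p)
    read_drug_response(p, metric = drug_metric), "drugs_a")
  drugs_b <- take(drugs_b, function(p)
    read_drug_response(p, metric = drug_metric), "drugs_b")
  mutations <- take(mutations, read_mutation_matrix, "mutations")
  if (is.character(tissue_labels) && length(tissue_labels) == 1L) {
    checksums[["tissues"]] <- unname(tools::md5sum(tissue_labels))
    tt <- read.delim(tissue_labels, colClasses = "character")
    tissue_labels <- setNames(tt[[2L]], tt[[1L]])
  }

  harmonized <- .stage("harmonize", log_file,
                       harmonize_datasets(expr_a, expr_b))

  res_a <- .cluster_one_dataset(harmonized$a, graph, config, "dataset_a",
                                log_file)
  res_b <- .cluster_one_dataset(harmonized$b, graph, config, "dataset_b",
                                log_file)

  similarity <- .stage("concordance", log_file,
                       build_similarity_matrix(res_a$clustering,
                                               res_b$clustering))
  accuracy <- concordance_accuracy(similarity)
  cl_match <- match_clusters(res_a$clustering, res_b$clustering)
  .log(log_file, sprintf("concordance accuracy: %.3f (jaccard) %.3f (rand)",
                         accuracy$jaccard, accuracy$rand))

  characterize <- function(res, expr, tag) {
    de_all <- list()
    gsea_all <- list()
    clusters <- sort(unique(res$clustering$labels))
    for (cl in clusters) {
      sizes <- table(res$clustering$labels)
      if (sizes[[cl]] < 2L || sum(sizes) - sizes[[cl]] < 2L) next
      de <- differential_expression(expr, res$clustering, cl)
      de_all[[cl]] <- de
      for (mi in seq_along(res$filter_reports)) {
        kept <- res$filter_reports[[mi]]$kept_gene_ids
        if (length(kept) == 0L || length(kept) >= nrow(expr)) next
        g <- preranked_gsea(de, structure(list(
          module_id = res$filter_reports[[mi]]$module_id,
          gene_ids = kept), class = "GeneModule"),
          n_permutations = config$gsea_permutations,
          seed = config$seed + 100L * mi + match(cl, clusters))
        gsea_all[[length(gsea_all) + 1L]] <-
          data.frame(cluster = cl, module_id = g$module_id, es = g$es,
                     nes = g$nes, p_value = g$p_value,
                     direction = g$direction, n_genes = g$n_hits,
                     stringsAsFactors = FALSE)
      }
    }
    list(de = de_all,
         gsea = if (length(gsea_all) > 0L) do.call(rbind, gsea_all)
           else NULL)
  }
  char_a <- .stage("characterization:dataset_a", log_file,
                   characterize(res_a, harmonized$a, "dataset_a"))
  char_b <- .stage("characterization:dataset_b", log_file,
                   characterize(res_b, harmonized$b, "dataset_b"))

  mut_enrich <- list(a = NULL, b = NULL)
  if (!is.null(mutations)) {
    mut_enrich$a <- .stage("mutation_enrichment:dataset_a", log_file,
                           mutation_enrichment(mutations, res_a$clustering))
    mut_enrich$b <- .stage("mutation_enrichment:dataset_b", log_file,
                           mutation_enrichment(mutations, res_b$clustering))
  }

  pf <- list(a = NULL, b = NULL)
  assoc <- list(a = NULL, b = NULL)
  robust <- NULL
  if (!is.null(drugs_a) && !is.null(drugs_b)) {
    sens_a <- transform_sensitivity(drugs_a)
    sens_b <- transform_sensitivity(drugs_b)
    if (!is.null(tissue_labels)) {
      pf$a <- .stage("pseudo_f:dataset_a", log_file,
                     compare_partitions(sens_a, res_a$clustering,
                                        tissue_labels))
      pf$b <- .stage("pseudo_f:dataset_b", log_file,
                     compare_partitions(sens_b, res_b$clustering,
                                        tissue_labels))
    }
    assoc$a <- .stage("associations:dataset_a", log_file,
                      cluster_drug_association(sens_a, res_a$clustering,
                                               config$fdr_alpha))
    assoc$b <- .stage("associations:dataset_b", log_file,
                      cluster_drug_association(sens_b, res_b$clustering,
                                               config$fdr_alpha))
    robust <- .stage("robust_associations", log_file,
                     robust_associations(assoc$a, assoc$b, cl_match))
  }

  paths <- .stage("write_results", log_file, {
    p <- function(f) file.path(out_dir, f)
    written <- character(0L)
    for (tag in c("a", "b")) {
      res <- if (tag == "a") res_a else res_b
      sel_path <- p(paste0("selected_genes_", tag, ".tsv"))
      prof <- compute_iqr_profile(if (tag == "a") harmonized$a
                                  else harmonized$b)
      prof$selected <- prof$gene_id %in% res$selected_genes
      .write_tsv(prof, sel_path)
      mod_tab <- do.call(rbind, lapply(res$modules, function(m)
        data.frame(module_id = m$module_id, gene_id = m$gene_ids,
                   stringsAsFactors = FALSE)))
      .write_tsv(mod_tab, p(paste0("gene_modules_", tag, ".tsv")))
      .write_tsv(filter_report_table(res$filter_reports),
                 p(paste0("filter_report_", tag, ".tsv")))
      write_clustering(res$clustering, p(paste0("clustering_", tag,
                                                ".tsv")))
      char <- if (tag == "a") char_a else char_b
      if (length(char$de) > 0L)
        .write_tsv(do.call(rbind, char$de),
                   p(paste0("differential_expression_", tag, ".tsv")))
      if (!is.null(char$gsea))
        .write_tsv(char$gsea, p(paste0("gsea_", tag, ".tsv")))
      if (!is.null(mut_enrich[[tag]]))
        .write_tsv(as.data.frame(mut_enrich[[tag]]),
                   p(paste0("mutation_enrichment_", tag, ".tsv")))
      if (!is.null(pf[[tag]]))
        .write_tsv(pf[[tag]]$per_drug, p(paste0("pseudo_f_", tag, ".tsv")))
      if (!is.null(assoc[[tag]]))
        .write_tsv(as.data.frame(assoc[[tag]]),
                   p(paste0("associations_", tag, ".tsv")))
    }
    sim_df <- data.frame(sample_id = similarity$sample_ids,
                         similarity$counts, check.names = FALSE,
                         stringsAsFactors = FALSE)
    .write_tsv(sim_df, p("similarity_matrix.tsv"))
    .write_tsv(data.frame(definition = c("jaccard", "rand"),
                          accuracy = c(accuracy$jaccard, accuracy$rand)),
               p("concordance_accuracy.tsv"))
    .write_tsv(data.frame(cluster_a = names(cl_match$mapping),
                          cluster_b = unname(cl_match$mapping),
                          stringsAsFactors = FALSE),
               p("cluster_match.tsv"))
    if (!is.null(robust))
      .write_tsv(as.data.frame(robust), p("robust_associations.tsv"))
    provenance <- list(config = unclass(config), seed = config$seed,
                       input_checksums = checksums,
                       n_genes_harmonized = nrow(harmonized$a),
                       n_samples_harmonized = ncol(harmonized$a))
    jsonlite::write_json(provenance, p("provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    p("")
  })

  invisible(list(harmonized = harmonized, dataset_a = res_a,
                 dataset_b = res_b, similarity = similarity,
                 accuracy = accuracy, match = cl_match,
                 de = list(a = char_a$de, b = char_b$de),
                 gsea = list(a = char_a$gsea, b = char_b$gsea),
                 mutation_enrichment = mut_enrich, pseudo_f = pf,
                 associations = assoc, robust = robust,
                 out_dir = out_dir))
}
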