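#' Prune a gene module against a scored interaction network
#'
#' A gene module obtained by co-expression consensus clustering is refined
#' in two steps. Step 1 keeps genes with at least one strong edge (combined
#' score >= `score_min`) to another module gene; the connected components of
#' this strong-edge subgraph are the module's "biological networks". Step 2
#' keeps, within each network, the genes whose expression agrees with the
#' other step-1 survivors of the same network: by default the mean Pearson
#' correlation with the other members must reach `corr_min` (set
#' `corr_mode = "max"` to require only the best pairwise correlation to
#' reach it). Networks reduced to a single gene are dropped. Genes absent
#' from the graph are treated as unconnected. Both steps are applied once,
#' not iterated.
#'
#' @param module `GeneModule` (or list with `module_id` and `gene_ids`).
#' @param graph `InteractionGraph` edge table.
#' @param expr expression matrix containing all module genes.
#' @param score_min minimum combined score for a "strong" edge, inclusive
#'   (default 0.7).
#' @param corr_min minimum within-network expression correlation, inclusive
#'   (default 0.5).
#' @param corr_mode `"mean"` (default) or `"max"`: how the per-gene
#'   correlation with the other network members is summarized.
#' @return list of class `"FilterReport"`: `module_id`, `kept_gene_ids`,
#'   `dropped` (named character vector gene -> reason, reasons
#'   `"no_strong_edge"` or `"low_correlation"`), `networks` (list of
#'   strong-edge components), and the thresholds used.
#' @export
filter_by_network <- function(module, graph, expr, score_min = 0.7,
                              corr_min = 0.5, corr_mode = c("mean", "max")) {
  corr_mode <- match.arg(corr_mode)
  stopifnot(is.list(module), !is.null(module$gene_ids))
  genes <- module$gene_ids
  if (length(genes) == 0L) stop("module is empty", call. = FALSE)
  validate_expression_matrix(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stop("module gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  genes <- sort(genes)  # output independent of input gene ordering

  # step 1: strong-edge subgraph restricted to the module
  e <- graph[graph$score >= score_min &
               graph$gene_a %in% genes & graph$gene_b %in% genes, ,
             drop = FALSE]
  dropped <- character(0L)
  if (nrow(e) == 0L) {
    dropped <- setNames(rep("no_strong_edge", length(genes)), genes)
    networks <- list()
    kept <- character(0L)
  } else {
    g <- igraph::graph_from_data_frame(e[order(e$gene_a, e$gene_b),
                                         c("gene_a", "gene_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    networks <- split(names(comp$membership), comp$membership)
    networks <- lapply(networks, sort)
    names(networks) <- paste0("network_", seq_along(networks))
    connected <- sort(unlist(networks, use.names = FALSE))
    no_edge <- setdiff(genes, connected)
    dropped <- setNames(rep("no_strong_edge", length(no_edge)), no_edge)

    # step 2: within-network co-expression on step-1 survivors; genes
    # failing the correlation criterion are peeled off one at a time (worst
    # first) so that one outlier cannot drag down well-correlated members
    kept <- character(0L)
    for (net in networks) {
      cc <- cor(t(expr[net, , drop = FALSE]))
      diag(cc) <- NA
      surv <- net
      while (length(surv) >= 2L) {
        sub <- cc[surv, surv, drop = FALSE]
        stat <- if (corr_mode == "mean") rowMeans(sub, na.rm = TRUE)
                else apply(sub, 1L, max, na.rm = TRUE)
        if (all(stat >= corr_min)) break
        worst <- surv[which.min(stat)]
        dropped[worst] <- "low_correlation"
        surv <- setdiff(surv, worst)
      }
      if (length(surv) < 2L) {       # a lone gene is not a network
        dropped[surv] <- "low_correlation"
        surv <- character(0L)
      }
      kept <- c(kept, surv)
    }
    kept <- sort(kept)
  }

  structure(list(module_id = module$module_id, kept_gene_ids = kept,
                 dropped = dropped[order(names(dropped))],
                 networks = networks, score_min = score_min,
                 corr_min = corr_min, corr_mode = corr_mode),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport for", x$module_id, ":", length(x$kept_gene_ids),
      "kept,", sum(x$dropped == "no_strong_edge"), "without strong edge,",
      sum(x$dropped == "low_correlation"), "poorly correlated\n")
  invisible(x)
}

#' Tabulate one or more filter reports
#'
#' @param reports list of `FilterReport` objects (or a single one).
#' @return data.frame with columns `module_id`, `gene_id`, `status`
#'   (`"kept"` or a drop reason).
#' @export
filter_report_table <- function(reports) {
  if (inherits(reports, "FilterReport")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(module_id = r$module_id,
               gene_id = c(r$kept_gene_ids, names(r$dropped)),
               status = c(rep("kept", length(r$kept_gene_ids)),
                          unname(r$dropped)),
               stringsAsFactors = FALSE)
  }))
}
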