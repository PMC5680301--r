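#' Cluster-versus-rest differential expression
#'
#' For one cluster, splits the cell lines into members and non-members and
#' compares mean expression gene by gene with a two-sample t statistic
#' (Welch by default, pooled-variance optionally; the mode used is recorded
#' on the result). Genes are returned ranked by descending signed t, the
#' ranking consumed by pre-ranked gene set enrichment.
#'
#' @param expr expression matrix (genes x samples).
#' @param clustering `CellLineClustering` covering the samples of `expr`.
#' @param cluster label of the cluster to contrast against the rest.
#' @param var_mode `"welch"` (default) or `"pooled"`.
#' @return data.frame of class `"DeResult"`, one row per gene, ranked:
#'   columns `gene_id`, `t_statistic`, `p_value`, `cluster`, `rank`.
#' @export
differential_expression <- function(expr, clustering, cluster,
                                    var_mode = c("welch", "pooled")) {
  var_mode <- match.arg(var_mode)
  validate_expression_matrix(expr)
  stopifnot(inherits(clustering, "CellLineClustering"))
  common <- intersect(colnames(expr), clustering$sample_ids)
  if (length(common) < 4L)
    stop("need >= 4 samples shared between expression and clustering",
         call. = FALSE)
  lab <- clustering$labels[common]
  if (!cluster %in% lab)
    stop("cluster '", cluster, "' has no member among the shared samples",
         call. = FALSE)
  x <- expr[, common, drop = FALSE]
  in_grp <- lab == cluster
  n1 <- sum(in_grp)
  n2 <- sum(!in_grp)
  if (n1 < 2L || n2 < 2L)
    stop("insufficient replicates: cluster '", cluster, "' has ", n1,
         " member(s) and ", n2, " non-member(s); need >= 2 in each group",
         call. = FALSE)
  m1 <- rowMeans(x[, in_grp, drop = FALSE])
  m2 <- rowMeans(x[, !in_grp, drop = FALSE])
  v1 <- rowSums((x[, in_grp, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, !in_grp, drop = FALSE] - m2)^2) / (n2 - 1)
  if (var_mode == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tt))
  }
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  ord <- order(-tt, rownames(x), method = "radix")
  out <- data.frame(gene_id = rownames(x)[ord], t_statistic = unname(tt[ord]),
                    p_value = unname(p[ord]), cluster = cluster,
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "var_mode") <- var_mode
  class(out) <- c("DeResult", "data.frame")
  out
}

# weighted Kolmogorov-Smirnov running-sum enrichment score (weight w = 1):
# hits step up proportionally to |stat|, misses step down uniformly; the
# score is the extremum of the running sum
.gsea_es <- function(stat_ranked, is_hit) {
  nh <- sum(is_hit)
  n <- length(stat_ranked)
  w <- abs(stat_ranked)
  denom_hit <- sum(w[is_hit])
  steps <- numeric(n)
  if (denom_hit == 0) {
    # all hit statistics are zero: hits contribute equal weights
    steps[is_hit] <- 1 / nh
  } else {
    steps[is_hit] <- w[is_hit] / denom_hit
  }
  steps[!is_hit] <- -1 / (n - nh)
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

#' Pre-ranked gene set enrichment of a gene module
#'
#' Computes the weighted running-sum enrichment score (ES) of a gene module
#' within a t-statistic-ranked gene list (weight exponent 1: hit increments
#' are proportional to |t|, miss decrements uniform; ES is the extremum of
#' the running sum). Significance comes from gene-label permutations: the
#' module positions are redrawn uniformly, and the p-value is the fraction
#' of same-sign permutation scores at least as extreme as the observed ES
#' (with a +1 continuity correction so p stays in (0, 1\]). The normalized
#' score (NES) divides ES by the mean magnitude of same-sign permutation
#' scores.
#'
#' @param ranked `DeResult` from [differential_expression()] (or any
#'   data.frame with `gene_id` and `t_statistic` ordered by descending
#'   statistic).
#' @param module `GeneModule` or character vector of member genes; must be
#'   a non-empty proper subset of the ranked genes.
#' @param n_permutations number of gene-label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list of class `"GseaResult"`: `module_id`, `cluster`, `es`,
#'   `nes`, `p_value`, `direction` (`"up"` or `"down"`), `n_hits`,
#'   `n_permutations`, `seed`.
#' @export
preranked_gsea <- function(ranked, module, n_permutations = 1000L, seed = 1L) {
  stopifnot(is.data.frame(ranked),
            all(c("gene_id", "t_statistic") %in% colnames(ranked)))
  if (is.unsorted(rev(ranked$t_statistic)))
    stop("ranked list must be ordered by descending t statistic",
         call. = FALSE)
  genes <- if (is.list(module)) module$gene_ids else module
  module_id <- if (is.list(module)) module$module_id else "module"
  extra <- setdiff(genes, ranked$gene_id)
  if (length(extra) > 0L)
    stop("module gene(s) absent from the ranked list: ",
         paste(utils::head(extra, 3L), collapse = ", "), call. = FALSE)
  is_hit <- ranked$gene_id %in% genes
  nh <- sum(is_hit)
  n <- nrow(ranked)
  if (nh == 0L || nh == n)
    stop("module must be a non-empty proper subset of the ranked genes",
         call. = FALSE)
  stat <- ranked$t_statistic
  es <- .gsea_es(stat, is_hit)

  perm_es <- .with_seed(seed, function()
    vapply(seq_len(n_permutations), function(i) {
      hit <- logical(n)
      hit[sample.int(n, nh)] <- TRUE
      .gsea_es(stat, hit)
    }, numeric(1L)))
  same_sign <- if (es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
  if (length(same_sign) == 0L) {
    p <- 1
    nes <- NA_real_
  } else {
    p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
    nes <- es / mean(abs(same_sign))
  }
  structure(list(module_id = module_id,
                 cluster = if ("cluster" %in% colnames(ranked))
                   ranked$cluster[1L] else NA_character_,
                 es = es, nes = nes, p_value = p,
                 direction = if (es >= 0) "up" else "down",
                 n_hits = nh, n_permutations = n_permutations, seed = seed),
            class = "GseaResult")
}

#' @export
print.GseaResult <- function(x, ...) {
  cat(sprintf("GseaResult: %s in cluster %s | ES %.3f (NES %.2f, %s), p = %.4g\n",
              x$module_id, x$cluster, x$es,
              if (is.na(x$nes)) NA else x$nes, x$direction, x$p_value))
  invisible(x)
}

#' Cluster-wise mutation enrichment by one-tailed Fisher tests
#'
#' For every (gene, cluster) pair, compares the mutation frequency inside
#' the cluster with that in all remaining cell lines combined through a
#' one-tailed (enrichment) Fisher exact test, then applies
#' Benjamini-Hochberg adjustment jointly across all (gene, cluster) pairs.
#' Genes with no mutation anywhere get p = 1.
#'
#' @param mut binary mutation matrix (genes x samples).
#' @param clustering `CellLineClustering` sharing samples with `mut`.
#' @return data.frame of class `"EnrichmentResult"`: `gene_id`, `cluster`,
#'   `mutated_in`, `unmutated_in`, `mutated_out`, `unmutated_out`,
#'   `p_value`, `adjusted_p`.
#' @export
mutation_enrichment <- function(mut, clustering) {
  validate_mutation_matrix(mut)
  stopifnot(inherits(clustering, "CellLineClustering"))
  common <- intersect(colnames(mut), clustering$sample_ids)
  if (length(common) < 2L)
    stop("mutation matrix and clustering share fewer than 2 samples",
         call. = FALSE)
  m <- mut[, common, drop = FALSE]
  lab <- clustering$labels[common]
  clusters <- sort(unique(lab))
  rows <- vector("list", nrow(m) * length(clusters))
  i <- 0L
  for (g in rownames(m)) {
    mg <- m[g, ]
    total_mut <- sum(mg)
    for (cl in clusters) {
      inc <- lab == cl
      a <- sum(mg[inc])
      b <- sum(inc) - a
      cc <- total_mut - a
      d <- sum(!inc) - cc
      p <- if (total_mut == 0L) 1 else
        fisher.test(matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE),
                    alternative = "greater")$p.value
      i <- i + 1L
      rows[[i]] <- data.frame(gene_id = g, cluster = cl, mutated_in = a,
                              unmutated_in = b, mutated_out = cc,
                              unmutated_out = d, p_value = p,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Label cell lines as epithelial, mesenchymal or neither
#'
#' Restricts the expression matrix to an EMT signature (genes upregulated in
#' mesenchymal cells and genes downregulated, i.e. epithelial markers),
#' standardizes each gene, hierarchically clusters the cell lines (Pearson
#' distance, Ward linkage) into three groups, and labels each group by the
#' contrast between its mean expression of up- and down-signature genes:
#' mesenchymal when up-genes dominate by more than `delta` standardized
#' units, epithelial when down-genes dominate by the same margin, neither
#' otherwise.
#'
#' @param expr expression matrix (genes x samples).
#' @param signature_up character vector: mesenchymal (upregulated) genes.
#' @param signature_down character vector: epithelial (downregulated) genes.
#' @param delta labeling margin on the standardized scale (default 0.5).
#' @param min_coverage minimum fraction of signature genes that must be
#'   present in `expr` (default 0.5).
#' @return data.frame of class `"EmtCall"`: `sample_id`, `label` in
#'   \{epithelial, mesenchymal, neither\}; per-group scores in
#'   `attr(, "group_scores")`.
#' @export
classify_emt <- function(expr, signature_up, signature_down, delta = 0.5,
                         min_coverage = 0.5) {
  validate_expression_matrix(expr)
  sig <- unique(c(signature_up, signature_down))
  present <- intersect(sig, rownames(expr))
  if (length(present) < min_coverage * length(sig)) {
    miss <- setdiff(sig, rownames(expr))
    stop("only ", length(present), "/", length(sig), " signature genes ",
         "present in the expression matrix; missing e.g. ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  x <- expr[present, , drop = FALSE]
  z <- (x - rowMeans(x)) / apply(x, 1L, sd)
  z <- z[is.finite(rowSums(z)), , drop = FALSE]  # drop constant genes
  if (nrow(z) < 2L)
    stop("fewer than 2 informative (non-constant) signature genes",
         call. = FALSE)
  hc <- hclust(.pearson_dist(t(z)), method = "ward.D2")
  grp <- cutree(hc, k = 3L)
  up <- intersect(signature_up, rownames(z))
  down <- intersect(signature_down, rownames(z))
  scores <- vapply(1:3, function(g) {
    cols <- grp == g
    mean(z[up, cols, drop = FALSE]) - mean(z[down, cols, drop = FALSE])
  }, numeric(1L))
  lab_for <- function(s) {
    if (is.na(s)) "neither"
    else if (s > delta) "mesenchymal"
    else if (s < -delta) "epithelial"
    else "neither"
  }
  group_label <- vapply(scores, lab_for, character(1L))
  out <- data.frame(sample_id = colnames(z), label = group_label[grp],
                    stringsAsFactors = FALSE)
  attr(out, "group_scores") <- setNames(scores, paste0("group_", 1:3))
  class(out) <- c("EmtCall", "data.frame")
  out
}

# two-component univariate Gaussian mixture call: is each sample in the
# higher-mean component? Falls back to "unimodal" (all negative) when the
# one-component model wins or a component holds fewer than 2 samples.
.bimodal_positive <- function(x, seed) {
  fit <- .with_seed(seed, function()
    suppressWarnings(mclust::Mclust(x, G = 1:2, modelNames = c("E", "V"),
                                    verbose = FALSE)))
  if (is.null(fit) || fit$G == 1L)
    return(list(positive = rep(FALSE, length(x)), unimodal = TRUE,
                means = if (is.null(fit)) NA else fit$parameters$mean))
  hi <- which.max(fit$parameters$mean)
  positive <- fit$z[, hi] > 0.5
  if (min(fit$parameters$pro) * length(x) < 2 || sum(positive) < 2 ||
      sum(!positive) < 2)
    return(list(positive = rep(FALSE, length(x)), unimodal = TRUE,
                means = fit$parameters$mean))
  list(positive = positive, unimodal = FALSE, means = fit$parameters$mean)
}

#' Call breast-cancer receptor subtypes from ESR1, PGR and ERBB2 expression
#'
#' Fits, per receptor gene, a two-component Gaussian mixture to its
#' expression across cell lines; a sample is "positive" for the gene when
#' its posterior probability of belonging to the higher-mean component
#' exceeds 0.5. Genes for which the single-component model is preferred, or
#' whose fitted components hold fewer than two samples, are flagged
#' unimodal and all samples are called negative for them (with a warning).
#' Subtypes follow receptor precedence: ERBB2-positive samples are `Her2+`
#' regardless of the other receptors; otherwise ESR1-positive samples are
#' `ER+Her2-`; samples negative for all three receptors are `TN`
#' (triple-negative); anything else is `other`.
#'
#' @param expr expression matrix containing rows for the three receptor
#'   genes and >= 10 samples.
#' @param genes character vector naming the rows to use, in the order
#'   (ESR1, PGR, ERBB2).
#' @param seed integer seed for the mixture fits.
#' @return data.frame of class `"SubtypeCall"`: `sample_id`, `label` in
#'   \{TN, ER+Her2-, Her2+, other\}; per-gene positivity in
#'   `attr(, "gene_calls")`, unimodal flags in `attr(, "unimodal")`.
#' @export
call_breast_subtypes <- function(expr, genes = c("ESR1", "PGR", "ERBB2"),
                                 seed = 1L) {
  validate_expression_matrix(expr)
  stopifnot(length(genes) == 3L)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0L)
    stop("receptor gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (ncol(expr) < 10L)
    stop("need at least 10 samples for mixture fitting", call. = FALSE)
  fits <- lapply(seq_along(genes), function(i)
    .bimodal_positive(expr[genes[i], ], seed + i))
  names(fits) <- c("ESR1", "PGR", "ERBB2")
  unimodal <- vapply(fits, `[[`, logical(1L), "unimodal")
  if (any(unimodal))
    warning("unimodal expression for ",
            paste(names(fits)[unimodal], collapse = ", "),
            "; all samples called negative for these gene(s)")
  pos <- vapply(fits, `[[`, logical(ncol(expr)), "positive")
  label <- ifelse(pos[, "ERBB2"], "Her2+",
                  ifelse(pos[, "ESR1"], "ER+Her2-",
                         ifelse(!pos[, "PGR"], "TN", "other")))
  out <- data.frame(sample_id = colnames(expr), label = label,
                    stringsAsFactors = FALSE)
  attr(out, "gene_calls") <- pos
  attr(out, "unimodal") <- unimodal
  class(out) <- c("SubtypeCall", "data.frame")
  out
}
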