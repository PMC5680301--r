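make_clustered_expr <- function(n_genes = 50, n_in = 6, n_out = 14,
                                shifted_gene = "g001", shift = 3, seed = 1) {
  set.seed(seed)
  n <- n_in + n_out
  x <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  x[shifted_gene, seq_len(n_in)] <- x[shifted_gene, seq_len(n_in)] + shift
  cl <- cell_line_clustering(setNames(rep(c("in", "out"), c(n_in, n_out)),
                                      colnames(x)))
  list(expr = x, clustering = cl)
}

test_that("a strongly shifted gene tops the cluster-vs-rest ranking", {
  hits <- vapply(1:20, function(s) {
    d <- make_clustered_expr(shift = 3, seed = s)
    de <- differential_expression(d$expr, d$clustering, "in")
    de$gene_id[1] == "g001" && de$t_statistic[1] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null differential expression has roughly uniform p-values", {
  set.seed(123)
  x <- matrix(rnorm(400 * 30), 400, 30,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:30)))
  cl <- cell_line_clustering(setNames(rep(c("a", "b"), each = 15),
                                      colnames(x)))
  de <- differential_expression(x, cl, "a")
  ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  # ranking is a permutation of the genes, ordered by descending t
  expect_setequal(de$gene_id, rownames(x))
  expect_false(is.unsorted(rev(de$t_statistic)))
})

test_that("undersized clusters are an error", {
  d <- make_clustered_expr(n_in = 1, n_out = 10)
  expect_error(differential_expression(d$expr, d$clustering, "in"),
               "insufficient replicates")
})

test_that("GSEA enrichment score matches the brute-force running sum", {
  # top-loaded module with equal |t|
  ranked <- data.frame(gene_id = paste0("g", 1:10),
                       t_statistic = rep(c(2, -2), each = 5))
  ranked <- ranked[order(-ranked$t_statistic), ]
  res <- preranked_gsea(ranked, paste0("g", 1:3), n_permutations = 50,
                        seed = 1)
  expect_equal(res$es, oracle_es(ranked$t_statistic,
                                 ranked$gene_id %in% paste0("g", 1:3)))
  expect_equal(res$es, 1)  # all 3 hits lead the list: running sum peaks at 1
  expect_identical(res$direction, "up")

  # random ranked lists of length <= 20, random modules
  set.seed(31)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    stat <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    ranked <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                         t_statistic = stat)
    nh <- sample(seq_len(n - 1), 1)
    hit_ids <- sample(ranked$gene_id, nh)
    res <- preranked_gsea(ranked, hit_ids, n_permutations = 10, seed = i)
    expect_equal(res$es, oracle_es(stat, ranked$gene_id %in% hit_ids),
                 info = paste("case", i))
  }
})

test_that("GSEA p-values are well-behaved under the null", {
  set.seed(77)
  pvals <- vapply(1:40, function(i) {
    stat <- sort(rnorm(40, sd = 2), decreasing = TRUE)
    ranked <- data.frame(gene_id = sprintf("g%02d", 1:40),
                         t_statistic = stat)
    preranked_gsea(ranked, sample(ranked$gene_id, 8),
                   n_permutations = 100, seed = i)$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.75)
  expect_true(all(pvals > 0 & pvals <= 1))
})

test_that("degenerate modules are rejected", {
  ranked <- data.frame(gene_id = paste0("g", 1:5),
                       t_statistic = c(3, 2, 1, 0, -1))
  expect_error(preranked_gsea(ranked, paste0("g", 1:5)), "proper subset")
  expect_error(preranked_gsea(ranked, character(0)), "proper subset")
  expect_error(preranked_gsea(ranked, "missing_gene"), "absent")
})

test_that("mutation enrichment matches the hypergeometric tail", {
  # 5/5 mutated in cluster, 0/5 outside: p = 1/252
  m <- matrix(c(rep(1, 5), rep(0, 5)), nrow = 1,
              dimnames = list("gene1", sprintf("s%02d", 1:10)))
  cl <- cell_line_clustering(setNames(rep(c("c1", "c2"), each = 5),
                                      colnames(m)))
  res <- mutation_enrichment(m, cl)
  p_c1 <- res$p_value[res$cluster == "c1"]
  expect_equal(p_c1, 1 / 252, tolerance = 1e-12)
  expect_equal(p_c1, oracle_fisher_greater(5, 0, 0, 5), tolerance = 1e-12)

  # balanced rates: one-tailed p above 0.5
  m2 <- matrix(rep(c(1, 1, 0, 0, 0), 2), nrow = 1,
               dimnames = list("gene1", sprintf("s%02d", 1:10)))
  res2 <- mutation_enrichment(m2, cl)
  expect_true(all(res2$p_value > 0.5))

  # no mutations anywhere: p = 1 by convention
  m3 <- matrix(0, 1, 10, dimnames = dimnames(m))
  expect_true(all(mutation_enrichment(m3, cl)$p_value == 1))
})

test_that("Fisher p-values agree with enumeration on all small tables", {
  cl2 <- cell_line_clustering(setNames(rep(c("c1", "c2"), c(4, 6)),
                                       sprintf("s%02d", 1:10)))
  for (n_mut_in in 0:4) for (n_mut_out in 0:6) {
    m <- matrix(c(rep(1, n_mut_in), rep(0, 4 - n_mut_in),
                  rep(1, n_mut_out), rep(0, 6 - n_mut_out)), nrow = 1,
                dimnames = list("g", sprintf("s%02d", 1:10)))
    res <- mutation_enrichment(m, cl2)
    expect_equal(res$p_value[res$cluster == "c1"],
                 oracle_fisher_greater(n_mut_in, 4 - n_mut_in,
                                       n_mut_out, 6 - n_mut_out),
                 tolerance = 1e-12,
                 info = paste(n_mut_in, n_mut_out))
  }
})

test_that("BH adjustment matches the sorted-definition oracle", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p),
                 info = paste("case", i))
  }
  # and the adjusted values surfaced by mutation_enrichment are BH over all
  # (gene, cluster) pairs jointly
  set.seed(9)
  m <- matrix(rbinom(4 * 12, 1, 0.3), 4, 12,
              dimnames = list(paste0("g", 1:4), sprintf("s%02d", 1:12)))
  cl <- cell_line_clustering(setNames(rep(c("c1", "c2", "c3"), each = 4),
                                      colnames(m)))
  res <- mutation_enrichment(m, cl)
  expect_equal(res$adjusted_p, oracle_bh(res$p_value))
})

test_that("EMT labels follow the planted signature contrast", {
  set.seed(15)
  up <- sprintf("mes%02d", 1:12)    # mesenchymal-high genes
  down <- sprintf("epi%02d", 1:15)  # epithelial-high genes
  n <- 30
  x <- matrix(rnorm(27 * n, sd = 0.5), 27, n,
              dimnames = list(c(up, down), sprintf("s%02d", seq_len(n))))
  mes <- 1:10         # mesenchymal block
  epi <- 11:20        # epithelial block
  x[up, mes] <- x[up, mes] + 2; x[down, mes] <- x[down, mes] - 2
  x[up, epi] <- x[up, epi] - 2; x[down, epi] <- x[down, epi] + 2
  calls <- classify_emt(x, up, down)
  expect_true(all(calls$label[mes] == "mesenchymal"))
  expect_true(all(calls$label[epi] == "epithelial"))
  # unsignatured noise samples have no correlation anchor; most, not
  # necessarily all, land in the low-contrast group
  expect_gte(mean(calls$label[21:30] == "neither"), 0.6)
  # flipped pattern flips the labels
  calls2 <- classify_emt(-x + 10, up, down)
  expect_true(all(calls2$label[mes] == "epithelial"))
  expect_true(all(calls2$label[epi] == "mesenchymal"))
})

test_that("EMT coverage below threshold is an error listing missing genes", {
  x <- matrix(rnorm(2 * 12), 2, 12,
              dimnames = list(c("mes01", "epi01"), sprintf("s%02d", 1:12)))
  expect_error(classify_emt(x, c("mes01", "mes02", "mes03"),
                            c("epi01", "epi02", "epi03")),
               "signature genes")
})

test_that("receptor subtype calls recover planted bimodal positives", {
  agreements <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    pos <- seq_len(n) <= 20
    esr1 <- ifelse(pos, rnorm(n, 8, 0.5), rnorm(n, 3, 0.5))
    x <- rbind(ESR1 = esr1, PGR = rnorm(n, 3, 0.5), ERBB2 = rnorm(n, 3, 0.5))
    colnames(x) <- sprintf("s%02d", seq_len(n))
    calls <- suppressWarnings(call_breast_subtypes(x, seed = s))
    esr1_pos <- attr(calls, "gene_calls")[, "ESR1"]
    mean(esr1_pos == pos)
  }, numeric(1))
  expect_gte(mean(agreements), 0.95)
})

test_that("subtype labels follow receptor precedence and unimodal convention", {
  set.seed(30)
  n <- 40
  hi <- seq_len(n) <= 15
  esr1 <- ifelse(hi, rnorm(n, 9, 0.4), rnorm(n, 3, 0.4))
  erbb2 <- ifelse(hi, rnorm(n, 10, 0.4), rnorm(n, 4, 0.4))
  x <- rbind(ESR1 = esr1, PGR = rnorm(n, 3, 0.4), ERBB2 = erbb2)
  colnames(x) <- sprintf("s%02d", seq_len(n))
  calls <- suppressWarnings(call_breast_subtypes(x, seed = 1))
  # ESR1-high & ERBB2-high samples: ERBB2 takes precedence
  expect_true(all(calls$label[hi] == "Her2+"))
  expect_true(all(calls$label[!hi] == "TN"))

  # all three receptors unimodal-low: everything triple-negative
  x2 <- rbind(ESR1 = rnorm(n, 3, 0.3), PGR = rnorm(n, 3, 0.3),
              ERBB2 = rnorm(n, 3, 0.3))
  colnames(x2) <- colnames(x)
  expect_warning(calls2 <- call_breast_subtypes(x2, seed = 2), "unimodal")
  expect_true(all(calls2$label == "TN"))
})
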