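sens_vec <- function(v, ids = sprintf("s%02d", seq_along(v)), drug = "d1") {
  structure(list(drug_id = drug, values = setNames(v, ids),
                 source_metric = "ic50_uM"), class = "SensitivityVector")
}

test_that("metric conversions land on the common high-is-sensitive scale", {
  ic50 <- drug_response_table(
    matrix(c(1, 0.1, NA, 10), 2, 2,
           dimnames = list(c("d1", "d2"), c("s1", "s2"))),
    metric = "ic50_uM")
  s <- transform_sensitivity(ic50)
  expect_equal(s[[1]]$values, c(s1 = 6, s2 = NA))        # 1 uM -> -log10(1e-6)
  expect_equal(s[[2]]$values, c(s1 = 7, s2 = 5))
  # lower IC50 means higher sensitivity score (strict monotonicity)
  set.seed(2)
  ic <- sort(runif(20, 0.001, 100))
  tr <- transform_sensitivity(drug_response_table(
    matrix(ic, 1, dimnames = list("d", paste0("s", 1:20))),
    metric = "ic50_uM"))[[1]]$values
  expect_true(all(diff(tr) < 0))

  via <- drug_response_table(
    matrix(c(0.25, 0.9), 1, dimnames = list("d1", c("s1", "s2"))),
    metric = "mean_viability")
  expect_equal(transform_sensitivity(via)[[1]]$values,
               c(s1 = 0.75, s2 = 0.1))

  auc <- drug_response_table(
    matrix(c(0.3, 0.8), 1, dimnames = list("d1", c("s1", "s2"))),
    metric = "auc", orientation = "high_is_sensitive")
  expect_equal(transform_sensitivity(auc)[[1]]$values, c(s1 = 0.3, s2 = 0.8))
  auc_r <- drug_response_table(auc$values, metric = "auc",
                               orientation = "high_is_resistant")
  expect_equal(transform_sensitivity(auc_r)[[1]]$values,
               c(s1 = 0.7, s2 = 0.2))

  bad <- drug_response_table(
    matrix(c(0, 1), 1, dimnames = list("d1", c("s1", "s2"))),
    metric = "ic50_uM")
  expect_error(transform_sensitivity(bad), "nonpositive IC50.*d1.*s1")
})

test_that("pseudo-F matches the hand variance decomposition", {
  part <- setNames(c("A", "A", "B", "B"), sprintf("s%02d", 1:4))
  rep <- pseudo_f(sens_vec(c(0, 1, 10, 11)), part)
  expect_equal(rep$between_ss, 100)
  expect_equal(rep$within_ss, 1)
  expect_equal(rep$pseudo_f, 200)          # (100/1)/(1/2)
  expect_equal(rep$pseudo_f_printed, 50)   # (100/2)/(1/1)

  # all equal -> 0; perfectly separated -> infinity flag, no crash
  expect_equal(pseudo_f(sens_vec(rep(3, 4)), part)$pseudo_f, 0)
  degen <- pseudo_f(sens_vec(c(0, 0, 10, 10)), part)
  expect_true(degen$infinite)
  expect_identical(degen$pseudo_f, Inf)
  expect_error(pseudo_f(sens_vec(c(1, 2, NA, NA)), part), ">= 2 groups")
})

test_that("pseudo-F equals the brute-force oracle on random instances", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    ids <- sprintf("s%02d", seq_len(n))
    v <- rnorm(n, sd = sample(c(0.5, 2, 10), 1))
    v[sample(n, floor(n / 5))] <- NA
    g <- setNames(sample(paste0("grp", 1:3), n, replace = TRUE), ids)
    if (length(unique(g[!is.na(setNames(v, ids))])) < 2) next
    rep <- tryCatch(pseudo_f(sens_vec(v, ids), g), error = function(e) NULL)
    if (is.null(rep) || rep$infinite) next
    expect_equal(rep$pseudo_f,
                 oracle_pseudo_f(setNames(v, ids)[names(g)], g),
                 tolerance = 1e-10, info = paste("case", i))
    # shift invariance and scale invariance of the ratio
    rep2 <- pseudo_f(sens_vec(v * 3.7 + 11, ids), g)
    expect_equal(rep2$pseudo_f, rep$pseudo_f, tolerance = 1e-8)
  }
})

test_that("partition comparison favors the partition aligned with the effects", {
  set.seed(41)
  n <- 60
  ids <- sprintf("s%02d", seq_len(n))
  cl <- setNames(rep(paste0("c", 1:4), each = 15), ids)
  ti <- setNames(sample(rep(paste0("t", 1:4), each = 15)), ids)
  clustering <- cell_line_clustering(cl)
  mk_drugs <- function(aligned_with) lapply(1:10, function(d) {
    eff <- 2 * (aligned_with == paste0(substr(aligned_with[1], 1, 1),
                                       (d %% 4) + 1))
    sens_vec(rnorm(n) + eff, ids, drug = paste0("drug", d))
  })
  cmp <- compare_partitions(mk_drugs(cl), clustering, ti)
  expect_gte(cmp$win_fraction, 0.8)
  expect_false(is.null(cmp$t_test))
  # effects aligned with tissues instead: the comparison reverses
  cmp_rev <- compare_partitions(mk_drugs(ti), clustering, ti)
  expect_lte(cmp_rev$win_fraction, 0.2)
  # single drug: no t-test
  cmp1 <- compare_partitions(mk_drugs(cl)[1], clustering, ti)
  expect_null(cmp1$t_test)
  expect_equal(cmp1$n_drugs, 1L)
})

test_that("cluster-drug associations call the planted phenotype", {
  set.seed(55)
  n <- 60
  ids <- sprintf("s%02d", seq_len(n))
  cl <- cell_line_clustering(setNames(rep(paste0("c", 1:4), each = 15), ids))
  hits <- vapply(1:50, function(i) {
    v <- rnorm(n)
    v[cl$labels == "c2"] <- v[cl$labels == "c2"] + 2
    res <- cluster_drug_association(sens_vec(v, ids), cl)
    row <- res[res$cluster == "c2", ]
    row$significant && row$phenotype == "sensitive"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("phenotype follows the sign of t and small groups are skipped", {
  set.seed(56)
  n <- 40
  ids <- sprintf("s%02d", seq_len(n))
  labels <- setNames(c(rep("big1", 19), rep("big2", 19), rep("tiny", 2)), ids)
  cl <- cell_line_clustering(labels)
  v <- rnorm(n)
  v[labels == "big1"] <- v[labels == "big1"] - 3   # resistant shift
  res <- cluster_drug_association(sens_vec(v, ids), cl)
  expect_false("tiny" %in% res$cluster)
  skipped <- attr(res, "skipped")
  expect_identical(skipped$cluster, "tiny")
  expect_identical(res$phenotype[res$cluster == "big1"], "resistant")
  expect_true(all((res$t_statistic > 0) == (res$phenotype == "sensitive")))
})

test_that("robust intersection keeps matched, sign-consistent significant calls", {
  mk_assoc <- function(df) {
    df$significant <- df$adjusted_p < 0.05
    class(df) <- c("AssociationResult", "data.frame")
    df
  }
  a <- mk_assoc(data.frame(
    drug_id = c("d1", "d1", "d2"), cluster = c("A", "B", "A"),
    t_statistic = c(4, -3, 5), p_value = c(1e-4, 1e-3, 1e-5),
    adjusted_p = c(1e-3, 1e-2, 1e-4),
    phenotype = c("sensitive", "resistant", "sensitive"),
    n_in = 10, n_out = 30, stringsAsFactors = FALSE))
  b <- mk_assoc(data.frame(
    drug_id = c("d1", "d1", "d2"), cluster = c("X", "Y", "X"),
    t_statistic = c(3.5, -2.8, -4), p_value = c(1e-3, 2e-3, 1e-4),
    adjusted_p = c(1e-2, 2e-2, 1e-3),
    phenotype = c("sensitive", "resistant", "resistant"),
    n_in = 12, n_out = 28, stringsAsFactors = FALSE))
  match <- structure(list(mapping = c(A = "X", B = "Y"),
                          unmatched_a = character(0),
                          unmatched_b = character(0)),
                     class = "ClusterMatch")
  rob <- robust_associations(a, b, match)
  # d2/A is significant in both but with opposite signs -> excluded
  expect_equal(nrow(rob), 2L)
  expect_setequal(paste(rob$drug_id, rob$cluster_a),
                  c("d1 A", "d1 B"))
  # identical inputs: intersection equals the significant set
  match_id <- structure(list(mapping = c(A = "A", B = "B"),
                             unmatched_a = character(0),
                             unmatched_b = character(0)),
                        class = "ClusterMatch")
  rob_id <- robust_associations(a, a, match_id)
  expect_equal(nrow(rob_id), sum(a$significant))
  # unmatched clusters are excluded and counted
  match_p <- structure(list(mapping = c(A = "X"),
                            unmatched_a = "B", unmatched_b = "Y"),
                       class = "ClusterMatch")
  rob_p <- robust_associations(a, b, match_p)
  expect_equal(attr(rob_p, "n_unmatched"), 1L)
})
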