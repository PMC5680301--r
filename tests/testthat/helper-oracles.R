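# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and closed forms, never the package's
# own code paths.

options(pharmclust.quiet = TRUE)

# knee of a sorted curve: exhaustive scan of perpendicular distances to the
# chord between first and last point, after rescaling both axes to [0,1];
# ties toward the larger index
oracle_knee <- function(y) {
  n <- length(y)
  x <- (seq_len(n) - 1) / (n - 1)
  yy <- (y - y[1]) / (y[n] - y[1])
  x1 <- x[1]; y1 <- yy[1]; x2 <- x[n]; y2 <- yy[n]
  dd <- vapply(seq_len(n), function(i)
    abs((y2 - y1) * x[i] - (x2 - x1) * yy[i] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2), numeric(1))
  max(which(abs(dd - max(dd)) < 1e-12))
}

# pseudo-F by explicit variance decomposition
oracle_pseudo_f <- function(v, g, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  keep <- !is.na(v)
  v <- v[keep]; g <- g[keep]
  n <- length(v); k <- length(unique(g))
  grand <- sum(v) / n
  between <- 0; within <- 0
  for (gr in unique(g)) {
    vi <- v[g == gr]
    between <- between + length(vi) * (mean(vi) - grand)^2
    within <- within + sum((vi - mean(vi))^2)
  }
  if (variant == "standard") (between / (k - 1)) / (within / (n - k))
  else (between / (n - k)) / (within / (k - 1))
}

# one-tailed (enrichment) Fisher p by hypergeometric tail enumeration with
# binomial coefficients only
oracle_fisher_greater <- function(a, b, cc, d) {
  n <- a + b + cc + d       # total samples
  K <- a + cc               # total mutated
  m <- a + b                # in-cluster size
  lo <- max(0, K + m - n); hi <- min(K, m)
  probs <- vapply(lo:hi, function(x)
    choose(K, x) * choose(n - K, m - x) / choose(n, m), numeric(1))
  sum(probs[(lo:hi) >= a])
}

# Benjamini-Hochberg by the sorted definition:
# adjusted_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# GSEA enrichment score by explicit running sum (weight exponent 1)
oracle_es <- function(stat, is_hit) {
  n <- length(stat)
  nh <- sum(is_hit)
  sum_hit <- sum(abs(stat[is_hit]))
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      run <- run + if (sum_hit == 0) 1 / nh else abs(stat[i]) / sum_hit
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Rand index by explicit pair counting
oracle_rand <- function(la, lb) {
  n <- length(la)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same_a <- la[i] == la[j]
    same_b <- lb[i] == lb[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / total
}

# best injective assignment by brute force over all injective mappings
oracle_assignment_value <- function(ov) {
  nr <- nrow(ov); nc <- ncol(ov)
  if (nr <= nc) {
    perms <- .permutations(seq_len(nc), nr)
    best <- 0
    for (r in seq_len(nrow(perms)))
      best <- max(best, sum(ov[cbind(seq_len(nr), perms[r, ])]))
    best
  } else {
    oracle_assignment_value(t(ov))
  }
}

.permutations <- function(v, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- .permutations(v[-i], k - 1)
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# small, fast generator settings shared by unit tests
tiny_config <- function(seed = 1, ...) {
  generator_config(n_genes = 90, n_decoy_genes = 30, n_samples = 48,
                   n_modules = 3, n_clusters = 3, n_drugs = 6,
                   n_tissues = 6, missing_fraction_a = 0.1,
                   missing_fraction_b = 0.2, seed = seed, ...)
}

# expression matrix with two planted sample blocks, each carrying its own
# signature genes (so both blocks cohere under correlation distance)
two_block_matrix <- function(n_genes = 40, n_per_block = 8, shift = 5,
                             seed = 1, noise = 1) {
  set.seed(seed)
  n <- 2 * n_per_block
  x <- matrix(rnorm(n_genes * n, sd = noise), n_genes, n)
  half <- seq_len(n_genes / 2)
  x[half, seq_len(n_per_block)] <- x[half, seq_len(n_per_block)] + shift
  x[-half, n_per_block + seq_len(n_per_block)] <-
    x[-half, n_per_block + seq_len(n_per_block)] + shift
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n)))
  x
}
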