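#' @section File dialect:
#' All tables are tab-separated UTF-8 with "." as decimal mark. Expression,
#' mutation and drug-response tables carry feature identifiers in the first
#' column and sample identifiers in the header row. Missing drug-response
#' entries are encoded as empty fields; expression and mutation tables must
#' be complete.
#' @name pharmclust-io
NULL

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate ", what, " identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix is a plain numeric matrix, genes in rows and samples
#' in columns, with unique row and column names and all values finite
#' (log-scale expression; no missing entries allowed).
#'
#' @param x numeric matrix with rownames (gene IDs) and colnames (sample IDs).
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  .check_unique(rownames(x), "gene")
  .check_unique(colnames(x), "sample")
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]], "'", call. = FALSE)
  }
  invisible(x)
}

.read_id_matrix <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stop(what, " table needs an ID column plus data columns",
                           call. = FALSE)
  ids <- tab[[1L]]
  .check_unique(ids, sub("s$", "", what))
  .check_unique(colnames(tab)[-1L], "sample")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(tab)[-1L])))
  list(ids = ids, values = num, raw = vals)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV file: first column gene IDs, header row sample IDs.
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path) {
  parsed <- .read_id_matrix(path, "gene")
  bad <- which(is.na(parsed$values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric expression value '", parsed$raw[bad[1L, 1L], bad[1L, 2L]],
         "' at gene '", parsed$ids[bad[1L, 1L]], "', column '",
         colnames(parsed$values)[bad[1L, 2L]], "'", call. = FALSE)
  validate_expression_matrix(parsed$values)
  parsed$values
}

#' Write an expression matrix to TSV
#'
#' @param x validated expression matrix.
#' @param path output file.
#' @param id_header name of the identifier column (first header field).
#' @export
write_expression_matrix <- function(x, path, id_header = "gene_id") {
  validate_expression_matrix(x)
  .write_id_matrix(x, path, id_header)
}

.write_id_matrix <- function(x, path, id_header) {
  tab <- data.frame(rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c(id_header, colnames(x))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Validate a binary mutation matrix
#'
#' @param x numeric matrix of 0/1 calls, genes in rows, samples in columns.
#' @return `x`, invisibly.
#' @export
validate_mutation_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("mutation matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("mutation matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  .check_unique(rownames(x), "gene")
  .check_unique(colnames(x), "sample")
  if (!all(x %in% c(0, 1)))
    stop("mutation matrix values must all be 0 or 1", call. = FALSE)
  invisible(x)
}

#' Read a binary mutation matrix from TSV
#' @param path TSV file, first column gene IDs, header sample IDs, 0/1 cells.
#' @return validated 0/1 matrix.
#' @export
read_mutation_matrix <- function(path) {
  parsed <- .read_id_matrix(path, "gene")
  validate_mutation_matrix(parsed$values)
  parsed$values
}

#' Write a mutation matrix to TSV
#' @inheritParams write_expression_matrix
#' @export
write_mutation_matrix <- function(x, path, id_header = "gene_id") {
  validate_mutation_matrix(x)
  .write_id_matrix(x, path, id_header)
}

#' Construct a drug-response table
#'
#' Couples a drugs-by-samples matrix of raw sensitivity measurements with
#' the metric it is expressed in and its orientation. Missing measurements
#' (e.g. non-extractable IC50s) are `NA`, never 0.
#'
#' @param values numeric matrix, drugs in rows, samples in columns; `NA`
#'   marks missing measurements.
#' @param metric one of `"ic50_uM"` (micromolar IC50), `"auc"` (area under
#'   the dose-response curve, in \[0,1\]) or `"mean_viability"` (mean
#'   surviving fraction, in \[0,1\]).
#' @param orientation `"high_is_sensitive"` or `"high_is_resistant"`,
#'   describing the raw values. IC50 and mean viability are inherently
#'   high-is-resistant.
#' @return object of class `"DrugResponseTable"`.
#' @export
drug_response_table <- function(values,
                                metric = c("ic50_uM", "auc", "mean_viability"),
                                orientation = c("high_is_resistant",
                                                "high_is_sensitive")) {
  metric <- match.arg(metric)
  orientation <- match.arg(orientation)
  if (!is.matrix(values) || !is.numeric(values))
    stop("drug-response values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("drug-response values need drug rownames and sample colnames",
         call. = FALSE)
  .check_unique(rownames(values), "drug")
  .check_unique(colnames(values), "sample")
  if (any(is.infinite(values)))
    stop("drug-response values must be finite or NA", call. = FALSE)
  structure(list(values = values, metric = metric, orientation = orientation),
            class = "DrugResponseTable")
}

#' @export
print.DrugResponseTable <- function(x, ...) {
  cat("DrugResponseTable:", nrow(x$values), "drugs x", ncol(x$values),
      "cell lines\n  metric:", x$metric, "| orientation:", x$orientation,
      "| missing:",
      sprintf("%.1f%%", 100 * mean(is.na(x$values))), "\n")
  invisible(x)
}

#' Read a drug-response table from TSV
#'
#' Empty fields are read as missing (`NA`).
#'
#' @param path TSV file, first column drug IDs, header sample IDs.
#' @inheritParams drug_response_table
#' @return `DrugResponseTable`.
#' @export
read_drug_response <- function(path, metric, orientation = "high_is_resistant") {
  parsed <- .read_id_matrix(path, "drug")
  empty <- parsed$raw == "" | is.na(parsed$raw)
  bad <- which(is.na(parsed$values) & !empty, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric drug-response value '",
         parsed$raw[bad[1L, 1L], bad[1L, 2L]], "' for drug '",
         parsed$ids[bad[1L, 1L]], "'", call. = FALSE)
  drug_response_table(parsed$values, metric = metric, orientation = orientation)
}

#' Write a drug-response table to TSV
#' @param x `DrugResponseTable`.
#' @param path output file.
#' @export
write_drug_response <- function(x, path) {
  stopifnot(inherits(x, "DrugResponseTable"))
  .write_id_matrix(x$values, path, "drug_id")
}

#' Read a scored gene-gene interaction graph from TSV
#'
#' Three columns: `gene_a`, `gene_b`, `score`. Scores are combined-score
#' style confidences in \[0,1\]; the graph is undirected, with no self-loops
#' and at most one edge per unordered pair.
#'
#' @param path 3-column TSV with header.
#' @return data.frame of class `"InteractionGraph"`.
#' @export
read_interaction_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("interaction graph needs gene_a, gene_b, score",
                           call. = FALSE)
  interaction_graph(tab[[1L]], tab[[2L]], as.numeric(tab[[3L]]))
}

#' Construct a validated interaction graph
#'
#' @param gene_a,gene_b character vectors of endpoint gene IDs.
#' @param score numeric confidence scores in \[0,1\].
#' @return data.frame (`gene_a`, `gene_b`, `score`) of class
#'   `"InteractionGraph"`, endpoints ordered within each row.
#' @export
interaction_graph <- function(gene_a, gene_b, score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1))
    stop("interaction scores must lie in [0,1]", call. = FALSE)
  if (any(gene_a == gene_b))
    stop("self-loop edge(s): ",
         paste(unique(gene_a[gene_a == gene_b]), collapse = ", "),
         call. = FALSE)
  a <- pmin(gene_a, gene_b)
  b <- pmax(gene_a, gene_b)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate edge(s) for pair(s): ",
         paste(unique(sub("\r", " - ", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  out <- data.frame(gene_a = a, gene_b = b, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  class(out) <- c("InteractionGraph", "data.frame")
  out
}

#' Write an interaction graph to TSV
#' @param x `InteractionGraph`.
#' @param path output file.
#' @export
write_interaction_graph <- function(x, path) {
  stopifnot(inherits(x, "InteractionGraph"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' One set per line: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 40), call. = FALSE)
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  .check_unique(names(sets), "gene-set")
  sets
}

#' Write gene signatures to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a cell-line clustering
#'
#' @param labels vector of cluster labels named by sample ID (every sample
#'   labeled exactly once).
#' @return object of class `"CellLineClustering"`: list with `sample_ids`,
#'   `labels` (character, named) and `k`.
#' @export
cell_line_clustering <- function(labels) {
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("clustering labels must be named by sample ID", call. = FALSE)
  .check_unique(names(labels), "sample")
  if (any(is.na(labels))) stop("every sample must be labeled", call. = FALSE)
  lab <- as.character(labels)
  names(lab) <- names(labels)
  structure(list(sample_ids = names(lab), labels = lab,
                 k = length(unique(lab))),
            class = "CellLineClustering")
}

#' @export
print.CellLineClustering <- function(x, ...) {
  cat("CellLineClustering:", length(x$sample_ids), "samples in", x$k,
      "clusters\n")
  print(table(x$labels))
  invisible(x)
}

#' Read a clustering from a two-column TSV (sample_id, cluster)
#' @param path TSV with header.
#' @return `CellLineClustering`.
#' @export
read_clustering <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  cell_line_clustering(setNames(tab[[2L]], tab[[1L]]))
}

#' Write a clustering to TSV
#' @param x `CellLineClustering`.
#' @param path output file.
#' @export
write_clustering <- function(x, path) {
  stopifnot(inherits(x, "CellLineClustering"))
  write.table(data.frame(sample_id = x$sample_ids, cluster = x$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
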