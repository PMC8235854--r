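## Expression-pattern discovery: expressed-gene selection, k-means
## clustering of per-stage profiles, and Z-score cell-type specificity.

## per-stage mean of log2(FPKM + 1); genes x stages
stage_profiles <- function(expr, log_transform = TRUE) {
  check_expression(expr)
  stages <- sample_stages(expr)
  vals <- if (log_transform) log2(expr + 1) else expr
  prof <- vapply(unique(stages), function(s)
    rowMeans(vals[, stages == s, drop = FALSE]), numeric(nrow(expr)))
  if (nrow(expr) == 1)
    prof <- matrix(prof, nrow = 1,
                   dimnames = list(rownames(expr), unique(stages)))
  prof
}

## row z-scores with sample (n-1) sd; constant rows -> NA rows
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / sd
  z[sd == 0, ] <- NA_real_
  z
}

#' Select bound, expressed genes
#'
#' Retains genes that are in the TF-bound set and have a per-stage mean
#' FPKM above `fpkm_min` in at least one cell type (strict `>`).
#'
#' @param expr Expression matrix.
#' @param bound Character vector of TF-bound gene ids.
#' @param fpkm_min Expression floor (default 1).
#' @return Character vector of retained gene ids (expression-matrix order).
#' @export
select_expressed <- function(expr, bound, fpkm_min = 1) {
  prof <- stage_profiles(expr, log_transform = FALSE)
  keep <- rownames(expr) %in% bound & apply(prof, 1, max) > fpkm_min
  rownames(expr)[keep]
}

#' Cluster stage expression profiles with k-means
#'
#' Per-stage mean log2(FPKM + 1) profiles are z-scored per gene and
#' clustered with Euclidean k-means under `n_init` random restarts; the
#' solution with the lowest total within-cluster sum of squares is kept.
#' Constant-expression genes (undefined z-score) are excluded with a
#' message.  Cluster ids are relabelled canonically — by decreasing
#' cluster size, ties by centroid lexicographic order — so assignments
#' are comparable across runs.
#'
#' @param expr Expression matrix.
#' @param genes Gene ids to cluster (must be rows of `expr`).
#' @param k Number of clusters; presets of interest are 10 (bound-lncRNA
#'   patterns) and 6 (resolved-bivalent-gene patterns).
#' @param seed Integer seed; fixes the restarts, hence the result.
#' @param n_init Number of random restarts (default 50).
#' @return List of class `"pattern_clustering"`: `assignment` (named
#'   integer vector), `centers` (k x stages matrix of z-profiles),
#'   `withinss`, `tot_withinss`, `betweenss`, `totss`, `excluded`.
#' @export
cluster_patterns <- function(expr, genes, k, seed = 1L, n_init = 50L) {
  stopifnot(all(genes %in% rownames(expr)))
  prof <- stage_profiles(expr[genes, , drop = FALSE])
  z <- zscore_rows(prof)
  const <- rownames(z)[!stats::complete.cases(z)]
  if (length(const))
    message(length(const),
            " constant-expression gene(s) excluded from clustering")
  z <- z[stats::complete.cases(z), , drop = FALSE]
  if (nrow(z) < k)
    stop2("need at least k = ", k, " non-constant genes, have ", nrow(z))
  set.seed(seed)
  if (nrow(z) == k) {
    ## degenerate exact solution: one gene per cluster, zero within-SS
    km <- list(cluster = seq_len(k), centers = z, size = rep(1L, k),
               withinss = rep(0, k), tot.withinss = 0,
               totss = sum(sweep(z, 2, colMeans(z))^2),
               betweenss = sum(sweep(z, 2, colMeans(z))^2))
  } else {
    km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100)
  }
  if (any(km$size == 0)) warning("empty cluster in k-means solution")
  ## canonical relabelling: size desc, then centroid lexicographic
  ord <- order(-km$size, apply(round(km$centers, 10), 1, paste, collapse = ","))
  relabel <- match(seq_len(k), ord)
  assignment <- relabel[km$cluster]
  names(assignment) <- rownames(z)
  structure(list(assignment = assignment,
                 centers = km$centers[ord, , drop = FALSE],
                 withinss = km$withinss[ord],
                 tot_withinss = km$tot.withinss,
                 betweenss = km$betweenss,
                 totss = km$totss,
                 excluded = const),
            class = "pattern_clustering")
}

#' @export
print.pattern_clustering <- function(x, ...) {
  k <- nrow(x$centers)
  cat("k-means expression patterns: k =", k, ",",
      length(x$assignment), "genes\n")
  cat("cluster sizes:", paste(tabulate(x$assignment, k), collapse = " "), "\n")
  cat("total within-SS:", format(x$tot_withinss, digits = 6), "\n")
  invisible(x)
}

#' Rank genes by cell-type-specific Z-score
#'
#' Per-stage mean expression values of each gene are transformed into
#' Z-scores across cell types; for each cell type, genes are sorted by
#' descending Z in that cell type (ties broken by gene_id) and the top
#' `top_n` returned.  Genes constant across cell types have undefined Z
#' and are excluded.
#'
#' @param expr Expression matrix.
#' @param top_n Number of genes per cell type (default 100).
#' @param genes Optional gene-id subset (default: all rows).
#' @return Named list (cell type -> data.frame gene_id, z), plus the full
#'   Z matrix as attribute `"z"`.
#' @export
zscore_specific <- function(expr, top_n = 100, genes = rownames(expr)) {
  prof <- stage_profiles(expr[genes, , drop = FALSE])
  z <- zscore_rows(prof)
  z <- z[stats::complete.cases(z), , drop = FALSE]
  if (top_n > nrow(z)) {
    warning("top_n exceeds available genes; returning all ", nrow(z))
    top_n <- nrow(z)
  }
  out <- lapply(colnames(z), function(ct) {
    ord <- order(-z[, ct], rownames(z))
    data.frame(gene_id = rownames(z)[ord][seq_len(top_n)],
               z = z[ord, ct][seq_len(top_n)],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- colnames(z)
  attr(out, "z") <- z
  out
}
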