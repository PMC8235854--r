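## Guilt-by-association function prediction for lncRNAs: correlation-ranked
## coding-gene lists, a preranked GSEA core (weighted running-sum ES,
## gene-set-permutation NES / p / FDR), the NES association matrix, and
## hypergeometric term enrichment.

#' Rank coding genes by Pearson correlation with a query gene
#'
#' Computes the Pearson correlation of the query gene's log2(FPKM + 1)
#' profile against every coding gene across all samples and returns the
#' coding genes sorted by descending correlation (ties broken by gene_id).
#' The query itself and zero-variance coding genes are excluded (the
#' latter with a message).
#'
#' @param query Query gene id (typically a lncRNA).
#' @param expr Expression matrix with at least 3 samples.
#' @param coding_genes Character vector of protein-coding gene ids.
#' @return data.frame gene_id, r, in rank order; the query id is attached
#'   as attribute `"query"`.
#' @export
rank_by_correlation <- function(query, expr, coding_genes) {
  check_expression(expr)
  if (ncol(expr) < 3) stop2("need at least 3 samples for correlation ranking")
  if (!query %in% rownames(expr)) stop2("query gene not in expression matrix: ", query)
  lx <- log2(expr + 1)
  q <- lx[query, ]
  if (stats::sd(q) == 0) stop2("query gene has zero variance: ", query)
  coding_genes <- setdiff(intersect(coding_genes, rownames(expr)), query)
  m <- lx[coding_genes, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    message(sum(sds == 0), " zero-variance coding gene(s) excluded from ranking")
  m <- m[sds > 0, , drop = FALSE]
  r <- as.vector(stats::cor(t(m), q))
  ord <- order(-r, rownames(m))
  out <- data.frame(gene_id = rownames(m)[ord], r = r[ord],
                    stringsAsFactors = FALSE)
  attr(out, "query") <- query
  out
}

#' Weighted running-sum enrichment score
#'
#' The classic preranked GSEA statistic: walking down the ranked list, the
#' running sum gains `|r_j|^p / sum(|r_hit|^p)` at each gene-set member
#' ("hit") and loses `1 / (N - N_hit)` at each non-member; the enrichment
#' score is the deviation of maximal magnitude.  With `p_weight = 0` this
#' reduces to the Kolmogorov-Smirnov statistic of the hit positions.  If
#' all hit weights are zero, equal weights are used.
#'
#' @param ranked Ranked list from [rank_by_correlation()] (data.frame with
#'   gene_id and r, in rank order).
#' @param gene_set Character vector of member gene ids.
#' @param p_weight Weighting exponent on |r| (default 1).
#' @return List with `es` (in \[-1, 1\]), `running` (length-N running-sum
#'   vector for plotting) and `n_hits`; `NULL` (with a message) when the
#'   set does not intersect the ranked universe.
#' @export
gsea_es <- function(ranked, gene_set, p_weight = 1) {
  hit <- ranked$gene_id %in% gene_set
  n_hits <- sum(hit)
  N <- nrow(ranked)
  if (n_hits == 0) {
    message("gene set has no overlap with the ranked list; skipped")
    return(NULL)
  }
  if (n_hits == N) stop2("gene set equals the ranked universe")
  w <- abs(ranked$r)^p_weight
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!hit) / (N - n_hits)
  running <- p_hit - p_miss
  up <- max(running); down <- min(running)
  es <- if (up >= -down) up else down  # exact ties resolve positive
  list(es = es, running = running, n_hits = n_hits)
}

## ES from sorted hit positions only — O(n_hits), used for permutations.
## pos: sorted 1-based hit positions; w: weights at those positions; N: list
## length.  Equivalent to gsea_es (property-tested against it).
es_from_positions <- function(pos, w, N) {
  nh <- length(pos)
  if (sum(w) == 0) w <- rep(1, nh)
  cumw <- cumsum(w) / sum(w)
  miss <- (pos - seq_len(nh)) / (N - nh)
  after <- cumw - miss           # running sum just after each hit
  before <- c(0, cumw[-nh]) - miss  # just before each hit
  up <- max(after)
  down <- min(before)
  if (up >= -down) up else down
}

#' Permutation significance for one gene set
#'
#' Draws `n_perm` random gene sets of the same size from the ranked
#' universe (gene-set permutation, as appropriate for correlation-ranked
#' lists with few samples), computes the null ES distribution, and
#' normalizes: NES = ES / mean(|null ES|) over nulls of matching sign; the
#' p-value is the fraction of same-sign nulls at least as extreme.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations (default 1000; < 100 warns,
#'   < 10 errors).
#' @param seed Integer seed for the permutation draws.
#' @return List of class `"gsea_result"`: es, nes, pval, n_hits, null_es
#'   (the permutation null), null_nes (sign-normalized null, used for
#'   batch FDR).  `NULL` if the set misses the universe.
#' @export
gsea_significance <- function(ranked, gene_set, n_perm = 1000, seed = 1L,
                              p_weight = 1) {
  if (n_perm < 10) stop2("n_perm must be at least 10")
  if (n_perm < 100) warning("n_perm < 100 gives unstable NES/FDR estimates")
  obs <- gsea_es(ranked, gene_set, p_weight)
  if (is.null(obs)) return(NULL)
  N <- nrow(ranked)
  nh <- obs$n_hits
  wall <- abs(ranked$r)^p_weight
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    pos <- sort.int(sample.int(N, nh))
    es_from_positions(pos, wall[pos], N)
  }, numeric(1))
  null_nes <- normalize_es(null_es, null_es)
  res <- list(es = obs$es,
              nes = normalize_es(obs$es, null_es),
              pval = perm_pvalue(obs$es, null_es),
              n_hits = nh,
              null_es = null_es,
              null_nes = null_nes)
  class(res) <- "gsea_result"
  res
}

## normalize ES values by the mean |null ES| of matching sign
normalize_es <- function(es, null_es) {
  pos_mean <- mean(null_es[null_es >= 0])
  neg_mean <- mean(abs(null_es[null_es < 0]))
  vapply(es, function(e) {
    denom <- if (e >= 0) pos_mean else neg_mean
    if (!is.finite(denom) || denom == 0) return(NA_real_)
    e / denom
  }, numeric(1))
}

perm_pvalue <- function(es, null_es) {
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  if (!length(same)) return(1)
  sum(abs(same) >= abs(es)) / length(same)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g, n_hits = %d (%d permutations)\n",
              x$es, x$nes, x$pval, x$n_hits, length(x$null_es)))
  invisible(x)
}

#' Batch GSEA over queries and gene sets with NES-based FDR
#'
#' Runs [gsea_significance()] for every (ranked list, gene set) pair and
#' computes the FDR of each observed NES against the pooled sign-matched
#' null NES distribution: for NES* >= 0,
#' FDR = \[fraction of positive null NES >= NES*\] /
#' \[fraction of positive observed NES >= NES*\], capped at 1 (negative
#' side symmetric).
#'
#' @param ranked_lists Named list of ranked lists (one per query).
#' @param gene_sets Named list of gene-id vectors ([read_gmt()]).
#' @inheritParams gsea_significance
#' @return data.frame query, gene_set, es, nes, pval, fdr, n_hits; pairs
#'   with no universe overlap are dropped.
#' @export
gsea_batch <- function(ranked_lists, gene_sets, n_perm = 1000, seed = 1L,
                       p_weight = 1) {
  stopifnot(!is.null(names(ranked_lists)), !is.null(names(gene_sets)))
  rows <- list()
  null_pool <- list()
  i <- 0L
  for (q in names(ranked_lists)) {
    for (gs in names(gene_sets)) {
      i <- i + 1L
      res <- suppressMessages(
        gsea_significance(ranked_lists[[q]], gene_sets[[gs]],
                          n_perm = n_perm, seed = seed + i, p_weight = p_weight))
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, gene_set = gs, es = res$es, nes = res$nes,
        pval = res$pval, n_hits = res$n_hits, stringsAsFactors = FALSE)
      null_pool[[length(null_pool) + 1L]] <- res$null_nes
    }
  }
  if (!length(rows))
    return(data.frame(query = character(), gene_set = character(),
                      es = numeric(), nes = numeric(), pval = numeric(),
                      fdr = numeric(), n_hits = integer()))
  out <- do.call(rbind, rows)
  nulls <- unlist(null_pool)
  out$fdr <- nes_fdr(out$nes, nulls)
  out[c("query", "gene_set", "es", "nes", "pval", "fdr", "n_hits")]
}

## NES-based FDR q-values against a pooled null NES distribution
nes_fdr <- function(obs_nes, null_nes) {
  null_nes <- null_nes[is.finite(null_nes)]
  vapply(obs_nes, function(x) {
    if (!is.finite(x)) return(NA_real_)
    if (x >= 0) {
      num_den <- sum(null_nes >= 0)
      num <- if (num_den) sum(null_nes >= x) / num_den else 0
      den_den <- sum(obs_nes >= 0, na.rm = TRUE)
      den <- if (den_den) sum(obs_nes >= x, na.rm = TRUE) / den_den else 1
    } else {
      num_den <- sum(null_nes < 0)
      num <- if (num_den) sum(null_nes <= x) / num_den else 0
      den_den <- sum(obs_nes < 0, na.rm = TRUE)
      den <- if (den_den) sum(obs_nes <= x, na.rm = TRUE) / den_den else 1
    }
    min(1, if (den > 0) num / den else 1)
  }, numeric(1))
}

#' Build the NES association matrix
#'
#' Queries x gene sets matrix holding the NES wherever the batch FDR
#' passed `fdr < fdr_keep` and NA elsewhere — the association matrix used
#' to summarize predicted lncRNA functions.
#'
#' @param results data.frame from [gsea_batch()].
#' @param fdr_keep FDR ceiling for retaining an entry (default 0.25).
#' @return Numeric matrix (rownames = queries, colnames = gene sets).
#' @export
build_association_matrix <- function(results, fdr_keep = 0.25) {
  queries <- unique(results$query)
  sets <- unique(results$gene_set)
  m <- matrix(NA_real_, length(queries), length(sets),
              dimnames = list(queries, sets))
  keep <- results[!is.na(results$fdr) & results$fdr < fdr_keep, , drop = FALSE]
  if (nrow(keep))
    m[cbind(keep$query, keep$gene_set)] <- keep$nes
  m
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test of a query gene list against each gene
#' set, within a stated universe: with universe size N, set size K (after
#' intersection with the universe), query size n and overlap k, the
#' p-value is P(X >= k); Benjamini-Hochberg adjustment across sets yields
#' the FDR; sets with `fdr < fdr_max` are returned.
#'
#' @param query_genes Character vector; must be a subset of `universe`.
#' @param collection Named list of gene-id vectors.
#' @param universe Character vector defining the test universe.
#' @param fdr_max FDR ceiling for the returned table (default 0.05).
#' @return data.frame gene_set, k, K, n, N, pval, fdr, sorted by pval,
#'   restricted to fdr < fdr_max; the unfiltered table is the
#'   `"full"` attribute.
#' @export
hypergeom_enrich <- function(query_genes, collection, universe, fdr_max = 0.05) {
  offenders <- setdiff(query_genes, universe)
  if (length(offenders))
    stop2("query genes outside the universe: ",
          paste(utils::head(offenders, 5), collapse = ", "))
  N <- length(unique(universe))
  n <- length(unique(query_genes))
  tab <- do.call(rbind, lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query_genes, set))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(gene_set = nm, k = k, K = K, n = n, N = N, pval = p,
               stringsAsFactors = FALSE)
  }))
  tab$fdr <- stats::p.adjust(tab$pval, method = "BH")
  tab <- tab[order(tab$pval, tab$gene_set), ]
  row.names(tab) <- NULL
  out <- tab[tab$fdr < fdr_max, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "full") <- tab
  out
}
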