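## Independent brute-force oracles. These deliberately share no code with
## the implementation: explicit loops, all-pairs scans, exhaustive
## enumeration.

overlaps1 <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

## peak filter by explicit predicate loop
oracle_filter_peaks <- function(peaks, fdr_max, fe_min) {
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks)))
    keep[i] <- peaks$fdr[i] < fdr_max && peaks$fold_enrichment[i] > fe_min
  peaks[keep, , drop = FALSE]
}

## all-pairs peak-to-gene assignment scan
oracle_assign <- function(peaks, genes, up = 5000) {
  out <- NULL
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      tss <- genes$tss[j]
      if (genes$strand[j] == "+") { ws <- tss - up; we <- tss }
      else { ws <- tss; we <- tss + up }
      body <- overlaps1(peaks$start[i], peaks$end[i], genes$start[j], genes$end[j])
      upwin <- up > 0 && overlaps1(peaks$start[i], peaks$end[i], ws, we)
      if (body || upwin)
        out <- rbind(out, data.frame(
          peak_idx = i, gene_id = genes$gene_id[j],
          zone = if (body) "gene_body" else "upstream_window"))
    }
  }
  out
}

## O(n^2) overlap fraction
oracle_overlap_fraction <- function(a, b) {
  hit <- 0
  for (i in seq_len(nrow(a))) {
    found <- FALSE
    for (j in seq_len(nrow(b)))
      if (a$chrom[i] == b$chrom[j] &&
          overlaps1(a$start[i], a$end[i], b$start[j], b$end[j])) found <- TRUE
    hit <- hit + found
  }
  hit / nrow(a)
}

## union-find transitive interval merge with mark provenance
oracle_merge <- function(k4, k27) {
  iv <- rbind(
    if (nrow(k4)) data.frame(chrom = k4$chrom, start = k4$start, end = k4$end, src = "K4"),
    if (nrow(k27)) data.frame(chrom = k27$chrom, start = k27$start, end = k27$end, src = "K27"))
  n <- nrow(iv)
  parent <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      ri <- i; while (parent[ri] != ri) ri <- parent[ri]
      rj <- j; while (parent[rj] != rj) rj <- parent[rj]
      if (ri != rj && iv$chrom[i] == iv$chrom[j] &&
          overlaps1(iv$start[i], iv$end[i], iv$start[j], iv$end[j])) {
        parent[max(ri, rj)] <- min(ri, rj); changed <- TRUE
      }
    }
    if (!changed) break
  }
  root <- vapply(seq_len(n), function(x) { while (parent[x] != x) x <- parent[x]; x }, 0L)
  ## transitive closure: merging two members can bridge two clusters via a
  ## third interval, so iterate until cluster extents are stable
  repeat {
    ext <- do.call(rbind, lapply(unique(root), function(r) {
      m <- root == r
      data.frame(r = r, chrom = iv$chrom[which(m)[1]],
                 start = min(iv$start[m]), end = max(iv$end[m]))
    }))
    merged_any <- FALSE
    for (i in seq_len(nrow(ext))) for (j in seq_len(nrow(ext))) {
      if (i >= j) next
      if (ext$chrom[i] == ext$chrom[j] &&
          overlaps1(ext$start[i], ext$end[i], ext$start[j], ext$end[j])) {
        root[root == ext$r[j]] <- ext$r[i]; merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  out <- do.call(rbind, lapply(unique(root), function(r) {
    m <- root == r
    srcs <- unique(iv$src[m])
    data.frame(chrom = iv$chrom[which(m)[1]],
               start = min(iv$start[m]), end = max(iv$end[m]),
               kind = if (length(srcs) == 2) "bivalent"
                      else if (srcs == "K4") "K4_only" else "K27_only")
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

## position-by-position weighted running sum (loop form)
oracle_es <- function(r, hit, p = 1) {
  N <- length(r); nh <- sum(hit)
  wsum <- sum(abs(r[hit])^p)
  run <- numeric(N); cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) cur <- cur + (if (wsum > 0) abs(r[i])^p / wsum else 1 / nh)
    else cur <- cur - 1 / (N - nh)
    run[i] <- cur
  }
  up <- max(run); down <- min(run)
  list(es = if (up >= -down) up else down, running = run)
}

## hypergeometric upper tail P(X >= k) by explicit pmf summation
oracle_hyper_tail <- function(k, K, N, n) {
  tot <- 0
  for (x in k:min(K, n))
    tot <- tot + choose(K, x) * choose(N - K, n - x)
  tot / choose(N, n)
}

## exhaustive best k-partition by within-cluster SS (points as matrix rows)
oracle_best_partition <- function(x, k) {
  n <- nrow(x)
  stopifnot(n <= 8)
  best <- NULL; best_ss <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    if (length(unique(a)) < k) next
    ss <- 0
    for (c in seq_len(k)) {
      pts <- x[a == c, , drop = FALSE]
      ctr <- colMeans(pts)
      ss <- ss + sum(sweep(pts, 2, ctr)^2)
    }
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- a }
  }
  list(assignment = best, ss = best_ss)
}

## NB upper tail P(X >= x) by direct pmf summation (gamma-function form)
oracle_nb_tail <- function(x, size, mu, upto = 4000) {
  p <- size / (size + mu)
  pmf <- function(j) exp(lgamma(j + size) - lgamma(size) - lfactorial(j) +
                           size * log(p) + j * log(1 - p))
  sum(vapply(x:upto, pmf, numeric(1)))
}

## Welch two-sample t-test p-value from the textbook formula
oracle_welch_p <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                   vy^2 / (length(y)^2 * (length(y) - 1)))
  2 * stats::pt(-abs(t), df)
}

## Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  n <- length(p); o <- order(p)
  adj <- numeric(n); prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val; prev <- val
  }
  adj
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000,
                         mark = "TF") {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(50:2000, n, replace = TRUE),
             name = sprintf("p%d", seq_len(n)), strand = rep(".", n),
             fold_enrichment = stats::runif(n, 0, 12),
             fdr = stats::runif(n), mark = rep(mark, n),
             stringsAsFactors = FALSE)
}

random_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  g <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                  chrom = sample(chroms, n, replace = TRUE),
                  start = start, end = start + sample(500:8000, n, replace = TRUE),
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  biotype = sample(c("coding", "lncRNA"), n, replace = TRUE),
                  stringsAsFactors = FALSE)
  chromdyn:::validate_genes(g)
}
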