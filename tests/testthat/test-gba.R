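rk <- function(ids, r) data.frame(gene_id = ids, r = r, stringsAsFactors = FALSE)

test_that("correlation ranking matches the textbook formula and tie rules", {
  set.seed(501)
  n <- 20; s <- 6
  ids <- c("lnc1", sprintf("c%02d", 1:(n - 1)))
  m <- matrix(stats::rexp(n * s, 0.3), n, s,
              dimnames = list(ids, paste0("A_", 1:s)))
  m["c01", ] <- m["lnc1", ]                 # identical profile -> r = 1
  ranked <- rank_by_correlation("lnc1", m, ids[-1])
  expect_equal(ranked$gene_id[1], "c01")
  expect_equal(ranked$r[1], 1)

  ## direct covariance/sd oracle across all coding genes
  lx <- log2(m + 1)
  for (i in seq_len(nrow(ranked))) {
    g <- ranked$gene_id[i]
    x <- lx["lnc1", ]; y <- lx[g, ]
    r_or <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(ranked$r[i], unname(r_or), tolerance = 1e-12)
  }
  expect_true(all(diff(ranked$r) <= 1e-12))  # descending

  ## exact negation of the log profile ranks last with r = -1
  m2 <- 2^rbind(q = c(1, 2, 3, 4, 5, 6), neg = c(6, 5, 4, 3, 2, 1)) - 1
  colnames(m2) <- paste0("A_", 1:6)
  ranked2 <- rank_by_correlation("q", m2, "neg")
  expect_equal(ranked2$r, -1)

  ## zero-variance handling
  m3 <- rbind(q = c(1, 2, 3), flat = c(2, 2, 2), ok = c(3, 1, 2))
  colnames(m3) <- paste0("A_", 1:3)
  expect_message(r3 <- rank_by_correlation("q", m3, c("flat", "ok")),
                 "zero-variance")
  expect_equal(r3$gene_id, "ok")
  m3["q", ] <- 1
  expect_error(rank_by_correlation("q", m3, "ok"), "zero variance")
})

test_that("the enrichment score matches hand-computed running sums", {
  ## N = 10, set = first 5, all |r| equal: hits gain 1/5, misses lose 1/5;
  ## the running sum peaks at 1 after the 5th gene
  ranked <- rk(paste0("g", 1:10), rep(0.5, 10))
  out <- gsea_es(ranked, paste0("g", 1:5))
  expect_equal(out$es, 1)
  expect_equal(out$running, c(1:5 / 5, 4:0 / 5))

  ## independent loop oracle on the same input
  or <- oracle_es(ranked$r, ranked$gene_id %in% paste0("g", 1:5))
  expect_equal(out$es, or$es)
  expect_equal(out$running, or$running)

  ## bottom-ranked set gives a negative score
  r2 <- rk(paste0("g", 1:10), seq(1, -1, length.out = 10))
  expect_lt(gsea_es(r2, paste0("g", 8:10))$es, 0)

  ## p_weight = 0 reduces to the KS statistic of hit positions
  set.seed(502)
  r3 <- rk(paste0("g", 1:50), sort(stats::rnorm(50), decreasing = TRUE))
  hits <- sample(r3$gene_id, 12)
  es0 <- gsea_es(r3, hits, p_weight = 0)$es
  pos <- which(r3$gene_id %in% hits)
  ks <- 0
  for (i in 1:50) {  # direct KS deviation of the empirical position CDFs
    d <- sum(pos <= i) / 12 - (i - sum(pos <= i)) / 38
    if (abs(d) > abs(ks)) ks <- d
  }
  expect_equal(es0, ks)

  expect_message(expect_null(gsea_es(r3, c("nope1", "nope2"))), "no overlap")
})

test_that("ES equals brute force on all list lengths up to 12", {
  set.seed(503)
  for (N in 2:12) {
    for (rep in 1:8) {
      r <- sort(stats::rnorm(N), decreasing = TRUE)
      ids <- sprintf("g%02d", 1:N)
      nh <- sample(1:(N - 1), 1)
      set <- sample(ids, nh)
      got <- gsea_es(rk(ids, r), set)
      or <- oracle_es(r, ids %in% set)
      expect_equal(got$es, or$es, tolerance = 1e-12)
      expect_lte(abs(got$es), 1)
      expect_equal(got$running[N], 0, tolerance = 1e-9)
      ## fast position-based path agrees
      pos <- which(ids %in% set)
      expect_equal(chromdyn:::es_from_positions(pos, abs(r[pos]), N),
                   or$es, tolerance = 1e-12)
    }
  }
})

test_that("ES agrees with an external preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(504)
  for (rep in 1:5) {
    N <- 40
    r <- sort(stats::rnorm(N), decreasing = TRUE)
    ids <- sprintf("g%02d", 1:N)
    set <- sample(ids, 9)
    mine <- gsea_es(rk(ids, r), set)$es
    ext <- fgsea::calcGseaStat(stats::setNames(r, ids),
                               selectedStats = which(ids %in% set),
                               gseaParam = 1)
    expect_equal(mine, ext, tolerance = 1e-9)
  }
})

test_that("permutation NES is calibrated and deterministic", {
  set.seed(505)
  N <- 200
  ranked <- rk(sprintf("g%03d", 1:N), sort(stats::rnorm(N), decreasing = TRUE))
  ## random sets: |NES| should average about 1
  nes <- vapply(1:40, function(i) {
    set <- sample(ranked$gene_id, 15)
    gsea_significance(ranked, set, n_perm = 500, seed = i)$nes
  }, numeric(1))
  expect_equal(mean(abs(nes)), 1, tolerance = 0.1)

  a <- gsea_significance(ranked, ranked$gene_id[1:15], n_perm = 200, seed = 7)
  b <- gsea_significance(ranked, ranked$gene_id[1:15], n_perm = 200, seed = 7)
  expect_identical(a, b)
  expect_error(gsea_significance(ranked, ranked$gene_id[1:5], n_perm = 5), "at least")
  expect_warning(gsea_significance(ranked, ranked$gene_id[1:5], n_perm = 50),
                 "unstable")
})

test_that("the association matrix keeps exactly the FDR-passing entries", {
  res <- data.frame(query = c("q1", "q1", "q2"),
                    gene_set = c("s1", "s2", "s1"),
                    es = c(0.5, -0.4, 0.6), nes = c(1.8, -1.2, 2.0),
                    pval = c(0.01, 0.3, 0.005), fdr = c(1, 1, 1),
                    n_hits = c(5L, 5L, 5L))
  expect_true(all(is.na(build_association_matrix(res))))
  res$fdr <- c(0.1, 0.9, 0.3)
  m <- build_association_matrix(res)
  expect_equal(sum(!is.na(m)), 1)
  expect_equal(m["q1", "s1"], 1.8)

  set.seed(506)
  res$fdr <- stats::runif(3)
  m <- build_association_matrix(res, fdr_keep = 0.5)
  for (i in 1:3)
    expect_equal(!is.na(m[res$query[i], res$gene_set[i]]), res$fdr[i] < 0.5)
})

test_that("a planted coexpression module attains the top NES with low FDR", {
  cfg <- sim_config(n_genes = 250, seed = 12, n_modules = 2, module_size = 20)
  gen <- simulate_genome(cfg)
  ex <- simulate_expression(cfg, gen$genes, gen$truth)
  coding <- gen$genes$gene_id[gen$genes$biotype == "coding"]
  d1 <- gen$truth$gene_id[gen$truth$module_role == "driver" &
                            gen$truth$module == 1]
  ranked <- list(suppressMessages(rank_by_correlation(d1, ex$expr, coding)))
  names(ranked) <- d1
  res <- gsea_batch(ranked, ex$gene_sets, n_perm = 300, seed = 3)
  best <- res$gene_set[which.max(res$nes)]
  expect_equal(best, "module1_members")
  expect_lt(res$fdr[res$gene_set == "module1_members"], 0.25)
})

test_that("hypergeometric enrichment matches closed forms and pmf sums", {
  universe <- paste0("u", 1:10)
  coll <- list(hit = universe[1:5], other = universe[6:9])
  res <- attr(hypergeom_enrich(universe[1:5], coll, universe), "full")
  expect_equal(res$pval[res$gene_set == "hit"], 1 / choose(10, 5),
               tolerance = 1e-12)                      # = 1/252
  expect_equal(res$pval[res$gene_set == "other"], 1)   # k = 0 -> P(X>=0)=1

  expect_error(hypergeom_enrich(c("u1", "zz"), coll, universe), "zz")

  set.seed(507)
  universe <- paste0("u", 1:60)
  coll <- lapply(1:8, function(i) sample(universe, sample(5:20, 1)))
  names(coll) <- paste0("s", 1:8)
  q <- sample(universe, 15)
  res <- attr(hypergeom_enrich(q, coll, universe, fdr_max = 1), "full")
  for (i in seq_len(nrow(res))) {
    want <- if (res$k[i] == 0) 1 else
      oracle_hyper_tail(res$k[i], res$K[i], res$N[i], res$n[i])
    expect_equal(res$pval[i], want, tolerance = 1e-10)
  }
  ## BH adjusted values are non-decreasing in raw p rank
  expect_true(all(diff(res$fdr[order(res$pval)]) >= -1e-12))
  expect_equal(res$fdr, oracle_bh(res$pval), tolerance = 1e-12)  # already sorted
})
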