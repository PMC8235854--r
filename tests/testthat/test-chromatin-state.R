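hp <- function(chrom, start, end, mark) {
  data.frame(chrom = chrom, start = start, end = end,
             name = paste0(mark, start), strand = ".",
             fold_enrichment = 8, fdr = 0.001, mark = mark,
             stringsAsFactors = FALSE)
}

test_that("overlapping opposite marks merge into bivalent domains", {
  d <- build_domains(hp("chr1", 100, 200, "K4"), hp("chr1", 150, 250, "K27"))
  expect_equal(d, data.frame(chrom = "chr1", start = 100L, end = 250L,
                             kind = "bivalent"), ignore_attr = TRUE)

  d <- build_domains(hp("chr1", 0, 50, "K4"), hp("chr1", 100, 150, "K27"))
  expect_equal(d$kind, c("K4_only", "K27_only"))

  ## transitive chain across alternating marks
  k4 <- rbind(hp("chr1", 0, 100, "K4"), hp("chr1", 170, 260, "K4"))
  k27 <- hp("chr1", 90, 180, "K27")
  d <- build_domains(k4, k27)
  expect_equal(d, data.frame(chrom = "chr1", start = 0L, end = 260L,
                             kind = "bivalent"), ignore_attr = TRUE)
})

test_that("merging matches the union-find oracle and conserves coverage", {
  set.seed(201)
  for (rep in 1:25) {
    k4 <- random_peaks(sample(0:8, 1), chroms = "chr1", max_pos = 3000, mark = "K4")
    k27 <- random_peaks(sample(1:8, 1), chroms = "chr1", max_pos = 3000, mark = "K27")
    got <- build_domains(k4, k27)
    want <- oracle_merge(k4, k27)
    expect_equal(got, want, ignore_attr = TRUE)
    ## covered bp conserved: union of inputs == union of domains
    cover <- function(df) {
      x <- rep(FALSE, 5100)
      for (i in seq_len(nrow(df))) x[(df$start[i] + 1):df$end[i]] <- TRUE
      x
    }
    expect_equal(cover(got), cover(rbind(k4[1:3], k27[1:3])))
    ## idempotence: re-merging the domains (kinds as sources) returns itself
    as_pk <- function(d, mark) data.frame(
      chrom = d$chrom, start = d$start, end = d$end,
      name = sprintf("d%d", seq_len(nrow(d))), strand = rep(".", nrow(d)),
      fold_enrichment = rep(8, nrow(d)), fdr = rep(0.001, nrow(d)),
      mark = rep(mark, nrow(d)), stringsAsFactors = FALSE)
    again <- build_domains(as_pk(got[got$kind != "K27_only", ], "K4"),
                           as_pk(got[got$kind != "K4_only", ], "K27"))
    expect_equal(again, got, ignore_attr = TRUE)
  }
})

test_that("gene state rules follow the exclusive-evidence convention", {
  g <- chromdyn:::validate_genes(data.frame(
    gene_id = "g1", chrom = "chr1", start = 10000, end = 20000,
    strand = "+", biotype = "coding"))
  dom <- function(...) data.frame(..., stringsAsFactors = FALSE)

  biv <- dom(chrom = "chr1", start = 9500, end = 10500, kind = "bivalent")
  expect_equal(classify_genes(biv, g)$state, "bivalent")

  mixed <- rbind(biv, dom(chrom = "chr1", start = 8500, end = 9000, kind = "K4_only"))
  expect_equal(classify_genes(mixed, g)$state, "other")

  expect_equal(classify_genes(biv[0, ], g)$state, "other")

  k4far <- dom(chrom = "chr1", start = 12000, end = 13000, kind = "K4_only")
  expect_equal(classify_genes(k4far, g)$state, "other")  # outside the window

  ## exactly one state per gene; partition property on a random layout
  set.seed(202)
  genes <- random_genes(30)
  d <- build_domains(random_peaks(20, mark = "K4"), random_peaks(20, mark = "K27"))
  calls <- classify_genes(d, genes)
  expect_equal(nrow(calls), 30)
  expect_equal(sum(table(calls$state)), 30)
})

test_that("state dynamics finds the bivalent-to-K4 resolution pattern", {
  mkcalls <- function(states, ids = paste0("g", seq_along(states)))
    data.frame(gene_id = ids, state = states, stringsAsFactors = FALSE)
  calls <- list(
    NSC = mkcalls(c("bivalent", "K4_only", "bivalent")),
    OPC = mkcalls(c("K4_only", "K4_only", "bivalent")),
    NFO = mkcalls(c("K4_only", "K4_only", "K27_only")))
  dyn <- state_dynamics(calls)
  expect_equal(dyn$bivalent_to_k4, "g1")
  expect_equal(unname(dyn$sequences["g2", ]), rep("K4_only", 3))
  tr <- dyn$transitions[["NSC->OPC"]]
  expect_equal(unname(tr["bivalent", "K4_only"]), 1)
  expect_equal(unname(tr["bivalent", "bivalent"]), 1)

  ## missing gene treated as other, with a message
  calls$NFO <- calls$NFO[1:2, ]
  expect_message(dyn2 <- state_dynamics(calls), "missing")
  expect_equal(unname(dyn2$sequences["g3", "NFO"]), "other")
})

test_that("planted state sequences are recovered exactly without decoys", {
  cfg <- sim_config(n_genes = 80, seed = 9, n_modules = 0)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, gen$genes, gen$truth)
  calls <- lapply(cfg$stages, function(s)
    classify_genes(build_domains(filter_peaks(pk[[s]]$K4, 0.05, 3.5),
                                 filter_peaks(pk[[s]]$K27, 0.05, 3.5)),
                   gen$genes))
  names(calls) <- cfg$stages
  for (s in cfg$stages)
    expect_equal(calls[[s]]$state, gen$truth[[paste0("state_", s)]])
  dyn <- state_dynamics(calls)
  want <- gen$truth$gene_id[
    gen$truth$state_NSC == "bivalent" &
      gen$truth$state_OPC == "K4_only" & gen$truth$state_NFO == "K4_only"]
  expect_setequal(dyn$bivalent_to_k4, want)
})

test_that("Venn region counts equal brute-force membership enumeration", {
  mkcalls <- function(ids) data.frame(gene_id = ids,
                                      state = "bivalent",
                                      stringsAsFactors = FALSE)
  same <- list(A = mkcalls(c("x", "y")), B = mkcalls(c("x", "y")),
               C = mkcalls(c("x", "y")))
  cs <- common_states(same, "bivalent")
  expect_setequal(cs$common, c("x", "y"))
  expect_equal(unname(cs$venn[["A&B&C"]]), 2)

  disj <- list(A = mkcalls("x"), B = mkcalls("y"), C = mkcalls("z"))
  expect_equal(length(common_states(disj, "bivalent")$common), 0)

  set.seed(203)
  pool <- paste0("g", 1:30)
  rnd <- list(A = mkcalls(sample(pool, 12)), B = mkcalls(sample(pool, 15)),
              C = mkcalls(sample(pool, 9)))
  cs <- common_states(rnd, "bivalent")
  for (g in unique(unlist(lapply(rnd, `[[`, "gene_id")))) {
    region <- paste(names(rnd)[vapply(rnd, function(d) g %in% d$gene_id,
                                      TRUE)], collapse = "&")
    expect_gte(cs$venn[[region]], 1)
  }
  expect_equal(sum(cs$venn), length(unique(unlist(lapply(rnd, `[[`, "gene_id")))))
  expect_setequal(cs$common,
                  Reduce(intersect, lapply(rnd, `[[`, "gene_id")))
})
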