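small_cfg <- function(...) {
  sim_config(n_genes = 60, n_modules = 1, module_size = 8,
             frac_lncrna = 0.2, ...)
}

test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 1)
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(a, b)
  pa <- simulate_peaks(cfg, a$genes, a$truth)
  pb <- simulate_peaks(cfg, b$genes, b$truth)
  expect_identical(pa, pb)
  ea <- simulate_expression(cfg, a$genes, a$truth)
  eb <- simulate_expression(cfg, b$genes, b$truth)
  expect_identical(ea$expr, eb$expr)
  expect_identical(ea$rip, eb$rip)
})

test_that("gene layout honours biotype fraction and spacing", {
  gen <- simulate_genome(sim_config(n_genes = 60, frac_lncrna = 0,
                                    n_modules = 0, seed = 2))
  expect_true(all(gen$genes$biotype == "coding"))

  gen <- simulate_genome(small_cfg(seed = 3))
  g <- gen$genes
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1)
      expect_true(min(gc$start[-1] - gc$end[-nrow(gc)]) >= 10000)
  }
  expect_error(
    simulate_genome(sim_config(n_genes = 500, n_chroms = 1,
                               chrom_length = 1e6, seed = 1)),
    "infeasible")
})

test_that("planted peaks realize the truth states", {
  cfg <- small_cfg(seed = 4)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, gen$genes, gen$truth)
  s <- cfg$stages[1]
  biv <- gen$truth$gene_id[gen$truth[[paste0("state_", s)]] == "bivalent"]
  for (gid in biv) {
    k4 <- pk[[s]]$K4[grepl(paste0("_", gid, "$"), pk[[s]]$K4$name), ]
    k27 <- pk[[s]]$K27[grepl(paste0("_", gid, "$"), pk[[s]]$K27$name), ]
    expect_equal(nrow(k4), 1)
    expect_true(k4$start < k27$end && k27$start < k4$end)  # >= 1 bp overlap
  }
  ## decoys off: every peak passes the default quality filters
  for (st in cfg$stages) for (mk in c("TF", "K4", "K27")) {
    p <- pk[[st]][[mk]]
    fe_min <- if (mk == "TF") 5 else 3.5
    expect_equal(nrow(filter_peaks(p, 0.05, fe_min)), nrow(p))
  }
})

test_that("uncoupled genes get no TF peak in their annotation window", {
  cfg <- small_cfg(seed = 5)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, gen$genes, gen$truth)
  none <- gen$truth$gene_id[gen$truth$tf_label == "none"]
  for (s in cfg$stages) {
    tf <- pk[[s]]$TF
    for (gid in none) {  # exhaustive window scan
      g <- gen$genes[gen$genes$gene_id == gid, ]
      if (g$strand == "+") { ws <- g$tss - 5000; we <- g$end }
      else { ws <- g$start; we <- g$tss + 5000 }
      inwin <- tf$chrom == g$chrom & tf$start < we & ws < tf$end
      expect_false(any(inwin))
    }
  }
})

test_that("decoy peaks fail a quality filter and do not disturb state calls", {
  cfg <- small_cfg(seed = 14, decoy_rate = 0.5)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks(cfg, gen$genes, gen$truth)
  for (s in cfg$stages) {
    for (mk in c("TF", "K4", "K27")) {
      p <- pk[[s]][[mk]]
      dec <- p[grepl("^decoy_", p$name), ]
      fe_min <- if (mk == "TF") 5 else 3.5
      if (nrow(dec))
        expect_true(all(dec$fdr >= 0.05 | dec$fold_enrichment <= fe_min))
    }
    dom <- build_domains(filter_peaks(pk[[s]]$K4, 0.05, 3.5),
                         filter_peaks(pk[[s]]$K27, 0.05, 3.5))
    expect_equal(classify_genes(dom, gen$genes)$state,
                 gen$truth[[paste0("state_", s)]])
  }
})

test_that("noiseless module members correlate perfectly with their driver", {
  cfg <- small_cfg(seed = 6, noise_sd = 0, module_cor = 1)
  gen <- simulate_genome(cfg)
  ex <- simulate_expression(cfg, gen$genes, gen$truth)
  d <- gen$truth$gene_id[gen$truth$module_role == "driver"]
  mem <- gen$truth$gene_id[gen$truth$module_role == "member"]
  lx <- log2(ex$expr)
  for (m in mem)
    expect_equal(stats::cor(lx[d, ], lx[m, ]), 1, tolerance = 1e-12)
})

test_that("planted TF effects pass the DEG filter, matching a hand Welch+BH oracle", {
  cfg <- small_cfg(seed = 7, noise_sd = 0.1)
  gen <- simulate_genome(cfg)
  ex <- simulate_expression(cfg, gen$genes, gen$truth)
  de <- ex$de[[paste0(cfg$stages[2], "_vs_", cfg$stages[1])]]

  ## recompute the stand-in DE table independently
  lx <- log2(ex$expr)
  st <- sub("_[^_]*$", "", colnames(ex$expr))
  p_or <- vapply(gen$genes$gene_id, function(g)
    oracle_welch_p(lx[g, st == cfg$stages[2]], lx[g, st == cfg$stages[1]]),
    numeric(1))
  expect_equal(unname(de$pvalue), unname(p_or), tolerance = 1e-9)
  expect_equal(de$fdr, oracle_bh(de$pvalue), tolerance = 1e-9)

  degs <- suppressMessages(filter_degs(de, ex$expr))
  planted <- gen$truth$gene_id[gen$truth$tf_label == "activated"]
  expect_true(all(planted %in% degs$gene_id))

  expect_error(simulate_expression(small_cfg(n_reps = 1), gen$genes, gen$truth),
               "n_reps")
})

test_that("fixture directories are byte-identical across reruns", {
  cfg <- small_cfg(seed = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 13)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
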