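## Seeded synthetic-data generator: a gene annotation laid out on synthetic
## chromosomes, per-stage TF / H3K4me3 / H3K27me3 peak sets realizing
## planted promoter chromatin states, an FPKM matrix with planted stage
## effects and lncRNA-driven coexpression modules, Welch+BH DE tables (a
## stand-in for an external DE tool, used only for fixtures), and RIP
## count tables with planted enriched transcripts.  Everything is
## deterministic under the config seed and ships with a truth table.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: three stages of oligodendrocyte
#' lineage differentiation (NSC, OPC, NFO), ~2,000 genes with a planted
#' promoter-state Markov chain in which bivalency decays toward
#' H3K4me3-only as differentiation proceeds, TF binding coupled to
#' expression direction with |log2FC| = 3, lncRNA-driven coexpression
#' modules, and RIP counts with 4-fold planted enrichment.
#'
#' @param n_genes Number of genes (default 2000).
#' @param frac_lncrna Fraction of lncRNA biotype genes (default 0.15).
#' @param stages Ordered stage labels (default NSC, OPC, NFO).
#' @param n_reps Replicates per stage (default 4; the per-gene Welch
#'   stand-in needs one more replicate than a moderated DE tool would to
#'   reach comparable power at the study's FDR threshold).
#' @param noise_sd SD of log2-scale expression noise (default 0.2).
#' @param decoy_rate Sub-threshold decoy peaks per true peak (default 0).
#' @param state_init Initial chromatin-state probabilities
#'   (K4_only, K27_only, bivalent, other).
#' @param state_trans 4x4 stage-to-stage state transition matrix
#'   (rows = from, cols = to, state order as `state_init`).
#' @param tf_frac Fraction of genes coupled to the TF (default 0.1),
#'   split evenly between activated and repressed.
#' @param tf_effect Planted |log2 fold change| of TF-coupled genes
#'   (default 3).
#' @param n_modules Number of lncRNA coexpression modules (default 3).
#' @param module_size Coding members per module (default 30).
#' @param module_cor Target driver-member Pearson correlation (default 0.9).
#' @param rip_enriched_frac Fraction of transcripts with planted RIP
#'   enrichment (default 0.05).
#' @param rip_fc True IP/control fold change of enriched transcripts
#'   (default 4).
#' @param rip_dispersion NB size of simulated counts (default 20,
#'   i.e. moderate overdispersion beyond Poisson).
#' @param rip_libsize IP and control library size (default 1e6).
#' @param spacing_bp Minimum gap between adjacent genes (default 10000).
#' @param n_chroms,chrom_length Synthetic chromosome count and length.
#' @param seed Integer master seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, frac_lncrna = 0.15,
                       stages = c("NSC", "OPC", "NFO"), n_reps = 4,
                       noise_sd = 0.2, decoy_rate = 0,
                       state_init = c(K4_only = 0.40, K27_only = 0.15,
                                      bivalent = 0.20, other = 0.25),
                       state_trans = default_state_trans(),
                       tf_frac = 0.1, tf_effect = 3,
                       n_modules = 3, module_size = 30, module_cor = 0.9,
                       rip_enriched_frac = 0.05, rip_fc = 4,
                       rip_dispersion = 20, rip_libsize = 1e6,
                       spacing_bp = 10000, n_chroms = 5,
                       chrom_length = 6e7, seed = 1L) {
  stopifnot(n_genes >= 1, length(stages) >= 2)
  fracs <- c(frac_lncrna, decoy_rate, tf_frac, rip_enriched_frac, module_cor)
  if (any(fracs < 0 | fracs > 1))
    stop2("fractions/rates/correlation targets must lie in [0,1]")
  if (abs(sum(state_init) - 1) > 1e-8) stop2("state_init must sum to 1")
  if (any(abs(rowSums(state_trans) - 1) > 1e-8))
    stop2("state_trans rows must sum to 1")
  if (noise_sd < 0) stop2("noise_sd must be non-negative")
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_state_trans <- function() {
  m <- rbind(
    K4_only  = c(0.90, 0.02, 0.03, 0.05),
    K27_only = c(0.05, 0.85, 0.05, 0.05),
    bivalent = c(0.25, 0.10, 0.55, 0.10),
    other    = c(0.05, 0.05, 0.02, 0.88))
  colnames(m) <- rownames(m)
  m
}

#' Lay out a synthetic genome with planted truth
#'
#' Places genes sequentially on synthetic chromosomes with at least
#' `spacing_bp` between neighbours (so default annotation windows of
#' different genes never collide), draws strand and biotype, and plants
#' the per-stage chromatin state sequence (Markov chain), TF-coupling
#' labels, and coexpression module membership.
#'
#' @param cfg A [sim_config()].
#' @return List with `genes` (gene data.frame) and `truth` (one row per
#'   gene: state_<stage> columns, tf_label, tf_effect, module id,
#'   module_role, rip_enriched).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  len <- sample(2000:20000, n, replace = TRUE)
  gap <- cfg$spacing_bp + sample(0:5000, n, replace = TRUE)
  chrom_of <- rep(seq_len(cfg$n_chroms), length.out = n)
  start <- integer(n); chrom <- character(n)
  cursor <- rep(10000L, cfg$n_chroms)
  for (i in seq_len(n)) {
    ci <- chrom_of[i]
    start[i] <- cursor[ci]
    cursor[ci] <- cursor[ci] + len[i] + gap[i]
    if (cursor[ci] > cfg$chrom_length)
      stop2("chromosome length ", cfg$chrom_length,
            " infeasible for ", n, " genes at spacing ", cfg$spacing_bp)
    chrom[i] <- paste0("chr", ci)
  }
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = chrom, start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = "coding", stringsAsFactors = FALSE)
  n_lnc <- round(cfg$frac_lncrna * n)
  if (n_lnc > 0)
    genes$biotype[sample.int(n, n_lnc)] <- "lncRNA"
  genes <- validate_genes(genes)

  ## chromatin state sequences: initial draw then Markov transitions
  states <- matrix("", n, length(cfg$stages),
                   dimnames = list(genes$gene_id, cfg$stages))
  states[, 1] <- sample(names(cfg$state_init), n, replace = TRUE,
                        prob = cfg$state_init)
  for (s in seq_along(cfg$stages)[-1]) {
    for (from in rownames(cfg$state_trans)) {
      idx <- which(states[, s - 1] == from)
      if (length(idx))
        states[idx, s] <- sample(colnames(cfg$state_trans), length(idx),
                                 replace = TRUE, prob = cfg$state_trans[from, ])
    }
  }

  ## TF coupling
  tf_label <- rep("none", n)
  n_tf <- round(cfg$tf_frac * n)
  if (n_tf > 0) {
    coupled <- sample.int(n, n_tf)
    tf_label[coupled] <- rep_len(c("activated", "repressed"), n_tf)
  }
  tf_effect <- ifelse(tf_label == "activated", cfg$tf_effect,
                      ifelse(tf_label == "repressed", -cfg$tf_effect, 0))

  ## coexpression modules: lncRNA drivers, coding uncoupled members
  module <- integer(n); role <- rep("none", n)
  lnc_free <- which(genes$biotype == "lncRNA" & tf_label == "none")
  cod_free <- which(genes$biotype == "coding" & tf_label == "none")
  n_mod <- min(cfg$n_modules, length(lnc_free),
               length(cod_free) %/% max(cfg$module_size, 1))
  if (n_mod < cfg$n_modules)
    warning("only ", n_mod, " coexpression module(s) fit the gene pool")
  if (n_mod > 0) {
    drivers <- sample(lnc_free, n_mod)
    members <- sample(cod_free, n_mod * cfg$module_size)
    for (m in seq_len(n_mod)) {
      module[drivers[m]] <- m; role[drivers[m]] <- "driver"
      mem <- members[((m - 1) * cfg$module_size + 1):(m * cfg$module_size)]
      module[mem] <- m; role[mem] <- "member"
    }
  }

  ## RIP enrichment
  rip_enriched <- rep(FALSE, n)
  n_rip <- round(cfg$rip_enriched_frac * n)
  if (n_rip > 0) rip_enriched[sample.int(n, n_rip)] <- TRUE

  truth <- data.frame(gene_id = genes$gene_id, biotype = genes$biotype,
                      stringsAsFactors = FALSE)
  for (s in cfg$stages) truth[[paste0("state_", s)]] <- states[, s]
  truth$tf_label <- tf_label
  truth$tf_effect <- tf_effect
  truth$module <- module
  truth$module_role <- role
  truth$rip_enriched <- rip_enriched
  list(genes = genes, truth = truth)
}

#' Simulate per-stage peak sets realizing the planted truth
#'
#' For each stage, a gene with planted state `bivalent` receives one
#' H3K4me3 and one H3K27me3 peak that overlap each other within 2 kb of
#' its TSS; `K4_only` / `K27_only` genes receive the single mark;
#' TF-coupled genes receive a TF peak in the upstream window.  All true
#' peaks pass the default quality filters.  `decoy_rate` adds
#' sub-threshold peaks (failing either the FDR or the fold-enrichment
#' cut) at random gene promoters.
#'
#' @param cfg A [sim_config()].
#' @param genes,truth Output of [simulate_genome()].
#' @return Named list stage -> list(TF, K4, K27) of peak data.frames.
#' @export
simulate_peaks <- function(cfg, genes, truth) {
  set.seed(cfg$seed + 1L)
  sgn <- ifelse(genes$strand == "+", 1L, -1L)  # upstream direction is -sgn
  out <- list()
  for (s in cfg$stages) {
    st <- truth[[paste0("state_", s)]]
    k4_genes <- which(st %in% c("K4_only", "bivalent"))
    k27_genes <- which(st %in% c("K27_only", "bivalent"))
    tf_genes <- which(truth$tf_label != "none")
    mk <- function(idx, lo, hi, mark, fe_lo, fe_hi) {
      if (!length(idx)) return(empty_peaks())
      tss <- genes$tss[idx]
      a <- tss + ifelse(sgn[idx] > 0, lo, -hi)
      b <- tss + ifelse(sgn[idx] > 0, hi, -lo)
      validate_peaks(data.frame(
        chrom = genes$chrom[idx], start = pmax(a, 0L), end = b,
        name = paste0(mark, "_", s, "_", genes$gene_id[idx]),
        strand = ".", fold_enrichment = stats::runif(length(idx), fe_lo, fe_hi),
        fdr = stats::runif(length(idx), 1e-6, 0.049),
        mark = mark, stringsAsFactors = FALSE))
    }
    ## K4 [-1500, -500) and K27 [-1000, +1000) relative to TSS on the
    ## coding strand: overlapping for bivalent genes, both within the
    ## promoter window.
    k4 <- mk(k4_genes, -1500L, -500L, "K4", 4, 15)
    k27 <- mk(k27_genes, -1000L, 1000L, "K27", 4, 15)
    tf <- mk(tf_genes, -3000L, -2600L, "TF", 6, 20)
    if (cfg$decoy_rate > 0) {
      n_true <- nrow(k4) + nrow(k27) + nrow(tf)
      n_dec <- round(cfg$decoy_rate * n_true)
      if (n_dec > 0) {
        idx <- sample.int(nrow(genes), n_dec, replace = TRUE)
        dec_mark <- sample(c("TF", "K4", "K27"), n_dec, replace = TRUE)
        off <- sample(-1500:500, n_dec, replace = TRUE)
        fail_fdr <- stats::runif(n_dec) < 0.5
        dec <- validate_peaks(data.frame(
          chrom = genes$chrom[idx],
          start = pmax(genes$tss[idx] + off, 0L),
          end = genes$tss[idx] + off + 800L,
          name = paste0("decoy_", s, "_", seq_len(n_dec)),
          strand = ".",
          fold_enrichment = ifelse(fail_fdr,
                                   stats::runif(n_dec, 6, 20),
                                   stats::runif(n_dec, 0.5, 3.4)),
          fdr = ifelse(fail_fdr, stats::runif(n_dec, 0.05, 0.8),
                       stats::runif(n_dec, 1e-6, 0.049)),
          mark = dec_mark, stringsAsFactors = FALSE))
        tf <- rbind(tf, dec[dec$mark == "TF", ])
        k4 <- rbind(k4, dec[dec$mark == "K4", ])
        k27 <- rbind(k27, dec[dec$mark == "K27", ])
      }
    }
    out[[s]] <- list(TF = tf, K4 = k4, K27 = k27)
  }
  out
}

#' Simulate expression, DE tables and RIP counts
#'
#' Log2 FPKM is baseline + planted stage effects + Normal(0, noise_sd).
#' TF-activated (repressed) genes gain (lose) `tf_effect` log2 units after
#' the first stage; module drivers follow module-specific stage profiles
#' and members track their driver's realized profile with noise calibrated
#' to the target Pearson correlation.  DE tables for adjacent stage pairs
#' come from a per-gene Welch t-test with BH adjustment — a labelled
#' stand-in used only for synthetic fixtures; real runs consume external
#' DE tables.  RIP counts are negative binomial with `rip_fc`-fold planted
#' enrichment.
#'
#' @inheritParams simulate_peaks
#' @return List: `expr` (FPKM matrix), `de` (named list of DE data.frames,
#'   names "B_vs_A"), `rip` (count data.frame), `gene_sets` (named list:
#'   each module's member set plus size-matched random decoy sets).
#' @export
simulate_expression <- function(cfg, genes, truth) {
  if (cfg$n_reps < 2) stop2("n_reps must be >= 2 to compute DE tables")
  set.seed(cfg$seed + 2L)
  n <- nrow(genes); S <- length(cfg$stages); R <- cfg$n_reps
  baseline <- stats::runif(n, 2, 7)
  mu <- matrix(baseline, n, S, dimnames = list(genes$gene_id, cfg$stages))
  later <- seq_len(S)[-1]
  mu[, later] <- mu[, later] + truth$tf_effect  # 0 for uncoupled genes

  ## module drivers: distinct on/off stage profiles (binary code per module)
  n_mod <- max(truth$module)
  driver_prof <- NULL
  if (n_mod > 0) {
    driver_prof <- t(vapply(seq_len(n_mod), function(m)
      3 * as.integer(intToBits(m))[seq_len(S)], numeric(S)))
    for (m in seq_len(n_mod)) {
      d <- which(truth$module == m & truth$module_role == "driver")
      mu[d, ] <- baseline[d] + driver_prof[m, ]
    }
  }

  samples <- paste(rep(cfg$stages, each = R), rep(seq_len(R), S), sep = "_")
  lx <- mu[, rep(seq_len(S), each = R)] +
    matrix(stats::rnorm(n * S * R, 0, cfg$noise_sd), n, S * R)
  colnames(lx) <- samples

  ## members copy the driver's realized sample profile + calibrated noise
  if (n_mod > 0) {
    for (m in seq_len(n_mod)) {
      d <- which(truth$module == m & truth$module_role == "driver")
      mem <- which(truth$module == m & truth$module_role == "member")
      if (!length(mem)) next
      dvec <- lx[d, ]
      sd_d <- stats::sd(dvec)
      sd_e <- if (cfg$module_cor >= 1 || sd_d == 0) 0
              else sd_d * sqrt(1 / cfg$module_cor^2 - 1)
      shift <- baseline[mem] - mean(dvec)
      lx[mem, ] <- matrix(rep(dvec, each = length(mem)), length(mem)) +
        shift + matrix(stats::rnorm(length(mem) * ncol(lx), 0, sd_e),
                       length(mem))
    }
  }
  expr <- 2^lx
  check_expression(expr)

  ## Welch + BH DE stand-in on log2 FPKM, adjacent stage pairs
  de <- list()
  stage_of <- rep(cfg$stages, each = R)
  for (i in seq_len(S - 1)) {
    a <- cfg$stages[i]; b <- cfg$stages[i + 1]
    xa <- lx[, stage_of == a, drop = FALSE]
    xb <- lx[, stage_of == b, drop = FALSE]
    lfc <- rowMeans(xb) - rowMeans(xa)
    pv <- vapply(seq_len(n), function(g) {
      if (stats::sd(xa[g, ]) == 0 && stats::sd(xb[g, ]) == 0)
        return(if (abs(lfc[g]) > 0) 0 else 1)
      stats::t.test(xb[g, ], xa[g, ])$p.value
    }, numeric(1))
    de[[paste0(b, "_vs_", a)]] <- data.frame(
      gene_id = genes$gene_id, log2fc = lfc,
      fdr = stats::p.adjust(pv, "BH"), pvalue = pv,
      stringsAsFactors = FALSE)
  }

  ## RIP counts: NB, planted fold change on the IP library
  c_mu <- stats::runif(n, 20, 200)
  control <- stats::rnbinom(n, size = cfg$rip_dispersion, mu = c_mu)
  ip_mu <- c_mu * ifelse(truth$rip_enriched, cfg$rip_fc, 1)
  ip <- stats::rnbinom(n, size = cfg$rip_dispersion, mu = ip_mu)
  rip <- data.frame(transcript_id = genes$gene_id,
                    ip_count = ip, control_count = control,
                    length_bp = genes$end - genes$start,
                    ip_libsize = cfg$rip_libsize,
                    control_libsize = cfg$rip_libsize,
                    stringsAsFactors = FALSE)

  ## gene-set collection: true module member sets + random decoys
  gene_sets <- list()
  if (n_mod > 0) {
    coding <- genes$gene_id[genes$biotype == "coding"]
    for (m in seq_len(n_mod)) {
      mem <- genes$gene_id[truth$module == m & truth$module_role == "member"]
      gene_sets[[paste0("module", m, "_members")]] <- mem
    }
    for (j in seq_len(2 * n_mod)) {
      gene_sets[[paste0("random_set", j)]] <-
        sample(coding, cfg$module_size)
    }
  }
  list(expr = expr, de = de, rip = rip, gene_sets = gene_sets)
}

#' Write a complete synthetic fixture directory
#'
#' Runs the three generators under the config seed and writes every file
#' in the formats the readers consume: `genes.tsv`, per-stage
#' `peaks_<stage>_<mark>.bed` (BED6+, fold enrichment col 7, FDR col 8),
#' `expression.tsv`, `de_<B>_vs_<A>.tsv`, `rip_counts.tsv`,
#' `gene_sets.gmt` and `truth.tsv`.  Re-running with the same config is
#' byte-identical.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- simulate_genome(cfg)
  peaks <- simulate_peaks(cfg, gen$genes, gen$truth)
  ex <- simulate_expression(cfg, gen$genes, gen$truth)
  write_gene_table(gen$genes, file.path(dir, "genes.tsv"))
  for (s in names(peaks))
    for (mk in names(peaks[[s]]))
      write_peaks(peaks[[s]][[mk]],
                  file.path(dir, sprintf("peaks_%s_%s.bed", s, mk)))
  write_expression(ex$expr, file.path(dir, "expression.tsv"))
  for (ctr in names(ex$de))
    write_de_table(ex$de[[ctr]], file.path(dir, paste0("de_", ctr, ".tsv")))
  utils::write.table(ex$rip, file.path(dir, "rip_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(ex$gene_sets))
    write_gmt(ex$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(gen$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genes = gen$genes, truth = gen$truth, peaks = peaks,
                 expr = ex$expr, de = ex$de, rip = ex$rip,
                 gene_sets = ex$gene_sets))
}
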