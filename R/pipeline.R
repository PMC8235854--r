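## End-to-end orchestration over a fixture/run directory laid out the way
## simulate_dataset() writes it: genes.tsv, peaks_<stage>_<mark>.bed,
## expression.tsv, de_<B>_vs_<A>.tsv, optional gene_sets.gmt and
## rip_counts.tsv.

#' Pipeline run configuration
#'
#' Bundles the input directory, ordered stage labels, the random seed, and
#' every analysis threshold.  Defaults are the study's printed values: TF
#' peaks FDR < 0.05 and fold enrichment > 5, histone peaks FDR < 0.05 and
#' fold enrichment > 3.5, 5 kb upstream + gene-body TF annotation, TSS
#' +/- 2 kb promoter window, DEGs at |log2FC| > 1, FDR < 0.01, FPKM > 1,
#' GSEA association FDR < 0.25, term enrichment FDR < 0.05, RIP targets at
#' fold change > 2, p < 0.01, RPKM > 1.
#'
#' @param input_dir Directory holding the input files.
#' @param stages Ordered stage labels.
#' @param seed Integer seed used for every stochastic step.
#' @param tf_fdr_max,tf_fe_min TF peak quality filter.
#' @param hist_fdr_max,hist_fe_min Histone peak quality filter.
#' @param upstream_bp TF annotation upstream window (bp).
#' @param promoter_window_bp Promoter half-window for state calls (bp).
#' @param deg_lfc_min,deg_fdr_max,fpkm_min DEG filter thresholds.
#' @param k_patterns,n_init,top_n Expression-pattern parameters.
#' @param gsea_n_perm,gsea_fdr_keep,gba_max_queries GSEA parameters.
#' @param enrich_fdr_max Hypergeometric enrichment FDR ceiling.
#' @param rip_fc_min,rip_p_max,rip_rpkm_min RIP target filter thresholds.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(input_dir, stages = c("NSC", "OPC", "NFO"), seed = 1L,
                       tf_fdr_max = 0.05, tf_fe_min = 5,
                       hist_fdr_max = 0.05, hist_fe_min = 3.5,
                       upstream_bp = 5000, promoter_window_bp = 2000,
                       deg_lfc_min = 1, deg_fdr_max = 0.01, fpkm_min = 1,
                       k_patterns = 10, n_init = 50, top_n = 100,
                       gsea_n_perm = 1000, gsea_fdr_keep = 0.25,
                       gba_max_queries = 5, enrich_fdr_max = 0.05,
                       rip_fc_min = 2, rip_p_max = 0.01, rip_rpkm_min = 1) {
  structure(as.list(environment()), class = "run_config")
}

req_file <- function(dir, name, stage) {
  p <- file.path(dir, name)
  if (!file.exists(p))
    stop2("pipeline stage '", stage, "': missing input file ", p)
  p
}

#' Run the full pipeline
#'
#' Executes annotation, chromatin-state, DEG-integration,
#' expression-pattern, guilt-by-association (when `gene_sets.gmt` is
#' present) and RIP (when `rip_counts.tsv` is present) stages, writing
#' per-stage TSV outputs plus a machine-readable `summary.json` to
#' `out_dir`.  Re-running with identical config and inputs is
#' byte-identical.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_all <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dir <- cfg$input_dir
  summary <- list(stages = as.list(cfg$stages), seed = cfg$seed)
  tsv <- function(x, name)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  ## -- annotate ------------------------------------------------------
  genes <- read_gene_table(req_file(dir, "genes.tsv", "annotate"))
  bound <- list(); n_tf_peaks <- list()
  for (s in cfg$stages) {
    tf <- read_peaks(req_file(dir, sprintf("peaks_%s_TF.bed", s), "annotate"),
                     mark = "TF", dialect = "bed6plus", fe_col = 7, fdr_col = 8)
    tf <- filter_peaks(tf, cfg$tf_fdr_max, cfg$tf_fe_min)
    links <- assign_peaks_to_genes(tf, genes, cfg$upstream_bp)
    bound[[s]] <- unique(links$gene_id)
    n_tf_peaks[[s]] <- nrow(tf)
    tsv(links, sprintf("tf_links_%s.tsv", s))
    loc <- classify_peak_location(tf, genes)
    dist <- as.data.frame(attr(loc, "distribution"))
    names(dist) <- c("category", "count")
    tsv(dist, sprintf("tf_location_%s.tsv", s))
  }
  summary$annotate <- list(n_tf_peaks = n_tf_peaks,
                           n_bound_genes = lapply(bound, length))

  ## -- chromstate ----------------------------------------------------
  calls <- list()
  for (s in cfg$stages) {
    k4 <- read_peaks(req_file(dir, sprintf("peaks_%s_K4.bed", s), "chromstate"),
                     mark = "K4", dialect = "bed6plus", fe_col = 7, fdr_col = 8)
    k27 <- read_peaks(req_file(dir, sprintf("peaks_%s_K27.bed", s), "chromstate"),
                      mark = "K27", dialect = "bed6plus", fe_col = 7, fdr_col = 8)
    dom <- build_domains(filter_peaks(k4, cfg$hist_fdr_max, cfg$hist_fe_min),
                         filter_peaks(k27, cfg$hist_fdr_max, cfg$hist_fe_min))
    calls[[s]] <- classify_genes(dom, genes, cfg$promoter_window_bp)
    tsv(calls[[s]], sprintf("states_%s.tsv", s))
  }
  dyn <- state_dynamics(calls)
  tsv(data.frame(gene_id = rownames(dyn$sequences), dyn$sequences,
                 row.names = NULL), "state_sequences.tsv")
  venn <- common_states(calls, "bivalent")
  state_counts <- lapply(calls, function(d) as.list(table(d$state)))
  first <- cfg$stages[1]
  n_biv_first <- sum(calls[[first]]$state == "bivalent")
  summary$chromstate <- list(
    state_counts = state_counts,
    bivalent_common = length(venn$common),
    bivalent_venn = as.list(venn$venn),
    bivalent_to_k4 = length(dyn$bivalent_to_k4),
    bivalent_to_k4_percent =
      if (n_biv_first > 0)
        fraction_percent(length(dyn$bivalent_to_k4), n_biv_first) else NA)

  ## -- integrate -----------------------------------------------------
  expr <- read_expression(req_file(dir, "expression.tsv", "integrate"))
  stage_of <- sample_stages(expr)
  integrate_summary <- list()
  for (i in seq_along(cfg$stages)[-1]) {
    a <- cfg$stages[i - 1]; b <- cfg$stages[i]
    ctr <- paste0(b, "_vs_", a)
    de_path <- file.path(dir, paste0("de_", ctr, ".tsv"))
    if (!file.exists(de_path)) next
    de <- read_de_table(de_path)
    sub <- expr[, stage_of %in% c(a, b), drop = FALSE]
    degs <- suppressMessages(
      filter_degs(de, sub, cfg$deg_lfc_min, cfg$deg_fdr_max, cfg$fpkm_min))
    reg <- intersect_bound(degs, bound[[b]])
    tsv(degs, sprintf("degs_%s.tsv", ctr))
    tsv(reg, sprintf("regulation_%s.tsv", ctr))
    integrate_summary[[ctr]] <- list(
      n_deg = nrow(degs),
      n_bound_deg = nrow(reg),
      n_up_bound = unname(attr(reg, "counts")["n_up_bound"]),
      n_down_bound = unname(attr(reg, "counts")["n_down_bound"]))
  }
  summary$integrate <- integrate_summary

  ## -- patterns ------------------------------------------------------
  lnc <- genes$gene_id[genes$biotype == "lncRNA"]
  bound_any <- unique(unlist(bound))
  sel <- select_expressed(expr, intersect(bound_any, lnc), cfg$fpkm_min)
  summary$patterns <- list(n_selected_lncrna = length(sel))
  if (length(sel) >= cfg$k_patterns) {
    cl <- suppressMessages(
      cluster_patterns(expr, sel, cfg$k_patterns, seed = cfg$seed,
                       n_init = cfg$n_init))
    tsv(data.frame(gene_id = names(cl$assignment),
                   cluster = unname(cl$assignment)), "pattern_clusters.tsv")
    tsv(data.frame(cluster = seq_len(nrow(cl$centers)), cl$centers,
                   row.names = NULL), "pattern_centers.tsv")
    summary$patterns$cluster_sizes <-
      as.list(tabulate(cl$assignment, cfg$k_patterns))
  } else {
    message("patterns: only ", length(sel),
            " selected lncRNAs (< k); clustering skipped")
  }
  spec <- zscore_specific(expr, cfg$top_n)
  for (ct in names(spec)) tsv(spec[[ct]], sprintf("specific_%s.tsv", ct))

  ## -- gba -----------------------------------------------------------
  gmt_path <- file.path(dir, "gene_sets.gmt")
  if (file.exists(gmt_path)) {
    sets <- read_gmt(gmt_path)
    coding <- genes$gene_id[genes$biotype == "coding"]
    queries <- utils::head(sel, cfg$gba_max_queries)
    if (length(queries)) {
      ranked <- lapply(queries, function(q)
        suppressMessages(rank_by_correlation(q, expr, coding)))
      names(ranked) <- queries
      res <- gsea_batch(ranked, sets, n_perm = cfg$gsea_n_perm,
                        seed = cfg$seed)
      tsv(res, "gsea_results.tsv")
      assoc <- build_association_matrix(res, cfg$gsea_fdr_keep)
      tsv(data.frame(query = rownames(assoc), assoc, row.names = NULL,
                     check.names = FALSE), "association_matrix.tsv")
      summary$gba <- list(n_queries = length(queries),
                          n_pairs = nrow(res),
                          n_associations = sum(!is.na(assoc)))
    }
  }

  ## -- rip -----------------------------------------------------------
  rip_path <- file.path(dir, "rip_counts.tsv")
  if (file.exists(rip_path)) {
    rip <- utils::read.table(rip_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    disp <- estimate_dispersion(rip$ip_count, rip$control_count,
                                rip$ip_libsize, rip$control_libsize)
    tst <- rip_test(rip$ip_count, rip$control_count,
                    rip$ip_libsize, rip$control_libsize, dispersion = disp)
    calls_rip <- data.frame(
      transcript_id = rip$transcript_id,
      fold_change = tst$fold_change, pval = tst$pval,
      rpkm = rpkm(rip$ip_count, rip$length_bp, rip$ip_libsize))
    targets <- filter_targets(calls_rip, cfg$rip_fc_min, cfg$rip_p_max,
                              cfg$rip_rpkm_min)
    tsv(targets, "rip_targets.tsv")
    summary$rip <- list(n_transcripts = nrow(rip), n_targets = nrow(targets))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
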