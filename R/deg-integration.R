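## DEG filtering at the study thresholds and intersection with TF-bound
## gene sets to call putative activated / repressed targets.

#' Filter differential-expression records
#'
#' Keeps genes with `|log2fc| > lfc_min`, `fdr < fdr_max` and a maximum
#' FPKM across all supplied samples `> fpkm_min` (all strict).  Direction
#' is the sign of log2fc.  Genes absent from the expression matrix are
#' skipped with a message.
#'
#' @param de DE data.frame ([read_de_table()]).
#' @param expr Expression matrix restricted to (or containing) the samples
#'   of the two contrasted stages; the expression floor uses the
#'   per-replicate maximum over its columns.
#' @param lfc_min Absolute log2 fold-change floor (default 1; strict `>`).
#' @param fdr_max FDR ceiling (default 0.01; strict `<`).
#' @param fpkm_min Expression floor (default 1; strict `>`).
#' @return data.frame gene_id, log2fc, fdr, direction (`up` / `down`).
#' @export
filter_degs <- function(de, expr, lfc_min = 1, fdr_max = 0.01, fpkm_min = 1) {
  check_expression(expr)
  missing <- setdiff(de$gene_id, rownames(expr))
  if (length(missing)) {
    message(length(missing), " DE gene(s) absent from expression matrix; skipped")
    de <- de[de$gene_id %in% rownames(expr), , drop = FALSE]
  }
  if (!nrow(de))
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      fdr = numeric(), direction = character()))
  max_fpkm <- apply(expr[de$gene_id, , drop = FALSE], 1, max)
  keep <- abs(de$log2fc) > lfc_min & de$fdr < fdr_max & max_fpkm > fpkm_min
  out <- de[keep, c("gene_id", "log2fc", "fdr"), drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  row.names(out) <- NULL
  out
}

#' DEG filter on p-values and linear fold change
#'
#' Variant filter for experiments reported with raw p-values and linear
#' fold-change thresholds (p < 0.05, |fold-change| > 1.5 by default);
#' otherwise identical in contract to [filter_degs()].
#'
#' @inheritParams filter_degs
#' @param p_max Raw p-value ceiling (strict `<`); requires a `pvalue`
#'   column in `de`.
#' @return Same shape as [filter_degs()].
#' @export
alt_threshold_filter <- function(de, expr, lfc_min = log2(1.5), p_max = 0.05,
                                 fpkm_min = 1) {
  if (!"pvalue" %in% names(de))
    stop2("alt_threshold_filter needs a 'pvalue' column")
  de2 <- de
  de2$fdr <- de$pvalue
  filter_degs(de2, expr, lfc_min = lfc_min, fdr_max = p_max, fpkm_min = fpkm_min)
}

#' Label TF-bound DEGs as putative activated or repressed
#'
#' Intersects a filtered DEG list with the set of genes bound by the
#' transcription factor in the relevant stage: upregulated and bound ->
#' `putative_activated`; downregulated and bound -> `putative_repressed`.
#'
#' @param degs Output of [filter_degs()].
#' @param bound_genes Character vector of TF-bound gene ids for the stage.
#' @return data.frame gene_id, direction, label; `"counts"` attribute
#'   holds n_up_bound / n_down_bound.
#' @export
intersect_bound <- function(degs, bound_genes) {
  hit <- degs[degs$gene_id %in% bound_genes, , drop = FALSE]
  hit$label <- ifelse(hit$direction == "up",
                      "putative_activated", "putative_repressed")
  row.names(hit) <- NULL
  attr(hit, "counts") <- c(n_up_bound = sum(hit$direction == "up"),
                           n_down_bound = sum(hit$direction == "down"))
  hit
}
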