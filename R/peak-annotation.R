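## Peak quality filtering, peak-to-gene assignment under the promoter /
## gene-body window conventions, genomic location classification, and
## peak-set overlap fractions.

#' Filter peaks on FDR and fold enrichment
#'
#' Retains peaks with `fdr < fdr_max` and `fold_enrichment > fe_min`, both
#' strict, preserving input order.  Defaults are the transcription-factor
#' thresholds (FDR < 0.05, fold enrichment > 5); histone marks are
#' conventionally filtered at `fe_min = 3.5`.
#'
#' @param peaks Peak data.frame ([read_peaks()]).
#' @param fdr_max FDR cutoff in (0, 1]; strict `<`.
#' @param fe_min Fold-enrichment floor; strict `>`.
#' @return The retained rows of `peaks`.
#' @export
filter_peaks <- function(peaks, fdr_max = 0.05, fe_min = 5) {
  stopifnot(is.finite(fdr_max), is.finite(fe_min))
  if (fdr_max <= 0 || fdr_max > 1) stop2("fdr_max must lie in (0, 1]")
  peaks[peaks$fdr < fdr_max & peaks$fold_enrichment > fe_min, , drop = FALSE]
}

## strand-aware upstream window [tss - up, tss) for '+', [tss, tss + up) for '-'
upstream_window <- function(genes, upstream_bp) {
  data.frame(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$tss - upstream_bp, genes$tss),
    end = ifelse(genes$strand == "+", genes$tss, genes$tss + upstream_bp)
  )
}

#' Assign peaks to genes via upstream-window or gene-body overlap
#'
#' A peak links to a gene when it overlaps, by at least 1 bp, either the
#' strand-aware upstream window of width `upstream_bp` ending at the TSS or
#' the gene body `[start, end)`.  A peak may link to several genes; when a
#' peak overlaps both zones of one gene, `gene_body` takes precedence.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene data.frame ([read_gene_table()]); must be stranded.
#' @param upstream_bp Width of the upstream window in bp (default 5000).
#' @return data.frame with columns peak_name, peak_idx, gene_id, zone
#'   (`upstream_window` or `gene_body`), one row per (peak, gene) link.
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream_bp = 5000) {
  if (!all(genes$strand %in% c("+", "-"))) stop2("genes must be stranded")
  empty <- data.frame(peak_name = character(), peak_idx = integer(),
                      gene_id = character(), zone = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(peaks) || !nrow(genes)) return(empty)
  pg <- as_granges0(peaks)
  body <- as_granges0(genes)
  up <- upstream_window(genes, upstream_bp)
  up$start <- pmax(up$start, 0L)
  keep_up <- up$end > up$start
  hits_body <- GenomicRanges::findOverlaps(pg, body, ignore.strand = TRUE)
  links <- data.frame(
    peak_idx = S4Vectors::queryHits(hits_body),
    gene = S4Vectors::subjectHits(hits_body),
    zone = rep("gene_body", length(hits_body)))
  if (any(keep_up)) {
    upg <- as_granges0(up[keep_up, , drop = FALSE])
    hits_up <- GenomicRanges::findOverlaps(pg, upg, ignore.strand = TRUE)
    links <- rbind(links, data.frame(
      peak_idx = S4Vectors::queryHits(hits_up),
      gene = which(keep_up)[S4Vectors::subjectHits(hits_up)],
      zone = rep("upstream_window", length(hits_up))))
  }
  if (!nrow(links)) return(empty)
  ## gene_body wins when a (peak, gene) pair overlaps both zones
  links <- links[order(links$peak_idx, links$gene, links$zone != "gene_body"), ]
  links <- links[!duplicated(links[c("peak_idx", "gene")]), ]
  data.frame(peak_name = peaks$name[links$peak_idx],
             peak_idx = links$peak_idx,
             gene_id = genes$gene_id[links$gene],
             zone = links$zone,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify peak genomic locations by midpoint
#'
#' Each peak midpoint is placed in exactly one category by a fixed priority
#' ladder: `promoter_le1kb` (within 1 kb of some TSS), `promoter_1to5kb`,
#' `gene_body`, `downstream_le5kb` (within 5 kb of a gene's 3' end on the
#' downstream side), else `distal_intergenic`.
#'
#' @param peaks Peak data.frame.
#' @param genes Gene data.frame.
#' @return Character vector of categories, one per peak, plus a count table
#'   as the `"distribution"` attribute.
#' @export
classify_peak_location <- function(peaks, genes) {
  cats <- c("promoter_le1kb", "promoter_1to5kb", "gene_body",
            "downstream_le5kb", "distal_intergenic")
  if (!nrow(peaks)) {
    out <- character()
    attr(out, "distribution") <- table(factor(character(), levels = cats))
    return(out)
  }
  mid <- (peaks$start + peaks$end) %/% 2L
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g)) return("distal_intergenic")
    dtss <- abs(mid[i] - g$tss)
    if (any(dtss <= 1000)) return("promoter_le1kb")
    if (any(dtss <= 5000)) return("promoter_1to5kb")
    if (any(mid[i] >= g$start & mid[i] < g$end)) return("gene_body")
    tail3 <- ifelse(g$strand == "+", g$end, g$start)
    downstream <- ifelse(g$strand == "+",
                         mid[i] >= tail3 & mid[i] < tail3 + 5000,
                         mid[i] < tail3 & mid[i] >= tail3 - 5000)
    if (any(downstream)) return("downstream_le5kb")
    "distal_intergenic"
  }, character(1))
  attr(out, "distribution") <- table(factor(out, levels = cats))
  out
}

#' Fraction of one peak set overlapping another
#'
#' Fraction of peaks in `a` that overlap at least one peak in `b` by at
#' least 1 bp (e.g. inferred TF-activated peaks vs H3K27ac peaks).
#'
#' @param a,b Peak data.frames; `a` must be non-empty.
#' @return A number in \[0, 1\].
#' @export
peak_overlap_fraction <- function(a, b) {
  if (!nrow(a)) stop2("cannot compute an overlap fraction of an empty peak set")
  if (!nrow(b)) return(0)
  ## suppress the seqlevel-mismatch warning for fully disjoint chromosomes
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b),
                                ignore.strand = TRUE))
  length(unique(S4Vectors::queryHits(hits))) / nrow(a)
}
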