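## Bivalent-domain construction from H3K4me3 / H3K27me3 peak sets,
## per-gene promoter state classification, and cross-stage dynamics.

STATES <- c("K4_only", "K27_only", "bivalent", "other")

#' Merge H3K4me3 and H3K27me3 peaks into mark domains
#'
#' Pools both mark sets and merges all overlapping intervals transitively
#' to a fixed point (bedtools-merge semantics on the pooled set).  A merged
#' region whose sources include at least one K4 and one K27 peak is a
#' `bivalent` domain; single-mark regions become `K4_only` or `K27_only`.
#' Output intervals are disjoint and sorted by (chrom, start).
#'
#' @param k4,k27 Peak data.frames for the two marks, already
#'   quality-filtered with [filter_peaks()].
#' @return data.frame with columns chrom, start, end, kind
#'   (`K4_only` / `K27_only` / `bivalent`).
#' @export
build_domains <- function(k4, k27) {
  pooled <- rbind(
    if (nrow(k4)) data.frame(chrom = k4$chrom, start = k4$start, end = k4$end,
                             src = "K4") else NULL,
    if (nrow(k27)) data.frame(chrom = k27$chrom, start = k27$start, end = k27$end,
                              src = "K27") else NULL)
  if (is.null(pooled) || !nrow(pooled))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  gr <- as_granges0(pooled)
  merged <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  src_by_dom <- split(pooled$src[S4Vectors::queryHits(hits)],
                      S4Vectors::subjectHits(hits))
  kind <- vapply(src_by_dom, function(s) {
    has4 <- "K4" %in% s; has27 <- "K27" %in% s
    if (has4 && has27) "bivalent" else if (has4) "K4_only" else "K27_only"
  }, character(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    kind = unname(kind[as.character(seq_along(merged))]),
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Classify gene promoter chromatin states from mark domains
#'
#' Considers domains overlapping the promoter window
#' `[tss - window_bp, tss + window_bp)` of each gene.  A gene is `bivalent`
#' iff the window holds at least one bivalent domain and no single-mark
#' domain; `K4_only` / `K27_only` iff it holds only that single mark and no
#' bivalent domain; every other configuration (mixed evidence or an empty
#' window) is `other`.
#'
#' @param domains Domain data.frame from [build_domains()].
#' @param genes Gene data.frame.
#' @param window_bp Promoter half-window in bp (default 2000).
#' @return data.frame gene_id, state; one row per gene.
#' @export
classify_genes <- function(domains, genes, window_bp = 2000) {
  state <- rep("other", nrow(genes))
  if (nrow(domains) && nrow(genes)) {
    win <- data.frame(chrom = genes$chrom,
                      start = pmax(genes$tss - window_bp, 0L),
                      end = genes$tss + window_bp)
    hits <- GenomicRanges::findOverlaps(as_granges0(win), as_granges0(domains),
                                        ignore.strand = TRUE)
    kinds <- split(domains$kind[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
    for (g in names(kinds)) {
      k <- kinds[[g]]
      n4 <- sum(k == "K4_only"); n27 <- sum(k == "K27_only")
      nb <- sum(k == "bivalent")
      state[as.integer(g)] <-
        if (nb >= 1 && n4 == 0 && n27 == 0) "bivalent"
        else if (n4 >= 1 && n27 == 0 && nb == 0) "K4_only"
        else if (n27 >= 1 && n4 == 0 && nb == 0) "K27_only"
        else "other"
    }
  }
  data.frame(gene_id = genes$gene_id, state = state, stringsAsFactors = FALSE)
}

#' Cross-stage chromatin state dynamics
#'
#' Builds the per-gene state sequence across ordered stages, pairwise
#' stage-to-stage transition counts, and the set of genes that are
#' bivalent at the first stage and `K4_only` at every later stage (the
#' poised-to-active resolution pattern).  A gene missing from a stage's
#' calls is treated as `other` and reported via message.
#'
#' @param calls_by_stage Named list (stage -> data.frame from
#'   [classify_genes()]), in stage order.
#' @return List with `sequences` (genes x stages character matrix),
#'   `transitions` (per adjacent stage pair, a 4x4 state count table), and
#'   `bivalent_to_k4` (gene ids bivalent at stage 1, K4_only afterwards).
#' @export
state_dynamics <- function(calls_by_stage) {
  stopifnot(length(calls_by_stage) >= 2, !is.null(names(calls_by_stage)))
  all_genes <- unique(unlist(lapply(calls_by_stage, `[[`, "gene_id")))
  seqs <- matrix("other", nrow = length(all_genes), ncol = length(calls_by_stage),
                 dimnames = list(all_genes, names(calls_by_stage)))
  for (s in names(calls_by_stage)) {
    calls <- calls_by_stage[[s]]
    missing <- setdiff(all_genes, calls$gene_id)
    if (length(missing))
      message(length(missing), " gene(s) missing from stage ", s,
              "; treated as 'other'")
    seqs[calls$gene_id, s] <- calls$state
  }
  stages <- names(calls_by_stage)
  transitions <- lapply(seq_len(length(stages) - 1), function(i) {
    table(from = factor(seqs[, i], levels = STATES),
          to = factor(seqs[, i + 1], levels = STATES))
  })
  names(transitions) <- paste(stages[-length(stages)], stages[-1], sep = "->")
  later <- seqs[, -1, drop = FALSE]
  biv_to_k4 <- rownames(seqs)[seqs[, 1] == "bivalent" &
                                rowSums(later == "K4_only") == ncol(later)]
  list(sequences = seqs, transitions = transitions, bivalent_to_k4 = biv_to_k4)
}

#' Venn counts of a chromatin state across stages
#'
#' For a given state, computes the membership region counts of the per-stage
#' gene sets (all 2^k - 1 regions for k stages) and their full intersection.
#'
#' @param calls_by_stage Named list of [classify_genes()] outputs.
#' @param state State to compare, one of `K4_only`, `K27_only`, `bivalent`,
#'   `other`.
#' @return List with `sets` (per-stage gene-id vectors), `venn` (named
#'   region counts, names like "NSC&OPC"), and `common` (intersection of
#'   all stages).
#' @export
common_states <- function(calls_by_stage, state = "bivalent") {
  stopifnot(state %in% STATES)
  sets <- lapply(calls_by_stage, function(d) d$gene_id[d$state == state])
  stages <- names(calls_by_stage)
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, function(m) paste(stages[m], collapse = "&"))
  venn <- integer(0)
  for (i in seq_along(stages)) {
    combs <- utils::combn(stages, i, paste, collapse = "&")
    venn[combs] <- vapply(combs, function(k) sum(key == k), integer(1))
  }
  common <- genes[rowSums(member) == length(stages)]
  list(sets = sets, venn = venn, common = common)
}
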