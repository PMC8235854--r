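## Readers and writers for the external formats the pipeline touches.
## All coordinates are 0-based half-open after parsing, whatever the dialect.

PEAK_COLS <- c("chrom", "start", "end", "name", "strand",
               "fold_enrichment", "fdr", "mark")
MARKS <- c("TF", "K4", "K27", "other")

#' Read called peaks from narrowPeak, broadPeak or BED6+ files
#'
#' Parses ENCODE narrowPeak (10 columns) or broadPeak (9 columns), mapping
#' `signalValue` to fold enrichment and the `qValue` column (stored as
#' -log10) to an FDR via `10^-q`; a negative `qValue` (ENCODE's "missing"
#' sentinel) becomes FDR 1.  The `bed6plus` dialect takes plain
#' fold-enrichment and FDR values from explicitly named extra columns.
#'
#' @param path Path to a tab-separated peak file without header.
#' @param mark Mark label attached to every peak: one of
#'   `"TF"`, `"K4"`, `"K27"`, `"other"`.
#' @param dialect One of `"narrowPeak"`, `"broadPeak"`, `"bed6plus"`.
#' @param fe_col,fdr_col For `bed6plus` only: 1-based column indices holding
#'   fold enrichment and FDR (FDR on the plain probability scale).
#' @return A peak data.frame with columns chrom, start, end, name, strand,
#'   fold_enrichment, fdr, mark in file order.  Coordinates 0-based
#'   half-open.
#' @export
read_peaks <- function(path, mark = c("TF", "K4", "K27", "other"),
                       dialect = c("narrowPeak", "broadPeak", "bed6plus"),
                       fe_col = NULL, fdr_col = NULL) {
  mark <- match.arg(mark)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- switch(dialect, narrowPeak = 10L, broadPeak = 9L, bed6plus = 6L)
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad))
    stop2(sprintf("malformed %s line %d in %s: expected >= %d fields, got %d",
                  dialect, bad[1], path, need, nf[bad[1]]))
  get <- function(i) vapply(fields, `[[`, "", i)
  chrom <- get(1)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end))
    stop2("non-numeric coordinate in ", path, " at line ",
          which(is.na(start) | is.na(end))[1])
  if (any(start < 0))
    stop2("negative coordinate in ", path, " at line ", which(start < 0)[1])
  name <- get(4)
  strand <- get(6)
  if (dialect %in% c("narrowPeak", "broadPeak")) {
    fe <- as.numeric(get(7))
    q <- as.numeric(get(9))
    fdr <- ifelse(q < 0, 1, 10^(-q))
  } else {
    if (is.null(fe_col) || is.null(fdr_col))
      stop2("bed6plus dialect requires fe_col and fdr_col")
    if (any(nf < max(fe_col, fdr_col)))
      stop2("bed6plus line shorter than fe_col/fdr_col in ", path)
    fe <- as.numeric(get(fe_col))
    fdr <- as.numeric(get(fdr_col))
  }
  pk <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   strand = strand, fold_enrichment = fe, fdr = fdr,
                   mark = mark, stringsAsFactors = FALSE)
  validate_peaks(pk)
}

validate_peaks <- function(pk) {
  check_intervals(pk, "peak")
  if (any(pk$fdr < 0 | pk$fdr > 1)) stop2("peak FDR outside [0,1]")
  if (any(pk$fold_enrichment < 0)) stop2("negative fold enrichment")
  if (!all(pk$strand %in% c("+", "-", "."))) stop2("peak strand must be +, - or .")
  if (!all(pk$mark %in% MARKS)) stop2("unknown peak mark")
  pk
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), strand = character(),
             fold_enrichment = numeric(), fdr = numeric(),
             mark = character(), stringsAsFactors = FALSE)
}

#' Write peaks in the package's BED6+ dialect
#'
#' Emits BED6 plus fold_enrichment (column 7) and FDR (column 8); reading
#' back with `read_peaks(dialect = "bed6plus", fe_col = 7, fdr_col = 8)`
#' round-trips.
#'
#' @param peaks Peak data.frame as produced by [read_peaks()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    0L, peaks$strand,
                    format(peaks$fold_enrichment, trim = TRUE,
                           scientific = FALSE, digits = 15),
                    format(peaks$fdr, trim = TRUE, digits = 15))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a tab-separated file with header
#' `gene_id  chrom  start  end  strand  biotype`; biotype is `coding` or
#' `lncRNA`, strand must be `+` or `-`.  The TSS is derived per strand
#' (start for `+`, end for `-`; coordinates 0-based half-open).
#'
#' @param path Path to the TSV.
#' @return data.frame with the input columns plus `tss`.
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(g)))
    stop2("gene table must have columns: ", paste(need, collapse = ", "))
  validate_genes(g[need])
}

validate_genes <- function(g) {
  check_intervals(g, "gene")
  if (anyDuplicated(g$gene_id))
    stop2("duplicate gene_id: ", g$gene_id[duplicated(g$gene_id)][1])
  if (!all(g$strand %in% c("+", "-")))
    stop2("gene strand must be '+' or '-' (unstranded genes not allowed)")
  if (!all(g$biotype %in% c("coding", "lncRNA")))
    stop2("unknown biotype: ", setdiff(g$biotype, c("coding", "lncRNA"))[1])
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g
}

#' @rdname read_gene_table
#' @param genes Gene data.frame.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(
    genes[c("gene_id", "chrom", "start", "end", "strand", "biotype")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' A GMT line is `name<TAB>description<TAB>member1<TAB>member2...`.  The
#' collection is returned as a named list of character vectors of unique
#' member gene ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop2("GMT line ", short[1], " has no members")
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) stop2("duplicate gene-set name: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @param descriptions Optional per-set description strings (defaults to
#'   the set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop2("gene sets must be named")
  desc <- descriptions %||% names(sets)
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), desc, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read and write FPKM expression matrices
#'
#' Tab-separated with header; first column `gene_id`, remaining columns one
#' sample each, named `<stage>_<replicate>` (e.g. `NSC_1`).  Values are
#' non-negative FPKM.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, rownames = gene ids, colnames = sample labels.
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- lengths(fields)
  if (length(unique(width)) != 1)
    stop2("ragged expression matrix: line ", which(width != width[1])[1],
          " has ", width[width != width[1]][1], " fields, expected ", width[1])
  header <- fields[[1]]
  body <- fields[-1]
  gene_ids <- vapply(body, `[[`, "", 1)
  vals <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(width[1] - 1)))
  if (width[1] == 2) vals <- matrix(vals, ncol = 1)
  rownames(vals) <- gene_ids
  colnames(vals) <- header[-1]
  check_expression(vals)
}

#' @rdname read_expression
#' @param expr Expression matrix.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write differential-expression tables
#'
#' Tab-separated with header `gene_id  log2fc  fdr` (an optional `pvalue`
#' column is carried through when present).  These tables are consumed, not
#' produced, by the pipeline: real runs take them from an external DE tool.
#'
#' @param path Path to the TSV.
#' @return data.frame with gene_id, log2fc, fdr (and pvalue if present).
#' @export
read_de_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  if (!all(c("gene_id", "log2fc", "fdr") %in% names(d)))
    stop2("DE table must have columns gene_id, log2fc, fdr")
  if (any(d$fdr < 0 | d$fdr > 1, na.rm = TRUE)) stop2("DE FDR outside [0,1]")
  keep <- intersect(c("gene_id", "log2fc", "fdr", "pvalue"), names(d))
  d[keep]
}

#' @rdname read_de_table
#' @param de DE data.frame.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
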