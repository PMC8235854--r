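#' @keywords internal
"_PACKAGE"

## Shared validators and small helpers used across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Express a subset count as a percentage of a total
#'
#' One-decimal percentage reporter used throughout the pipeline summaries,
#' e.g. for the fraction of stage-one bivalent genes that resolve to an
#' H3K4me3-only promoter state at later stages.
#'
#' @param n_subset Count in the subset.
#' @param n_total Total count; must be positive.
#' @param digits Decimal places to round to (default 1).
#' @return Numeric percentage on the 0-100 scale.
#' @examples
#' fraction_percent(459, 1984)  # 23.1
#' @export
fraction_percent <- function(n_subset, n_total, digits = 1) {
  if (length(n_total) != 1 || !is.finite(n_total) || n_total <= 0)
    stop2("n_total must be a single positive number")
  if (any(n_subset < 0) || any(n_subset > n_total))
    stop2("n_subset must lie in [0, n_total]")
  round(100 * n_subset / n_total, digits)
}

## --- interval validation -------------------------------------------------

check_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(df$start < 0 | df$end <= df$start | !nzchar(df$chrom))
  if (length(bad))
    stop2(sprintf("invalid %s at row(s) %s: need start >= 0, end > start, non-empty chrom",
                  what, paste(utils::head(bad, 5), collapse = ", ")))
  invisible(df)
}

## Peaks and genes live in plain data.frames; these convert to GRanges for
## the interval algebra (coordinates are 0-based half-open throughout the
## package; GRanges is 1-based closed, hence the +1 on start).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) ifelse(df$strand %in% c("+", "-"), df$strand, "*") else "*"
  )
}

## stage labels from ExpressionMatrix column names "<stage>_<rep>"
sample_stages <- function(expr) {
  sub("_[^_]*$", "", colnames(expr))
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop2("expression matrix must be a numeric matrix with gene rownames")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop2("expression matrix needs gene rownames and '<stage>_<rep>' colnames")
  if (any(expr < 0)) stop2("FPKM values must be non-negative")
  invisible(expr)
}
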