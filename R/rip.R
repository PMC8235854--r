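## RIP-Seq target screening: RPKM, a negative-binomial enrichment test of
## IP over IgG control counts, the three-criteria target filter, and
## AU-rich element scanning of transcript sequence.

#' Reads (fragments) per kilobase per million mapped reads
#'
#' @param count Tag count (non-negative).
#' @param length_bp Transcript length in bp (> 0).
#' @param libsize Library size in reads (> 0).
#' @return `count / (length_bp/1000) / (libsize/1e6)`.
#' @export
rpkm <- function(count, length_bp, libsize) {
  if (any(length_bp <= 0)) stop2("length_bp must be positive")
  if (any(libsize <= 0)) stop2("libsize must be positive")
  if (any(count < 0)) stop2("counts must be non-negative")
  count / (length_bp / 1000) / (libsize / 1e6)
}

#' Negative-binomial enrichment test of IP vs control counts
#'
#' Library-size-scaled fold change with a pseudocount, and an upper-tail
#' negative-binomial p-value for observing at least the IP count under a
#' null whose mean is the library-scaled control count.  The dispersion is
#' user-supplied (e.g. from [estimate_dispersion()]); the NB null with a
#' global dispersion is a deliberately simple significance model — the
#' three-criteria filter downstream is the decision rule.
#'
#' @param ip_count,control_count Tag counts for IP and IgG control.
#' @param ip_libsize,control_libsize Library sizes.
#' @param pseudocount Added to both counts for the fold change (default 1).
#' @param dispersion NB size parameter (> 0); smaller = more overdispersed.
#' @param scale_libsize Set FALSE to compare raw counts without library
#'   scaling.
#' @return data.frame fold_change, pval (vectorized over transcripts).
#' @export
rip_test <- function(ip_count, control_count, ip_libsize, control_libsize,
                     pseudocount = 1, dispersion = 1, scale_libsize = TRUE) {
  if (any(dispersion <= 0)) stop2("dispersion must be positive")
  if (!scale_libsize) ip_libsize <- control_libsize <- 1
  fc <- ((ip_count + pseudocount) / ip_libsize) /
    ((control_count + pseudocount) / control_libsize)
  mu <- pmax(control_count * ip_libsize / control_libsize, 1e-8)
  pval <- ifelse(ip_count == 0, 1,
                 stats::pnbinom(ip_count - 1, size = dispersion, mu = mu,
                                lower.tail = FALSE))
  data.frame(fold_change = fc, pval = pval)
}

#' Paired method-of-moments NB dispersion
#'
#' Estimates the effective dispersion of the IP-vs-control comparison from
#' the count pairs themselves: under the null, the library-scaled IP and
#' control counts share a mean, so `E[(ip - ctrl)^2 / 2] = mu + mu^2/size`
#' per transcript; pooling moments across transcripts gives
#' `size = sum(m^2) / sum(d^2/2 - m)` with `m` the pair mean and `d` the
#' pair difference.  Because enriched transcripts violate the null, the
#' pairs with the largest mean-standardized squared differences are
#' trimmed before pooling.  Falls back to a large size (near-Poisson) if
#' the counts are underdispersed.
#'
#' @param ip_count,control_count Paired tag counts.
#' @param ip_libsize,control_libsize Library sizes (IP counts are scaled
#'   to the control library before pairing).
#' @param trim Fraction of most-discrepant pairs to drop (default 0.1).
#' @return Positive dispersion (NB size).
#' @export
estimate_dispersion <- function(ip_count, control_count,
                                ip_libsize = 1, control_libsize = 1,
                                trim = 0.1) {
  ip_s <- ip_count * control_libsize / ip_libsize
  m <- (ip_s + control_count) / 2
  d2 <- (ip_s - control_count)^2 / 2
  ratio <- d2 / pmax(m, 1)
  keep <- ratio <= stats::quantile(ratio, 1 - trim)
  den <- sum(d2[keep] - m[keep])
  if (den <= 0) return(1e8)
  sum(m[keep]^2) / den
}

#' Three-criteria RIP target filter
#'
#' Retains transcripts with fold change > `fc_min`, p-value < `p_max` and
#' RPKM > `rpkm_min` (all strict), sorted by ascending p-value.
#'
#' @param calls data.frame with columns transcript_id, fold_change, pval,
#'   rpkm (e.g. assembled from [rip_test()] and [rpkm()]).
#' @param fc_min Fold-change floor (default 2).
#' @param p_max P-value ceiling (default 0.01).
#' @param rpkm_min RPKM floor (default 1).
#' @return The retained rows, ascending pval.
#' @export
filter_targets <- function(calls, fc_min = 2, p_max = 0.01, rpkm_min = 1) {
  need <- c("transcript_id", "fold_change", "pval", "rpkm")
  if (!all(need %in% names(calls)))
    stop2("calls must have columns: ", paste(need, collapse = ", "))
  keep <- calls$fold_change > fc_min & calls$pval < p_max & calls$rpkm > rpkm_min
  out <- calls[keep, , drop = FALSE]
  out <- out[order(out$pval, out$transcript_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Scan a transcript sequence for AU-rich element pentamers
#'
#' Finds every (possibly overlapping) occurrence of the ARE pentamer
#' `ATTTA` (DNA alphabet for the AUUUA RNA motif), case-insensitive.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @return data.frame position (0-based offset), motif.
#' @export
scan_are <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s))
    stop2("sequence contains non-ACGTN characters")
  m <- gregexpr("(?=ATTTA)", s, perl = TRUE)[[1]]
  pos <- if (m[1] == -1) integer() else as.integer(m) - 1L
  data.frame(position = pos,
             motif = rep("ATTTA", length(pos)),
             stringsAsFactors = FALSE)
}
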