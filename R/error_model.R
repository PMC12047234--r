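# Sequencing error-rate measurement against a known reference, and
# Phred conversions.

#' Phred quality from an error rate
#'
#' `Q = floor(-10 * log10(e))`; truncation (floor) is used throughout,
#' so 0.00674 maps to Q21 and 0.00072 to Q31. The unrounded value is
#' attached as attribute `"exact"`.
#'
#' @param e Error rate(s) in `(0, 1]`.
#' @param zero_as_cap If `TRUE`, `e = 0` returns the cap Q60 instead of
#'   erroring (an infinite Q is otherwise undefined).
#' @return Integer Phred score(s) with attribute `exact`.
#' @export
phred_from_rate <- function(e, zero_as_cap = FALSE) {
  stop_if(any(e < 0) || any(e > 1), "`e` must lie in [0, 1]")
  if (any(e == 0)) {
    stop_if(!zero_as_cap,
            "e = 0 has no finite Phred score; set `zero_as_cap = TRUE` for Q60")
    exact <- ifelse(e == 0, 60, -10 * log10(e))
  } else {
    exact <- -10 * log10(e)
  }
  structure(as.integer(floor(exact)), exact = exact)
}

#' Measure the per-base substitution error rate of aligned reads
#'
#' Implements the germline-masked error-rate protocol: reads overlapping
#' any germline-variant position are removed, reads below `mapq_min` are
#' removed, at most `subsample` mutually nonoverlapping reads are kept
#' (coordinate-order greedy nonoverlap selection followed by a seeded
#' random subsample), and the error rate is the total substitution count
#' divided by total aligned bases — insertions and deletions are
#' excluded from the numerator.
#'
#' @param reads `data.frame` with columns `chrom`, `start` (0-based),
#'   `end`, `mapq`, `seq` (reference-aligned, substitution-only), and
#'   optionally `n_ins` (insertion count, ignored in the numerator).
#' @param reference Named character vector of chromosome sequences.
#' @param germline_mask Optional `data.frame` with `chrom` and `pos`
#'   (0-based) of germline-variant positions to mask.
#' @param mapq_min Minimum mapping quality (default 60).
#' @param subsample Maximum number of nonoverlapping reads retained
#'   (default 400000).
#' @param seed Optional integer seed for the subsample.
#' @return List of class `"error_rate_result"`: `error_rate`, `phred`,
#'   `n_reads_used`, `n_bases`, `n_mismatches`.
#' @export
compute_error_rate <- function(reads, reference, germline_mask = NULL,
                               mapq_min = 60, subsample = 400000L,
                               seed = NULL) {
  stop_if(!is.data.frame(reads) ||
            !all(c("chrom", "start", "end", "mapq", "seq") %in% names(reads)),
          "`reads` must have chrom, start, end, mapq, seq columns")
  keep <- reads$mapq >= mapq_min
  if (!is.null(germline_mask) && nrow(germline_mask) > 0) {
    for (ch in unique(germline_mask$chrom)) {
      pos <- germline_mask$pos[germline_mask$chrom == ch]
      on_ch <- reads$chrom == ch
      if (!any(on_ch)) next
      hit <- vapply(which(on_ch), function(i)
        any(pos >= reads$start[i] & pos < reads$end[i]), TRUE)
      keep[which(on_ch)[hit]] <- FALSE
    }
  }
  reads <- reads[keep, , drop = FALSE]
  stop_if(nrow(reads) == 0, "no usable reads after filtering")
  # greedy nonoverlap selection in coordinate order
  ord <- order(reads$chrom, reads$start, reads$end)
  sel <- logical(nrow(reads))
  last_end <- -Inf; last_chrom <- ""
  for (i in ord) {
    if (reads$chrom[i] != last_chrom || reads$start[i] >= last_end) {
      sel[i] <- TRUE
      last_chrom <- reads$chrom[i]; last_end <- reads$end[i]
    }
  }
  idx <- which(sel)
  if (length(idx) > subsample)
    idx <- with_seed_(seed, sample(idx, subsample))
  reads <- reads[idx, , drop = FALSE]
  n_mm <- 0L; n_bases <- 0L
  for (i in seq_len(nrow(reads))) {
    ref <- substr(reference[[reads$chrom[i]]],
                  reads$start[i] + 1L, reads$end[i])
    a <- utf8ToInt(reads$seq[i]); b <- utf8ToInt(ref)
    stop_if(length(a) != length(b),
            "read length disagrees with its reference span")
    n_mm <- n_mm + sum(a != b)
    n_bases <- n_bases + length(a)
  }
  rate <- n_mm / n_bases
  structure(list(
    error_rate = rate,
    phred = if (rate > 0) phred_from_rate(rate) else
      phred_from_rate(0, zero_as_cap = TRUE),
    n_reads_used = nrow(reads), n_bases = n_bases, n_mismatches = n_mm
  ), class = "error_rate_result")
}

#' @export
print.error_rate_result <- function(x, ...) {
  cat(sprintf("Error rate %.3g (Q%d) from %d reads / %d aligned bases\n",
              x$error_rate, as.integer(x$phred), x$n_reads_used, x$n_bases))
  invisible(x)
}
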