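# Majority-vote consensus over RCA concatemer subread stacks, backbone
# trimming, coordinate deduplication, and the exact per-column error
# theory used as the oracle for the Monte Carlo tests.

#' Call a consensus read from a concatemer subread stack
#'
#' Per template column, the consensus base is the plurality base over the
#' subreads. Ties are broken by (1) highest summed subread quality,
#' (2) the template-agreeing base if it is among the tied, (3) the
#' lexicographically smallest base. Consensus quality per column is the
#' summed Phred quality of agreeing subreads minus that of disagreeing
#' subreads, floored at 2 and capped at 60. Reads with fewer than
#' `min_repeats` subreads are rejected (consensus of at least 3 repeats
#' is required for error suppression).
#'
#' @param read A `"concatemer_read"` (see [generate_concatemer_reads()]).
#' @param min_repeats Minimum subread count; reads below it return `NULL`.
#' @return A `"consensus_read"` object (fields `template_id`, `seq`,
#'   `qual`, `n_repeats`, `coords`, `timestamp`), or `NULL` on rejection.
#' @export
call_consensus <- function(read, min_repeats = 3L) {
  stopifnot(inherits(read, "concatemer_read"))
  if (read$n_repeats < min_repeats) return(NULL)
  L <- nchar(read$template_seq)
  stop_if(any(nchar(read$subreads) != L),
          "ragged subread lengths: subreads must be column-aligned to the template")
  r <- read$n_repeats
  # r x L integer matrices of bases and qualities
  base_mat <- matrix(unlist(lapply(read$subreads, function(s)
    utf8ToInt(s))), nrow = r, byrow = TRUE)
  qual_mat <- matrix(unlist(read$subread_quals), nrow = r, byrow = TRUE)
  tmpl <- utf8ToInt(read$template_seq)
  codes <- utf8ToInt(paste(BASES, collapse = ""))
  # per-base score: count dominates, then summed quality, then
  # template agreement, then lexicographic rank
  score <- matrix(0, nrow = L, ncol = 4L)
  counts <- matrix(0L, nrow = L, ncol = 4L)
  for (b in 1:4) {
    hit <- base_mat == codes[b]
    cnt <- if (r == 1L) as.integer(hit[1L, ]) else colSums(hit)
    qs <- if (r == 1L) qual_mat[1L, ] * hit[1L, ] else colSums(qual_mat * hit)
    counts[, b] <- cnt
    score[, b] <- cnt * 1e8 + qs * 10 + (tmpl == codes[b]) * 2 + (4 - b) * 0.25
  }
  win <- max.col(score, ties.method = "first")
  seq <- intToUtf8(codes[win], multiple = FALSE)
  tot_q <- if (r == 1L) qual_mat[1L, ] else colSums(qual_mat)
  win_q <- vapply(seq_len(L), function(i) {
    hit <- base_mat[, i] == codes[win[i]]
    sum(qual_mat[hit, i])
  }, 0)
  qual <- pmin(pmax(as.integer(2 * win_q - tot_q), 2L), 60L)
  structure(list(
    template_id = read$template_id, seq = seq, qual = qual,
    n_repeats = r, coords = read$coords, timestamp = read$timestamp
  ), class = "consensus_read")
}

#' Construct a consensus read from explicit fields
#'
#' @param template_id Read identifier.
#' @param seq Consensus base string.
#' @param qual Per-base integer Phred qualities (default flat Q40).
#' @param n_repeats Subread count the consensus was built from.
#' @param chrom,start,end Insert coordinates (0-based half-open).
#' @param timestamp Minutes since run start.
#' @return A `"consensus_read"`.
#' @export
consensus_read <- function(template_id, seq, qual = rep(40L, nchar(seq)),
                           n_repeats = 3L, chrom = "chr1", start = 0L,
                           end = start + nchar(seq), timestamp = 0) {
  stop_if(length(qual) != nchar(seq), "seq and qual lengths differ")
  structure(list(
    template_id = template_id, seq = seq, qual = as.integer(qual),
    n_repeats = as.integer(n_repeats),
    coords = list(chrom = chrom, start = start, end = end),
    timestamp = timestamp
  ), class = "consensus_read")
}

#' @export
print.consensus_read <- function(x, ...) {
  cat(sprintf("Consensus read %s: %d bp, %d repeats, %s:%d-%d, t=%.1f min\n",
              x$template_id, nchar(x$seq), x$n_repeats,
              x$coords$chrom, x$coords$start, x$coords$end, x$timestamp))
  invisible(x)
}

#' Trim residual backbone sequence from a consensus read
#'
#' Removes the maximal 5' prefix matching a suffix of the backbone and
#' the maximal 3' suffix matching a prefix of the backbone, allowing up
#' to 10% mismatches within the matched flank (RCA geometry: a truncated
#' flank adjacent to the insert retains the backbone end facing it).
#' Coordinates are untouched — they refer to the insert.
#'
#' @param consensus A `"consensus_read"`.
#' @param backbone_seq Backbone linker sequence (configurable; the
#'   production linker is proprietary).
#' @param max_mismatch_frac Mismatch tolerance within a flank.
#' @param min_flank Shortest flank considered a backbone remnant, bp.
#' @return The trimmed `"consensus_read"`, or `NULL` if trimming would
#'   empty the read.
#' @export
trim_backbone <- function(consensus, backbone_seq,
                          max_mismatch_frac = 0.10, min_flank = 8L) {
  stopifnot(inherits(consensus, "consensus_read"))
  stop_if(nchar(backbone_seq) == 0, "empty backbone sequence")
  s <- utf8ToInt(consensus$seq)
  bb <- utf8ToInt(backbone_seq)
  L <- length(s); B <- length(bb)
  flank5 <- 0L
  if (min(L, B) >= min_flank) for (k in min(L, B):min_flank) {
    # read prefix vs backbone suffix
    if (sum(s[1:k] != bb[(B - k + 1):B]) <= floor(max_mismatch_frac * k)) {
      flank5 <- k; break
    }
  }
  flank3 <- 0L
  if (min(L - flank5, B) >= min_flank) for (k in min(L - flank5, B):min_flank) {
    if (sum(s[(L - k + 1):L] != bb[1:k]) <= floor(max_mismatch_frac * k)) {
      flank3 <- k; break
    }
  }
  if (flank5 + flank3 >= L) return(NULL)
  keep <- seq.int(flank5 + 1L, L - flank3)
  consensus$seq <- intToUtf8(s[keep], multiple = FALSE)
  consensus$qual <- consensus$qual[keep]
  consensus
}

#' Deduplicate consensus reads by genomic coordinates
#'
#' Reads mapped to the same coordinates within `tol` bp on both ends are
#' merged: clusters are formed by single linkage on the relation
#' "same chrom, |start difference| <= tol and |end difference| <= tol",
#' and each cluster is represented by its member with the most repeats
#' (ties broken by the earlier timestamp). Output is sorted by
#' coordinates. Idempotent for `tol`-separated clusters.
#'
#' @param reads List of `"consensus_read"` objects.
#' @param tol Coordinate tolerance in bp (default 1).
#' @return List of unique `"consensus_read"` objects sorted by
#'   (chrom, start, end).
#' @export
deduplicate <- function(reads, tol = 1L) {
  if (length(reads) == 0) return(reads)
  chrom <- vapply(reads, function(r) r$coords$chrom, "")
  start <- vapply(reads, function(r) as.numeric(r$coords$start), 0)
  end <- vapply(reads, function(r) as.numeric(r$coords$end), 0)
  nrep <- vapply(reads, function(r) as.numeric(r$n_repeats), 0)
  ts <- vapply(reads, function(r) as.numeric(r$timestamp), 0)
  n <- length(reads)
  # union-find over reads linked within tol; links only possible between
  # reads whose starts are within tol, so scan a start-sorted window
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ord <- order(chrom, start, end)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (chrom[j] != chrom[i] || start[j] - start[i] > tol) break
      if (abs(end[j] - end[i]) <= tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  keep <- vapply(split(seq_len(n), roots), function(idx) {
    idx[order(-nrep[idx], ts[idx])][1]
  }, 0L)
  keep <- keep[order(chrom[keep], start[keep], end[keep])]
  unname(reads[keep])
}

#' Exact expected consensus error per column
#'
#' Exhaustive enumeration of the per-column outcome of `r` iid subreads
#' under the uniform-three-alternative substitution model with per-base
#' error `e`: each subread shows the true base with probability `1 - e`
#' and each wrong base with probability `e / 3`. The consensus base is
#' the plurality base; at a count tie involving the true base the true
#' base wins (equal flat qualities make the quality tie-break moot, and
#' the template rule then applies), so the consensus errs exactly when
#' some wrong base strictly outnumbers the true base.
#'
#' @param e Per-base subread error probability in `[0, 1)`.
#' @param r Repeat (subread) count, `>= 1`.
#' @return Expected consensus per-base error probability.
#' @export
consensus_error_theory <- function(e, r) {
  stop_if(e < 0 || e >= 1, "`e` must lie in [0, 1)")
  r <- assert_count(r, "r")
  if (e == 0) return(0)
  p_err <- 0
  for (k0 in 0:r) {
    rem <- r - k0
    # partitions of the `rem` wrong draws over 3 alternative bases
    for (k1 in 0:rem) for (k2 in 0:(rem - k1)) {
      k3 <- rem - k1 - k2
      if (max(k1, k2, k3) > k0) {
        # multinomial probability: r! / (k0! k1! k2! k3!) (1-e)^k0 (e/3)^rem
        p <- exp(lfactorial(r) - lfactorial(k0) - lfactorial(k1) -
                   lfactorial(k2) - lfactorial(k3) +
                   k0 * log1p(-e) + rem * log(e / 3))
        p_err <- p_err + p
      }
    }
  }
  p_err
}
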