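# Shared fixtures and independent oracles, all built in code.

# Panel in which every site has the same VAF (closed-form expectations).
uniform_panel <- function(n_sites, vaf, purity = 1) {
  variant_panel(
    chrom = rep("chr1", n_sites), pos = seq_len(n_sites) * 1000L,
    ref = rep("A", n_sites), alt = rep("G", n_sites),
    vaf = rep(vaf, n_sites), purity = purity
  )
}

# Brute-force single-linkage clustering of consensus reads by
# coordinates within +-tol on both ends: O(n^2) pairwise linking,
# independent of the production implementation.
brute_force_dedup_count <- function(reads, tol = 1) {
  n <- length(reads)
  if (n == 0) return(0L)
  chrom <- vapply(reads, function(r) r$coords$chrom, "")
  start <- vapply(reads, function(r) as.numeric(r$coords$start), 0)
  end <- vapply(reads, function(r) as.numeric(r$coords$end), 0)
  cl <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (chrom[i] == chrom[j] && abs(start[i] - start[j]) <= tol &&
          abs(end[i] - end[j]) <= tol && cl[i] != cl[j]) {
        cl[cl == cl[j]] <- cl[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(cl))
}

# Detrended autocorrelation period estimate of a length histogram:
# remove an 11-bp moving average, then return the lag in `periods`
# maximizing the acf.
histogram_period <- function(counts, periods = 5:15) {
  trend <- stats::filter(counts, rep(1 / 11, 11), sides = 2)
  res <- as.numeric(counts - trend)
  res <- res[!is.na(res)]
  ac <- stats::acf(res, lag.max = max(periods), plot = FALSE)$acf[, 1, 1]
  periods[which.max(ac[periods + 1])]
}

# Random DNA string helper for constructed reads.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
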