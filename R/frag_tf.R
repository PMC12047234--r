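# Fragment-length profiles, fixed-signature NMF decomposition into a
# fragmentomics tumor fraction, and the AFM nm -> bp conversion.

#' Build a normalized fragment-length profile
#'
#' 1-bp histogram of fragment lengths over `[lo, hi]` (30-220 bp is the
#' window used for signature decomposition), out-of-range lengths
#' dropped, normalized to sum to one.
#'
#' @param lengths Integer vector of fragment lengths in bp.
#' @param lo,hi Window bounds in bp (inclusive).
#' @return Named numeric vector of class `"length_profile"` (names are
#'   lengths in bp; values sum to 1).
#' @export
build_length_profile <- function(lengths, lo = 30L, hi = 220L) {
  stop_if(length(lengths) == 0, "`lengths` must be nonempty")
  stop_if(lo >= hi, "`lo` must be below `hi`")
  lengths <- lengths[lengths >= lo & lengths <= hi]
  stop_if(length(lengths) == 0, "no lengths within [lo, hi]")
  counts <- tabulate(lengths - lo + 1L, nbins = hi - lo + 1L)
  structure(stats::setNames(counts / sum(counts), lo:hi),
            class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  rng <- range(as.integer(names(x)))
  cat(sprintf("Length profile over %d-%d bp, mode at %s bp\n",
              rng[1], rng[2], names(x)[which.max(x)]))
  invisible(x)
}

#' Fragment-length signature matrix
#'
#' Validates and wraps a 2 x L nonnegative matrix whose rows are the
#' healthy-dominant (Signature 1) and tumor-indicative (Signature 2)
#' fragment-length signatures; rows are renormalized to sum to one.
#'
#' @param s1,s2 Nonnegative numeric vectors over the same bp support.
#' @param support Integer vector of lengths in bp the signatures cover.
#' @param provenance Free-text provenance label.
#' @return Matrix of class `"signature_matrix"` with rows
#'   `signature_1`, `signature_2` and columns named by bp.
#' @export
signature_matrix <- function(s1, s2, support, provenance = "user") {
  stop_if(length(s1) != length(support) || length(s2) != length(support),
          "signatures and support must have equal length")
  stop_if(any(s1 < 0) || any(s2 < 0), "signatures must be nonnegative")
  stop_if(sum(s1) == 0 || sum(s2) == 0, "signatures must not be all zero")
  m <- rbind(signature_1 = s1 / sum(s1), signature_2 = s2 / sum(s2))
  colnames(m) <- support
  attr(m, "provenance") <- provenance
  class(m) <- c("signature_matrix", class(m))
  m
}

#' Packaged default fragment-length signatures
#'
#' Parametric stand-in signatures on the 30-220 bp window, synthetic by
#' construction: Signature 1 is the healthy fragment-length model
#' density; Signature 2 is the tumor-shifted density with 10-bp
#' periodicity, whose mode sits below Signature 1's. Literature-derived
#' signature values can be supplied instead via
#' [read_signatures_tsv()] and passed to [nmf_tf()].
#'
#' @param model A [fragment_length_model()] used for both signatures.
#' @param lo,hi Support window in bp.
#' @return A `"signature_matrix"`.
#' @export
default_signatures <- function(model = fragment_length_model(),
                               lo = 30L, hi = 220L) {
  grid <- model$min_len:model$max_len
  sel <- grid >= lo & grid <= hi
  s1 <- fragment_length_density(model, tumor = FALSE)[sel]
  s2 <- fragment_length_density(model, tumor = TRUE)[sel]
  signature_matrix(s1, s2, grid[sel], provenance = "synthetic-parametric")
}

#' Fragmentomics tumor fraction by fixed-signature NMF
#'
#' Decomposes a normalized fragment-length profile onto the two fixed
#' signature rows by nonnegative least squares (single-step NMF with a
#' frozen basis) and returns the contribution of the tumor-indicative
#' Signature 2, `w2 / (w1 + w2)`, capped at 1.0.
#'
#' @param profile A [build_length_profile()] profile whose support
#'   matches the signatures'.
#' @param signatures A `"signature_matrix"` (default:
#'   [default_signatures()]).
#' @return Tumor fraction in `[0, 1]`.
#' @export
nmf_tf <- function(profile, signatures = default_signatures()) {
  stop_if(!inherits(signatures, "signature_matrix"),
          "`signatures` must be a signature_matrix")
  p <- as.numeric(profile)
  stop_if(length(p) != ncol(signatures) ||
            !identical(names(profile), colnames(signatures)),
          "profile support does not match the signature support")
  stop_if(sum(p) == 0, "all-zero profile")
  fit <- pracma::lsqnonneg(t(unclass(signatures)), p)
  w <- fit$x
  stop_if(sum(w) == 0, "degenerate decomposition: both weights zero")
  min(w[2] / (w[1] + w[2]), 1.0)
}

#' Convert AFM contour lengths from nm to bp
#'
#' Calibration against a DNA ladder imaged by atomic force microscopy:
#' `L_bp = (L_nm + 10) / 0.341`.
#'
#' @param length_nm Nonnegative contour length(s) in nm.
#' @return Length(s) in bp.
#' @export
afm_nm_to_bp <- function(length_nm) {
  stop_if(any(length_nm < 0), "`length_nm` must be nonnegative")
  (length_nm + 10) / 0.341
}
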