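# Tumor-informed SNV allele counting, real-time MUT-ratio tracking,
# enrichment testing, and the Monte Carlo grid-search tumor-fraction
# estimator.

#' Tally REF / MUT / ERR calls at panel sites
#'
#' @param observations An `"allele_obs"` object.
#' @param panel The [generate_variant_panel()] panel the observations
#'   were drawn against (site indices are validated against it).
#' @return List of class `"allele_counts"`: `n_ref`, `n_mut`, `n_err`,
#'   `n_obs`.
#' @export
count_alleles <- function(observations, panel) {
  stopifnot(inherits(observations, "allele_obs"),
            inherits(panel, "variant_panel"))
  stop_if(nrow(observations) > 0 &&
            (min(observations$site_index) < 1 ||
               max(observations$site_index) > nrow(panel)),
          "observation site_index outside the panel")
  tab <- table(factor(observations$call, levels = c("REF", "MUT", "ERR")))
  structure(list(
    n_ref = as.integer(tab[["REF"]]), n_mut = as.integer(tab[["MUT"]]),
    n_err = as.integer(tab[["ERR"]]),
    n_obs = as.integer(sum(tab))
  ), class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("Allele counts: REF %d, MUT %d, ERR %d (n = %d)\n",
              x$n_ref, x$n_mut, x$n_err, x$n_obs))
  invisible(x)
}

#' Cumulative MUT ratio over sequencing time
#'
#' Real-time tracking of the cumulative `MUT / (MUT + REF)` ratio in
#' bins of `bin_minutes`: at each bin boundary the ratio over all
#' observations seen so far is reported; bins with no new observations
#' carry the previous value forward (0 before any MUT or REF is seen).
#' ERR calls are excluded from both numerator and denominator.
#'
#' @param observations An `"allele_obs"` object with timestamps.
#' @param bin_minutes Bin width in minutes.
#' @param t_max End of the tracked window in minutes; defaults to the
#'   observation set's run duration.
#' @return `data.frame` with `t` (bin end, minutes) and `ratio`.
#' @export
cumulative_mut_ratio <- function(observations, bin_minutes = 10,
                                 t_max = NULL) {
  stopifnot(inherits(observations, "allele_obs"))
  if (is.null(t_max)) t_max <- attr(observations, "run_minutes")
  if (is.null(t_max)) t_max <- max(observations$timestamp, 0)
  edges <- seq(bin_minutes, t_max, by = bin_minutes)
  if (length(edges) == 0 || edges[length(edges)] < t_max)
    edges <- c(edges, t_max)
  keep <- observations$call != "ERR"
  ts <- observations$timestamp[keep]
  is_mut <- observations$call[keep] == "MUT"
  ratio <- vapply(edges, function(tt) {
    seen <- ts <= tt
    n <- sum(seen)
    if (n == 0) NA_real_ else sum(is_mut[seen]) / n
  }, 0)
  # carry forward through empty leading/intermediate bins
  for (i in seq_along(ratio)) {
    if (is.na(ratio[i])) ratio[i] <- if (i == 1) 0 else ratio[i - 1]
  }
  data.frame(t = edges, ratio = ratio)
}

#' One-sided Fisher test for MUT-allele enrichment
#'
#' Tests whether the patient's MUT fraction exceeds the control's on the
#' 2x2 table `[MUT, REF] x [patient, control]` (ERR calls excluded),
#' with the one-sided alternative "patient enriched".
#'
#' @param patient,control `"allele_counts"` objects.
#' @return The one-sided p-value.
#' @export
fisher_mut_enrichment <- function(patient, control) {
  stopifnot(inherits(patient, "allele_counts"),
            inherits(control, "allele_counts"))
  tab <- matrix(c(patient$n_mut, patient$n_ref,
                  control$n_mut, control$n_ref), nrow = 2, byrow = TRUE)
  if (sum(tab) == 0) {
    warning("degenerate (all-zero) table; returning p = 1")
    return(1)
  }
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Probability of observing the MUT allele on a tumor-derived fragment
#'
#' A tumor-derived cfDNA fragment overlapping a panel site carries the
#' MUT allele with probability `purity * vaf`: e.g. purity 0.60 and
#' VAF 0.50 give a 30% probability.
#'
#' @param purity Tumor purity in `(0, 1]`.
#' @param vaf Variant allele frequency (or vector thereof) in `(0, 1]`.
#' @return `purity * vaf`.
#' @export
mut_probability <- function(purity, vaf) {
  assert_fraction(purity, "purity", open_left = TRUE)
  assert_fraction(vaf, "vaf", open_left = TRUE)
  purity * vaf
}

#' Monte Carlo distribution of MUT counts at a fixed tumor fraction
#'
#' Simulates `n_trials` sequencing experiments of `n_obs` observations
#' against the panel. Each observation falls on a uniformly chosen panel
#' site and is MUT with probability `tf * purity * vaf_site +
#' (1 - tf) * error_rate / 3`. Because site choice is uniform and
#' observations are independent, the trial total is distributed
#' `Binomial(n_obs, mean_site(p))` exactly; the default path draws one
#' binomial per trial. `by_site = TRUE` instead samples the per-site
#' observation allocation and per-site binomials literally (slower;
#' used as an independent route in the test suite).
#'
#' @param panel A [generate_variant_panel()] panel.
#' @param n_obs Observations per trial.
#' @param tf Tumor fraction in `[0, 1]`.
#' @param n_trials Number of Monte Carlo trials (default 10000).
#' @param error_rate Per-base sequencing error rate; healthy-origin
#'   observations mimic MUT with probability `error_rate / 3`. 0
#'   recovers the error-free model in which healthy fragments never
#'   show MUT.
#' @param seed Optional integer seed.
#' @param by_site Use the literal per-site sampling path.
#' @return Integer vector of `n_trials` MUT counts.
#' @export
simulate_mut_counts <- function(panel, n_obs, tf, n_trials = 10000L,
                                error_rate = 0, seed = NULL,
                                by_site = FALSE) {
  stopifnot(inherits(panel, "variant_panel"))
  stop_if(n_obs < 0, "`n_obs` must be nonnegative")
  assert_fraction(tf, "tf")
  if (n_obs == 0) return(integer(n_trials))
  p_site <- tf * mut_probability(attr(panel, "purity"), panel$vaf) +
    (1 - tf) * error_rate / 3
  with_seed_(seed, {
    if (by_site) {
      alloc <- stats::rmultinom(n_trials, n_obs,
                                rep(1, nrow(panel)))  # sites x trials
      muts <- matrix(
        stats::rbinom(length(alloc), as.vector(alloc), rep(p_site, n_trials)),
        nrow = nrow(panel)
      )
      as.integer(colSums(muts))
    } else {
      stats::rbinom(n_trials, n_obs, mean(p_site))
    }
  })
}

#' Monte Carlo grid-search tumor-fraction estimate from allele counts
#'
#' Systematically varies the tumor fraction over 100 linear grid values
#' in `[0, 1]`; at each grid value, [simulate_mut_counts()] produces
#' `n_trials` simulated MUT counts, and the grid value's alignment
#' weight is the fraction of its trials whose count matches the observed
#' MUT count (if no grid value matches exactly, the match window is
#' widened to the smallest `+-k` counts giving nonzero mass). Weights
#' are normalized over the grid; the point estimate is the
#' highest-weight grid value and the 95% confidence interval is the
#' 2.5% / 97.5% quantile pair of the normalized weight distribution over
#' the grid. If the point estimate falls below 0.05, the procedure is
#' repeated on a fine grid of 0 plus 99 log-spaced values up to 0.10.
#'
#' @param counts An `"allele_counts"` object (observed data).
#' @param panel The matching [generate_variant_panel()] panel.
#' @param n_trials Trials per grid value (default 10000).
#' @param error_rate Sequencing error rate passed to the simulator.
#' @param seed Optional integer seed.
#' @return List of class `"tf_estimate"`: `tf_point`, `ci_low`,
#'   `ci_high`, `grid`, `grid_weights`, `n_trials`, `refined`,
#'   `match_halfwidth`.
#' @export
estimate_tf_snv <- function(counts, panel, n_trials = 10000L,
                            error_rate = 0, seed = NULL) {
  stopifnot(inherits(counts, "allele_counts"),
            inherits(panel, "variant_panel"))
  stop_if(counts$n_obs < 1, "no observations to estimate from")
  grid <- seq(0, 1, length.out = 100)
  est <- with_seed_(seed, {
    e <- tf_grid_search(grid, counts, panel, n_trials, error_rate)
    if (e$tf_point < 0.05) {
      fine <- c(0, 10^seq(log10(1e-4), log10(0.10), length.out = 99))
      e <- tf_grid_search(fine, counts, panel, n_trials, error_rate)
      e$refined <- TRUE
    }
    e
  })
  structure(est, class = "tf_estimate")
}

#' @noRd
tf_grid_search <- function(grid, counts, panel, n_trials, error_rate) {
  sim <- lapply(grid, function(tf)
    simulate_mut_counts(panel, counts$n_obs, tf, n_trials, error_rate))
  k <- 0L
  repeat {
    hits <- vapply(sim, function(x)
      sum(abs(x - counts$n_mut) <= k), 0) / n_trials
    if (sum(hits) > 0) break
    k <- k + 1L
  }
  w <- hits / sum(hits)
  tf_point <- grid[which.max(w)]
  cw <- cumsum(w)
  ci_low <- grid[which(cw >= 0.025)[1]]
  ci_high <- grid[which(cw >= 0.975)[1]]
  list(tf_point = tf_point,
       ci_low = min(ci_low, tf_point), ci_high = max(ci_high, tf_point),
       grid = grid, grid_weights = w, n_trials = n_trials,
       refined = FALSE, match_halfwidth = k)
}

#' @export
print.tf_estimate <- function(x, ...) {
  cat(sprintf("SNV tumor fraction: %.4f (95%% CI %.4f-%.4f)%s\n",
              x$tf_point, x$ci_low, x$ci_high,
              if (x$refined) " [log-refined grid]" else ""))
  invisible(x)
}
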