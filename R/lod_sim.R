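# In-silico limit-of-detection experiment across sequencing platform
# presets, and admixture arithmetic.

#' Expected tumor fraction of a dilution admixture
#'
#' Mixing a `fraction` of a source sample of tumor fraction `source_tf`
#' into a TF-zero healthy background gives expected TF
#' `fraction * source_tf` (e.g. a 10% admixture of a TF-0.71 source has
#' expected TF 0.071).
#'
#' @param fraction Admixture fraction in `[0, 1]`.
#' @param source_tf Tumor fraction of the source sample in `[0, 1]`.
#' @return Expected tumor fraction of the mixture.
#' @export
expected_admixture_tf <- function(fraction, source_tf) {
  assert_fraction(fraction, "fraction")
  assert_fraction(source_tf, "source_tf")
  fraction * source_tf
}

#' Sequencing platform presets for the LoD experiment
#'
#' The four platform/chemistry combinations compared in silico: native
#' nanopore reads on MinION (0.25x, error 0.00674) and PromethION (3x,
#' error 0.00674), and consensus-called RCA reads on MinION (0.04x,
#' error 0.00072) and PromethION (0.8x, error 0.00072).
#'
#' @param name One of `"raw-minion"`, `"raw-promethion"`,
#'   `"nanorcs-minion"`, `"nanorcs-promethion"`.
#' @param coverage,error_rate Optional overrides of the preset values.
#' @return List of class `"platform_preset"`: `name`, `coverage`,
#'   `error_rate`.
#' @export
platform_preset <- function(name = c("raw-minion", "raw-promethion",
                                     "nanorcs-minion",
                                     "nanorcs-promethion"),
                            coverage = NULL, error_rate = NULL) {
  name <- match.arg(name)
  defaults <- list(
    "raw-minion" = c(0.25, 0.00674),
    "raw-promethion" = c(3, 0.00674),
    "nanorcs-minion" = c(0.04, 0.00072),
    "nanorcs-promethion" = c(0.8, 0.00072)
  )[[name]]
  cov <- if (is.null(coverage)) defaults[1] else coverage
  err <- if (is.null(error_rate)) defaults[2] else error_rate
  stop_if(cov <= 0, "`coverage` must be positive")
  structure(list(name = name, coverage = cov, error_rate = err),
            class = "platform_preset")
}

#' Detection threshold from a null MUT-count distribution
#'
#' Smallest integer threshold `t` such that the empirical false positive
#' rate of the null distribution, `P(count >= t)`, does not exceed
#' `1 - tnr_min` — i.e. calling "detected" at `count >= t` keeps the
#' true negative rate at or above `tnr_min`.
#'
#' @param null_counts Integer vector of MUT counts simulated at TF = 0
#'   (at least 1000 trials recommended).
#' @param tnr_min Required true negative rate (default 0.68).
#' @return Integer threshold; observations with `count >= t` count as
#'   detections.
#' @export
detection_threshold <- function(null_counts, tnr_min = 0.68) {
  assert_fraction(tnr_min, "tnr_min")
  for (t in 0:(max(null_counts) + 1L)) {
    if (mean(null_counts >= t) <= 1 - tnr_min) return(t)
  }
}

#' Default TF grid of the LoD experiment
#'
#' TF 0 plus 50 log-spaced values between 0.001 and 1.
#' @return Numeric vector of 51 tumor fractions.
#' @export
lod_tf_grid <- function() {
  c(0, 10^seq(log10(0.001), 0, length.out = 50))
}

#' In-silico limit-of-detection experiment for one panel and platform
#'
#' For each tumor fraction on the grid, simulates `n_trials` sequencing
#' runs: per trial the observation count is Poisson with mean
#' `coverage * n_sites`, and the MUT count is drawn from the panel's
#' per-observation MUT probability at that TF and the preset's error
#' rate (via the same probability model as [simulate_mut_counts()]).
#' The TF = 0 row gives the null ("background noise") distribution; the
#' detection threshold holds the true negative rate at `tnr_min`, and
#' the lowest detectable TF is the smallest grid TF whose true positive
#' rate exceeds `tpr_min`.
#'
#' @param panel A [generate_variant_panel()] panel.
#' @param preset A [platform_preset()].
#' @param tf_grid Tumor-fraction grid (must contain 0); default
#'   [lod_tf_grid()].
#' @param n_trials Trials per grid TF (default 10000).
#' @param tpr_min Required true positive rate (default 0.95).
#' @param tnr_min Required true negative rate (default 0.68).
#' @param seed Optional integer seed.
#' @return List of class `"lod_result"`: `tf_grid`, `tpr`, `tnr`,
#'   `threshold`, `lowest_detectable_tf` (`NA` if no grid TF qualifies),
#'   `n_trials`, `preset`.
#' @export
run_lod <- function(panel, preset, tf_grid = lod_tf_grid(),
                    n_trials = 10000L, tpr_min = 0.95, tnr_min = 0.68,
                    seed = NULL) {
  stopifnot(inherits(panel, "variant_panel"),
            inherits(preset, "platform_preset"))
  stop_if(nrow(panel) == 0, "empty panel")
  stop_if(!any(tf_grid == 0), "`tf_grid` must contain the null TF 0")
  tf_grid <- sort(tf_grid)
  p_mut <- mut_probability(attr(panel, "purity"), panel$vaf)
  mean_obs <- preset$coverage * nrow(panel)
  with_seed_(seed, {
    counts <- lapply(tf_grid, function(tf) {
      pbar <- mean(tf * p_mut + (1 - tf) * preset$error_rate / 3)
      n_obs <- stats::rpois(n_trials, mean_obs)
      stats::rbinom(n_trials, n_obs, pbar)
    })
    null_counts <- counts[[which(tf_grid == 0)]]
    thr <- detection_threshold(null_counts, tnr_min)
    tpr <- vapply(counts, function(x) mean(x >= thr), 0)
    tnr <- mean(null_counts < thr)
    ok <- tf_grid > 0 & tpr > tpr_min
    structure(list(
      tf_grid = tf_grid, tpr = tpr, tnr = tnr, threshold = thr,
      lowest_detectable_tf = if (any(ok)) min(tf_grid[ok]) else NA_real_,
      n_trials = n_trials, preset = preset
    ), class = "lod_result")
  })
}

#' @export
print.lod_result <- function(x, ...) {
  lod <- if (is.na(x$lowest_detectable_tf)) "not detectable"
         else sprintf("%.4g", x$lowest_detectable_tf)
  cat(sprintf(
    "LoD [%s, %.2fx, e=%.2g]: lowest detectable TF %s (TNR %.3f, threshold %d)\n",
    x$preset$name, x$preset$coverage, x$preset$error_rate, lod,
    x$tnr, x$threshold))
  invisible(x)
}

#' Bookkeeping size of a full LoD experiment
#'
#' Total number of simulated datasets: `n_trials * n_tfs *
#' n_techniques` (e.g. 10000 x 51 x 4 = 2,040,000 per patient).
#'
#' @param n_trials,n_tfs,n_techniques Positive integers.
#' @return Their product.
#' @export
lod_experiment_size <- function(n_trials, n_tfs, n_techniques) {
  n_trials <- assert_count(n_trials, "n_trials")
  n_tfs <- assert_count(n_tfs, "n_tfs")
  n_techniques <- assert_count(n_techniques, "n_techniques")
  as.numeric(n_trials) * n_tfs * n_techniques
}
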