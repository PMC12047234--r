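# Seeded generators for every synthetic input the toolkit consumes:
# cfDNA fragment lengths, tumor-informed variant panels, concatemer
# subread stacks, per-site allele observations, and admixtures.

#' Fragment-length model for cell-free DNA
#'
#' Parametric model of the cfDNA fragment-length distribution: a
#' two-component (mono- and di-nucleosomal) truncated double-exponential
#' (Laplace) mixture for healthy cfDNA, plus a tumor variant in which
#' both modes are shortened by `tumor_shift` base pairs and the
#' sub-170 bp density is modulated with a 10-bp periodicity of amplitude
#' `periodicity_amp`.
#'
#' Healthy plasma cfDNA peaks sharply near 167 bp (mono-nucleosomal)
#' with a secondary di-nucleosomal peak near 332 bp; tumor-derived
#' fragments are typically 4-5 bp shorter and show a 10-bp oscillation
#' below the mono-nucleosomal peak. Laplace components reproduce the
#' cusp-like modal peaks of real profiles (a Gaussian's flat top leaves
#' the histogram mode unresolved at realistic sample sizes).
#'
#' @param mono_mode Mono-nucleosomal mode in bp (default 167).
#' @param di_mode Di-nucleosomal mode in bp (default 332).
#' @param mono_sd,di_sd Dispersion (Laplace scale) of the two components
#'   in bp.
#' @param di_weight Mixture weight of the di-nucleosomal component.
#' @param tumor_shift Shortening of both modes for tumor fragments, bp.
#' @param periodicity_amp Amplitude in `[0, 1]` of the 10-bp cosine
#'   modulation applied to the tumor density below 170 bp (healthy
#'   fragments are never modulated).
#' @param min_len,max_len Truncation range in bp.
#' @return An object of class `"frag_model"`.
#' @examples
#' m <- fragment_length_model()
#' lens <- generate_fragment_lengths(1000, m, tumor_fraction = 0, seed = 1)
#' @export
fragment_length_model <- function(mono_mode = 167, di_mode = 332,
                                  mono_sd = 10, di_sd = 15,
                                  di_weight = 0.15, tumor_shift = 4.5,
                                  periodicity_amp = 0.5,
                                  min_len = 30, max_len = 700) {
  assert_fraction(di_weight, "di_weight")
  assert_fraction(periodicity_amp, "periodicity_amp")
  stop_if(mono_sd <= 0 || di_sd <= 0, "component sds must be positive")
  stop_if(min_len >= max_len, "`min_len` must be below `max_len`")
  stop_if(mono_mode < min_len || mono_mode > max_len ||
            di_mode < min_len || di_mode > max_len,
          "modes must lie within [min_len, max_len]")
  structure(
    list(mono_mode = mono_mode, di_mode = di_mode, mono_sd = mono_sd,
         di_sd = di_sd, di_weight = di_weight, tumor_shift = tumor_shift,
         periodicity_amp = periodicity_amp,
         min_len = as.integer(min_len), max_len = as.integer(max_len)),
    class = "frag_model"
  )
}

#' Discrete fragment-length density of a model
#'
#' Evaluates the model's probability mass over the integer grid
#' `min_len:max_len`, normalized to sum to one. The tumor variant shifts
#' both modes down by `tumor_shift` and multiplies the density below
#' 170 bp by `1 + amp * cos(2 * pi * (len - shifted_mode) / 10)` —
#' a 10-bp oscillation phase-anchored at the shortened mono-nucleosomal
#' mode — before renormalizing.
#'
#' @param model A [fragment_length_model()].
#' @param tumor Logical; evaluate the tumor-shifted, periodic variant.
#' @return Numeric vector of probabilities named by length in bp.
#' @export
fragment_length_density <- function(model, tumor = FALSE) {
  stopifnot(inherits(model, "frag_model"))
  grid <- model$min_len:model$max_len
  shift <- if (tumor) model$tumor_shift else 0
  dlap <- function(x, m, b) exp(-abs(x - m) / b) / (2 * b)
  d <- (1 - model$di_weight) *
    dlap(grid, model$mono_mode - shift, model$mono_sd) +
    model$di_weight * dlap(grid, model$di_mode - shift, model$di_sd)
  if (tumor && model$periodicity_amp > 0) {
    mod <- 1 + model$periodicity_amp *
      cos(2 * pi * (grid - (model$mono_mode - shift)) / 10)
    d <- d * ifelse(grid < 170, pmax(mod, 0), 1)
  }
  stats::setNames(d / sum(d), grid)
}

#' Generate cfDNA fragment lengths from a healthy/tumor mixture
#'
#' Each fragment is tumor-derived with probability `tumor_fraction` and
#' drawn from the tumor-shifted, periodicity-modulated density; otherwise
#' it is drawn from the healthy density.
#'
#' @param n Number of fragments.
#' @param model A [fragment_length_model()].
#' @param tumor_fraction Probability in `[0, 1]` that a fragment is
#'   tumor-derived.
#' @param seed Optional integer seed; fixed seeds give bit-identical
#'   output.
#' @return Integer vector of `n` lengths in `[min_len, max_len]`.
#' @export
generate_fragment_lengths <- function(n, model = fragment_length_model(),
                                      tumor_fraction = 0, seed = NULL) {
  n <- assert_count(n, "n")
  assert_fraction(tumor_fraction, "tumor_fraction")
  grid <- model$min_len:model$max_len
  d_h <- fragment_length_density(model, tumor = FALSE)
  d_t <- fragment_length_density(model, tumor = TRUE)
  with_seed_(seed, {
    is_tumor <- stats::runif(n) < tumor_fraction
    out <- integer(n)
    if (any(!is_tumor))
      out[!is_tumor] <- sample(grid, sum(!is_tumor), TRUE, prob = d_h)
    if (any(is_tumor))
      out[is_tumor] <- sample(grid, sum(is_tumor), TRUE, prob = d_t)
    out
  })
}

#' Generate a tumor-informed somatic SNV panel
#'
#' Draws a panel of somatic single-nucleotide variant sites with variant
#' allele frequencies (VAF) from a normal distribution truncated to
#' `(0, 1]`, unique genomic positions, and a single tumor purity. Panels
#' of 10 to a few hundred sites are typical of tumor-informed cfDNA
#' assays.
#'
#' @param n_sites Number of SNV sites.
#' @param vaf_mean,vaf_sd Mean and sd of the truncated-normal VAF draw.
#' @param purity Tumor purity of the biopsy the VAFs were measured in,
#'   in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `"variant_panel"` with columns
#'   `chrom`, `pos` (0-based), `ref`, `alt`, `vaf`, and attribute
#'   `purity`.
#' @export
generate_variant_panel <- function(n_sites, vaf_mean = 0.5, vaf_sd = 0.2,
                                   purity = 1, seed = NULL) {
  n_sites <- assert_count(n_sites, "n_sites")
  assert_fraction(purity, "purity", open_left = TRUE)
  with_seed_(seed, {
    chrom <- sample(paste0("chr", 1:22), n_sites, replace = TRUE)
    # rejection-free uniqueness: positions drawn without replacement per chrom
    pos <- integer(n_sites)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- sample.int(200000000L, length(idx))
    }
    ref <- sample(BASES, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
    vaf <- numeric(0)
    while (length(vaf) < n_sites) {
      cand <- stats::rnorm(2L * (n_sites - length(vaf)), vaf_mean, vaf_sd)
      vaf <- c(vaf, cand[cand > 0 & cand <= 1])
    }
    vaf <- vaf[seq_len(n_sites)]
    panel <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        vaf = vaf, row.names = NULL)
    new_variant_panel(panel, purity)
  })
}

#' Construct a variant panel from explicit site data
#'
#' For user-supplied panels (e.g. fixed-VAF benchmark panels); validates
#' the same invariants as [generate_variant_panel()].
#'
#' @param chrom,pos,ref,alt,vaf Per-site vectors (`pos` 0-based).
#' @param purity Tumor purity in `(0, 1]`.
#' @return A `"variant_panel"`.
#' @export
variant_panel <- function(chrom, pos, ref, alt, vaf, purity = 1) {
  assert_fraction(purity, "purity", open_left = TRUE)
  new_variant_panel(
    data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               vaf = vaf, row.names = NULL),
    purity
  )
}

#' Construct allele observations from explicit records
#'
#' @param site_index 1-based panel site index per record.
#' @param call Character vector of `"REF"` / `"MUT"` / `"ERR"` calls.
#' @param timestamp Minutes since run start per record.
#' @param panel The `"variant_panel"` the records refer to.
#' @param run_minutes Run duration in minutes.
#' @return An `"allele_obs"` object.
#' @export
allele_observations <- function(site_index, call, timestamp, panel,
                                run_minutes = 4320) {
  stopifnot(inherits(panel, "variant_panel"))
  stop_if(length(site_index) > 0 &&
            (min(site_index) < 1 || max(site_index) > nrow(panel)),
          "site_index outside the panel")
  df <- data.frame(site_index = as.integer(site_index), call = call,
                   timestamp = timestamp, row.names = NULL)
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  new_allele_obs(df, panel, run_minutes)
}

#' Construct a concatemer read from explicit subreads
#'
#' @param template_id Read identifier.
#' @param template_seq Template base string.
#' @param subreads Character vector of subread sequences, each the same
#'   length as the template.
#' @param chrom,start,end Template coordinates (0-based half-open).
#' @param subread_quals Optional list of per-base integer quality
#'   vectors (default flat Q20).
#' @param backbone_len Backbone linker length in bp.
#' @param timestamp Minutes since run start.
#' @return A `"concatemer_read"`.
#' @export
concatemer_read <- function(template_id, template_seq, subreads,
                            chrom = "chr1", start = 0L,
                            end = start + nchar(template_seq),
                            subread_quals = NULL, backbone_len = 120L,
                            timestamp = 0) {
  stop_if(nchar(template_seq) == 0, "empty template sequence")
  if (is.null(subread_quals))
    subread_quals <- lapply(nchar(subreads), function(L) rep(20L, L))
  structure(list(
    template_id = template_id, template_seq = template_seq,
    coords = list(chrom = chrom, start = start, end = end),
    n_repeats = length(subreads), subreads = subreads,
    subread_quals = subread_quals, backbone_len = backbone_len,
    timestamp = timestamp
  ), class = "concatemer_read")
}

#' @noRd
new_variant_panel <- function(df, purity) {
  stop_if(anyNA(df$vaf) || any(df$vaf <= 0 | df$vaf > 1),
          "VAFs must lie in (0, 1]")
  stop_if(any(df$ref == df$alt), "ref and alt alleles must differ")
  stop_if(anyDuplicated(df[c("chrom", "pos")]) > 0,
          "panel positions must be unique per chromosome")
  attr(df, "purity") <- purity
  class(df) <- c("variant_panel", "data.frame")
  df
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("Tumor-informed SNV panel: %d sites, purity %.2f, mean VAF %.3f\n",
              nrow(x), attr(x, "purity"), mean(x$vaf)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @noRd
panel_fingerprint <- function(panel) {
  c(nrow(panel), sum(as.numeric(panel$pos)) %% 2147483647)
}

#' Generate template cfDNA fragments with coordinates
#'
#' Convenience generator of template fragments for the concatemer
#' simulator: random sequence, lengths from the fragment-length model,
#' random (synthetic) genomic coordinates.
#'
#' @inheritParams generate_fragment_lengths
#' @return A `data.frame` with `template_id`, `seq`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @export
generate_templates <- function(n, model = fragment_length_model(),
                               tumor_fraction = 0, seed = NULL) {
  n <- assert_count(n, "n")
  with_seed_(seed, {
    len <- generate_fragment_lengths(n, model, tumor_fraction)
    chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
    start <- sample.int(200000000L, n, replace = TRUE)
    data.frame(
      template_id = sprintf("tmpl%06d", seq_len(n)),
      seq = vapply(len, random_dna, ""),
      chrom = chrom, start = start, end = start + len,
      row.names = NULL
    )
  })
}

#' Generate RCA concatemer reads from template fragments
#'
#' Each template yields one concatemer: `n_repeats` subread copies of the
#' template, each carrying iid substitution errors at `error_rate` per
#' base (the erroneous base is uniform over the three alternatives).
#' Repeat counts are drawn from `repeat_dist`; the default,
#' `1 + Poisson(5)`, has median 6 and minimum 1, matching typical RCA
#' concatemer depth. Subreads carry flat per-base Phred qualities of
#' `floor(-10 * log10(error_rate))` (40 when `error_rate = 0`).
#'
#' @param templates A `data.frame` as returned by [generate_templates()].
#' @param repeat_dist Function `n -> integer vector` of repeat counts
#'   (all `>= 1`), or `NULL` for the default.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param backbone_len Length in bp of the backbone linker recorded on
#'   each read (the linker itself sits between subreads and is not part
#'   of the template-aligned stack).
#' @param run_minutes Sequencing run length; timestamps are uniform over
#'   `[0, run_minutes]`. Default 4320 (a 72-h nanopore run).
#' @param seed Optional integer seed.
#' @return A list of `"concatemer_read"` objects with fields
#'   `template_id`, `template_seq`, `coords`, `n_repeats`, `subreads`,
#'   `subread_quals`, `backbone_len`, `timestamp`.
#' @export
generate_concatemer_reads <- function(templates, repeat_dist = NULL,
                                      error_rate = 0.00674,
                                      backbone_len = 120,
                                      run_minutes = 4320, seed = NULL) {
  stop_if(!is.data.frame(templates) || nrow(templates) == 0,
          "`templates` must be a nonempty data.frame")
  stop_if(any(nchar(templates$seq) == 0), "empty template sequence")
  stop_if(error_rate < 0 || error_rate >= 1,
          "`error_rate` must lie in [0, 1)")
  if (is.null(repeat_dist)) repeat_dist <- function(n) 1L + stats::rpois(n, 5)
  qual <- if (error_rate > 0) as.integer(floor(-10 * log10(error_rate))) else 40L
  with_seed_(seed, {
    n <- nrow(templates)
    reps <- as.integer(repeat_dist(n))
    stop_if(any(reps < 1), "repeat_dist produced counts below 1")
    ts <- stats::runif(n, 0, run_minutes)
    lapply(seq_len(n), function(i) {
      tmpl <- templates$seq[i]
      L <- nchar(tmpl)
      subreads <- vapply(seq_len(reps[i]), function(j)
        mutate_seq(tmpl, error_rate), "")
      structure(list(
        template_id = templates$template_id[i],
        template_seq = tmpl,
        coords = list(chrom = templates$chrom[i],
                      start = templates$start[i], end = templates$end[i]),
        n_repeats = reps[i],
        subreads = subreads,
        subread_quals = replicate(reps[i], rep(qual, L), simplify = FALSE),
        backbone_len = backbone_len,
        timestamp = ts[i]
      ), class = "concatemer_read")
    })
  })
}

# Substitute each base independently with probability `e`; the wrong base
# is uniform over the 3 alternatives.
#' @noRd
mutate_seq <- function(seq, e) {
  if (e <= 0) return(seq)
  L <- nchar(seq)
  k <- stats::rbinom(1L, L, e)
  if (k == 0L) return(seq)
  pos <- sample.int(L, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(BASES, b), 1L), "")
  paste(chars, collapse = "")
}

#' Generate per-site allele observations at panel sites
#'
#' Simulates the cfDNA reads overlapping each tumor-informed SNV site.
#' Per site the read count is Poisson with mean `coverage`. Each read is
#' tumor-derived with probability `tf`; tumor reads carry the MUT allele
#' with probability `purity * vaf` (else REF). Healthy reads carry REF,
#' except for sequencing error at rate `error_rate`: the erroneous base
#' is uniform over the three alternatives, so a healthy read mimics MUT
#' with probability `error_rate / 3` and yields an ERR (non-REF, non-MUT)
#' call with probability `2 * error_rate / 3`. Timestamps are uniform
#' over the run.
#'
#' @param panel A [generate_variant_panel()] panel.
#' @param tf True tumor fraction in `[0, 1]`.
#' @param coverage Mean reads per site.
#' @param error_rate Per-base substitution error rate.
#' @param run_minutes Run duration in minutes (default 72 h).
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `"allele_obs"` with columns
#'   `site_index`, `call` (`"REF"`, `"MUT"`, `"ERR"`), `timestamp`
#'   (minutes), sorted by timestamp.
#' @export
generate_allele_observations <- function(panel, tf, coverage,
                                         error_rate = 0,
                                         run_minutes = 4320, seed = NULL) {
  stopifnot(inherits(panel, "variant_panel"))
  assert_fraction(tf, "tf")
  stop_if(coverage < 0, "`coverage` must be nonnegative")
  assert_fraction(error_rate, "error_rate", open_right = TRUE)
  purity <- attr(panel, "purity")
  with_seed_(seed, {
    n_per_site <- stats::rpois(nrow(panel), coverage)
    site_index <- rep(seq_len(nrow(panel)), n_per_site)
    N <- length(site_index)
    call <- rep("REF", N)
    if (N > 0) {
      p_mut <- purity * panel$vaf[site_index]
      is_tumor <- stats::runif(N) < tf
      u <- stats::runif(N)
      # tumor-origin reads: MUT w.p. purity*vaf, else REF
      call[is_tumor & u < p_mut] <- "MUT"
      # healthy-origin reads: sequencing error only
      err <- !is_tumor & u < error_rate
      mimics <- err & u < error_rate / 3
      call[mimics] <- "MUT"
      call[err & !mimics] <- "ERR"
    }
    ts <- stats::runif(N, 0, run_minutes)
    ord <- order(ts)
    new_allele_obs(
      data.frame(site_index = site_index[ord], call = call[ord],
                 timestamp = ts[ord], row.names = NULL),
      panel, run_minutes
    )
  })
}

#' @noRd
new_allele_obs <- function(df, panel, run_minutes) {
  stop_if(!all(df$call %in% c("REF", "MUT", "ERR")),
          "calls must be REF, MUT or ERR")
  attr(df, "panel_fingerprint") <- panel_fingerprint(panel)
  attr(df, "run_minutes") <- run_minutes
  class(df) <- c("allele_obs", "data.frame")
  df
}

#' @export
print.allele_obs <- function(x, ...) {
  tab <- table(factor(x$call, levels = c("REF", "MUT", "ERR")))
  cat(sprintf("Allele observations: %d records (REF %d, MUT %d, ERR %d)\n",
              nrow(x), tab[["REF"]], tab[["MUT"]], tab[["ERR"]]))
  invisible(x)
}

#' Mix tumor and healthy allele observations
#'
#' Emulates a laboratory cfDNA admixture: each record of the tumor set is
#' retained with probability `fraction`, each record of the healthy set
#' with probability `1 - fraction`, so total size is preserved in
#' expectation and the effective tumor fraction of the mixture is
#' `fraction` times the tumor set's. Both sets must have been generated
#' against the same panel.
#'
#' @param obs_tumor,obs_healthy `"allele_obs"` objects drawn against the
#'   same [generate_variant_panel()] panel.
#' @param fraction Retention probability for tumor records, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An `"allele_obs"` object.
#' @export
make_admixture <- function(obs_tumor, obs_healthy, fraction, seed = NULL) {
  stopifnot(inherits(obs_tumor, "allele_obs"),
            inherits(obs_healthy, "allele_obs"))
  assert_fraction(fraction, "fraction")
  stop_if(!identical(attr(obs_tumor, "panel_fingerprint"),
                     attr(obs_healthy, "panel_fingerprint")),
          "observation sets were drawn against different panels")
  with_seed_(seed, {
    keep_t <- stats::runif(nrow(obs_tumor)) < fraction
    keep_h <- stats::runif(nrow(obs_healthy)) < 1 - fraction
    df <- rbind(as.data.frame(obs_tumor)[keep_t, , drop = FALSE],
                as.data.frame(obs_healthy)[keep_h, , drop = FALSE])
    df <- df[order(df$timestamp), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "panel_fingerprint") <- attr(obs_tumor, "panel_fingerprint")
    attr(df, "run_minutes") <- attr(obs_tumor, "run_minutes")
    class(df) <- c("allele_obs", "data.frame")
    df
  })
}

#' Generate reference-aligned reads for error-rate measurement
#'
#' Draws reads uniformly from a reference genome (named character vector
#' of chromosome sequences) and injects iid substitution errors, giving a
#' ground-truth dataset for [compute_error_rate()].
#'
#' @param reference Named character vector of chromosome sequences.
#' @param n_reads Number of reads.
#' @param read_len Read length in bp (must fit in every chromosome).
#' @param error_rate Per-base substitution probability.
#' @param mapq Mapping quality assigned to every read.
#' @param seed Optional integer seed.
#' @return A `data.frame` with `chrom`, `start` (0-based), `end`, `mapq`,
#'   `seq`, `n_ins` (always 0 for this generator).
#' @export
generate_aligned_reads <- function(reference, n_reads, read_len,
                                   error_rate = 0, mapq = 60L,
                                   seed = NULL) {
  n_reads <- assert_count(n_reads, "n_reads")
  stop_if(is.null(names(reference)), "`reference` must be named by chrom")
  stop_if(any(nchar(reference) < read_len),
          "`read_len` exceeds a reference sequence length")
  with_seed_(seed, {
    chrom <- sample(names(reference), n_reads, replace = TRUE,
                    prob = nchar(reference))
    start <- vapply(chrom, function(ch)
      sample.int(nchar(reference[[ch]]) - read_len + 1L, 1L) - 1L, 0L)
    seq <- vapply(seq_len(n_reads), function(i) {
      s <- substr(reference[[chrom[i]]], start[i] + 1L, start[i] + read_len)
      mutate_seq(s, error_rate)
    }, "")
    data.frame(chrom = chrom, start = start, end = start + read_len,
               mapq = as.integer(mapq), seq = seq, n_ins = 0L,
               row.names = NULL)
  })
}
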