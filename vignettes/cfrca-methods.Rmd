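---
title: "Models and design choices in cfrca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in cfrca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrca)
```

`cfrca` models the computational pipeline of rolling-circle-amplified
(RCA) nanopore cell-free DNA (cfDNA) sequencing: consensus calling over
concatemer subread stacks, sequencing-error measurement, and
tumor-fraction (TF) estimation from two orthogonal signals — somatic
SNV allele counts and fragment-length profiles — plus an in-silico
limit-of-detection (LoD) experiment. Everything runs on synthetic data
from seeded generators, so every number in the test suite is
reproducible and every estimator can be checked against the ground
truth that generated its input. This vignette explains the underlying
models, the tunable parameters, and the design decisions taken where
the problem left the design open.

## The synthetic cfDNA model

### Fragment lengths

Healthy plasma cfDNA shows a sharp mono-nucleosomal peak near 167 bp
and a smaller di-nucleosomal peak near 332 bp. `fragment_length_model()`
represents this as a two-component **double-exponential (Laplace)
mixture** on the integer grid 30–700 bp: modes 167 and 332 bp, scales
10 and 15 bp, weights 0.85/0.15. We chose Laplace rather than Gaussian
components deliberately: real cfDNA length profiles have cusp-like
peaks, and a Gaussian's flat top leaves the 1-bp histogram argmax
rattling over several base pairs even at 10⁵ fragments, whereas the
Laplace cusp pins the empirical mode to the model mode. The
di-nucleosomal scale (15 bp) keeps the secondary mode resolvable at
±2 bp from 10⁵ draws, which is the sample size the package's own
checks use.

Tumor-derived fragments are shortened by `tumor_shift` (default
4.5 bp) on both modes, and the density below 170 bp is multiplied by
`1 + amp · cos(2π (ℓ − m)/10)` with `m` the shortened mono-nucleosomal
mode — a 10-bp periodicity of amplitude `periodicity_amp` (default
0.5). The cosine is phase-anchored at the shifted mode rather than at
ℓ = 0: an unanchored phase places the nearest modulation crest at a
multiple of 10 bp and drags the histogram mode there (160 bp),
decoupling the mode from `tumor_shift`; anchoring preserves both the
intended mode (163 bp) and the lag-10 autocorrelation signature. The
periodicity is detectable as the maximal autocorrelation lag of the
detrended 30–170 bp histogram.

`generate_fragment_lengths(n, model, tumor_fraction)` draws each
fragment from the tumor density with probability `tumor_fraction`,
else from the healthy density.

### Variant panels and allele observations

A tumor-informed panel (`generate_variant_panel()`) carries sites with
variant allele frequencies (VAF) drawn from a normal distribution
truncated to (0, 1] (defaults: mean 0.5, sd 0.2) and a single biopsy
purity. Panels of 10–600 sites reflect the realistic range of
tumor-informed assays.

`generate_allele_observations()` simulates the cfDNA reads overlapping
panel sites. Per site the read count is Poisson(`coverage`) — the
standard shallow-WGS assumption. Each read is tumor-derived with
probability `tf`. A tumor read shows the MUT allele with probability
`P = purity × VAF` (`mut_probability()`), else REF. A healthy read
shows REF except for sequencing error at per-base rate `e`: the wrong
base is uniform over the three alternatives, so a healthy read mimics
the site's MUT allele with probability `e/3` and produces an ERR
(non-REF, non-MUT) call with probability `2e/3`. Setting `e = 0`
recovers the idealized model in which healthy fragments never show
MUT. Timestamps are uniform over a 72-h run (4320 min), matching a
standard long nanopore run.

The expected MUT fraction is therefore
`tf · purity · mean(VAF) + (1 − tf) · e/3`, which the test suite
verifies at n = 10⁵ within three binomial standard deviations.

### Concatemers

`generate_concatemer_reads()` copies each template into `n_repeats`
subreads with iid substitutions (no indels — the error metric counts
mismatches excluding indels, and template-coordinate alignment is
outside this package's scope). Repeat counts default to
`1 + Poisson(5)`, which has median 6 and minimum 1. Subread base
qualities are flat at `⌊−10 log₁₀ e⌋`; qualities only feed the
consensus quality aggregation, while the error process itself is
governed by `error_rate`.

## Consensus calling

`call_consensus()` takes a column-aligned subread stack and emits, per
column, the plurality base. Ties are resolved by summed subread
quality, then by agreement with the template, then lexicographically.
Reads with fewer than `min_repeats = 3` subreads are rejected.
Consensus quality is the summed Phred score of agreeing subreads minus
disagreeing ones, floored at 2 and capped at 60.

`consensus_error_theory(e, r)` enumerates all multinomial outcomes of
`r` draws over {correct, 3 wrong bases} and sums the probability that
some wrong base strictly outnumbers the correct one (count ties retain
the correct base under the tie rules above, since flat qualities make
the quality tie-break vacuous and the template rule then applies). At
`r = 3` the sum collapses algebraically to `e²` — the package's Monte
Carlo consensus agrees with this closed form within three binomial
standard deviations over 10⁶ columns, and at `e = 0.00674` the
consensus error (~4.5 × 10⁻⁵) sits two orders of magnitude below the
raw rate.

`trim_backbone()` removes the maximal read prefix matching a backbone
suffix and read suffix matching a backbone prefix (RCA geometry: a
truncated flank adjacent to the insert retains the backbone end facing
it), allowing 10% mismatches within the flank and requiring at least
8 bp — short enough to catch real remnants, long enough that a random
match is vanishingly unlikely (≤ 4⁻⁸ per position). `deduplicate()`
single-links reads whose starts and ends both agree within ±1 bp and
keeps the deepest member (ties to the earliest timestamp).

## Error-rate measurement

`compute_error_rate()` follows the germline-masked protocol: drop
reads overlapping any germline-variant position, drop reads with
MAPQ < 60, keep at most 400,000 mutually nonoverlapping reads, and
divide substitutions by aligned bases. Nonoverlap is resolved greedily
in coordinate order; if more reads survive than the cap, a seeded
random subsample is taken. Phred conversion floors
(`0.00674 → Q21`, `0.00072 → Q31`); floor is the only convention
consistent with Q21 at 0.00674, and we apply it uniformly.

## SNV tumor-fraction estimation

Given observed counts (`n_mut` of `n_obs`), `estimate_tf_snv()` scans
100 linear TF values in [0, 1]. At each grid TF it simulates 10,000
trials of `n_obs` observations; each observation falls on a uniformly
chosen panel site and is MUT with probability
`tf · P_site + (1 − tf) e/3`. Under uniform assignment the trial total
is exactly Binomial(`n_obs`, mean of the per-site probabilities), so
the simulator draws one binomial per trial; the literal per-site
sampling path is retained (`by_site = TRUE`) and the test suite checks
the two routes agree by chi-square. The grid value's weight is the
fraction of trials matching the observed MUT count exactly; if no grid
value ever matches (large `n_obs`), the window widens to the smallest
±k with nonzero mass. "Alignment with the observed distribution" is
not otherwise defined, and exact-count matching is its sharpest
operationalization.

The point estimate is the highest-weight grid TF. The 95% CI takes the
2.5%/97.5% quantiles of the normalized weight profile *in TF space* —
the interval is reported in TF units, which resolves the ambiguity
between count-space and TF-space quantiles in favour of the space the
result lives in. If the point estimate falls below 0.05 the search
repeats on a fine grid of 0 plus 99 log-spaced values in
[10⁻⁴, 0.10] (zero must be prepended by hand since a log grid cannot
contain it). Calibration, measured by the package's own acceptance
test, covers the true TF in ≥ 90% of 200 seeded replicates at TF 0.01,
0.1 and 0.5 with ~1000 observations each.

Supporting analyses: `cumulative_mut_ratio()` tracks the running
MUT/(MUT+REF) ratio in time bins for real-time detection;
`fisher_mut_enrichment()` gives the one-sided Fisher exact p for
patient-versus-control MUT enrichment on the 2×2 MUT/REF table. Note
that identical nonzero tables give a large one-sided p (~0.6), not
exactly 1 — the one-sided tail includes the observed table's own mass;
p = 1 arises only when the patient shows zero MUT alleles.

## Fragmentomics tumor fraction

`build_length_profile()` histograms lengths at 1 bp over 30–220 bp and
normalizes to 1. `nmf_tf()` solves nonnegative least squares for the
weights of two fixed signature rows (single-step NMF with a frozen
basis — the numerical content of "NMF with fixed signatures") and
returns `w₂/(w₁+w₂)` capped at 1.0. Normalizing both profile and
signatures makes the weights sum near 1 and the cap a true boundary.
Exact mixtures `α·S₂ + (1−α)·S₁` are recovered to ≤ 10⁻⁶ for any α.

The packaged default signatures are **parametric, synthetic
stand-ins** — the healthy model density (Signature 1) and the
tumor-shifted periodic density (Signature 2) on 30–220 bp — because
the literature-derived signature values are not redistributable here.
`read_signatures_tsv()` is the override path for externally supplied
signatures; the estimator itself is agnostic to their provenance.

`afm_nm_to_bp()` applies the atomic-force-microscopy ladder
calibration `L_bp = (L_nm + 10)/0.341` for cross-checking length
profiles against direct imaging.

## Limit-of-detection simulation

`run_lod()` simulates, for each TF on a 51-point grid (0 plus 50
log-spaced in [0.001, 1]) and a platform preset (coverage × error
rate), 10,000 sequencing runs with Poisson(`coverage × n_sites`)
observations each. Detection uses the simplest statistic consistent
with allele counting: the MUT count meets or exceeds a threshold
calibrated on the TF = 0 null so the empirical false positive rate
does not exceed `1 − tnr_min` (TNR ≥ 68%). The lowest detectable TF is
the smallest grid TF with TPR > 95%. The threshold construction uses
the weak inequality; it is the only form whose degenerate limit
(`tnr_min = 0`) yields "everything detected".

One caveat worth knowing: LoD is monotone in error rate only where the
null threshold separates between error rates. When two error rates
share a threshold (low coverage, small null means), the healthy-read
leakage `(1 − tf)e/3` marginally *helps* cross the unchanged count
threshold, and the ordering can invert by one grid step. The
monotonicity checks therefore use coverage/error grids
(0.25/1/4×, 0.0007/0.007/0.03) on which thresholds separate.

The four presets — raw MinION (0.25×, e = 0.00674), raw PromethION
(3×, 0.00674), consensus MinION (0.04×, 0.00072), consensus PromethION
(0.8×, 0.00072) — encode the throughput-versus-accuracy trade-off:
consensus calling costs coverage but buys an error rate ~9.4× lower.
On a 5000-site VAF-0.3 panel the consensus-PromethION preset detects
at or below the raw-MinION preset's LoD, reproducing the expected
direction that both lower error and higher throughput improve
minimal-residual-disease detection. A full experiment over 10,000
trials × 51 TFs × 4 techniques is 2,040,000 simulated datasets per
patient (`lod_experiment_size()`).

## Problem sizes and numerical choices

The package's own checks run at sizes chosen to make each property
decisive yet quick on a single core: 10⁵ fragments for mode locations,
10⁶ consensus columns for the error-theory comparison, 200 replicates
per TF for CI calibration, and 2000 trials per grid point for LoD
orderings (LoD values at this trial count are stable across seeds).
Degenerate inputs are handled explicitly: empty observation sets,
all-zero Fisher tables (p = 1 with a warning), profiles with no
in-range lengths, zero-weight NMF solutions, and reads fully consumed
by backbone trimming all error or reject rather than returning
fabricated values.

## What the synthetic data does and does not show

The generators emulate the *statistical* structure the estimators rely
on — bimodal nucleosomal lengths, tumor shortening and periodicity,
purity-and-VAF-scaled allele probabilities, Poisson site coverage,
uniform substitution errors — but not alignment artifacts, indels,
strand effects, GC-dependent error structure, mappability, or
fragment-end sequence biases of real cfDNA. Tests passing on this
model therefore validate the estimators' correctness under their
stated assumptions, not end-to-end accuracy on real sequencing runs;
the error-rate module, in particular, consumes reads already reduced
to substitution-only alignments, with the aligner itself out of scope.
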