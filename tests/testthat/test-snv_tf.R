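test_that("allele counting tallies the three classes exactly", {
  panel <- uniform_panel(20, vaf = 0.5)
  empty <- allele_observations(integer(0), character(0), numeric(0), panel)
  c0 <- count_alleles(empty, panel)
  expect_equal(c(c0$n_ref, c0$n_mut, c0$n_err, c0$n_obs), c(0, 0, 0, 0))

  obs <- allele_observations(
    rep(1:7, length.out = 14),
    c(rep("REF", 10), rep("MUT", 3), "ERR"),
    seq_len(14), panel
  )
  cts <- count_alleles(obs, panel)
  expect_equal(c(cts$n_ref, cts$n_mut, cts$n_err), c(10, 3, 1))

  gen <- generate_allele_observations(uniform_panel(100, 0.5), 0.5, 1000,
                                      seed = 101)
  g <- count_alleles(gen, uniform_panel(100, 0.5))
  se <- sqrt(0.25 * 0.75 / g$n_obs)
  expect_lt(abs(g$n_mut / g$n_obs - 0.25), 3 * se)
})

test_that("cumulative MUT ratio tracks arithmetic and separates tumor from healthy", {
  panel <- uniform_panel(5, 0.5)
  flat <- allele_observations(rep(1, 20), rep("REF", 20),
                              seq(1, 100, length.out = 20), panel,
                              run_minutes = 100)
  expect_true(all(cumulative_mut_ratio(flat, 10)$ratio == 0))

  steps <- allele_observations(rep(1, 4), c("MUT", "MUT", "REF", "REF"),
                               c(2, 5, 12, 15), panel, run_minutes = 20)
  rr <- cumulative_mut_ratio(steps, 10)
  expect_equal(rr$ratio[1], 1.0)
  expect_equal(rr$ratio[2], 0.5)

  tum <- generate_allele_observations(uniform_panel(100, 0.5), 0.3, 100,
                                      run_minutes = 180, seed = 102)
  hc <- generate_allele_observations(uniform_panel(100, 0.5), 0, 100,
                                     run_minutes = 180, seed = 103)
  ct <- cumulative_mut_ratio(tum, 10, t_max = 180)
  ch <- cumulative_mut_ratio(hc, 10, t_max = 180)
  late <- ct$t > 20
  expect_true(all(ct$ratio[late] > ch$ratio[late]))
})

test_that("Fisher enrichment test matches the hypergeometric tail", {
  mk <- function(mut, ref) structure(list(n_ref = ref, n_mut = mut,
                                          n_err = 0L,
                                          n_obs = mut + ref),
                                     class = "allele_counts")
  # identical nonzero tables: no enrichment signal (one-sided p includes
  # the observed table's own probability mass, so it is large but not 1)
  expect_gt(fisher_mut_enrichment(mk(5, 95), mk(5, 95)), 0.5)
  p <- fisher_mut_enrichment(mk(50, 50), mk(0, 100))
  expect_lt(p, 1e-9)
  # hypergeometric tail oracle
  oracle <- phyper(50 - 1, 50, 150, 100, lower.tail = FALSE)
  expect_equal(p, oracle, tolerance = 1e-10)
  expect_equal(fisher_mut_enrichment(mk(0, 100), mk(0, 100)), 1)
  expect_warning(p0 <- fisher_mut_enrichment(mk(0, 0), mk(0, 0)),
                 "degenerate")
  expect_equal(p0, 1)
})

test_that("MUT-allele probability is purity times VAF", {
  expect_equal(mut_probability(0.6, 0.5), 0.30)
  expect_equal(mut_probability(1.0, 0.37), 0.37)
  expect_equal(mut_probability(0.8, 0.25), 0.20)
  expect_error(mut_probability(0, 0.5), "purity")
  expect_error(mut_probability(0.5, 1.2), "vaf")
})

test_that("simulated MUT counts follow the per-site probability model", {
  panel1 <- uniform_panel(1, vaf = 0.3)
  expect_true(all(simulate_mut_counts(panel1, 500, tf = 0, n_trials = 200,
                                      error_rate = 0, seed = 111) == 0))
  cts <- simulate_mut_counts(panel1, 1000, tf = 1, n_trials = 2000,
                             seed = 112)
  se <- sqrt(1000 * 0.3 * 0.7) / sqrt(2000)
  expect_lt(abs(mean(cts) - 300), 3 * se)

  # dual route: literal per-site sampling versus the binomial closed
  # form; P = purity * vaf = 0.25 at every site, tf 0.5 -> p = 0.125
  panel <- uniform_panel(25, vaf = 0.5, purity = 0.5)
  x <- simulate_mut_counts(panel, 400, tf = 0.5, n_trials = 5000,
                           seed = 113, by_site = TRUE)
  breaks <- c(-Inf, qbinom(seq(0.1, 0.9, 0.1), 400, 0.125), Inf)
  obs <- table(cut(x, breaks))
  expp <- diff(pbinom(c(-Inf, qbinom(seq(0.1, 0.9, 0.1), 400, 0.125), Inf),
                      400, 0.125))
  chi <- sum((as.numeric(obs) - 5000 * expp)^2 / (5000 * expp))
  expect_lt(chi, qchisq(0.99, df = length(expp) - 1))
})

test_that("TF estimator finds the truth and behaves monotonically", {
  panel <- uniform_panel(100, vaf = 0.5)
  mk <- function(mut, obs) structure(list(n_ref = obs - mut, n_mut = mut,
                                          n_err = 0L, n_obs = obs),
                                     class = "allele_counts")
  # no MUT observed, no error model -> TF pinned at zero
  est0 <- estimate_tf_snv(mk(0, 1000), panel, n_trials = 2000, seed = 121)
  expect_equal(est0$tf_point, 0)
  expect_true(est0$refined)
  expect_equal(sum(est0$grid_weights), 1)
  # with no error and no MUT, surviving weight sits where trials can
  # produce zero counts, i.e. expected count below ~1
  expect_true(all(0.5 * 1000 * est0$grid[est0$grid_weights > 0.01] < 5))

  # generator ground truth at tf = 0.5
  obs <- generate_allele_observations(panel, 0.5, 100, seed = 122)
  cts <- count_alleles(obs, panel)
  est <- estimate_tf_snv(cts, panel, seed = 123)
  expect_gt(est$tf_point, 0.45)
  expect_lt(est$tf_point, 0.55)
  expect_true(est$ci_low <= 0.5 && 0.5 <= est$ci_high)
  expect_true(est$ci_low <= est$tf_point && est$tf_point <= est$ci_high)

  # monotone nondecreasing in the observed MUT count
  pts <- vapply(c(50, 150, 300), function(m)
    estimate_tf_snv(mk(m, 1000), panel, n_trials = 4000,
                    seed = 124)$tf_point, 0)
  expect_true(all(diff(pts) >= 0))
})

test_that("admixture dilution series yields decreasing TF estimates", {
  panel <- uniform_panel(300, vaf = 0.5)
  tum <- generate_allele_observations(panel, 0.71, 80, seed = 131)
  hc <- generate_allele_observations(panel, 0, 80, seed = 132)
  fracs <- c(1, 0.10, 0.02, 0.01, 0.005)
  tfs <- numeric(length(fracs))
  for (i in seq_along(fracs)) {
    mix <- make_admixture(tum, hc, fracs[i], seed = 133 + i)
    est <- estimate_tf_snv(count_alleles(mix, panel), panel,
                           n_trials = 4000, seed = 140 + i)
    tfs[i] <- est$tf_point
    expected <- expected_admixture_tf(fracs[i], 0.71)
    expect_true(est$ci_low <= expected * 1.6 + 0.002 &&
                  expected * 0.4 - 0.002 <= est$ci_high)
  }
  expect_true(all(diff(tfs) < 0))
})
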