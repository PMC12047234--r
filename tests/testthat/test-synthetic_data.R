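test_that("fragment length model validates its parameters", {
  expect_error(fragment_length_model(di_weight = 1.5), "di_weight")
  expect_error(fragment_length_model(mono_sd = -1), "positive")
  expect_error(fragment_length_model(min_len = 700, max_len = 30), "min_len")
  expect_error(fragment_length_model(mono_mode = 10, min_len = 30), "modes")
})

test_that("healthy fragment lengths peak at the nucleosomal modes", {
  lens <- generate_fragment_lengths(100000, seed = 11)
  expect_true(all(lens >= 30 & lens <= 700))
  h <- tabulate(lens, nbins = 700)
  expect_equal(which.max(h), 167)
  expect_equal(249 + which.max(h[250:400]), 332, tolerance = 0)
  expect_length(generate_fragment_lengths(1, seed = 1), 1)
})

test_that("tumor lengths are shortened and carry a 10-bp periodicity", {
  lens <- generate_fragment_lengths(100000, tumor_fraction = 1, seed = 12)
  h <- tabulate(lens, nbins = 700)
  mode <- which.max(h)
  expect_true(abs(mode - (167 - round(4.5))) <= 2)
  expect_identical(histogram_period(h[30:170]), 10L)
})

test_that("fragment generators are deterministic under a fixed seed", {
  expect_identical(generate_fragment_lengths(500, seed = 3),
                   generate_fragment_lengths(500, seed = 3))
  expect_identical(generate_variant_panel(50, seed = 4),
                   generate_variant_panel(50, seed = 4))
  t1 <- generate_templates(5, seed = 5)
  r1 <- generate_concatemer_reads(t1, seed = 6)
  r2 <- generate_concatemer_reads(t1, seed = 6)
  expect_identical(r1, r2)
})

test_that("variant panels honour their invariants at small and large sizes", {
  p <- generate_variant_panel(10, vaf_mean = 0.5, purity = 1.0, seed = 7)
  expect_s3_class(p, "variant_panel")
  expect_equal(nrow(p), 10)
  expect_true(all(p$vaf > 0 & p$vaf <= 1))
  expect_true(all(p$ref != p$alt))
  big <- generate_variant_panel(582, seed = 8)
  expect_equal(nrow(big), 582)
  expect_equal(anyDuplicated(big[c("chrom", "pos")]), 0)
  expect_error(generate_variant_panel(5, purity = 0), "purity")
  expect_error(generate_variant_panel(5, purity = 1.2), "purity")
})

test_that("error-free concatemers reproduce the template exactly", {
  tmpl <- generate_templates(20, seed = 21)
  reads <- generate_concatemer_reads(tmpl, error_rate = 0, seed = 22)
  for (r in reads) expect_true(all(r$subreads == r$template_seq))
  expect_error(
    generate_concatemer_reads(data.frame(template_id = "x", seq = "",
                                         chrom = "chr1", start = 0, end = 0)),
    "empty template"
  )
})

test_that("subread substitution rate matches the requested error rate", {
  tmpl <- generate_templates(1, seed = 31)
  tmpl$seq <- rand_seq(200)
  tmpl$end <- tmpl$start + 200
  reads <- generate_concatemer_reads(tmpl, repeat_dist = function(n) 10000L,
                                     error_rate = 0.00674, seed = 32)
  sub <- reads[[1]]$subreads
  tchars <- utf8ToInt(tmpl$seq)
  mm <- vapply(sub, function(s) sum(utf8ToInt(s) != tchars), 0)
  n_bases <- 200 * 10000
  rate <- sum(mm) / n_bases
  se <- sqrt(0.00674 * (1 - 0.00674) / n_bases)
  expect_lt(abs(rate - 0.00674), 3 * se)
})

test_that("default repeat-count distribution has median six", {
  # independent oracle: direct simulation of the declared distribution
  oracle <- withr::with_seed(41, median(1L + rpois(10000, 5)))
  expect_identical(oracle, 6)
  tmpl <- generate_templates(10000, seed = 42)
  tmpl$seq <- substr(tmpl$seq, 1, 5)  # short templates, we only need counts
  reads <- generate_concatemer_reads(tmpl, seed = 43)
  reps <- vapply(reads, `[[`, 0L, "n_repeats")
  expect_equal(median(reps), 6)
  expect_gte(min(reps), 1)
})

test_that("null allele observations contain no MUT or ERR calls", {
  panel <- generate_variant_panel(50, seed = 51)
  obs <- generate_allele_observations(panel, tf = 0, coverage = 20,
                                      error_rate = 0, seed = 52)
  expect_true(all(obs$call == "REF"))
})

test_that("MUT fraction follows tf * purity * vaf plus error leakage", {
  # worked probability example: purity 0.6, VAF 0.5, tf = 1 -> 30%
  panel <- uniform_panel(100, vaf = 0.5, purity = 0.6)
  obs <- generate_allele_observations(panel, tf = 1, coverage = 1000,
                                      error_rate = 0, seed = 53)
  frac <- mean(obs$call == "MUT")
  se <- sqrt(0.3 * 0.7 / nrow(obs))
  expect_lt(abs(frac - 0.30), 3 * se)

  # closed form tf * purity * vaf at tf = 0.5
  panel2 <- uniform_panel(100, vaf = 0.5, purity = 1)
  obs2 <- generate_allele_observations(panel2, tf = 0.5, coverage = 1000,
                                       error_rate = 0, seed = 54)
  expect_lt(abs(mean(obs2$call == "MUT") - 0.25), 0.005)

  # full invariant incl. error leakage across parameter sets
  cases <- list(c(tf = 0.2, vaf = 0.4, purity = 0.8, e = 0.01),
                c(tf = 0.05, vaf = 0.6, purity = 0.5, e = 0.003))
  for (cs in cases) {
    pan <- uniform_panel(100, vaf = cs[["vaf"]], purity = cs[["purity"]])
    ob <- generate_allele_observations(pan, cs[["tf"]], coverage = 1000,
                                       error_rate = cs[["e"]], seed = 55)
    expected <- cs[["tf"]] * cs[["purity"]] * cs[["vaf"]] +
      (1 - cs[["tf"]]) * cs[["e"]] / 3
    se <- sqrt(expected * (1 - expected) / nrow(ob))
    expect_lt(abs(mean(ob$call == "MUT") - expected), 3 * se)
  }
})

test_that("admixtures behave as identity at the extremes and dilute TF", {
  panel <- uniform_panel(200, vaf = 0.5, purity = 1)
  tum <- generate_allele_observations(panel, 0.71, 100, seed = 61)
  hc <- generate_allele_observations(panel, 0, 100, seed = 62)
  all_t <- make_admixture(tum, hc, fraction = 1, seed = 63)
  expect_equal(nrow(all_t), nrow(tum))
  expect_equal(mean(all_t$call == "MUT"), mean(tum$call == "MUT"))
  all_h <- make_admixture(tum, hc, fraction = 0, seed = 64)
  expect_equal(mean(all_h$call == "MUT"), mean(hc$call == "MUT"))

  mix <- make_admixture(tum, hc, fraction = 0.10, seed = 65)
  expected <- 0.10 * 0.71 * 0.5  # effective TF 0.071 times purity*vaf
  se <- sqrt(expected * (1 - expected) / nrow(mix))
  expect_lt(abs(mean(mix$call == "MUT") - expected), 3 * se)

  other <- generate_allele_observations(uniform_panel(150, 0.5), 0, 100,
                                        seed = 66)
  expect_error(make_admixture(tum, other, 0.5), "different panels")
})
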