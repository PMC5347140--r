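make_nuclei <- function(phh3_mean, phh3_max, border = FALSE) {
  data.frame(phh3_mean = phh3_mean, phh3_max = phh3_max, border = border)
}

test_that("pHH3 positivity needs both intensity conditions", {
  n <- make_nuclei(c(200, 200, 50, 200), c(900, 300, 900, 900),
                   border = c(FALSE, FALSE, FALSE, TRUE))
  pct <- classify_phh3(n, mean_threshold = 100, max_threshold = 500)
  # only nucleus 1 passes both; nucleus 4 would pass but is on the border
  expect_equal(as.numeric(pct), 100 * 1 / 3)
  expect_equal(attr(pct, "n_total"), 3)
  all_border <- make_nuclei(200, 900, border = TRUE)
  expect_warning(p0 <- classify_phh3(all_border, 100, 500), "undefined")
  expect_true(is.na(p0))
})

test_that("raising either pHH3 threshold never increases the positive fraction", {
  spec <- mechanism_spec("mda_cytotoxic")
  nuc <- gen_nuclei(spec, dose = 2e-6, seed = 61, n = 3000)
  ths <- seq(60, 400, by = 20)
  pcts_mean <- vapply(ths, function(t) {
    as.numeric(classify_phh3(nuc, t, 300))
  }, numeric(1))
  pcts_max <- vapply(ths * 3, function(t) {
    as.numeric(classify_phh3(nuc, 100, t))
  }, numeric(1))
  expect_true(all(diff(pcts_mean) <= 0))
  expect_true(all(diff(pcts_max) <= 0))
})

test_that("a seeded bimodal population recovers its known positive fraction", {
  spec <- mechanism_spec("mda_cytotoxic")
  nuc <- gen_nuclei(spec, dose = 0, seed = 62, n = 5000, phh3_positive = 0.10)
  th <- phh3_thresholds_from_vehicle(gen_nuclei(spec, 0, seed = 63, n = 5000,
                                                phh3_positive = 0))
  pct <- classify_phh3(nuc, th["mean_threshold"], th["max_threshold"])
  # binomial 99% CI half-width at n ~ 4500 is ~1.2 percentage points
  expect_lt(abs(as.numeric(pct) - 10), 1.5)
})

test_that("condensed-DNA linear classifier counts score exceedances", {
  n_all_low <- data.frame(cond_density = rep(0.5, 10), area = rep(120, 10))
  n_all_high <- data.frame(cond_density = rep(3, 10), area = rep(40, 10))
  expect_equal(as.numeric(condensed_fraction(n_all_low, 1.2)), 0)
  expect_equal(as.numeric(condensed_fraction(n_all_high, 1.2)), 100)
  spec <- mechanism_spec("mda_cytotoxic")
  mix <- rbind(gen_nuclei(spec, 0, seed = 65, n = 3000),
               within(gen_nuclei(spec, 0, seed = 66, n = 1000), {
                 cond_density <- rnorm(1000, 3, 0.3)
                 area <- rnorm(1000, 40, 8)
               }))
  pct <- condensed_fraction(mix, 1.2)
  expect_lt(abs(as.numeric(pct) - 25), 3)  # 25% condensed by construction
  expect_error(condensed_fraction(data.frame(a = 1), 0), "missing feature")
})

test_that("cell-cycle gating recovers constructed mixtures", {
  spec <- mechanism_spec("mda_cytotoxic")
  pure_g1 <- gen_nuclei(spec, 0, seed = 71, n = 2000,
                        baseline_fractions = c(subG1 = 0, G1 = 1, S = 0, G2M = 0))
  fr <- cell_cycle_fractions(pure_g1$dna_int)
  expect_gt(fr["G1"], 99)
  expect_equal(sum(fr), 100, tolerance = 1e-9)

  mix <- gen_nuclei(spec, 0, seed = 72, n = 6000,
                    baseline_fractions = c(subG1 = 0, G1 = 0.6, S = 0.1,
                                           G2M = 0.3))
  fr2 <- cell_cycle_fractions(mix$dna_int)
  expect_lt(abs(fr2["G1"] - 60), 3)
  expect_lt(abs(fr2["S"] - 10), 3)
  expect_lt(abs(fr2["G2M"] - 30), 3)
  expect_equal(sum(fr2), 100, tolerance = 1e-9)

  # invariance to global linear rescaling of intensities
  fr3 <- cell_cycle_fractions(mix$dna_int * 7.3)
  expect_equal(as.numeric(fr3), as.numeric(fr2), tolerance = 0.2)
  expect_error(cell_cycle_fractions(numeric(0)), "too few")
})

test_that("dose shifts cycle composition by mechanism", {
  doses <- c(0, 5e-7, 2e-6, 1e-5)
  mda <- mechanism_spec("mda_cytotoxic")
  arrested <- vapply(seq_along(doses), function(i) {
    fr <- cell_cycle_fractions(gen_nuclei(mda, doses[i], seed = 80 + i,
                                          n = 4000)$dna_int)
    unname(fr["G2M"] + fr["subG1"])
  }, numeric(1))
  expect_true(all(diff(arrested) > 0))

  pi3k <- mechanism_spec("pi3k_cytostatic")
  g1 <- vapply(seq_along(doses), function(i) {
    fr <- cell_cycle_fractions(gen_nuclei(pi3k, doses[i], seed = 90 + i,
                                          n = 4000)$dna_int)
    unname(fr["G1"])
  }, numeric(1))
  expect_true(all(diff(g1) > 0))
})

test_that("proliferation percent feeds a dose-response fit", {
  expect_equal(proliferation_from_counts(500, 500), 100)
  expect_equal(proliferation_from_counts(250, 500), 50)
  expect_error(proliferation_from_counts(10, 0), "positive")
  concs <- dilution_series()
  counts <- round(1200 * four_pl(concs, -6, -2) / 100)
  fit <- fit_sigmoid(data.frame(
    conc_M = concs, response = proliferation_from_counts(counts, 1200)
  ))
  expect_equal(fit$log_ic50, -6, tolerance = 0.02)
  expect_equal(fit$hill_slope, -2, tolerance = 0.1)
})
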