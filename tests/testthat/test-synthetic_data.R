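test_that("generators are pure functions of spec and seed", {
  spec <- scenario_spec("bkm120_like")
  expect_identical(gen_panel(spec, seed = 5, n_lines = 3),
                   gen_panel(spec, seed = 5, n_lines = 3))
  expect_false(identical(gen_panel(spec, seed = 5, n_lines = 3)$response,
                         gen_panel(spec, seed = 6, n_lines = 3)$response))
  expect_identical(gen_nuclei(spec, 1e-6, seed = 5),
                   gen_nuclei(spec, 1e-6, seed = 5))
  expect_identical(gen_kymo_events(seed = 5), gen_kymo_events(seed = 5))
  expect_identical(gen_binding(1e-7, 13.9e-9, 25e-9, seed = 5),
                   gen_binding(1e-7, 13.9e-9, 25e-9, seed = 5))
  # the caller's RNG stream is not consumed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_panel(spec, seed = 5, n_lines = 2))
  expect_identical(rnorm(1), before)
})

test_that("noiseless single-line panels are recovered exactly by the fits", {
  spec <- mechanism_spec("pi3k_cytostatic", noise_sd = 0,
                         line_ic50_dispersion = 0, arm_jitter = 0)
  p <- gen_panel(spec, seed = 1, n_lines = 1, n_replicates = 1)
  viab <- fit_sigmoid(p[p$readout == "viability", c("conc_M", "response")])
  expect_equal(viab$log_ic50, log10(spec$pi3k_ec50), tolerance = 1e-5)
  expect_equal(viab$hill_slope, spec$pi3k_hill, tolerance = 1e-5)
  ppkb <- fit_sigmoid(p[p$readout == "pPKB", c("conc_M", "response")])
  expect_equal(ppkb$log_ic50,
               log10(spec$pi3k_ec50 * spec$ppkb_ec50_ratio), tolerance = 1e-5)
})

test_that("a dual mechanism steepens the fitted viability slope", {
  # generic dual with equal component EC50s: the product of survival
  # curves fits steeper than the shallow PI3K arm
  dual_eq <- mechanism_spec("dual", noise_sd = 0, line_ic50_dispersion = 0,
                            arm_jitter = 0)
  p_eq <- gen_panel(dual_eq, seed = 2, n_lines = 1, n_replicates = 1)
  f_eq <- fit_sigmoid(p_eq[p_eq$readout == "viability",
                           c("conc_M", "response")], model = "full4p")
  expect_lt(f_eq$hill_slope, dual_eq$pi3k_hill - 0.5)

  # dual-drug scenario (MDA arm just below the PI3K growth arm):
  # steep, MDA-like composite slope
  dual <- scenario_spec("bkm120_like", noise_sd = 0,
                        line_ic50_dispersion = 0, arm_jitter = 0)
  p <- gen_panel(dual, seed = 2, n_lines = 1, n_replicates = 1)
  f <- fit_sigmoid(p[p$readout == "viability", c("conc_M", "response")],
                   model = "full4p")
  expect_lte(f$hill_slope, -2)
  expect_gt(f$hill_slope, dual$mda_hill)  # shoulder of the shallow arm
})

test_that("panel Hill slopes separate mechanisms through the full fit pipeline", {
  fit_mean_slope <- function(kind, seed) {
    spec <- mechanism_spec(kind)
    p <- gen_panel(spec, seed = seed, n_lines = 6)
    slopes <- vapply(split(p, p$cell_line), function(d) {
      f <- fit_sigmoid(d[d$readout == "viability", c("conc_M", "response")],
                       model = "full4p")
      if (f$ambiguous) NA_real_ else f$hill_slope
    }, numeric(1))
    mean(slopes, na.rm = TRUE)
  }
  expect_lt(abs(fit_mean_slope("pi3k_cytostatic", 11) + 1), 0.3)
  expect_lt(fit_mean_slope("mda_cytotoxic", 12), -2)
})

test_that("kymograph generator encodes rates in its event structure", {
  ev <- gen_kymo_events(v_g_um_min = 3, f_cat_per_min = 0.4, noise = 0,
                        n_events = 100, n_movies = 2, seed = 8)
  g <- ev[ev$phase == "growth", ]
  expect_equal(g$length_um, 3 * g$duration_s / 60, tolerance = 1e-9)
  expect_true(all(ev$duration_s > 0))
  expect_true(all(c("growth", "shortening") %in% ev$phase))
  expect_true(all(ev$end_fate[ev$phase == "growth"] == "catastrophe"))
})

test_that("binding generator saturates at zero inhibitor", {
  plate <- gen_binding(1e-7, 13.9e-9, 25e-9, seed = 3, noise_sd = 0)
  bg <- plate[plate$role == "background", ]
  veh <- plate[plate$role == "vehicle", ]
  smp <- plate[plate$role == "sample", ]
  r_veh <- emission_ratio(veh$s665, veh$s620, mean(bg$s665), mean(bg$s620))
  r_smp <- emission_ratio(smp$s665, smp$s620, mean(bg$s665), mean(bg$s620))
  expect_true(all(r_smp <= r_veh[1] + 1e-12))  # vehicle is maximal occupancy
  occ0 <- 25e-9 / (25e-9 + 13.9e-9)
  expect_equal(r_veh[1], 18000 * occ0 / 10000, tolerance = 1e-9)
})

test_that("the dual scenario clusters with the MDA drug yet shares the PI3Ki IC50", {
  # panel of three drugs through fit -> Hill table -> penalty scores
  seed <- 31
  drugs <- list(dual = "bkm120_like", pi3ki = "pqr309_like",
                mda = "mtd147_like")
  fits <- list()
  for (i in seq_along(drugs)) {
    spec <- scenario_spec(drugs[[i]], noise_sd = 2)
    p <- gen_panel(spec, seed = seed, n_lines = 6, drug = names(drugs)[i])
    for (d in split(p, p$cell_line)) {
      f <- fit_sigmoid(d[d$readout == "viability", c("conc_M", "response")],
                       model = "full4p")
      fits[[length(fits) + 1L]] <- data.frame(
        cell_line = d$cell_line[1], drug = names(drugs)[i],
        hill_slope = f$hill_slope, ic50_M = 10^f$log_ic50,
        ambiguous = f$ambiguous
      )
    }
  }
  fits <- do.call(rbind, fits)
  tab <- hill_slope_table(fits)
  pen <- penalty_score_matrix(tab$slopes)
  # slope-based clustering: dual pairs with mda, not with the PI3K inhibitor
  expect_lt(pen["dual", "mda"], pen["dual", "pi3ki"])
  # same seed, same line factors: viability IC50s of dual and pi3ki within 2x
  ic <- tapply(fits$ic50_M, fits$drug, stats::median)
  expect_lt(ic[["dual"]] / ic[["pi3ki"]], 2)
})
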