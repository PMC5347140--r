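test_that("event filtering removes short growth and incomplete events", {
  ev <- rbind(
    make_event_table(c(0.4, 0.5, 2.0), c(30, 30, 60)),
    make_event_table(1.5, 45, complete = FALSE),
    make_event_table(0.3, 20, phase = "shortening", fate = "rescue")
  )
  out <- suppressMessages(filter_events(ev))
  expect_equal(nrow(out), 3)
  expect_false(any(out$phase == "growth" & out$length_um < 0.5))
  expect_true(0.5 %in% out$length_um)        # boundary inclusive
  expect_true(all(out$complete))
  expect_true("shortening" %in% out$phase)   # length filter only for growth
  expect_equal(unname(attr(out, "audit")["retained"]), 3)
})

test_that("growth rates are length/duration averaged per movie", {
  ev <- make_event_table(c(2, 2, 2), c(60, 60, 60))
  gr <- growth_rate(ev)
  expect_equal(gr$per_event, c(2, 2, 2))     # 2 um in 60 s = 2 um/min
  expect_equal(gr$mean, 2)
  expect_equal(gr$sd, NA_real_)              # single movie: no spread
  ev2 <- rbind(make_event_table(2, 60, id = "m1"),
               make_event_table(4, 60, id = "m2"))
  gr2 <- growth_rate(ev2)
  expect_equal(gr2$mean, 3)
  expect_equal(gr2$sd, sd(c(2, 4)))
})

test_that("catastrophe estimators match their defining arithmetic", {
  # single growth event of 100 s -> 0.01 s^-1
  one <- make_event_table(5, 100)
  expect_equal(as.numeric(catastrophe_frequency(one, "in_vitro")), 0.01)
  # 10 events, 5 min total growth -> 2 min^-1
  ten <- make_event_table(rep(1, 10), rep(30, 10))
  expect_equal(as.numeric(catastrophe_frequency(ten, "cellular")), 2)
  # within one movie N/sum(t) equals 1/mean(t)
  ev <- make_event_table(runif(20, 1, 5), runif(20, 20, 200))
  expect_equal(as.numeric(catastrophe_frequency(ev, "in_vitro")) * 60,
               as.numeric(catastrophe_frequency(ev, "cellular")))
  expect_error(catastrophe_frequency(one[0, ], "cellular"), "no growth")
})

test_that("catastrophe estimators converge to the generating rate", {
  # bias check: mean estimate over replicate tables
  est <- vapply(1:25, function(i) {
    ev <- gen_kymo_events(f_cat_per_min = 0.5, n_events = 200, n_movies = 1,
                          seed = 3000 + i)
    as.numeric(catastrophe_frequency(ev, "cellular"))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5) / 0.5, 0.1)
  est_iv <- vapply(1:25, function(i) {
    ev <- gen_kymo_events(f_cat_per_min = 0.5, n_events = 1000, n_movies = 1,
                          seed = 4000 + i)
    60 * as.numeric(catastrophe_frequency(ev, "in_vitro"))
  }, numeric(1))
  expect_lt(abs(mean(est_iv) - 0.5) / 0.5, 0.05)
})

test_that("rescue frequency is rescues per total shortening time", {
  ev <- rbind(
    make_event_table(rep(1, 3), rep(50, 3), phase = "shortening", fate = "rescue"),
    make_event_table(rep(1, 3), rep(50, 3), phase = "shortening",
                     fate = "unresolved")
  )
  expect_equal(as.numeric(rescue_frequency(ev)), 3 / 300)  # 0.01 s^-1
  none <- make_event_table(1, 100, phase = "shortening", fate = "unresolved")
  expect_equal(as.numeric(rescue_frequency(none)), 0)
  expect_warning(r <- rescue_frequency(make_event_table(1, 50)), "undefined")
  expect_true(is.na(r))
  # recovery of the generating rate (bias over replicates)
  est <- vapply(1:25, function(i) {
    ev <- gen_kymo_events(f_res_per_s = 0.01, n_events = 400, n_movies = 1,
                          seed = 5000 + i)
    as.numeric(rescue_frequency(ev))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.01) / 0.01, 0.1)
})

test_that("frequencies convert exactly between time units", {
  ev <- make_event_table(runif(50, 1, 4), rexp(50, 1 / 90))
  f_s <- as.numeric(catastrophe_frequency(ev, "in_vitro"))
  f_min <- as.numeric(catastrophe_frequency(ev, "cellular"))
  expect_equal(f_s * 60, f_min)
})

test_that("turbidity analysis normalizes delta-OD to the vehicle maximum", {
  times <- 0:60
  curve <- function(amp) amp * (1 - exp(-times / 15))
  mk <- function(well, cond, conc, amp) {
    data.frame(well = well, condition = cond, conc_M = conc,
               time_min = times, od340 = 0.05 + curve(amp))
  }
  concs <- c(1e-7, 1e-6, 3e-6, 1e-5, 3e-5)
  amps <- 0.3 * four_pl(concs, log10(3e-6), -1) / 100
  curves <- rbind(
    mk("v1", "DMSO", NA, 0.3),
    do.call(rbind, Map(mk, paste0("w", 1:5), "drug", concs, amps)),
    mk("flat", "dead", 1e-9, 0)
  )
  out <- turbidity_analysis(curves)
  nm <- out$normalized_max
  expect_equal(nm$pct_of_vehicle[nm$condition == "DMSO"], 100)
  expect_equal(nm$pct_of_vehicle[nm$condition == "dead"], 0)
  expect_true(all(abs(out$delta$delta_od[out$delta$time_min == 0]) < 1e-12))
  expect_equal(out$fits$drug$log_ic50, log10(3e-6), tolerance = 1e-3)
  expect_equal(out$fits$drug$hill_slope, -1, tolerance = 1e-3)
  expect_false("dead" %in% names(out$fits))  # too few concentrations
  bad <- curves[curves$condition == "dead", ]
  bad$condition <- "DMSO"
  expect_error(turbidity_analysis(rbind(bad)), "positive")
})

test_that("Mann-Whitney comparisons behave at the extremes", {
  expect_warning(p_id <- compare_conditions(c(1, 2), c(1, 2)), "underpowered")
  a <- c(1.0, 1.1, 1.2, 1.3, 1.4)
  # identical samples: p at (or numerically near) its maximum
  expect_gt(compare_conditions(a, a), 0.95)
  # disjoint supports n = 5 vs 5: minimal attainable two-sided exact p
  b <- a + 10
  expect_equal(compare_conditions(a, b), 2 / choose(10, 5), tolerance = 1e-9)
  # under the null the p-value distribution is roughly uniform
  set.seed(9)
  ps <- replicate(400, compare_conditions(rnorm(8), rnorm(8)))
  expect_gt(mean(ps > 0.5), 0.35)
  expect_lt(mean(ps < 0.05), 0.12)
})
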