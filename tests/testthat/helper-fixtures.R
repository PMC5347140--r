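# Shared fixtures: all built in code, no files.

# standard 9-point 3.16-fold dilution series, 3.16 nM .. 31.6 uM
dilution_series <- function(n = 9) 3.16e-9 * 3.16^(seq_len(n) - 1)

# a sigmoid_fit with known parameters, obtained by fitting its own
# noiseless curve (recovery is exact to numerical precision)
fit_from_params <- function(log_ic50, hill, top = 100, bottom = 0,
                            model = if (top == 100 && bottom == 0)
                              "normalized3p" else "full4p",
                            concs = dilution_series()) {
  d <- data.frame(conc_M = concs,
                  response = four_pl(concs, log_ic50, hill, top, bottom))
  fit_sigmoid(d, model = model)
}

# brute-force grid-search oracle for the normalized 3-parameter model:
# exhaustive RSS minimization over (log_ic50, hill)
grid_fit_oracle <- function(conc, resp,
                            l_grid = seq(log10(min(conc)) - 0.5,
                                         log10(max(conc)) + 0.5, by = 0.01),
                            h_grid = seq(-5, -0.1, by = 0.02)) {
  best <- c(NA, NA, Inf)
  lx <- log10(conc)
  for (h in h_grid) {
    # vectorized over the log_ic50 grid
    rss <- vapply(l_grid, function(L) {
      sum((resp - 100 / (1 + 10^((L - lx) * h)))^2)
    }, numeric(1))
    i <- which.min(rss)
    if (rss[i] < best[3]) best <- c(l_grid[i], h, rss[i])
  }
  list(log_ic50 = best[1], hill = best[2], rss = best[3])
}

make_event_table <- function(lengths, durations,
                             phase = "growth", fate = "catastrophe",
                             complete = TRUE, id = "m1") {
  data.frame(movie_or_cell_id = id, phase = phase, length_um = lengths,
             duration_s = durations, end_fate = fate, complete = complete)
}
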