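# Microtubule dynamic-instability statistics from kymograph event
# tables, and turbidity-based polymerization dose-response.
#
# Event tables carry one row per growth or shortening phase:
#   movie_or_cell_id, phase ("growth"/"shortening"), length_um,
#   duration_s, end_fate ("catastrophe"/"rescue"/"unresolved"), complete.

#' Filter kymograph events for analysis
#'
#' Removes growth events shorter than 0.5 um (boundary inclusive: events
#' of exactly 0.5 um are kept) and events without a clearly observed
#' start and end (`complete == FALSE`). An audit of removal counts is
#' attached as attribute `audit` and reported via `message()`.
#'
#' @param events kymograph event data.frame
#' @param min_growth_length_um growth-length cutoff (default 0.5)
#' @return filtered event data.frame
#' @export
filter_events <- function(events, min_growth_length_um = 0.5) {
  stopifnot(all(c("phase", "length_um", "duration_s", "complete") %in% names(events)))
  short <- events$phase == "growth" & events$length_um < min_growth_length_um
  incomplete <- !events$complete
  keep <- !(short | incomplete)
  audit <- c(short_growth = sum(short & !incomplete),
             incomplete = sum(incomplete),
             retained = sum(keep))
  message(sprintf("filter_events: removed %d short growth and %d incomplete event(s); %d retained",
                  audit[["short_growth"]], audit[["incomplete"]], audit[["retained"]]))
  out <- events[keep, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

#' Microtubule growth rates
#'
#' Per-event velocity is `length / duration`; velocities are averaged per
#' movie (in vitro convention) or per cell (cellular convention) and the
#' grouped means are summarized as mean +/- s.d. across groups.
#'
#' @param events filtered event data.frame; only growth phases are used
#' @return list with `per_event` (um/min), `per_group` (data.frame of
#'   group means), `mean` and `sd` (um/min across groups). Empty groups
#'   are dropped with a warning.
#' @export
growth_rate <- function(events) {
  g <- events[events$phase == "growth", , drop = FALSE]
  if (nrow(g) == 0L) stop("no growth events")
  v <- g$length_um / g$duration_s * 60  # um/min
  grp <- split(v, g$movie_or_cell_id)
  empty <- vapply(grp, length, 1L) == 0L
  if (any(empty)) {
    warning(sprintf("%d empty group(s) dropped", sum(empty)))
    grp <- grp[!empty]
  }
  means <- vapply(grp, mean, numeric(1))
  list(per_event = v,
       per_group = data.frame(id = names(means), mean_um_min = unname(means)),
       mean = mean(means), sd = stats::sd(means))
}

#' Catastrophe frequency
#'
#' Two estimator conventions are exposed because they are genuinely
#' different statistics:
#' \describe{
#'   \item{`in_vitro`}{per movie, the inverse of the mean growth
#'     duration (`1/mean(t)`, equal to `N / sum(t)` within a movie),
#'     averaged across movies; returned per second. Setting
#'     `per_event_inverse = TRUE` switches to the per-event mean of
#'     `1/duration` — note this variant is dominated by the shortest
#'     events and does not converge to the switching rate for
#'     exponential growth durations.}
#'   \item{`cellular`}{per cell, the total number of growth events
#'     divided by the total growth time in minutes, averaged across
#'     cells; returned per minute.}
#' }
#'
#' @param events filtered event data.frame; only growth phases are used
#' @param mode `"in_vitro"` or `"cellular"`
#' @param per_event_inverse use the per-event `mean(1/t)` variant of the
#'   in-vitro estimator
#' @return frequency (per s for `in_vitro`, per min for `cellular`) with
#'   attribute `unit`
#' @export
catastrophe_frequency <- function(events, mode = c("in_vitro", "cellular"),
                                  per_event_inverse = FALSE) {
  mode <- match.arg(mode)
  g <- events[events$phase == "growth", , drop = FALSE]
  if (nrow(g) == 0L || sum(g$duration_s) <= 0) stop("no growth time observed")
  grp <- split(g$duration_s, g$movie_or_cell_id)
  if (mode == "in_vitro") {
    per_movie <- vapply(grp, function(t) {
      if (per_event_inverse) mean(1 / t) else 1 / mean(t)
    }, numeric(1))
    structure(mean(per_movie), unit = "s^-1")
  } else {
    per_cell <- vapply(grp, function(t) length(t) / (sum(t) / 60), numeric(1))
    structure(mean(per_cell), unit = "min^-1")
  }
}

#' Rescue frequency
#'
#' Number of observed rescues divided by the total shortening time.
#'
#' @param events filtered event data.frame; only shortening phases are
#'   used
#' @return frequency per second. With no shortening time the result is
#'   `NA` with a warning; with shortening but no rescues it is 0.
#' @export
rescue_frequency <- function(events) {
  s <- events[events$phase == "shortening", , drop = FALSE]
  total <- sum(s$duration_s)
  if (nrow(s) == 0L || total <= 0) {
    warning("no shortening time observed: rescue frequency undefined")
    return(structure(NA_real_, unit = "s^-1"))
  }
  structure(sum(s$end_fate == "rescue") / total, unit = "s^-1")
}

#' Turbidity-based tubulin polymerization analysis
#'
#' Per well the initial OD340 is treated as background and subtracted
#' (`delta_od = od340 - od340(t = 0)`); the maximal change per condition
#' is normalized to the vehicle's maximal change (x100). When the
#' non-vehicle conditions form a concentration series, a dose-response
#' fit of the normalized maxima is returned.
#'
#' @param curves data.frame with columns `well`, `condition`, `conc_M`
#'   (`NA` for vehicle), `time_min`, `od340`
#' @param vehicle condition label of the DMSO control
#' @return list with `delta` (per-timepoint delta-OD table),
#'   `normalized_max` (per condition, percent of vehicle) and `fits`
#'   (one `sigmoid_fit` per non-vehicle condition with at least 4
#'   distinct concentrations)
#' @export
turbidity_analysis <- function(curves, vehicle = "DMSO") {
  stopifnot(all(c("well", "condition", "conc_M", "time_min", "od340") %in% names(curves)))
  if (!vehicle %in% curves$condition) stop("vehicle curves are required")
  delta <- do.call(rbind, lapply(split(curves, curves$well), function(w) {
    w <- w[order(w$time_min), , drop = FALSE]
    w$delta_od <- w$od340 - w$od340[1]
    w
  }))
  rownames(delta) <- NULL

  per_well <- do.call(rbind, lapply(split(delta, delta$well), function(w) {
    data.frame(well = w$well[1], condition = w$condition[1],
               conc_M = w$conc_M[1], delta_od = max(w$delta_od))
  }))
  cond_key <- paste(per_well$condition, per_well$conc_M)
  per_cond <- do.call(rbind, lapply(split(per_well, cond_key),
                                    function(g) {
    data.frame(condition = g$condition[1], conc_M = g$conc_M[1],
               delta_od = mean(g$delta_od))
  }))
  rownames(per_cond) <- NULL
  veh_max <- mean(per_well$delta_od[per_well$condition == vehicle])
  if (!is.finite(veh_max) || veh_max <= 0) {
    stop("vehicle maximal delta-OD340 must be positive")
  }
  per_cond$pct_of_vehicle <- 100 * per_cond$delta_od / veh_max

  dr <- per_cond[per_cond$condition != vehicle & is.finite(per_cond$conc_M), ,
                 drop = FALSE]
  fits <- lapply(split(dr, dr$condition), function(g) {
    if (length(unique(g$conc_M)) < 4L) return(NULL)
    fit_sigmoid(data.frame(conc_M = g$conc_M, response = g$pct_of_vehicle),
                model = "normalized3p")
  })
  fits <- Filter(Negate(is.null), fits)
  list(delta = delta, normalized_max = per_cond, fits = fits)
}

#' Compare dynamics summaries between two conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on per-movie or
#' per-cell summary values.
#'
#' @param summaries_a,summaries_b numeric vectors of per-group summaries
#' @return p-value
#' @export
compare_conditions <- function(summaries_a, summaries_b) {
  if (length(summaries_a) < 3L || length(summaries_b) < 3L) {
    warning("fewer than 3 summaries in a group: test is underpowered")
  }
  suppressWarnings(
    stats::wilcox.test(summaries_a, summaries_b, exact = TRUE)$p.value
  )
}
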