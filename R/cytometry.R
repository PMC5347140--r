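# High-content cytometry summaries from per-nucleus feature tables:
# pHH3-positive fraction (mitotic index), condensed-DNA fraction,
# DNA-content cell-cycle gating and proliferation from nuclei counts.
#
# Nuclei tables carry one row per nucleus with columns
#   dna_int, phh3_mean, phh3_max, border (logical), and for the
#   condensed classifier the configured feature columns.

#' Percent pHH3-positive nuclei (mitotic index)
#'
#' Two-step selection: a nucleus is positive iff its mean pHH3 intensity
#' exceeds `mean_threshold` AND its maximum pHH3 intensity exceeds
#' `max_threshold`. Nuclei at image borders are excluded from both the
#' classification and the denominator.
#'
#' @param nuclei per-nucleus data.frame with `phh3_mean`, `phh3_max`,
#'   `border`
#' @param mean_threshold,max_threshold intensity thresholds (a.u.)
#' @return percent positive among non-border nuclei, with attributes
#'   `n_positive` and `n_total`; `NA` (flagged with a warning) when no
#'   non-border nuclei remain
#' @export
classify_phh3 <- function(nuclei, mean_threshold, max_threshold) {
  stopifnot(all(c("phh3_mean", "phh3_max", "border") %in% names(nuclei)))
  nb <- nuclei[!nuclei$border, , drop = FALSE]
  if (nrow(nb) == 0L) {
    warning("no non-border nuclei: pHH3 fraction undefined")
    return(structure(NA_real_, n_positive = 0L, n_total = 0L))
  }
  pos <- nb$phh3_mean > mean_threshold & nb$phh3_max > max_threshold
  structure(100 * sum(pos) / nrow(nb),
            n_positive = sum(pos), n_total = nrow(nb))
}

#' Default pHH3 thresholds from vehicle wells
#'
#' Thresholds are set at a high percentile of the vehicle-well intensity
#' distributions (default the 99th), so that in untreated wells about 1%
#' of nuclei score positive.
#'
#' @param vehicle_nuclei per-nucleus table of vehicle wells
#' @param probs percentile used for both channels
#' @return named vector `mean_threshold`, `max_threshold`
#' @export
phh3_thresholds_from_vehicle <- function(vehicle_nuclei, probs = 0.99) {
  nb <- vehicle_nuclei[!vehicle_nuclei$border, , drop = FALSE]
  c(mean_threshold = unname(stats::quantile(nb$phh3_mean, probs)),
    max_threshold = unname(stats::quantile(nb$phh3_max, probs)))
}

#' Percent nuclei with condensed DNA
#'
#' Linear classifier: a nucleus is condensed when the weighted sum of
#' its features exceeds `threshold`. The default feature set (DNA
#' intensity density positively weighted, nuclear area negatively) is a
#' configurable stand-in for a screening platform's trained linear
#' classifier.
#'
#' @param nuclei per-nucleus data.frame containing the feature columns
#' @param threshold decision threshold on the linear score
#' @param weights named numeric vector: names are feature columns,
#'   values their weights
#' @return percent condensed (all nuclei in the denominator), with
#'   attribute `n_condensed`
#' @export
condensed_fraction <- function(nuclei, threshold,
                               weights = c(cond_density = 1, area = -0.01)) {
  miss <- setdiff(names(weights), names(nuclei))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  score <- as.matrix(nuclei[names(weights)]) %*% weights
  cond <- drop(score) > threshold
  structure(100 * sum(cond) / nrow(nuclei), n_condensed = sum(cond))
}

#' Cell-cycle fractions from DNA-content intensities
#'
#' Locates the G1 (2N) mode of the integrated DNA-intensity distribution
#' and gates nuclei at fixed multiples of it: sub-G1 below
#' `gates["sub_hi"]` x mode, G1 in `[sub_hi, g1_hi)`, S in
#' `[g1_hi, s_hi)`, G2/M in `[s_hi, g2m_hi]`; nuclei above `g2m_hi` are
#' reported separately as >4N and excluded from the normalization. The
#' four fractions sum to 100. Gating is invariant to a global linear
#' rescaling of the intensities.
#'
#' The G1 mode is the leftmost prominent density peak that has a
#' companion peak at about twice its position (the G2/M peak); with a
#' single-peaked distribution the global mode is used.
#'
#' @param dna_intensities integrated DNA intensities, one per nucleus
#'   (>= 100 nuclei recommended)
#' @param gates named vector of gate ratios relative to the G1 mode
#'   (defaults `sub_hi = 0.6`, `g1_hi = 1.3`, `s_hi = 1.7`,
#'   `g2m_hi = 2.6`)
#' @return named vector `subG1`, `G1`, `S`, `G2M` in percent (summing to
#'   100), with attributes `g1_mode` and `pct_over_4n`
#' @export
cell_cycle_fractions <- function(dna_intensities,
                                 gates = c(sub_hi = 0.6, g1_hi = 1.3,
                                           s_hi = 1.7, g2m_hi = 2.6)) {
  x <- dna_intensities[is.finite(dna_intensities) & dna_intensities > 0]
  if (length(x) < 10L) stop("too few nuclei for cell-cycle gating")
  if (length(x) < 100L) warning("fewer than 100 nuclei: gating is unstable")
  mode_g1 <- find_g1_mode(x)
  if (!is.finite(mode_g1)) stop("no detectable G1 mode")

  r <- x / mode_g1
  counts <- c(
    subG1 = sum(r < gates["sub_hi"]),
    G1 = sum(r >= gates["sub_hi"] & r < gates["g1_hi"]),
    S = sum(r >= gates["g1_hi"] & r < gates["s_hi"]),
    G2M = sum(r >= gates["s_hi"] & r <= gates["g2m_hi"])
  )
  over <- sum(r > gates["g2m_hi"])
  if (sum(counts) == 0L) stop("no nuclei fall inside the cell-cycle gates")
  out <- 100 * counts / sum(counts)
  names(out) <- c("subG1", "G1", "S", "G2M")
  attr(out, "g1_mode") <- mode_g1
  attr(out, "pct_over_4n") <- 100 * over / length(r)
  out
}

# G1-mode detection on the kernel density estimate. Peaks below 10% of
# the maximum density are ignored; among the remainder, prefer the
# leftmost peak that has a companion at 1.7-2.6x its position (a 4N
# peak), otherwise fall back to the global mode.
find_g1_mode <- function(x) {
  d <- stats::density(x, n = 512)
  y <- d$y
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(loc)) return(d$x[which.max(y)])
  loc <- loc[y[loc] >= 0.1 * max(y)]
  if (!length(loc)) return(d$x[which.max(y)])
  px <- d$x[loc]
  for (i in seq_along(px)) {
    ratio <- px / px[i]
    if (any(ratio >= 1.7 & ratio <= 2.6)) return(px[i])
  }
  d$x[which.max(y)]
}

#' Proliferation from nuclei counts
#'
#' Total nuclei per treated well as percent of the vehicle control; the
#' dose series of these values feeds [fit_sigmoid()] for a proliferation
#' IC50.
#'
#' @param n_treated,n_vehicle nuclei counts; `n_vehicle > 0`
#' @return percent of vehicle, vectorized over `n_treated`
#' @export
proliferation_from_counts <- function(n_treated, n_vehicle) {
  if (any(n_vehicle <= 0)) stop("vehicle count must be positive")
  100 * n_treated / n_vehicle
}

#' Per-well high-content summary
#'
#' Convenience wrapper bundling the mitotic index, condensed fraction
#' and cell-cycle fractions of one well's nuclei table.
#'
#' @param nuclei per-nucleus data.frame
#' @param phh3_mean_threshold,phh3_max_threshold pHH3 thresholds
#' @param condensed_threshold linear-score threshold
#' @param condensed_weights feature weights for the condensed classifier
#' @return list `n_nuclei`, `pct_phh3_positive`, `pct_condensed`,
#'   `cycle_fractions`
#' @export
well_summary <- function(nuclei, phh3_mean_threshold, phh3_max_threshold,
                         condensed_threshold,
                         condensed_weights = c(cond_density = 1, area = -0.01)) {
  list(
    n_nuclei = nrow(nuclei),
    pct_phh3_positive = classify_phh3(nuclei, phh3_mean_threshold,
                                      phh3_max_threshold),
    pct_condensed = condensed_fraction(nuclei, condensed_threshold,
                                       condensed_weights),
    cycle_fractions = cell_cycle_fractions(nuclei$dna_int)
  )
}
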