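# Target-engagement deconvolution: how much of each target's engagement
# is reached at the concentration that halves proliferation, the
# EC50(pHH3)/IC50(pPKB) ratio with the 20 uM non-responder convention,
# and the therapeutic-window report against plasma exposure.

# Fraction of maximal effect (0-100%) achieved at concentration x on a
# target curve, direction-aware: for inhibition readouts (hill < 0) the
# effect is the drop from the top asymptote; for activation readouts
# (hill > 0) the rise from the bottom.
target_effect <- function(fit, x) {
  y <- evaluate_sigmoid(fit, x)
  span <- fit$top - fit$bottom
  if (span <= 0) stop("degenerate target curve: top <= bottom")
  if (fit$hill_slope < 0) 100 * (fit$top - y) / span else 100 * (y - fit$bottom) / span
}

#' Target engagement at the growth IC50
#'
#' Evaluates the target-readout curve (e.g. pPKB inhibition or pHH3
#' induction) at the concentration that halves proliferation, and
#' expresses the result as percent of that target's maximal effect.
#'
#' @param prolif_fit non-ambiguous `sigmoid_fit` of the proliferation
#'   dose-response; its IC50 sets the evaluation concentration
#' @param target_fit non-ambiguous `sigmoid_fit` of the target readout
#' @return percent of maximal target effect (0-100). If the proliferation
#'   IC50 falls outside the target curve's tested concentration range the
#'   value carries attribute `extrapolated = TRUE`.
#' @export
engagement_at_growth_ic50 <- function(prolif_fit, target_fit) {
  stopifnot(inherits(prolif_fit, "sigmoid_fit"), inherits(target_fit, "sigmoid_fit"))
  if (isTRUE(prolif_fit$ambiguous) || isTRUE(target_fit$ambiguous)) {
    stop("both fits must be non-ambiguous")
  }
  x <- 10^prolif_fit$log_ic50
  eng <- target_effect(target_fit, x)
  rng <- target_fit$conc_range
  if (!is.null(rng) && (x < rng[1] || x > rng[2])) {
    attr(eng, "extrapolated") <- TRUE
  }
  eng
}

#' Ratio of mitotic arrest to PI3K inhibition potency
#'
#' `EC50(pHH3) / IC50(pPKB)` per cell line and drug. When a drug elicits
#' no detectable increase in the mitotic cell population the pHH3 EC50 is
#' replaced by the non-responder cap (20 uM by convention); pass
#' `ec50_phh3 = NA` for such drugs.
#'
#' @param mean_ec50_phh3 mean pHH3 EC50 in molar, or `NA` for a
#'   non-responder
#' @param mean_ic50_ppkb mean pPKB IC50 in molar, > 0
#' @param nonresponder_cap cap in molar (default `20e-6`)
#' @return dimensionless ratio; attribute `capped = TRUE` when the cap
#'   was applied
#' @export
mitosis_pi3k_ratio <- function(mean_ec50_phh3, mean_ic50_ppkb,
                               nonresponder_cap = 20e-6) {
  if (!is.finite(mean_ic50_ppkb) || mean_ic50_ppkb <= 0) {
    stop("IC50(pPKB) must be positive")
  }
  capped <- !is.finite(mean_ec50_phh3)
  num <- if (capped) nonresponder_cap else mean_ec50_phh3
  out <- num / mean_ic50_ppkb
  if (capped) attr(out, "capped") <- TRUE
  out
}

#' Concentration required for a given engagement level
#'
#' Inverse of the target curve at an engagement level expressed as
#' percent of the target's maximal effect.
#'
#' @param target_fit non-ambiguous `sigmoid_fit`
#' @param level percent of maximal effect, strictly inside (0, 100)
#' @return concentration in molar
#' @export
concentration_for_engagement <- function(target_fit, level) {
  stopifnot(inherits(target_fit, "sigmoid_fit"))
  if (level <= 0 || level >= 100) {
    stop("engagement level must lie strictly inside (0, 100)")
  }
  span <- target_fit$top - target_fit$bottom
  y <- if (target_fit$hill_slope < 0) {
    target_fit$top - level / 100 * span
  } else {
    target_fit$bottom + level / 100 * span
  }
  invert_sigmoid(target_fit, y)
}

#' Mean plasma concentration from a daily exposure AUC
#'
#' Steady-state average: `AUC0-24h / 24 h`.
#'
#' @param auc_0_24 area under the plasma concentration-time curve over
#'   24 h, in uM*h; must be > 0
#' @return mean plasma concentration in uM
#' @export
plasma_mean_concentration <- function(auc_0_24) {
  if (any(auc_0_24 <= 0)) stop("AUC must be positive")
  auc_0_24 / 24
}

#' Therapeutic window for selective PI3K inhibition
#'
#' The window is the concentration interval between (i) the concentration
#' reaching the required PI3K engagement and (ii) the concentration at
#' which the tolerated level of microtubule-destabilizing activity is
#' already exceeded. A window exists iff (i) < (ii); for a dual-activity
#' drug whose two curves sit on top of each other there is none.
#'
#' @param pi3k_fit non-ambiguous fit of the PI3K engagement readout
#' @param mda_fit non-ambiguous fit of the MDA readout (e.g. pHH3)
#' @param pi3k_required percent PI3K engagement that must be reached
#' @param mda_tolerated percent of maximal MDA effect still tolerated
#' @return list with `window_exists`, `window_low`, `window_high`,
#'   `reason`
#' @export
therapeutic_window <- function(pi3k_fit, mda_fit, pi3k_required, mda_tolerated) {
  low <- tryCatch(concentration_for_engagement(pi3k_fit, pi3k_required),
                  error = function(e) NA_real_)
  high <- tryCatch(concentration_for_engagement(mda_fit, mda_tolerated),
                   error = function(e) NA_real_)
  if (!is.finite(low) || !is.finite(high)) {
    return(list(window_exists = FALSE, window_low = low, window_high = high,
                reason = "required engagement level unreachable on a curve"))
  }
  exists <- low < high
  list(
    window_exists = exists, window_low = low, window_high = high,
    reason = if (exists) "PI3K engagement attainable below MDA-active concentrations"
             else "MDA activity sets in at or below the PI3K-effective concentration"
  )
}

#' Summarize engagement across cell lines
#'
#' Arithmetic mean and standard deviation (and, for convenience, the
#' standard error) of per-line engagement levels.
#'
#' @param levels numeric vector of per-line engagement percentages
#' @return named vector `mean`, `sd`, `sem`, `n`
#' @export
summarize_engagement <- function(levels) {
  levels <- levels[is.finite(levels)]
  n <- length(levels)
  c(mean = mean(levels), sd = stats::sd(levels),
    sem = stats::sd(levels) / sqrt(n), n = n)
}
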