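# TR-FRET competitive-binding analysis: emission ratio -> displacement
# IC50 -> Kd by the Cheng-Prusoff competition correction; plus
# AlphaScreen activity IC50s.

#' TR-FRET emission ratio
#'
#' Background (wells with buffer only) is subtracted from both channels
#' and the acceptor/donor ratio `(s665 - bg665) / (s620 - bg620)` is
#' formed. Wells whose background-corrected donor signal is non-positive
#' are returned as `NA` with a warning.
#'
#' @param s665,s620 raw acceptor (665 nm) and donor (620 nm) signals
#' @param mean_background_665,mean_background_620 mean signals of the
#'   background wells in each channel
#' @return dimensionless emission ratio, vectorized
#' @export
emission_ratio <- function(s665, s620, mean_background_665, mean_background_620) {
  den <- s620 - mean_background_620
  bad <- den <= 0
  if (any(bad)) {
    warning(sprintf("%d well(s) dropped: background-corrected 620 nm signal <= 0",
                    sum(bad)))
  }
  out <- (s665 - mean_background_665) / den
  out[bad] <- NA_real_
  out
}

#' Displacement IC50 from tracer emission ratios
#'
#' Fits the normalized sigmoidal dose-response model with variable slope
#' to emission ratios expressed as percent of the DMSO control.
#'
#' @param concs compound concentrations in molar
#' @param ratios_pct emission ratios as percent of the vehicle-control
#'   mean
#' @return a `sigmoid_fit` (normalized 3-parameter model)
#' @export
displacement_ic50 <- function(concs, ratios_pct) {
  keep <- is.finite(concs) & is.finite(ratios_pct)
  fit_sigmoid(data.frame(conc_M = concs[keep], response = ratios_pct[keep]),
              model = "normalized3p")
}

#' Kd from a competition IC50 (Cheng-Prusoff)
#'
#' Converts a tracer-displacement IC50 into a dissociation constant:
#' `Kd = IC50 / (1 + tracer_conc / kd_tracer)`. The correction only
#' shrinks, so `Kd <= IC50`; with vanishing tracer it is the identity.
#'
#' @param ic50 displacement IC50, molar
#' @param tracer_conc final tracer concentration in the assay, molar
#'   (one third of the printed 3x stock for an equal-volume 3-component
#'   mix)
#' @param kd_tracer dissociation constant of the tracer for the isoform,
#'   molar
#' @return Kd in molar
#' @export
kd_from_ic50 <- function(ic50, tracer_conc, kd_tracer) {
  if (any(c(ic50, tracer_conc, kd_tracer) <= 0)) {
    stop("all inputs must be positive")
  }
  ic50 / (1 + tracer_conc / kd_tracer)
}

#' Affinity fold between a compound and its regioisomer
#'
#' @param kd_parent Kd of the high-affinity parent compound, molar
#' @param kd_regioisomer Kd of the regioisomer, molar
#' @return fold loss of affinity, `kd_regioisomer / kd_parent`
#' @export
regioisomer_fold <- function(kd_parent, kd_regioisomer) {
  if (any(kd_parent <= 0) || any(kd_regioisomer <= 0)) {
    stop("Kd values must be positive")
  }
  kd_regioisomer / kd_parent
}

#' AlphaScreen activity IC50
#'
#' Normalizes raw AlphaScreen signals (relative luminescence units) to
#' the vehicle mean and fits the normalized variable-slope model.
#'
#' @param concs compound concentrations in molar
#' @param rlu raw AlphaScreen signals for the same wells
#' @param vehicle_rlu raw signals of vehicle wells defining 100%
#' @return a `sigmoid_fit`
#' @export
alphascreen_ic50 <- function(concs, rlu, vehicle_rlu) {
  v <- mean(vehicle_rlu)
  if (!is.finite(v) || v <= 0) stop("vehicle signal must be positive")
  fit_sigmoid(data.frame(conc_M = concs, response = 100 * rlu / v),
              model = "normalized3p")
}

#' Tracer constants for the class-I PI3K isoforms
#'
#' Tracer dissociation constants and final assay tracer concentrations
#' (printed 3x stocks divided by 3) used for Kd derivation, in molar.
#'
#' @return data.frame with `isoform`, `kd_tracer_M`, `tracer_conc_M`
#' @export
pi3k_tracer_constants <- function() {
  data.frame(
    isoform = c("p110alpha", "p110beta", "p110gamma", "p110delta"),
    kd_tracer_M = c(2.2e-9, 3.5e-9, 13.9e-9, 4.1e-9),
    tracer_conc_M = c(60e-9, 75e-9, 75e-9, 30e-9) / 3
  )
}

#' Full binding-plate analysis to a KdResult
#'
#' Runs emission ratios, vehicle normalization, displacement fit and the
#' Cheng-Prusoff correction on one isoform's plate.
#'
#' @param plate data.frame with columns `conc_M`, `s665`, `s620`, `role`
#'   (`"sample"`, `"vehicle"`, `"background"`)
#' @param kd_tracer,tracer_conc tracer constants in molar
#' @param isoform optional label carried into the result
#' @return list with `isoform`, `fit`, `ic50`, `kd`, `hill`
#' @export
binding_kd <- function(plate, kd_tracer, tracer_conc, isoform = NA_character_) {
  stopifnot(all(c("conc_M", "s665", "s620", "role") %in% names(plate)))
  bg <- plate[plate$role == "background", , drop = FALSE]
  if (nrow(bg) == 0L) stop("background wells are required")
  wells <- plate[plate$role != "background", , drop = FALSE]
  ratio <- emission_ratio(wells$s665, wells$s620, mean(bg$s665), mean(bg$s620))
  veh <- ratio[wells$role == "vehicle"]
  if (!length(veh) || mean(veh, na.rm = TRUE) <= 0) {
    stop("vehicle wells with positive emission ratio are required")
  }
  pct <- 100 * ratio / mean(veh, na.rm = TRUE)
  smp <- wells$role == "sample"
  fit <- displacement_ic50(wells$conc_M[smp], pct[smp])
  list(isoform = isoform, fit = fit, ic50 = ic50(fit),
       kd = kd_from_ic50(ic50(fit), tracer_conc, kd_tracer),
       hill = fit$hill_slope)
}
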