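# Raw-readout normalization to percent scales.

#' Normalize a 72 h viability plate to percent growth
#'
#' Percent growth after 72 h is
#' `100 * luminescence_t72 / luminescence_untreated_t72`, per well. When a
#' `t0` signal is supplied a doubling-time QC is computed from the
#' untreated 0 h and 72 h signals and attached as attribute
#' `doubling_time_h`; without `t0` the QC is skipped with a warning.
#'
#' @param raw_t72 data.frame of treated wells with columns `conc_M` and
#'   `luminescence` (additional id columns are carried through)
#' @param untreated_t72 scalar luminescence of the untreated 72 h control
#'   (vehicle wells), must be > 0
#' @param t0 optional scalar luminescence at the time of compound addition
#' @return `raw_t72` with a `response` column on the percent-growth scale
#' @export
normalize_viability <- function(raw_t72, untreated_t72, t0 = NULL) {
  stopifnot(is.data.frame(raw_t72),
            all(c("conc_M", "luminescence") %in% names(raw_t72)))
  if (!is.finite(untreated_t72) || untreated_t72 <= 0) {
    stop("untreated 72 h signal must be positive")
  }
  out <- raw_t72
  out$response <- 100 * out$luminescence / untreated_t72
  if (is.null(t0)) {
    warning("no t0 signal supplied; doubling-time QC skipped")
  } else {
    attr(out, "doubling_time_h") <- 72 * log(2) / log(untreated_t72 / t0)
  }
  out
}

#' Normalize an in-cell western plate to percent of DMSO
#'
#' Background (wells without primary antibody) is subtracted from both
#' channels, the target signal is corrected for cellular protein by the
#' tubulin channel, and the corrected ratio is expressed as percent of
#' the mean DMSO-control ratio (DMSO wells define 100%).
#'
#' @param plate data.frame with columns `conc_M`, `ppkb`, `tubulin` and
#'   `role` (one of `"sample"`, `"dmso"`, `"background"`)
#' @return data.frame of sample and DMSO wells with a `response` column
#'   (percent of DMSO). Wells whose background-corrected tubulin signal is
#'   non-positive are dropped with a warning.
#' @export
normalize_incellwestern <- function(plate) {
  stopifnot(is.data.frame(plate),
            all(c("conc_M", "ppkb", "tubulin", "role") %in% names(plate)))
  bg <- plate[plate$role == "background", , drop = FALSE]
  if (nrow(bg) == 0L) stop("background wells (no primary antibody) are required")
  bg_p <- mean(bg$ppkb)
  bg_t <- mean(bg$tubulin)

  wells <- plate[plate$role != "background", , drop = FALSE]
  tub <- wells$tubulin - bg_t
  bad <- tub <= 0
  if (any(bad)) {
    warning(sprintf("%d well(s) dropped: background-corrected tubulin <= 0", sum(bad)))
    wells <- wells[!bad, , drop = FALSE]
    tub <- tub[!bad]
  }
  ratio <- (wells$ppkb - bg_p) / tub
  dmso <- ratio[wells$role == "dmso"]
  if (length(dmso) == 0L) stop("DMSO control wells are required")
  wells$response <- 100 * ratio / mean(dmso)
  wells
}
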