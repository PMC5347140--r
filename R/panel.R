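# Panel-level mechanism classification: Hill-slope tables with the
# ambiguity exclusion rule, least-square penalty scores, relative
# sensitivity profiles and pHH3 fold-change summaries.

#' Hill-slope matrix for a cell-line x drug panel
#'
#' Builds the cell-line-by-drug matrix of fitted Hill slopes, excluding
#' every cell line that carries an ambiguous fit for at least one drug
#' (such lines are removed for all drugs, not just the offending one).
#'
#' @param fits data.frame with columns `cell_line`, `drug`, `hill_slope`
#'   and `ambiguous` (one row per fit)
#' @return list of class `hill_slope_table` with elements `slopes`
#'   (matrix, rows = retained cell lines), `excluded_lines` and `audit`
#'   (data.frame naming each excluded line and the drugs whose fits were
#'   ambiguous)
#' @export
hill_slope_table <- function(fits) {
  stopifnot(is.data.frame(fits),
            all(c("cell_line", "drug", "hill_slope", "ambiguous") %in% names(fits)))
  amb <- fits[fits$ambiguous, , drop = FALSE]
  excluded <- sort(unique(amb$cell_line))
  audit <- if (nrow(amb)) {
    stats::aggregate(drug ~ cell_line, data = amb,
                     FUN = function(d) paste(sort(unique(d)), collapse = ";"))
  } else {
    data.frame(cell_line = character(), drug = character())
  }
  keep <- fits[!(fits$cell_line %in% excluded), , drop = FALSE]
  if (nrow(keep) == 0L) stop("no cell lines remain after ambiguity exclusion")

  lines <- sort(unique(keep$cell_line))
  drugs <- sort(unique(keep$drug))
  m <- matrix(NA_real_, length(lines), length(drugs),
              dimnames = list(lines, drugs))
  m[cbind(match(keep$cell_line, lines), match(keep$drug, drugs))] <- keep$hill_slope
  structure(list(slopes = m, excluded_lines = excluded, audit = audit),
            class = "hill_slope_table")
}

#' @export
print.hill_slope_table <- function(x, ...) {
  cat(sprintf("<hill_slope_table> %d cell lines x %d drugs (%d line(s) excluded)\n",
              nrow(x$slopes), ncol(x$slopes), length(x$excluded_lines)))
  if (length(x$excluded_lines)) {
    cat("  excluded:", paste(x$excluded_lines, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Least-square penalty score for a drug pair
#'
#' Per cell line the penalty is the squared Hill-slope difference
#' `(h_a - h_b)^2`; the pair's score is the sum over all retained lines.
#' Like-mechanism pairs stay near baseline; pairing a steep-slope
#' (cytotoxic) drug with a slope-of-one (cytostatic) drug drives the sum
#' far above it.
#'
#' @param slopes_a,slopes_b named numeric vectors of Hill slopes on the
#'   same set of non-excluded cell lines
#' @param drug_a,drug_b optional identifiers carried into the result
#' @return list of class `penalty_score` with `per_line` and `total`
#' @export
penalty_score <- function(slopes_a, slopes_b, drug_a = "A", drug_b = "B") {
  if (length(slopes_a) != length(slopes_b)) {
    stop("slope vectors must be aligned on the same cell lines")
  }
  if (!is.null(names(slopes_a)) && !is.null(names(slopes_b)) &&
      !identical(names(slopes_a), names(slopes_b))) {
    stop("slope vectors must be aligned on the same cell lines")
  }
  per_line <- (slopes_a - slopes_b)^2
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         per_line = per_line, total = sum(per_line)),
    class = "penalty_score"
  )
}

#' @export
print.penalty_score <- function(x, ...) {
  cat(sprintf("<penalty_score> %s vs %s over %d lines: total = %.3g\n",
              x$drug_a, x$drug_b, length(x$per_line), x$total))
  invisible(x)
}

#' Pairwise penalty-score matrix
#'
#' @param slopes cell-line x drug matrix of Hill slopes (e.g.
#'   `hill_slope_table(...)$slopes`)
#' @return symmetric drug x drug matrix of total penalty scores
#' @export
penalty_score_matrix <- function(slopes) {
  drugs <- colnames(slopes)
  m <- matrix(0, length(drugs), length(drugs), dimnames = list(drugs, drugs))
  for (i in seq_along(drugs)) {
    for (j in seq_along(drugs)) {
      if (i < j) {
        m[i, j] <- m[j, i] <-
          penalty_score(slopes[, i], slopes[, j])$total
      }
    }
  }
  m
}

#' Relative drug-sensitivity profile of a panel
#'
#' Each IC50 is expressed relative to the arithmetic mean IC50 of all
#' cell lines for that drug; rows are ordered from most to least
#' sensitive for `sort_drug` (lowest relative IC50 first). Missing IC50s
#' are excluded from the per-drug mean and remain `NA` in the output.
#'
#' @param ic50s cell-line x drug matrix of IC50s (molar)
#' @param sort_drug drug (column name) whose sensitivity orders the rows
#' @return matrix of IC50s relative to the per-drug panel mean
#' @export
sensitivity_profile <- function(ic50s, sort_drug) {
  stopifnot(is.matrix(ic50s), sort_drug %in% colnames(ic50s))
  if (anyNA(ic50s)) warning("missing IC50(s): excluded from the per-drug mean")
  rel <- sweep(ic50s, 2, colMeans(ic50s, na.rm = TRUE), "/")
  rel[order(rel[, sort_drug]), , drop = FALSE]
}

#' Drug-induced fold change of pHH3-positive cells
#'
#' @param treated_fraction,vehicle_fraction percent pHH3-positive cells
#'   under drug and vehicle; vectorized
#' @return data.frame with `fold` (treated/vehicle) and `direction`
#'   (`"increased"`, `"decreased"`, `"unchanged"`, or `"undefined"` when
#'   the vehicle fraction is zero, flagged with a warning)
#' @export
phh3_fold_change <- function(treated_fraction, vehicle_fraction) {
  fold <- ifelse(vehicle_fraction > 0, treated_fraction / vehicle_fraction, NA_real_)
  if (anyNA(fold)) warning("zero vehicle fraction: fold change undefined")
  direction <- ifelse(is.na(fold), "undefined",
               ifelse(fold > 1, "increased",
               ifelse(fold < 1, "decreased", "unchanged")))
  data.frame(fold = fold, direction = direction)
}

#' Count panel cell lines with reduced mitotic index per drug
#'
#' @param folds data.frame with columns `drug`, `cell_line`, `fold`
#' @return data.frame per drug: lines tested, lines with fold < 1,
#'   lines with fold > 1
#' @export
phh3_panel_summary <- function(folds) {
  stopifnot(all(c("drug", "cell_line", "fold") %in% names(folds)))
  out <- do.call(rbind, lapply(split(folds, folds$drug), function(d) {
    data.frame(drug = d$drug[1], n = nrow(d),
               decreased = sum(d$fold < 1, na.rm = TRUE),
               increased = sum(d$fold > 1, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
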