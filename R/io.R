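# Readers/writers, run configuration and the pipeline driver.

dose_response_schema <- c("drug", "cell_line", "readout", "conc_M",
                          "response", "replicate", "is_vehicle")

#' Read and validate a tidy dose-response CSV
#'
#' Expects columns `drug`, `cell_line`, `readout`, `conc_M` (molar),
#' `response`, `replicate`, `is_vehicle`. Rows failing validation
#' (non-numeric or non-positive concentrations on non-vehicle rows,
#' non-finite responses) abort with the offending file line numbers.
#'
#' @param path CSV file path
#' @return validated data.frame
#' @export
read_dose_response_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(dose_response_schema, names(raw))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  conc <- suppressWarnings(as.numeric(raw$conc_M))
  vehicle <- as.logical(raw$is_vehicle)
  bad_num <- !vehicle & !is.finite(conc)
  bad_pos <- !vehicle & is.finite(conc) & conc <= 0
  bad_resp <- !is.finite(suppressWarnings(as.numeric(raw$response)))
  problems <- c(
    if (any(bad_num)) sprintf("non-numeric conc_M at line(s) %s",
                              paste(line_no[bad_num], collapse = ", ")),
    if (any(bad_pos)) sprintf("non-positive conc_M at line(s) %s",
                              paste(line_no[bad_pos], collapse = ", ")),
    if (any(bad_resp)) sprintf("non-finite response at line(s) %s",
                               paste(line_no[bad_resp], collapse = ", "))
  )
  if (length(problems)) stop(paste(problems, collapse = "; "))
  raw$conc_M <- conc
  raw$response <- as.numeric(raw$response)
  raw$is_vehicle <- vehicle
  raw
}

#' Write a tidy dose-response CSV
#' @param data dose-response data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dose_response_csv <- function(data, path) {
  utils::write.csv(data[dose_response_schema], path, row.names = FALSE)
  invisible(path)
}

#' Collect sigmoid fits into a flat table
#'
#' @param fits list of `sigmoid_fit` objects
#' @param meta data.frame with one row of identifiers (`cell_line`,
#'   `drug`, `readout`, ...) per fit
#' @return data.frame of fit parameters joined to `meta`
#' @export
fits_to_df <- function(fits, meta) {
  stopifnot(length(fits) == nrow(meta))
  pars <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      log_ic50 = f$log_ic50, ic50_M = 10^f$log_ic50,
      hill_slope = f$hill_slope, top = f$top, bottom = f$bottom,
      se_log_ic50 = f$se_log_ic50, se_hill = f$se_hill,
      model = f$model, converged = f$converged, ambiguous = f$ambiguous,
      rss = f$rss, n = f$n
    )
  }))
  cbind(meta, pars, row.names = NULL)
}

#' Default pipeline configuration
#'
#' All tunables of [run_pipeline()] with their defaults: the simulated
#' drug scenarios, panel size and noise, engagement thresholds (90%
#' PI3K engagement required, 20% MDA effect tolerated), the 20 uM
#' non-responder cap, and the pHH3 fold threshold below which a drug is
#' declared a mitotic non-responder.
#'
#' @return named list
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    n_lines = 4L,
    n_concs = 9L,
    n_replicates = 2L,
    noise_sd = 3,
    drugs = list(BKM120like = "bkm120_like",
                 PQR309like = "pqr309_like",
                 MTD147like = "mtd147_like",
                 GDC0941like = "pqr309_like"),
    pi3k_required = 90,
    mda_tolerated = 20,
    nonresponder_cap = 20e-6,
    phh3_responder_fold = 1.5,
    output_dir = NULL
  )
}

#' Read a pipeline configuration file
#'
#' YAML config; unspecified keys fall back to [default_run_config()].
#'
#' @param path YAML file path
#' @return configuration list
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  cfg
}

# per-drug mean curve across lines: average parameters of non-ambiguous fits
mean_fit <- function(fits) {
  fits <- Filter(function(f) !is.null(f) && !f$ambiguous, fits)
  if (!length(fits)) return(NULL)
  rng <- range(unlist(lapply(fits, function(f) f$conc_range)))
  new_sigmoid_fit(
    log_ic50 = mean(vapply(fits, function(f) f$log_ic50, 1)),
    hill_slope = mean(vapply(fits, function(f) f$hill_slope, 1)),
    top = mean(vapply(fits, function(f) f$top, 1)),
    bottom = mean(vapply(fits, function(f) f$bottom, 1)),
    se_log_ic50 = NA_real_, se_hill = NA_real_,
    model = fits[[1]]$model, converged = TRUE, ambiguous = FALSE,
    rss = NA_real_, n = sum(vapply(fits, function(f) f$n, 1)),
    conc_range = rng
  )
}

#' Run the deconvolution pipeline
#'
#' Drives the full analysis on either a tidy dose-response CSV or (by
#' default) panels produced by the synthetic generator: per-line fits
#' for viability (full 4PL), pPKB and pHH3; the Hill-slope table with
#' ambiguity exclusion; pairwise penalty scores; per-line engagement at
#' the growth IC50; the EC50(pHH3)/IC50(pPKB) ratio table with the
#' 20 uM non-responder cap; and a per-drug therapeutic-window report.
#' Every excluded well or line is logged. With `config$output_dir` set,
#' CSV/JSON outputs and the exclusion log are written there.
#'
#' @param config list as from [default_run_config()] or
#'   [read_run_config()]; `config$input_csv` switches from simulation to
#'   file input
#' @return (invisibly) list with `fits`, `hill_table`, `penalty_matrix`,
#'   `engagement`, `ratios`, `windows`, `log`
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- utils::modifyList(default_run_config(), config)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(cfg$input_csv)) {
    panel <- read_dose_response_csv(cfg$input_csv)
    note("input: %s (%d rows)", cfg$input_csv, nrow(panel))
  } else {
    panels <- lapply(seq_along(cfg$drugs), function(i) {
      kind <- cfg$drugs[[i]]
      spec <- if (kind %in% c("bkm120_like", "pqr309_like", "mtd147_like")) {
        scenario_spec(kind, noise_sd = cfg$noise_sd)
      } else {
        mechanism_spec(kind = kind, noise_sd = cfg$noise_sd)
      }
      gen_panel(spec, seed = cfg$seed + i, n_lines = cfg$n_lines,
                n_concs = cfg$n_concs, n_replicates = cfg$n_replicates,
                drug = names(cfg$drugs)[i])
    })
    panel <- do.call(rbind, panels)
    note("simulated %d drug(s) x %d line(s), seed %d",
         length(cfg$drugs), cfg$n_lines, cfg$seed)
  }

  groups <- split(panel, list(panel$drug, panel$cell_line, panel$readout),
                  drop = TRUE)
  meta <- do.call(rbind, lapply(groups, function(g) {
    data.frame(drug = g$drug[1], cell_line = g$cell_line[1],
               readout = g$readout[1])
  }))
  fits <- lapply(groups, function(g) {
    model <- if (g$readout[1] %in% c("pPKB", "binding_ratio")) {
      "normalized3p"
    } else "full4p"
    fit_sigmoid(g[!g$is_vehicle, c("conc_M", "response")], model = model)
  })
  fit_df <- fits_to_df(fits, meta)
  for (k in which(fit_df$ambiguous)) {
    note("ambiguous fit: %s / %s / %s", fit_df$drug[k], fit_df$cell_line[k],
         fit_df$readout[k])
  }

  viab <- fit_df[fit_df$readout == "viability", ]
  hill_tab <- hill_slope_table(viab[, c("cell_line", "drug", "hill_slope",
                                        "ambiguous")])
  for (ln in hill_tab$excluded_lines) {
    note("cell line excluded from slope panel (ambiguous fit): %s", ln)
  }
  pen <- if (ncol(hill_tab$slopes) >= 2) penalty_score_matrix(hill_tab$slopes)
         else NULL

  key <- function(d, l, r) fits[[paste(d, l, r, sep = ".")]]
  drugs <- unique(fit_df$drug)
  lines <- unique(fit_df$cell_line)
  eng <- list(); ratios <- list(); windows <- list()
  for (d in drugs) {
    phh3_responder <- FALSE
    for (l in lines) {
      fv <- key(d, l, "viability"); fp <- key(d, l, "pPKB")
      fh <- key(d, l, "pHH3")
      if (is.null(fv) || fv$ambiguous) next
      prolif_ic50 <- 10^fv$log_ic50
      pi3k_eng <- if (!is.null(fp) && !fp$ambiguous) {
        engagement_at_growth_ic50(fv, fp)
      } else NA_real_
      # mitotic non-responder: induced fold over baseline below threshold
      h_responds <- !is.null(fh) && !fh$ambiguous && fh$hill_slope > 0 &&
        fh$bottom > 0 && (fh$top / fh$bottom) >= cfg$phh3_responder_fold
      mda_eng <- if (h_responds) engagement_at_growth_ic50(fv, fh) else NA_real_
      if (h_responds) phh3_responder <- TRUE
      ec50_phh3 <- if (h_responds) 10^fh$log_ic50 else NA_real_
      ic50_ppkb <- if (!is.null(fp) && !fp$ambiguous) 10^fp$log_ic50 else NA_real_
      eng[[paste(d, l)]] <- data.frame(
        drug = d, cell_line = l, prolif_ic50_M = prolif_ic50,
        pi3k_engagement_at_ic50 = as.numeric(pi3k_eng),
        mda_engagement_at_ic50 = as.numeric(mda_eng)
      )
      if (is.finite(ic50_ppkb)) {
        r <- mitosis_pi3k_ratio(ec50_phh3, ic50_ppkb, cfg$nonresponder_cap)
        ratios[[paste(d, l)]] <- data.frame(
          drug = d, cell_line = l, ec50_phh3_M = ec50_phh3,
          ic50_ppkb_M = ic50_ppkb, ratio = as.numeric(r),
          capped = isTRUE(attr(r, "capped"))
        )
        if (isTRUE(attr(r, "capped"))) {
          note("pHH3 non-responder, EC50 capped at %.3g M: %s / %s",
               cfg$nonresponder_cap, d, l)
        }
      }
    }
    fp_m <- mean_fit(lapply(lines, function(l) key(d, l, "pPKB")))
    fh_m <- if (phh3_responder) {
      mean_fit(Filter(function(f) !is.null(f) && f$hill_slope > 0,
                      lapply(lines, function(l) key(d, l, "pHH3"))))
    } else NULL
    windows[[d]] <- if (is.null(fp_m)) {
      list(drug = d, window_exists = FALSE, window_low = NA_real_,
           window_high = NA_real_, reason = "no usable PI3K engagement curve")
    } else if (is.null(fh_m)) {
      list(drug = d, window_exists = TRUE,
           window_low = concentration_for_engagement(fp_m, cfg$pi3k_required),
           window_high = Inf, reason = "no MDA activity detected")
    } else {
      c(list(drug = d),
        therapeutic_window(fp_m, fh_m, cfg$pi3k_required, cfg$mda_tolerated))
    }
  }
  eng <- do.call(rbind, c(eng, list(make.row.names = FALSE)))
  ratios <- do.call(rbind, c(ratios, list(make.row.names = FALSE)))

  out <- list(fits = fit_df, hill_table = hill_tab, penalty_matrix = pen,
              engagement = eng, ratios = ratios, windows = windows,
              log = log_lines)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fit_df, file.path(cfg$output_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(hill_tab$slopes),
                     file.path(cfg$output_dir, "hill_slopes.csv"))
    if (!is.null(pen)) {
      utils::write.csv(as.data.frame(pen),
                       file.path(cfg$output_dir, "penalty_scores.csv"))
    }
    if (!is.null(eng)) {
      utils::write.csv(eng, file.path(cfg$output_dir, "engagement.csv"),
                       row.names = FALSE)
    }
    if (!is.null(ratios)) {
      utils::write.csv(ratios, file.path(cfg$output_dir, "ratios.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(windows,
                         file.path(cfg$output_dir, "window_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(cfg$output_dir, "exclusions.log"))
  }
  invisible(out)
}
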