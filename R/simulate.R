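# Seeded synthetic-data generators. Every generator is a pure function
# of (spec, seed): the same seed and spec give bitwise-identical tables,
# and the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Mechanism specification for the panel generator
#'
#' Describes a drug as a combination of a cytostatic PI3K-inhibitor arm
#' (viability Hill slope near -1) and/or a cytotoxic
#' microtubule-destabilizing arm (viability Hill slope steeper than -2).
#' Growth-arm EC50s default to 1 uM for both mechanisms. Two coupling
#' ratios tie the target-engagement readouts to the growth arms:
#' `ppkb_ec50_ratio` places the pPKB IC50 well below the PI3K growth
#' EC50 (default 1/9, so that 90% PI3K inhibition is reached exactly at
#' the growth EC50 of a pure PI3K inhibitor), and `phh3_ec50_ratio`
#' places the pHH3 EC50 above the MDA growth EC50 (default 1.8 with
#' Hill +2, so that ~24% of maximal mitotic arrest suffices for
#' half-maximal growth inhibition).
#'
#' @param kind `"pi3k_cytostatic"`, `"mda_cytotoxic"` or `"dual"`
#' @param pi3k_ec50,mda_ec50 growth-arm EC50s, molar
#' @param pi3k_hill,mda_hill growth-arm Hill slopes (negative)
#' @param ppkb_ec50_ratio pPKB IC50 as a fraction of the PI3K growth EC50
#' @param phh3_ec50_ratio pHH3 EC50 as a multiple of the MDA growth EC50
#' @param phh3_hill Hill slope of the pHH3 activation curve (positive)
#' @param line_ic50_dispersion log10 s.d. of the per-line sensitivity
#'   factor shared by both arms (cell-line panels show correlated
#'   sensitivity across drugs, which is what makes sensitivity profiles
#'   informative)
#' @param arm_jitter log10 s.d. of the small arm-specific scatter on top
#'   of the shared line factor
#' @param noise_sd Gaussian noise s.d. on percent responses
#' @return list of class `mechanism_spec`
#' @export
mechanism_spec <- function(kind = c("pi3k_cytostatic", "mda_cytotoxic", "dual"),
                           pi3k_ec50 = 1e-6, pi3k_hill = -1,
                           mda_ec50 = 1e-6, mda_hill = -3,
                           ppkb_ec50_ratio = 1 / 9, phh3_ec50_ratio = 1.8,
                           phh3_hill = 2,
                           line_ic50_dispersion = 0.25, arm_jitter = 0.05,
                           noise_sd = 5) {
  kind <- match.arg(kind)
  stopifnot(pi3k_hill < 0, mda_hill < 0, phh3_hill > 0,
            line_ic50_dispersion >= 0, arm_jitter >= 0, noise_sd >= 0)
  structure(
    list(kind = kind, pi3k_ec50 = pi3k_ec50, pi3k_hill = pi3k_hill,
         mda_ec50 = mda_ec50, mda_hill = mda_hill,
         ppkb_ec50_ratio = ppkb_ec50_ratio,
         phh3_ec50_ratio = phh3_ec50_ratio, phh3_hill = phh3_hill,
         line_ic50_dispersion = line_ic50_dispersion,
         arm_jitter = arm_jitter, noise_sd = noise_sd),
    class = "mechanism_spec"
  )
}

#' Named drug scenarios
#'
#' Shorthand specs for the three study archetypes: a dual PI3K/MDA drug
#' (`"bkm120_like"`), a pure cytostatic pan-PI3K inhibitor
#' (`"pqr309_like"`) and a pure cytotoxic microtubule destabilizer
#' (`"mtd147_like"`). Growth EC50s sit at about 1 uM in all three; for
#' the dual drug the MDA arm (0.9 uM) lies just below the PI3K growth
#' arm (1.4 uM), matching the observation that its proliferation IC50 is
#' microtubule-driven while near-complete PI3K engagement is only
#' reached slightly above it.
#'
#' @param name scenario name
#' @param ... overrides passed to [mechanism_spec()]
#' @return a `mechanism_spec`
#' @export
scenario_spec <- function(name = c("bkm120_like", "pqr309_like", "mtd147_like"),
                          ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    bkm120_like = list(kind = "dual", pi3k_ec50 = 1.4e-6, mda_ec50 = 0.9e-6),
    pqr309_like = list(kind = "pi3k_cytostatic"),
    mtd147_like = list(kind = "mda_cytotoxic")
  )
  do.call(mechanism_spec, utils::modifyList(defaults, list(...)))
}

# 0..1 activation/inhibition fractions of the two arms
arm_fractions <- function(spec, x, line_pi3k = 1, line_mda = 1) {
  f_pi3k <- four_pl(x, log10(spec$pi3k_ec50 * line_pi3k), spec$pi3k_hill, 1, 0)
  f_mda <- four_pl(x, log10(spec$mda_ec50 * line_mda), spec$mda_hill, 1, 0)
  list(pi3k = f_pi3k, mda = f_mda)
}

# surviving fraction under response independence (Bliss-type product)
survival_fraction <- function(spec, x, line_pi3k = 1, line_mda = 1) {
  f <- arm_fractions(spec, x, line_pi3k, line_mda)
  switch(spec$kind,
    pi3k_cytostatic = f$pi3k,
    mda_cytotoxic = f$mda,
    dual = f$pi3k * f$mda
  )
}

#' Generate a synthetic dose-response panel
#'
#' Emulates a cell-line panel screened with a 9-point 3.16-fold dilution
#' series (3.16 nM to 31.6 uM): per cell line, growth-arm EC50s are
#' drawn lognormally around the spec values; viability of a
#' dual-mechanism drug composes the two arms by response independence
#' (product of surviving fractions); pPKB follows the PI3K arm, pHH3
#' (an activation readout, percent positive cells) follows the MDA arm;
#' Gaussian noise is added to every well.
#'
#' @param spec a [mechanism_spec()]
#' @param seed integer seed; identical seed and spec give identical
#'   tables
#' @param n_lines number of cell lines
#' @param n_concs points in the dilution series
#' @param n_replicates replicate wells per concentration
#' @param drug label written into the `drug` column
#' @param phh3_base vehicle percent of pHH3-positive cells
#' @param phh3_max maximal percent positive under full mitotic arrest
#' @return data.frame with columns `drug`, `cell_line`, `readout`
#'   (`viability`, `pPKB`, `pHH3`), `conc_M`, `response`, `replicate`,
#'   `is_vehicle`; per-line true parameters in attribute `truth`
#' @export
gen_panel <- function(spec, seed, n_lines = 5, n_concs = 9, n_replicates = 2,
                      drug = spec$kind, phh3_base = 2, phh3_max = 30) {
  stopifnot(inherits(spec, "mechanism_spec"))
  with_seed(seed, {
    concs <- 3.16e-9 * 3.16^(seq_len(n_concs) - 1)
    lines <- sprintf("line%02d", seq_len(n_lines))
    line_factor <- 10^stats::rnorm(n_lines, 0, spec$line_ic50_dispersion)
    truth <- data.frame(
      cell_line = lines,
      line_factor = line_factor,
      pi3k_factor = line_factor * 10^stats::rnorm(n_lines, 0, spec$arm_jitter),
      mda_factor = line_factor * 10^stats::rnorm(n_lines, 0, spec$arm_jitter)
    )
    rows <- vector("list", n_lines)
    for (i in seq_len(n_lines)) {
      lp <- truth$pi3k_factor[i]; lm <- truth$mda_factor[i]
      viab <- 100 * survival_fraction(spec, concs, lp, lm)
      ppkb <- if (spec$kind == "mda_cytotoxic") {
        rep(100, n_concs)
      } else {
        100 * four_pl(concs, log10(spec$pi3k_ec50 * lp * spec$ppkb_ec50_ratio),
                      spec$pi3k_hill, 1, 0)
      }
      act_mda <- four_pl(concs, log10(spec$mda_ec50 * lm * spec$phh3_ec50_ratio),
                         spec$phh3_hill, 1, 0)
      act_pi3k <- 1 - four_pl(concs,
                              log10(spec$pi3k_ec50 * lp * spec$ppkb_ec50_ratio),
                              spec$pi3k_hill, 1, 0)
      phh3 <- switch(spec$kind,
        mda_cytotoxic = phh3_base + (phh3_max - phh3_base) * act_mda,
        dual = phh3_base + (phh3_max - phh3_base) * act_mda,
        pi3k_cytostatic = phh3_base * (1 - 0.5 * act_pi3k)
      )
      per_readout <- list(viability = viab, pPKB = ppkb, pHH3 = phh3)
      noise_scale <- c(viability = 1, pPKB = 1, pHH3 = 0.1)
      sub <- lapply(names(per_readout), function(rd) {
        mu <- rep(per_readout[[rd]], times = n_replicates)
        data.frame(
          drug = drug, cell_line = lines[i], readout = rd,
          conc_M = rep(concs, times = n_replicates),
          response = mu + stats::rnorm(length(mu),
                                       0, spec$noise_sd * noise_scale[[rd]]),
          replicate = rep(seq_len(n_replicates), each = n_concs),
          is_vehicle = FALSE
        )
      })
      rows[[i]] <- do.call(rbind, sub)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Generate a synthetic per-nucleus feature table
#'
#' Emulates one well of a DNA-content / pHH3 high-content acquisition:
#' a mixture of sub-G1, G1 (2N), S and G2/M (4N) nuclei with lognormal
#' DNA-intensity peaks at 1x and 2x the G1 mode, a bimodal pHH3
#' intensity distribution, border flags, and the two condensed-DNA
#' classifier features. Under an MDA-arm spec increasing `dose` shifts
#' nuclei toward G2/M and sub-G1 and raises the pHH3-positive fraction;
#' under a PI3K spec it shifts them toward G1 and lowers it.
#'
#' @param spec a [mechanism_spec()]
#' @param dose concentration in molar (0 for vehicle)
#' @param seed integer seed
#' @param n number of nuclei
#' @param baseline_fractions vehicle cell-cycle composition (named:
#'   `subG1`, `G1`, `S`, `G2M`; must sum to 1)
#' @param g1_mode integrated DNA intensity of the G1 peak (a.u.)
#' @param phh3_positive override the pHH3-positive fraction (0-1);
#'   `NULL` derives it from the spec and dose
#' @return per-nucleus data.frame with `dna_int`, `phh3_mean`,
#'   `phh3_max`, `border`, `cond_density`, `area`, plus ground-truth
#'   columns `true_phase` and `true_phh3`
#' @export
gen_nuclei <- function(spec, dose, seed, n = 2000,
                       baseline_fractions = c(subG1 = 0.02, G1 = 0.60,
                                              S = 0.14, G2M = 0.24),
                       g1_mode = 1e6, phh3_positive = NULL) {
  stopifnot(inherits(spec, "mechanism_spec"),
            abs(sum(baseline_fractions) - 1) < 1e-8)
  with_seed(seed, {
    w_mda <- if (dose > 0 && spec$kind != "pi3k_cytostatic") {
      four_pl(dose, log10(spec$mda_ec50 * spec$phh3_ec50_ratio),
              spec$phh3_hill, 1, 0)
    } else 0
    w_pi3k <- if (dose > 0 && spec$kind != "mda_cytotoxic") {
      1 - four_pl(dose, log10(spec$pi3k_ec50 * spec$ppkb_ec50_ratio),
                  spec$pi3k_hill, 1, 0)
    } else 0

    target <- if (spec$kind == "pi3k_cytostatic") {
      c(subG1 = 0.01, G1 = 0.85, S = 0.04, G2M = 0.10)
    } else {
      c(subG1 = 0.15, G1 = 0.15, S = 0.05, G2M = 0.65)
    }
    w <- if (spec$kind == "pi3k_cytostatic") w_pi3k else w_mda
    frac <- (1 - w) * baseline_fractions[c("subG1", "G1", "S", "G2M")] +
      w * target
    phase <- sample(names(frac), n, replace = TRUE, prob = frac)

    dna <- numeric(n)
    # apoptotic debris forms a broad smear below 2N, not a sharp peak
    dna[phase == "subG1"] <- g1_mode *
      stats::runif(sum(phase == "subG1"), 0.2, 0.55)
    dna[phase == "G1"] <- g1_mode * exp(stats::rnorm(sum(phase == "G1"), 0, 0.06))
    dna[phase == "S"] <- g1_mode * stats::runif(sum(phase == "S"), 1.35, 1.65)
    dna[phase == "G2M"] <- 2 * g1_mode *
      exp(stats::rnorm(sum(phase == "G2M"), 0, 0.06))

    p_pos <- if (!is.null(phh3_positive)) {
      phh3_positive
    } else if (spec$kind == "pi3k_cytostatic") {
      0.02 * (1 - 0.5 * w_pi3k)
    } else {
      0.02 + 0.28 * w_mda
    }
    pos <- stats::runif(n) < p_pos
    phh3_mean <- ifelse(pos, 500 * exp(stats::rnorm(n, 0, 0.2)),
                        50 * exp(stats::rnorm(n, 0, 0.3)))
    phh3_max <- ifelse(pos, 1500 * exp(stats::rnorm(n, 0, 0.2)),
                       150 * exp(stats::rnorm(n, 0, 0.3)))

    p_cond <- if (spec$kind == "pi3k_cytostatic") 0.02 else 0.02 + 0.3 * w_mda
    cond <- stats::runif(n) < p_cond
    cond_density <- ifelse(cond, stats::rnorm(n, 3, 0.3), stats::rnorm(n, 1, 0.2))
    area <- ifelse(cond, stats::rnorm(n, 40, 8), stats::rnorm(n, 120, 20))

    data.frame(
      dna_int = dna, phh3_mean = phh3_mean, phh3_max = phh3_max,
      border = stats::runif(n) < 0.10,
      cond_density = cond_density, area = area,
      true_phase = phase, true_phh3 = pos
    )
  })
}

#' Generate a synthetic kymograph event table
#'
#' Growth durations are exponential with rate `f_cat_per_min` (the
#' dynamic-instability switching model); growth lengths are velocity x
#' duration with multiplicative noise; every growth phase is followed by
#' a shortening phase whose end fate is a rescue with probability
#' `f_res_per_s / shortening_rate_per_s`, so that rescues per total
#' shortening time equal `f_res_per_s` in expectation.
#'
#' @param v_g_um_min growth velocity, um/min
#' @param f_cat_per_min catastrophe rate, per minute of growth
#' @param f_res_per_s rescue rate, per second of shortening
#' @param n_events growth events per movie
#' @param seed integer seed
#' @param n_movies number of movies (or cells)
#' @param noise multiplicative s.d. on lengths
#' @param shortening_rate_per_s termination rate of shortening phases
#' @param v_s_um_min shortening velocity, um/min
#' @return kymograph event data.frame (`movie_or_cell_id`, `phase`,
#'   `length_um`, `duration_s`, `end_fate`, `complete`)
#' @export
gen_kymo_events <- function(v_g_um_min = 2, f_cat_per_min = 0.3,
                            f_res_per_s = 0.005, n_events = 50, seed = 1,
                            n_movies = 3, noise = 0.05,
                            shortening_rate_per_s = 0.05, v_s_um_min = 15) {
  stopifnot(f_res_per_s <= shortening_rate_per_s)
  with_seed(seed, {
    rows <- lapply(seq_len(n_movies), function(m) {
      dur_min <- stats::rexp(n_events, rate = f_cat_per_min)
      g_len <- pmax(v_g_um_min * dur_min * (1 + stats::rnorm(n_events, 0, noise)),
                    1e-3)
      s_dur <- stats::rexp(n_events, rate = shortening_rate_per_s)
      rescued <- stats::runif(n_events) < f_res_per_s / shortening_rate_per_s
      rbind(
        data.frame(
          movie_or_cell_id = sprintf("movie%02d", m), phase = "growth",
          length_um = g_len, duration_s = 60 * dur_min,
          end_fate = "catastrophe", complete = TRUE
        ),
        data.frame(
          movie_or_cell_id = sprintf("movie%02d", m), phase = "shortening",
          length_um = v_s_um_min * s_dur / 60, duration_s = s_dur,
          end_fate = ifelse(rescued, "rescue", "unresolved"), complete = TRUE
        )
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic TR-FRET competitive-binding plate
#'
#' Tracer occupancy follows the competitive one-site model
#' `bound = L / (L + Kd_tracer * (1 + I / Kd_I))`; acceptor signals are
#' a baseline plus a term proportional to occupancy, donor signals are
#' constant, and both carry multiplicative noise. Background wells
#' contain buffer only.
#'
#' @param kd_i true compound dissociation constant, molar
#' @param kd_tracer tracer Kd for the isoform, molar
#' @param tracer_conc final tracer concentration, molar
#' @param concs compound concentrations, molar (default: 11-point
#'   fourfold series from 40 uM, i.e. a 120 uM 3x stock diluted 3-fold)
#' @param seed integer seed
#' @param noise_sd multiplicative noise s.d. on signals
#' @param n_replicates wells per concentration
#' @return plate data.frame (`well`, `role`, `conc_M`, `s665`, `s620`)
#' @export
gen_binding <- function(kd_i, kd_tracer, tracer_conc,
                        concs = (120e-6 / 3) * 4^-(0:10), seed = 1,
                        noise_sd = 0.005, n_replicates = 2) {
  with_seed(seed, {
    occ <- function(I) tracer_conc / (tracer_conc + kd_tracer * (1 + I / kd_i))
    conc_all <- rep(concs, each = n_replicates)
    n_s <- length(conc_all)
    mk <- function(role, conc, o, n) {
      data.frame(
        well = paste0(role, seq_len(n)), role = role, conc_M = conc,
        s665 = (500 + 18000 * o) * (1 + stats::rnorm(n, 0, noise_sd)),
        s620 = (300 + 10000 * ifelse(role == "background", 0, 1)) *
          (1 + stats::rnorm(n, 0, noise_sd))
      )
    }
    out <- rbind(
      mk("sample", conc_all, occ(conc_all), n_s),
      mk("vehicle", 0, occ(0), 4),
      mk("background", NA_real_, 0, 4)
    )
    rownames(out) <- NULL
    out
  })
}
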