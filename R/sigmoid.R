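# Variable-slope logistic (4PL) on the log10-concentration scale:
#   y = bottom + (top - bottom) / (1 + 10^((log_ic50 - log10(x)) * hill))
# hill < 0 gives a response falling with concentration (inhibition
# readouts); hill > 0 a rising response (e.g. pHH3 activation).

#' Four-parameter logistic model function
#'
#' `bottom + (top - bottom) / (1 + 10^((log_ic50 - log10(x)) * hill))`.
#' Negative `hill` values describe inhibition readouts (response falls
#' with concentration), positive values activation readouts.
#'
#' @param x concentration, molar
#' @param log_ic50 log10 of the half-maximal concentration (log10 molar)
#' @param hill Hill slope
#' @param top,bottom asymptotic maximum/minimum response (percent)
#' @return response on the percent scale
#' @export
four_pl <- function(x, log_ic50, hill, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - log10(x)) * hill))
}

four_pl_log <- function(lx, log_ic50, hill, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + 10^((log_ic50 - lx) * hill))
}

new_sigmoid_fit <- function(log_ic50, hill_slope, top, bottom,
                            se_log_ic50, se_hill, model, converged,
                            ambiguous, rss, n, conc_range) {
  structure(
    list(
      log_ic50 = log_ic50, hill_slope = hill_slope,
      top = top, bottom = bottom,
      se_log_ic50 = se_log_ic50, se_hill = se_hill,
      model = model, converged = converged, ambiguous = ambiguous,
      rss = rss, n = n, conc_range = conc_range
    ),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit %s>  IC50 = %.4g M  hill = %.3g  top = %.4g  bottom = %.4g\n",
    x$model, 10^x$log_ic50, x$hill_slope, x$top, x$bottom
  ))
  cat(sprintf(
    "  se(logIC50) = %.3g  se(hill) = %.3g  rss = %.4g  converged: %s  ambiguous: %s\n",
    x$se_log_ic50, x$se_hill, x$rss, x$converged, x$ambiguous
  ))
  invisible(x)
}

#' Fit a variable-slope logistic dose-response curve
#'
#' Fits either the normalized 3-parameter model (top fixed at 100, bottom
#' at 0; only `log_ic50` and the Hill slope are free) or the full
#' 4-parameter logistic, by damped least squares
#' (Levenberg-Marquardt, [minpack.lm::nls.lm()]) with a multi-start over
#' Hill-slope magnitudes \{0.5, 1, 2, 4\} and log-IC50 starting values at
#' the quartiles of the tested concentration range. Steep-slope objectives
#' are multimodal, hence the multi-start; the best residual sum of squares
#' wins and ties go to the shallower slope.
#'
#' A fit is flagged `ambiguous` (and its Hill slope must not be used for
#' mechanism classification downstream) when any of these hold:
#' the optimizer fails to converge from every start; the relative standard
#' error of the Hill slope exceeds 0.5; or the fitted IC50 lies more than
#' one log10 unit outside the tested concentration range.
#'
#' @param data data.frame with columns `conc_M` (molar, strictly positive)
#'   and `response` (percent scale). Replicate wells are fitted jointly as
#'   individual points.
#' @param model `"normalized3p"` or `"full4p"`. The full model enforces
#'   `top >= bottom` by parameterizing the span `top - bottom >= 0`.
#' @return A `sigmoid_fit` object: `log_ic50` (log10 molar), `hill_slope`,
#'   `top`, `bottom`, standard errors from the local curvature of the
#'   objective, `converged`, `ambiguous`, `rss`, `n`, and the tested
#'   concentration range.
#' @examples
#' x <- 3.16e-9 * 3.16^(0:8)
#' d <- data.frame(conc_M = x, response = four_pl(x, -6, -1))
#' fit_sigmoid(d)
#' @export
fit_sigmoid <- function(data, model = c("normalized3p", "full4p")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data), all(c("conc_M", "response") %in% names(data)))
  conc <- data$conc_M
  resp <- data$response
  keep <- is.finite(conc) & is.finite(resp)
  conc <- conc[keep]; resp <- resp[keep]
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(conc)) < 4L) {
    stop("at least 4 distinct concentrations are required for fitting")
  }
  lx <- log10(conc)
  rng <- range(lx)

  # direction of the response decides the sign of the hill-slope starts
  dir <- suppressWarnings(stats::cor(lx, resp, method = "spearman"))
  hill_mags <- c(0.5, 1, 2, 4)
  hills <- if (!is.finite(dir) || abs(dir) < 0.2) {
    c(-hill_mags, hill_mags)
  } else if (dir < 0) -hill_mags else hill_mags
  l_starts <- unname(stats::quantile(rng, c(0.25, 0.5, 0.75)))

  resid_fn <- if (model == "normalized3p") {
    function(p) resp - four_pl_log(lx, p[1], p[2])
  } else {
    function(p) resp - four_pl_log(lx, p[1], p[2], p[3] + p[4], p[3])
  }

  best <- NULL
  for (h0 in hills) {
    for (l0 in l_starts) {
      p0 <- if (model == "normalized3p") c(l0, h0) else {
        c(l0, h0, min(resp), max(diff(range(resp)), 1))
      }
      lower <- if (model == "normalized3p") c(-Inf, -Inf) else c(-Inf, -Inf, -Inf, 0)
      res <- tryCatch(
        minpack.lm::nls.lm(
          par = p0, fn = resid_fn, lower = lower,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(res)) next
      rss <- sum(res$fvec^2)
      ok <- res$info %in% 1:4
      if (is.null(best) ||
          rss < best$rss * (1 - 1e-9) ||
          (abs(rss - best$rss) <= 1e-9 * max(rss, 1) &&
           abs(res$par[2]) < abs(best$par[2]))) {
        best <- list(par = res$par, rss = rss, ok = ok)
      }
    }
  }

  n <- length(resp)
  if (is.null(best)) {
    return(new_sigmoid_fit(NA_real_, NA_real_,
      top = if (model == "normalized3p") 100 else NA_real_,
      bottom = if (model == "normalized3p") 0 else NA_real_,
      se_log_ic50 = NA_real_, se_hill = NA_real_, model = model,
      converged = FALSE, ambiguous = TRUE, rss = NA_real_, n = n,
      conc_range = 10^rng
    ))
  }

  p <- best$par
  if (model == "normalized3p") {
    top <- 100; bottom <- 0
  } else {
    bottom <- p[3]; top <- p[3] + p[4]
  }

  se <- fit_standard_errors(resid_fn, p, n)
  ambiguous <- !best$ok ||
    !is.finite(se[2]) ||
    abs(se[2] / p[2]) > 0.5 ||
    p[1] < rng[1] - 1 || p[1] > rng[2] + 1

  new_sigmoid_fit(
    log_ic50 = p[1], hill_slope = p[2], top = top, bottom = bottom,
    se_log_ic50 = se[1], se_hill = se[2], model = model,
    converged = best$ok, ambiguous = ambiguous, rss = best$rss, n = n,
    conc_range = 10^rng
  )
}

# Gauss-Newton standard errors from a finite-difference Jacobian at the
# optimum: cov = sigma^2 (J'J)^{-1}, sigma^2 = rss / (n - p).
fit_standard_errors <- function(resid_fn, par, n) {
  p <- length(par)
  if (n <= p) return(rep(NA_real_, p))
  r0 <- resid_fn(par)
  J <- matrix(NA_real_, length(r0), p)
  for (j in seq_len(p)) {
    h <- max(1e-6, abs(par[j]) * 1e-6)
    pp <- par; pp[j] <- pp[j] + h
    J[, j] <- (resid_fn(pp) - r0) / h
  }
  sigma2 <- sum(r0^2) / (n - p)
  V <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
  if (is.null(V)) rep(NA_real_, p) else sqrt(pmax(diag(V), 0))
}

#' Evaluate a fitted dose-response curve
#'
#' Closed-form value of the logistic at concentration `x` (molar).
#'
#' @param fit a `sigmoid_fit`
#' @param x concentrations in molar, strictly positive
#' @return predicted response (percent scale), vectorized over `x`
#' @export
evaluate_sigmoid <- function(fit, x) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (any(x <= 0)) stop("x must be strictly positive")
  four_pl(x, fit$log_ic50, fit$hill_slope, fit$top, fit$bottom)
}

#' Invert a fitted dose-response curve
#'
#' Unique concentration at which the fitted curve attains response `y`.
#' Requires `bottom < y < top` and a non-ambiguous fit.
#'
#' @param fit a `sigmoid_fit`
#' @param y response level (percent), strictly inside `(bottom, top)`
#' @return concentration in molar
#' @export
invert_sigmoid <- function(fit, y) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (isTRUE(fit$ambiguous)) stop("cannot invert an ambiguous fit")
  if (any(y <= fit$bottom) || any(y >= fit$top)) {
    stop(sprintf(
      "requested response %.4g is outside the attainable range (%.4g, %.4g)",
      y[1], fit$bottom, fit$top
    ))
  }
  lx <- fit$log_ic50 - log10((fit$top - y) / (y - fit$bottom)) / fit$hill_slope
  10^lx
}

#' Half-maximal concentration of a fit
#' @param fit a `sigmoid_fit`
#' @return IC50/EC50 in molar
#' @export
ic50 <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  10^fit$log_ic50
}
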