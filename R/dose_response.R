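#' Construct a dose-response curve
#'
#' Responses of a readout (4-hour reporter level, or relative growth rate)
#' across an ethanol concentration grid.
#'
#' @param concentrations Percent v/v ethanol; non-negative, strictly
#'   increasing, at least 5 values for fitting.
#' @param response Mean response at each concentration.
#' @param replicates Optional matrix (concentration x replicate).
#' @param direction `"increasing"` (activation readouts) or
#'   `"decreasing"` (growth inhibition).
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(concentrations, response, replicates = NULL,
                                direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  concentrations <- as.numeric(concentrations)
  response <- as.numeric(response)
  if (length(concentrations) != length(response)) {
    stop("concentrations and response lengths differ")
  }
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing")
  }
  if (length(concentrations) < 5) stop("need at least 5 concentrations")
  structure(list(concentrations = concentrations, response = response,
                 replicates = replicates, direction = direction),
            class = "dose_response_curve")
}

#' Fit a Hill dose-response function
#'
#' Least-squares fit of
#' `r(c) = floor + (ceiling - floor) * c^n / (C50^n + c^n)`
#' for increasing curves, or the mirrored form
#' `r(c) = ceiling - (ceiling - floor) * c^n / (C50^n + c^n)`
#' for decreasing (growth-inhibition) curves. `C50` is the EC50 of an
#' activation readout or the IC50 of an inhibition readout. The Hill
#' coefficient starts at 4 and is bounded to `[0.5, 20]`; start values for
#' floor/ceiling come from the response extremes and `C50` from the
#' concentration nearest mid-response. A flat curve is returned as a
#' degenerate fit rather than an error.
#'
#' @param curve A [dose_response_curve()].
#' @return An object of class `hill_fit` with fields `floor`, `ceiling`,
#'   `C50`, `n`, `rss`, `direction`, `degenerate`.
#' @export
fit_hill <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  cc <- curve$concentrations
  r <- curve$response
  degenerate <- function(reason) {
    structure(list(floor = NA_real_, ceiling = NA_real_, C50 = NA_real_,
                   n = NA_real_, rss = NA_real_,
                   direction = curve$direction, degenerate = TRUE,
                   reason = reason),
              class = "hill_fit")
  }
  rng <- max(r) - min(r)
  if (rng <= 1e-12 * max(abs(r))) return(degenerate("flat curve"))

  mid <- min(r) + rng / 2
  c50_0 <- cc[which.min(abs(r - mid))]
  if (c50_0 <= 0) c50_0 <- cc[cc > 0][1]
  start <- list(fl = min(r), ce = max(r), C50 = c50_0, n = 4)
  sgn <- if (curve$direction == "increasing") 1 else -1
  model <- if (sgn > 0) {
    r ~ fl + (ce - fl) * cc^n / (C50^n + cc^n)
  } else {
    r ~ ce - (ce - fl) * cc^n / (C50^n + cc^n)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      model, start = start,
      lower = c(fl = -Inf, ce = -Inf, C50 = 1e-6, n = 0.5),
      upper = c(fl = Inf, ce = Inf, C50 = Inf, n = 20),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(degenerate("non-convergence"))
  cf <- stats::coef(fit)
  if (cf[["ce"]] < cf[["fl"]]) return(degenerate("inverted amplitude"))
  structure(list(floor = cf[["fl"]], ceiling = cf[["ce"]],
                 C50 = cf[["C50"]], n = cf[["n"]],
                 rss = sum(stats::resid(fit)^2),
                 direction = curve$direction, degenerate = FALSE,
                 reason = NULL),
            class = "hill_fit")
}

#' Evaluate a fitted Hill curve
#'
#' @param fit A non-degenerate `hill_fit`.
#' @param conc Concentrations (percent v/v).
#' @return Fitted responses.
#' @export
predict_hill <- function(fit, conc) {
  if (isTRUE(fit$degenerate)) stop("degenerate fit")
  h <- conc^fit$n / (fit$C50^fit$n + conc^fit$n)
  if (fit$direction == "increasing") {
    fit$floor + (fit$ceiling - fit$floor) * h
  } else {
    fit$ceiling - (fit$ceiling - fit$floor) * h
  }
}

#' Fit a per-concentration reporter time course
#'
#' High ethanol doses produce sigmoidal reporter induction, while at and
#' below 5 percent the response never leaves its baseline regime and a
#' sigmoid is unidentifiable; those series are fit with a quadratic
#' polynomial instead. The family boundary is fixed at 6 percent:
#' concentrations >= 6 use the four-parameter logistic, <= 5 use the
#' polynomial.
#'
#' @param times Times (min), >= 6 points.
#' @param values Reporter levels.
#' @param concentration Percent v/v ethanol for this series.
#' @return A list with `family` (`"logistic"` or `"polynomial"`), the fit
#'   object (`logistic_fit` or `lm`), `rss`, and `concentration`.
#' @export
fit_concentration_time_course <- function(times, values, concentration) {
  if (length(times) < 6) stop("need at least 6 time points")
  if (concentration >= 6) {
    tc <- gene_time_course(sprintf("etoh_%g", concentration), times, values)
    fit <- fit_logistic(tc)
    list(family = "logistic", fit = fit, rss = fit$rss,
         concentration = concentration)
  } else {
    df <- data.frame(t = times, v = values)
    fit <- stats::lm(v ~ stats::poly(t, 2), data = df)
    list(family = "polynomial", fit = fit,
         rss = sum(stats::resid(fit)^2), concentration = concentration)
  }
}
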