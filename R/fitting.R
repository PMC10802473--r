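#' Construct an observed reporter time course
#'
#' A strain-labelled series of mean fold-change measurements, as produced
#' by flow cytometry of the HSE-YFP reporter: time zero is the pre-stress
#' reference with fold change 1 by definition.
#'
#' @param strain Strain label.
#' @param times Strictly increasing measurement times (min), starting at 0.
#' @param values Mean fold-change values (> 0); `values[1]` must be 1.
#' @param sd Optional per-time standard deviations.
#' @param n_reps Replicate count (default 3).
#' @return An object of class `hsr_observed`.
#' @export
observed_time_course <- function(strain, times, values, sd = NULL, n_reps = 3) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1] != 0) stop("first time must be 0")
  if (abs(values[1] - 1) > 1e-9) stop("fold change at t = 0 must be 1")
  if (any(values <= 0)) stop("fold-change values must be > 0")
  if (!is.null(sd) && length(sd) != length(times)) {
    stop("sd length must match times")
  }
  structure(list(strain = strain, times = times, values = values,
                 sd = sd, n_reps = n_reps),
            class = "hsr_observed")
}

#' Residual sum of squares between observed and simulated fold changes
#'
#' Unweighted sum over the observation times of the squared difference
#' between the observed mean fold change and the simulated reporter fold
#' change. Observation times must all be present among the trajectory's
#' sample times.
#'
#' @param observed An [observed_time_course()] object.
#' @param simulated An `hsr_trajectory` from [hsr_simulate()].
#' @param weighted If `TRUE` and the observation carries per-time standard
#'   deviations, residuals are divided by them (off by default).
#' @return Non-negative scalar; zero iff the series agree at every
#'   observed time.
#' @export
rss <- function(observed, simulated, weighted = FALSE) {
  idx <- match(observed$times, simulated$times)
  if (anyNA(idx)) {
    stop("observation times are not a subset of trajectory sample times")
  }
  res <- observed$values - simulated$yfp_fold_change[idx]
  if (weighted) {
    if (is.null(observed$sd)) stop("weighted rss requires per-time sd")
    res <- res / observed$sd
  }
  sum(res^2)
}

#' Fit the productive release scale of an auxiliary feedback mutant
#'
#' Finds the single multiplier on the productive client release rate that
#' best reproduces an observed reporter time course, by minimizing the
#' residual sum of squares over scales in `[0.01, 1]`: a 40-point
#' log-spaced grid scan followed by golden-section refinement around the
#' grid minimum (absolute tolerance 1e-3 in the scale). Only reductions of
#' the release rate are searched, since the mutants modeled this way lose,
#' never gain, release activity; an optimum pinned at either search bound
#' is flagged rather than silently accepted.
#'
#' @param observed An [observed_time_course()] object.
#' @param base The wild-type `hsr_parameters` calibration.
#' @param protocol The [stress_protocol()] under which the data were
#'   collected; its sample times must contain the observation times.
#' @param bounds Search interval for the scale.
#' @return A list of class `hsr_release_fit`: `release_scale`, `rss`,
#'   `profile` (data frame of grid scales and their RSS), `fitted` (the
#'   trajectory at the optimum), and `convergence` (`"ok"` or
#'   `"boundary"`).
#' @export
fit_release_scale <- function(observed, base, protocol,
                              bounds = c(0.01, 1)) {
  validate_parameters(base)
  objective <- function(scale) {
    g <- strain_genotype("fit", "AUX_DHSE", release_scale = scale)
    traj <- hsr_simulate(make_parameters(g, base), protocol)
    rss(observed, traj)
  }
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = 40))
  grid_rss <- vapply(grid, objective, numeric(1))
  if (all(!is.finite(grid_rss))) stop("all grid simulations failed")
  i_min <- which.min(grid_rss)
  lo <- grid[max(1, i_min - 1)]
  hi <- grid[min(length(grid), i_min + 1)]
  opt <- stats::optimize(objective, lower = lo, upper = hi, tol = 1e-3)
  scale_hat <- opt$minimum
  rss_hat <- opt$objective
  # keep the grid point if refinement did not improve on it
  if (grid_rss[i_min] < rss_hat) {
    scale_hat <- grid[i_min]
    rss_hat <- grid_rss[i_min]
  }
  conv <- if (scale_hat <= bounds[1] * 1.05 || scale_hat >= bounds[2] * 0.999) {
    "boundary"
  } else {
    "ok"
  }
  g <- strain_genotype("fit", "AUX_DHSE", release_scale = scale_hat)
  structure(list(
    release_scale = scale_hat,
    rss = rss_hat,
    profile = data.frame(scale = grid, rss = grid_rss),
    fitted = hsr_simulate(make_parameters(g, base), protocol),
    convergence = conv
  ), class = "hsr_release_fit")
}

#' Re-calibrate client parameters for ethanol stress
#'
#' Ethanol induces the same circuit through a different client load:
#' holding the core feedback loop fixed, only the client production
#' fold-increase (`s_eth`) and the client-Hsp70 association rate (`k_bU`)
#' are re-fit to a wild-type ethanol time course. The two factors are
#' optimized as multiplicative adjustments in log space (scale-free and
#' positivity-preserving) by Nelder-Mead local search started from a 3 x 3
#' grid of initial multipliers; the best converged start wins.
#'
#' @param observed_wt Wild-type ethanol [observed_time_course()].
#' @param base The heat-calibrated wild-type `hsr_parameters`.
#' @param protocol An ethanol [stress_protocol()].
#' @return An `hsr_parameters` object identical to `base` except for
#'   `s_eth` and `k_bU`, with attribute `fit` carrying the achieved RSS
#'   and the fitted multipliers.
#' @export
fit_ethanol_baseline <- function(observed_wt, base, protocol) {
  if (protocol$stress_type != "ethanol") {
    stop("protocol must be an ethanol protocol")
  }
  validate_parameters(base)
  objective <- function(logmul) {
    logmul <- unname(logmul)
    p <- base
    p$s_eth <- max(base$s_eth * exp(logmul[1]), 1)
    p$k_bU <- base$k_bU * exp(logmul[2])
    tryCatch(rss(observed_wt, hsr_simulate(p, protocol)),
             error = function(e) Inf)
  }
  starts <- as.matrix(expand.grid(log(c(0.5, 1, 2)), log(c(0.5, 1, 2))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    if (is.finite(fit$value) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
    if (!is.null(best) && best$value < 1e-8) break
  }
  if (is.null(best)) stop("ethanol re-calibration failed from every start")
  par <- unname(best$par)
  p <- base
  p$s_eth <- max(base$s_eth * exp(par[1]), 1)
  p$k_bU <- base$k_bU * exp(par[2])
  attr(p, "fit") <- list(
    rss = best$value,
    s_eth_multiplier = p$s_eth / base$s_eth,
    k_bU_multiplier = p$k_bU / base$k_bU
  )
  p
}
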