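#' Define a stress protocol
#'
#' A protocol is a stimulus schedule plus the times at which the reporter is
#' sampled. The default schedule mirrors a standard heat shock experiment:
#' stress applied at time zero and the culture sampled at 10 time points
#' over 240 minutes. Stress onset is instantaneous and inclusive
#' (`t >= t_on`), matching an abrupt transfer to the stress condition.
#'
#' @param stress_type One of `"none"`, `"heat"`, `"ethanol"`.
#' @param t_on Stress onset time (min).
#' @param magnitude Temperature (deg C) for heat or ethanol fraction
#'   (percent v/v); recorded for provenance, the kinetic effect enters
#'   through the calibrated stress multipliers.
#' @param sample_times Strictly increasing sampling times (min); the first
#'   must be 0 (the pre-stress reference).
#' @return An object of class `hsr_protocol`.
#' @export
stress_protocol <- function(stress_type = c("heat", "ethanol", "none"),
                            t_on = 0, magnitude = 39,
                            sample_times = seq(0, 240, length.out = 10)) {
  stress_type <- match.arg(stress_type)
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) < 2 || any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing")
  }
  if (sample_times[1] != 0) stop("first sample time must be 0 (pre-stress)")
  if (t_on < 0) stop("t_on must be >= 0")
  structure(list(stress_type = stress_type, t_on = t_on,
                 magnitude = magnitude, sample_times = sample_times),
            class = "hsr_protocol")
}

#' Client production multiplier at a given time
#'
#' Stress is realized as a step increase in the influx of unfolded clients:
#' the production term in the client equation is `k_U0` times this
#' multiplier. Before onset (or with no stress) the multiplier is 1; from
#' onset onward it is the heat or ethanol fold-increase from the parameter
#' set. Onset is inclusive: `t = t_on` is stressed.
#'
#' @param protocol An [stress_protocol()] object.
#' @param params An `hsr_parameters` object.
#' @param t Time (min), scalar or vector; must be non-negative.
#' @return Dimensionless multiplier(s), same length as `t`.
#' @export
stress_multiplier <- function(protocol, params, t) {
  if (any(t < 0)) stop("t must be >= 0")
  s_on <- switch(protocol$stress_type,
                 none = 1,
                 heat = params$s_heat,
                 ethanol = params$s_eth)
  ifelse(protocol$stress_type != "none" & t >= protocol$t_on, s_on, 1)
}

state_names <- c("U", "Hf", "HU", "HF", "Ff", "Y", "Ym")

#' Time derivatives of the Hsf1-Hsp70 circuit
#'
#' Mass-action realization of the feedback architecture. Free Hsp70 (`Hf`)
#' binds unfolded clients (`U`) to form `HU`; the complex resolves either
#' productively (rate `k_rel`, client folded and consumed) or
#' non-productively (rate `k_offU`, client returned to the pool). Free
#' Hsp70 also binds free Hsf1 (`Ff`) to form the repressed complex `HF`,
#' with an association rate attenuated by accumulated clients through a
#' Hill-type affinity switch (representing titration of the cochaperone
#' Sis1 away from Hsf1):
#' `k_bF(U) = k_bF0 / (1 + (U / K_sis)^h_sis)`.
#' Free Hsf1 drives Hsp70 synthesis (the core feedback) and transcription
#' of the immature reporter `Y`, which matures into `Ym`. All species are
#' diluted at rate `gamma` except Hsf1, which is conserved:
#' `Ff + HF = F_tot` at all times (when the Hsf1-Hsp70 complex is diluted,
#' its Hsf1 moiety returns to the free pool).
#'
#' @param state Named numeric vector with components `U`, `Hf`, `HU`,
#'   `HF`, `Ff`, `Y`, `Ym` (all a.u.).
#' @param params An `hsr_parameters` object.
#' @param s Dimensionless stress multiplier on client production.
#' @return Named numeric vector of rates (a.u./min), same names as `state`.
#' @export
hsr_derivatives <- function(state, params, s = 1) {
  p <- params
  U <- state[["U"]]; Hf <- state[["Hf"]]; HU <- state[["HU"]]
  HF <- state[["HF"]]; Ff <- state[["Ff"]]
  Y <- state[["Y"]]; Ym <- state[["Ym"]]

  k_bF <- p$k_bF0 / (1 + (U / p$K_sis)^p$h_sis)
  hill_hsf <- Ff^p$n_hsf / (p$K_hsf^p$n_hsf + Ff^p$n_hsf)
  hill_y <- Ff^p$n_y / (p$K_y^p$n_y + Ff^p$n_y)

  bindU <- p$k_bU * Hf * U
  bindF <- k_bF * Hf * Ff

  dU <- p$k_U0 * s - bindU + p$k_offU * HU - p$gamma * U
  dHU <- bindU - (p$k_rel + p$k_offU + p$gamma) * HU
  dHf <- p$beta0 + p$beta1 * hill_hsf + (p$k_rel + p$k_offU) * HU -
    bindU - bindF + p$k_uF * HF - p$gamma * Hf
  dHF <- bindF - (p$k_uF + p$gamma) * HF
  dFf <- -bindF + (p$k_uF + p$gamma) * HF
  dY <- p$alpha_y * hill_y - (p$m_mat + p$gamma) * Y
  dYm <- p$m_mat * Y - p$gamma * Ym

  rates <- as.numeric(c(dU, dHf, dHU, dHF, dFf, dY, dYm))
  names(rates) <- state_names
  rates
}

# deSolve-format wrapper around hsr_derivatives
deriv_desolve <- function(t, y, parms) {
  list(hsr_derivatives(y, parms$params, parms$s))
}

#' Pre-stress steady state
#'
#' Relaxes the system from a neutral initial condition under basal client
#' production (multiplier 1) for a long horizon, then polishes the root of
#' the rate equations with damped Newton iterations on the reduced system
#' (the Hsf1-Hsp70 complex is eliminated through the Hsf1 conservation
#' law, which would otherwise make the Jacobian singular).
#'
#' @param params An `hsr_parameters` object.
#' @param t_relax Relaxation horizon (min); at least 5000.
#' @param tol Max-norm tolerance on the derivative at the returned state.
#' @return Named state vector at steady state, with mature reporter > 0.
#' @export
basal_steady_state <- function(params, t_relax = 6000, tol = 1e-8) {
  validate_parameters(params)
  t_relax <- max(t_relax, 5000)
  y0 <- c(U = 0, Hf = params$beta0 / params$gamma, HU = 0,
          HF = 0, Ff = params$F_tot, Y = 0, Ym = 1e-6)
  sol <- deSolve::lsoda(y0, times = c(0, t_relax), func = deriv_desolve,
                        parms = list(params = params, s = 1),
                        rtol = 1e-8, atol = 1e-10, maxsteps = 100000)
  y <- sol[nrow(sol), state_names]
  y <- newton_polish(y, params, tol = tol)
  resid <- max(abs(hsr_derivatives(y, params, 1)))
  if (resid >= tol) {
    stop(sprintf("steady state did not converge: residual max-norm %.3e", resid))
  }
  if (y[["Ym"]] <= 0) stop("steady state has non-positive mature reporter")
  y
}

# Newton root-polish on the 6-dim reduced system (HF = F_tot - Ff)
newton_polish <- function(y, params, tol = 1e-8, max_iter = 50) {
  reduced <- c("U", "Hf", "HU", "Ff", "Y", "Ym")
  expand <- function(x) {
    st <- c(U = x[[1]], Hf = x[[2]], HU = x[[3]],
            HF = params$F_tot - x[[4]], Ff = x[[4]], Y = x[[5]], Ym = x[[6]])
    st
  }
  fn <- function(x) {
    d <- hsr_derivatives(expand(x), params, 1)
    d[reduced]
  }
  x <- y[reduced]
  for (iter in seq_len(max_iter)) {
    fx <- fn(x)
    if (max(abs(fx)) < tol * 1e-2) break
    jac <- numeric_jacobian(fn, x)
    step <- tryCatch(solve(jac, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      x_new <- x + lambda * step
      if (all(x_new[c("U", "Hf", "HU", "Y", "Ym")] >= 0) &&
          x_new[["Ff"]] >= 0 && x_new[["Ff"]] <= params$F_tot &&
          max(abs(fn(x_new))) < max(abs(fx))) {
        x <- x_new
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    if (lambda < 1e-6) break
  }
  expand(x)
}

numeric_jacobian <- function(fn, x, eps = 1e-7) {
  n <- length(x)
  f0 <- fn(x)
  jac <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(x[[j]]), 1)
    xp <- x
    xp[[j]] <- xp[[j]] + h
    jac[, j] <- (fn(xp) - f0) / h
  }
  jac
}

#' Simulate a stress time course
#'
#' Integrates the circuit from its pre-stress steady state with an adaptive
#' stiff-capable solver (lsoda; relative tolerance 1e-8, absolute 1e-10).
#' The stress step at onset is handled by integrating the pre- and
#' post-onset segments separately so the discontinuity never crosses a
#' solver step. States within solver noise of zero (down to -1e-9) are
#' clipped to zero; anything more negative is an integration error.
#'
#' @param params An `hsr_parameters` object.
#' @param protocol An [stress_protocol()] object.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `hsr_trajectory`: a list with `times`, the
#'   states matrix, and derived series `yfp_fold_change` (mature reporter
#'   over its pre-stress value), `free_hsf1_fraction`, and
#'   `available_hsp70` (free Hsp70, the proxy for its nuclear-available
#'   pool).
#' @export
hsr_simulate <- function(params, protocol, rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  if (!inherits(protocol, "hsr_protocol")) stop("protocol must be an hsr_protocol")
  y0 <- basal_steady_state(params)
  times <- protocol$sample_times
  t_on <- protocol$t_on

  integrate_segment <- function(y, tt, s) {
    if (length(tt) < 2) {
      return(matrix(y, nrow = length(tt), ncol = length(y), byrow = TRUE,
                    dimnames = list(NULL, names(y))))
    }
    sol <- deSolve::lsoda(y, times = tt, func = deriv_desolve,
                          parms = list(params = params, s = s),
                          rtol = rtol, atol = atol, maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
    unclass(sol)[, state_names, drop = FALSE]
  }

  if (protocol$stress_type == "none") {
    states <- integrate_segment(y0, times, 1)
  } else if (t_on <= times[1]) {
    s_on <- stress_multiplier(protocol, params, t_on)
    states <- integrate_segment(y0, times, s_on)
  } else {
    pre_t <- times[times < t_on]
    post_t <- times[times >= t_on]
    pre <- integrate_segment(y0, unique(c(pre_t, t_on)), 1)
    y_on <- pre[nrow(pre), ]
    s_on <- stress_multiplier(protocol, params, t_on)
    post <- integrate_segment(y_on, unique(c(t_on, post_t)), s_on)
    states <- rbind(
      pre[match(pre_t, unique(c(pre_t, t_on))), , drop = FALSE],
      post[match(post_t, unique(c(t_on, post_t))), , drop = FALSE]
    )
  }

  low <- min(states)
  if (low < -1e-9) {
    stop(sprintf("negative state in integration output (min %.3e)", low))
  }
  states[states < 0] <- 0

  traj <- list(
    times = times,
    states = states,
    yfp_fold_change = states[, "Ym"] / states[1, "Ym"],
    free_hsf1_fraction = states[, "Ff"] / params$F_tot,
    available_hsp70 = states[, "Hf"],
    params = params,
    protocol = protocol
  )
  traj$yfp_fold_change[1] <- 1
  class(traj) <- "hsr_trajectory"
  traj
}

#' @export
print.hsr_trajectory <- function(x, ...) {
  cat(sprintf("HSR trajectory: %d samples over %g min (%s stress)\n",
              length(x$times), max(x$times), x$protocol$stress_type))
  cat(sprintf("  final reporter fold change: %.3f\n",
              x$yfp_fold_change[length(x$times)]))
  invisible(x)
}

#' Instantaneous reporter transcription rate along a trajectory
#'
#' The promoter-activity readout used to assess adaptation: the Hill-type
#' transcription rate of the reporter evaluated at the free Hsf1 level of
#' each sampled state. In an adapting wild type this returns close to its
#' basal value by the end of a sustained stress; with the core feedback
#' broken it stays high.
#'
#' @param traj An `hsr_trajectory`.
#' @return Numeric vector of transcription rates (a.u./min) at each sample
#'   time.
#' @export
transcription_rate <- function(traj) {
  p <- traj$params
  Ff <- traj$states[, "Ff"]
  p$alpha_y * Ff^p$n_y / (p$K_y^p$n_y + Ff^p$n_y)
}

#' Convert a trajectory to a tidy data frame
#'
#' @param x An `hsr_trajectory`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @return Long data frame with columns `time_min`, `species`, `value`;
#'   species include the seven state variables and the derived
#'   `yfp_fold_change`.
#' @export
as.data.frame.hsr_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  wide <- data.frame(time_min = x$times, x$states,
                     yfp_fold_change = x$yfp_fold_change,
                     check.names = FALSE)
  species <- setdiff(names(wide), "time_min")
  long <- data.frame(
    time_min = rep(wide$time_min, times = length(species)),
    species = rep(species, each = nrow(wide)),
    value = unlist(wide[species], use.names = FALSE)
  )
  long
}
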