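#' Load the versioned default calibration
#'
#' All model defaults and the ground-truth constants used by the synthetic
#' data generators live in one YAML file shipped with the package
#' (`inst/extdata/default_calibration.yaml`). Analyses and tests reference
#' this single config so that the calibration is versioned, not scattered.
#'
#' @param path Optional path to an alternative calibration YAML.
#' @return A named list with elements `parameters` (model parameter values),
#'   `synthetic` (generator ground truths such as the true EC50/IC50, regulon
#'   basal span and fold-change range) and `version`.
#' @export
hsr_calibration <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_calibration.yaml", package = "hsrkit")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("calibration file not found: ", path)
  }
  yaml::read_yaml(path)
}

#' Construct a validated model parameter set
#'
#' Parameters of the Hsf1-Hsp70 feedback circuit. Units are arbitrary
#' concentration units (a.u.) and minutes; reporter output is always
#' compared as fold change over the pre-stress level, which cancels units.
#'
#' @param k_U0 basal client production rate (a.u./min).
#' @param s_heat fold-increase of client production during heat stress.
#' @param s_eth fold-increase of client production during ethanol stress.
#' @param k_bU Hsp70-client association rate (1/(a.u. min)).
#' @param k_rel productive client release rate (1/min); the auxiliary
#'   feedback parameter, tuned down to model release-deficient mutants.
#' @param k_offU non-productive client release rate (1/min).
#' @param k_bF0 maximal Hsp70-Hsf1 association rate (1/(a.u. min)).
#' @param k_uF Hsp70-Hsf1 dissociation rate (1/min).
#' @param K_sis client level at half-maximal affinity switch (a.u.).
#' @param h_sis affinity-switch Hill coefficient.
#' @param beta0 basal Hsp70 synthesis rate (a.u./min).
#' @param beta1 maximal Hsf1-dependent Hsp70 synthesis rate (a.u./min).
#' @param K_hsf,n_hsf Hill constant (a.u.) and coefficient for Hsf1-driven
#'   Hsp70 synthesis.
#' @param alpha_y,K_y,n_y maximal reporter transcription rate (a.u./min),
#'   Hill constant (a.u.) and coefficient for the HSE-YFP promoter.
#' @param m_mat YFP maturation rate (1/min).
#' @param gamma dilution/degradation rate applied to all species (1/min).
#' @param F_tot total Hsf1 (a.u.; conserved).
#' @return An object of class `hsr_parameters` (a named list).
#' @export
model_parameters <- function(k_U0, s_heat, s_eth, k_bU, k_rel, k_offU,
                             k_bF0, k_uF, K_sis, h_sis, beta0, beta1,
                             K_hsf, n_hsf, alpha_y, K_y, n_y,
                             m_mat, gamma, F_tot) {
  p <- list(
    k_U0 = k_U0, s_heat = s_heat, s_eth = s_eth, k_bU = k_bU,
    k_rel = k_rel, k_offU = k_offU, k_bF0 = k_bF0, k_uF = k_uF,
    K_sis = K_sis, h_sis = h_sis, beta0 = beta0, beta1 = beta1,
    K_hsf = K_hsf, n_hsf = n_hsf, alpha_y = alpha_y, K_y = K_y,
    n_y = n_y, m_mat = m_mat, gamma = gamma, F_tot = F_tot
  )
  p <- lapply(p, as.numeric)
  class(p) <- "hsr_parameters"
  validate_parameters(p)
  p
}

#' @export
print.hsr_parameters <- function(x, ...) {
  cat("Hsf1-Hsp70 circuit parameters:\n")
  print(unlist(x))
  invisible(x)
}

validate_parameters <- function(p) {
  stopifnot(inherits(p, "hsr_parameters"))
  vals <- unlist(p)
  if (anyNA(vals)) stop("model parameters contain NA")
  if (any(vals < 0)) {
    stop("negative model parameter(s): ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  if (p$gamma <= 0) stop("gamma must be > 0")
  if (p$F_tot <= 0) stop("F_tot must be > 0")
  if (p$h_sis < 1) stop("h_sis must be >= 1")
  if (p$n_hsf < 1) stop("n_hsf must be >= 1")
  if (p$n_y < 1) stop("n_y must be >= 1")
  if (p$s_heat < 1) stop("s_heat must be >= 1")
  if (p$s_eth < 1) stop("s_eth must be >= 1")
  invisible(p)
}

#' Default wild-type parameter set
#'
#' Reads the shipped calibration config and returns the wild-type parameter
#' set. The defaults were calibrated once so that the wild-type heat shock
#' reporter rises a few fold and plateaus within the four-hour time course,
#' the core-feedback-broken mutant keeps rising, and release-rate reductions
#' of 60-80 percent produce an elevated plateau.
#'
#' @param calibration Optional calibration list from [hsr_calibration()].
#' @return An `hsr_parameters` object.
#' @export
default_parameters <- function(calibration = hsr_calibration()) {
  do.call(model_parameters, calibration$parameters)
}
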