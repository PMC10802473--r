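#' Define a strain genotype
#'
#' Genotypes map onto parameter overrides of the base (wild-type) model:
#' `WT` is the identity; `HSP70_DFBL` removes Hsf1-dependent Hsp70 induction
#' (the core feedback loop) while preserving the pre-stress Hsp70 level;
#' `AUX_DHSE` scales down the productive client release rate, the single
#' parameter through which the auxiliary feedback mutants (fes1, ubi4,
#' gre3, pin3 HSE deletions) act.
#'
#' @param name Strain label.
#' @param kind One of `"WT"`, `"HSP70_DFBL"`, `"AUX_DHSE"`.
#' @param release_scale Multiplier on the productive release rate, in
#'   (0, 1]. Only meaningful for `AUX_DHSE`; must be 1 for `WT` and is not
#'   carried by `HSP70_DFBL`.
#' @return An object of class `hsr_genotype`.
#' @export
strain_genotype <- function(name, kind = c("WT", "HSP70_DFBL", "AUX_DHSE"),
                            release_scale = 1) {
  kind <- match.arg(kind)
  if (kind == "WT" && release_scale != 1) {
    stop("WT genotype must have release_scale = 1")
  }
  if (kind == "AUX_DHSE") {
    if (!is.numeric(release_scale) || release_scale <= 0 || release_scale > 1) {
      stop("release_scale must lie in (0, 1]")
    }
  }
  g <- list(name = name, kind = kind)
  if (kind != "HSP70_DFBL") g$release_scale <- release_scale
  class(g) <- "hsr_genotype"
  g
}

#' Apply a genotype to a base parameter set
#'
#' `AUX_DHSE` multiplies the productive release rate `k_rel` by the
#' genotype's `release_scale`. `HSP70_DFBL` sets the Hsf1-dependent Hsp70
#' synthesis rate `beta1` to zero and raises the basal rate `beta0` so that
#' the pre-stress steady-state total Hsp70 (free + client-bound +
#' Hsf1-bound) matches the wild type: the feedback loop is removed but
#' basal chaperone expression is preserved. `WT` returns `base` unchanged.
#'
#' @param genotype An [strain_genotype()] object.
#' @param base A validated `hsr_parameters` object (the wild-type
#'   calibration).
#' @return A new `hsr_parameters` object; `base` is never modified.
#' @export
make_parameters <- function(genotype, base) {
  if (!inherits(genotype, "hsr_genotype")) {
    stop("genotype must be an hsr_genotype object")
  }
  validate_parameters(base)
  switch(genotype$kind,
    WT = base,
    AUX_DHSE = {
      p <- base
      p$k_rel <- base$k_rel * genotype$release_scale
      p
    },
    HSP70_DFBL = {
      wt_total <- total_hsp70(basal_steady_state(base))
      p <- base
      p$beta1 <- 0
      # total basal Hsp70 increases monotonically with beta0; bracket from
      # the wild-type basal rate up to the rate that would match the full
      # feedback-driven synthesis
      match_total <- function(b0) {
        q <- p
        q$beta0 <- b0
        total_hsp70(basal_steady_state(q)) - wt_total
      }
      upper <- base$beta0 + base$beta1
      root <- stats::uniroot(match_total, lower = base$beta0, upper = upper,
                             tol = 1e-10 * wt_total)
      p$beta0 <- root$root
      p
    },
    stop("unknown genotype kind: ", genotype$kind)
  )
}

total_hsp70 <- function(state) {
  unname(state["Hf"] + state["HU"] + state["HF"])
}
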