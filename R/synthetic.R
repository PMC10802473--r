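#' Specification of a synthetic regulon reporter library
#'
#' Describes the statistical structure of the emulated 42-gene reporter
#' library: basal expression spread over several decades, induction fold
#' changes from barely detectable to strong, and a negative coupling
#' between induction timing and magnitude (rapidly induced genes induce
#' more). Defaults come from the shipped calibration config.
#'
#' @param n_genes Number of regulon genes (>= 5).
#' @param basal_decades Width of the basal-expression range in log10
#'   units.
#' @param basal_min Lowest basal level (a.u.).
#' @param fold_range Two-element range of induction fold changes.
#' @param t50_range Two-element range of half-max induction times (min).
#' @param kinetic_rho Target (Gaussian-copula) correlation between fold
#'   change and t50; negative couples rapid induction to large induction.
#' @param times Sampling times (min).
#' @param replicate_cv Multiplicative replicate coefficient of variation.
#' @param n_reps Replicates per gene.
#' @return An object of class `regulon_spec`.
#' @export
regulon_spec <- function(n_genes = NULL, basal_decades = NULL,
                         basal_min = NULL, fold_range = NULL,
                         t50_range = NULL, kinetic_rho = NULL,
                         times = seq(0, 240, length.out = 10),
                         replicate_cv = NULL, n_reps = 3) {
  syn <- hsr_calibration()$synthetic
  spec <- list(
    n_genes = if (is.null(n_genes)) syn$n_genes else n_genes,
    basal_decades = if (is.null(basal_decades)) syn$basal_decades else basal_decades,
    basal_min = if (is.null(basal_min)) syn$basal_min else basal_min,
    fold_range = if (is.null(fold_range)) unlist(syn$fold_range) else fold_range,
    t50_range = if (is.null(t50_range)) unlist(syn$t50_range) else t50_range,
    kinetic_rho = if (is.null(kinetic_rho)) syn$kinetic_rho else kinetic_rho,
    times = as.numeric(times),
    replicate_cv = if (is.null(replicate_cv)) syn$replicate_cv else replicate_cv,
    n_reps = n_reps
  )
  if (spec$n_genes < 5) stop("n_genes must be >= 5")
  if (spec$basal_decades <= 0) stop("basal_decades must be > 0")
  if (spec$fold_range[1] <= 1 || diff(spec$fold_range) <= 0) {
    stop("invalid fold_range")
  }
  if (any(diff(spec$times) <= 0)) stop("times must be strictly increasing")
  class(spec) <- "regulon_spec"
  spec
}

#' Specification of measurement noise for synthetic data
#'
#' @param replicate_cv Multiplicative coefficient of variation between
#'   biological replicates.
#' @param cell_sigma Lognormal sigma of per-cell normalized expression.
#' @param ssc_sigma Lognormal sigma of per-cell side scatter.
#' @param dead_fraction Fraction of events that are dead cells, in
#'   `[0, 1)`.
#' @param dead_ssc_atten Side-scatter attenuation of dead events.
#' @param dead_fluor_atten Additional fluorescence attenuation of dead
#'   events (dead cells lose signal faster than scatter).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(replicate_cv = 0.05, cell_sigma = 0.1,
                       ssc_sigma = 0.4, dead_fraction = 0,
                       dead_ssc_atten = 0.2, dead_fluor_atten = 0.05) {
  if (replicate_cv < 0 || cell_sigma < 0 || ssc_sigma < 0) {
    stop("noise CVs must be >= 0")
  }
  if (dead_fraction < 0 || dead_fraction >= 1) {
    stop("dead_fraction must be in [0, 1)")
  }
  structure(list(replicate_cv = replicate_cv, cell_sigma = cell_sigma,
                 ssc_sigma = ssc_sigma, dead_fraction = dead_fraction,
                 dead_ssc_atten = dead_ssc_atten,
                 dead_fluor_atten = dead_fluor_atten),
            class = "noise_spec")
}

# stratified sample over [0, 1]: one draw per equal bin (jittered within the
# central half of the bin, so the configured range extremes are realized),
# shuffled
stratified_unif <- function(n) {
  sample((seq_len(n) - 1 + 0.25 + 0.5 * stats::runif(n)) / n)
}

#' Generate a synthetic regulon reporter library
#'
#' Per gene, the basal level is drawn log-uniformly (stratified across
#' equal log-width bins so the configured decade span is actually
#' realized), the induction fold change is drawn log-uniformly over the
#' configured range the same way, and the half-max time is coupled to the
#' fold change through a Gaussian copula with the configured negative
#' correlation. The mean trace is a four-parameter logistic from basal to
#' basal times fold change; replicates are the mean times multiplicative
#' lognormal noise. Bit-identical for a fixed seed.
#'
#' @param spec A [regulon_spec()].
#' @param seed Integer seed.
#' @return A list of [gene_time_course()] objects with attribute `truth`
#'   (data frame of the generating `basal`, `fold`, `k`, `t50` per gene).
#' @export
gen_regulon_library <- function(spec = regulon_spec(), seed = 1) {
  stopifnot(inherits(spec, "regulon_spec"))
  withr::with_seed(seed, {
    n <- spec$n_genes
    basal <- spec$basal_min * 10^(stratified_unif(n) * spec$basal_decades)
    lfr <- log(spec$fold_range)
    fold <- exp(lfr[1] + stratified_unif(n) * diff(lfr))
    # couple t50 to fold change: rank-based Gaussian copula
    z_fold <- stats::qnorm(rank(fold) / (n + 1))
    rho <- spec$kinetic_rho
    z_t50 <- rho * z_fold + sqrt(1 - rho^2) * stats::rnorm(n)
    t50 <- spec$t50_range[1] + diff(spec$t50_range) * stats::pnorm(z_t50)
    # rapid genes rise steeply: rate inversely proportional to t50, with
    # jitter; k*t50 >= 5 keeps the pre-stress level at the baseline so the
    # realized induction reaches the configured fold change
    k <- 5 * exp(abs(stats::rnorm(n, 0, 0.25))) / t50

    courses <- vector("list", n)
    for (g in seq_len(n)) {
      mean_trace <- basal[g] + (basal[g] * fold[g] - basal[g]) /
        (1 + exp(-k[g] * (spec$times - t50[g])))
      reps <- vapply(seq_len(spec$n_reps), function(r) {
        mean_trace * exp(stats::rnorm(length(spec$times), 0, spec$replicate_cv))
      }, numeric(length(spec$times)))
      courses[[g]] <- gene_time_course(sprintf("gene%02d", g), spec$times,
                                       mean_trace, replicates = reps)
    }
    names(courses) <- vapply(courses, function(tc) tc$gene, character(1))
    attr(courses, "truth") <- data.frame(
      gene = names(courses), basal = basal, fold = fold, k = k, t50 = t50
    )
    courses
  })
}

#' Generate a synthetic mutant reporter panel
#'
#' Simulates each genotype with the circuit model, samples the reporter
#' fold change at the protocol's times, and applies multiplicative
#' lognormal noise per replicate; per-replicate fold changes are
#' re-referenced to their own time-zero value, as in the flow-cytometry
#' workflow, and averaged.
#'
#' @param genotypes List of [strain_genotype()] objects.
#' @param protocol A [stress_protocol()].
#' @param noise A [noise_spec()].
#' @param base Wild-type `hsr_parameters`.
#' @param seed Integer seed.
#' @param n_reps Replicates (default 3).
#' @return Named list of [observed_time_course()] objects, each with
#'   attribute `truth` (the generating genotype and trajectory).
#' @export
gen_mutant_panel <- function(genotypes, protocol, noise = noise_spec(),
                             base = default_parameters(), seed = 1,
                             n_reps = 3) {
  withr::with_seed(seed, {
    panel <- lapply(genotypes, function(g) {
      traj <- hsr_simulate(make_parameters(g, base), protocol)
      fc <- traj$yfp_fold_change
      reps <- vapply(seq_len(n_reps), function(r) {
        noisy <- fc * exp(stats::rnorm(length(fc), 0, noise$replicate_cv))
        noisy / noisy[1]
      }, numeric(length(fc)))
      values <- rowMeans(reps)
      values[1] <- 1
      obs <- observed_time_course(g$name, protocol$sample_times, values,
                                  sd = apply(reps, 1, stats::sd),
                                  n_reps = n_reps)
      attr(obs, "truth") <- list(genotype = g, trajectory = traj)
      obs
    })
    names(panel) <- vapply(genotypes, function(g) g$name, character(1))
    panel
  })
}

#' Generate a synthetic ethanol dose-response panel
#'
#' Four-hour reporter responses are drawn from an increasing Hill curve
#' and relative growth responses from a decreasing Hill curve; the true
#' half-maximal concentrations (EC50 for the reporter, IC50 for growth)
#' and Hill shapes come from the shipped calibration config, never from
#' hard-coded constants. Per-concentration reporter time courses are also
#' emitted: sigmoidal in time above the activation threshold, a shallow
#' drift below it.
#'
#' @param concentrations Percent v/v grid; must include 0 and bracket the
#'   half-maximal region.
#' @param times Times (min) for the per-concentration time courses.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param calibration Calibration list (see [hsr_calibration()]).
#' @param n_reps Replicates.
#' @return A list with `yfp` and `growth` ([dose_response_curve()]
#'   objects, replicate means), `time_courses` (per-concentration data
#'   frames), and `truth`.
#' @export
gen_ethanol_panel <- function(concentrations = c(0, 2, 4, 5, 6, 7, 8, 9, 10, 12),
                              times = seq(0, 240, length.out = 10),
                              noise = noise_spec(), seed = 1,
                              calibration = hsr_calibration(), n_reps = 3) {
  syn <- calibration$synthetic
  if (!0 %in% concentrations) stop("concentration grid must include 0")
  if (max(concentrations) < syn$ec50_true || min(concentrations) > syn$ec50_true) {
    stop("concentration grid must span the half-maximal region")
  }
  withr::with_seed(seed, {
    hill <- function(cc, c50, n) cc^n / (c50^n + cc^n)
    yfp_true <- syn$yfp_floor +
      (syn$yfp_ceiling - syn$yfp_floor) *
        hill(concentrations, syn$ec50_true, syn$hill_n_yfp)
    growth_true <- 1 - (1 - syn$growth_floor) *
      hill(concentrations, syn$ic50_true, syn$hill_n_growth)

    noisy_mean <- function(mu) {
      reps <- vapply(seq_len(n_reps), function(r) {
        mu * exp(stats::rnorm(length(mu), 0, noise$replicate_cv))
      }, numeric(length(mu)))
      list(mean = rowMeans(reps), reps = reps)
    }
    yfp <- noisy_mean(yfp_true)
    growth <- noisy_mean(growth_true)

    tc <- lapply(seq_along(concentrations), function(i) {
      cc <- concentrations[i]
      if (cc >= 6) {
        k <- 0.04
        t50 <- 100
        g <- stats::plogis(k * (times - t50))
        g <- (g - g[1]) / (stats::plogis(k * (240 - t50)) - g[1])
        mu <- syn$yfp_floor + (yfp_true[i] - syn$yfp_floor) * g
      } else {
        # sub-threshold: shallow linear drift around baseline
        mu <- syn$yfp_floor * (1 + 0.05 * times / max(times))
      }
      vals <- mu * exp(stats::rnorm(length(mu), 0, noise$replicate_cv))
      data.frame(concentration_pct = cc, time_min = times, value = vals)
    })

    list(
      yfp = dose_response_curve(concentrations, yfp$mean,
                                replicates = yfp$reps,
                                direction = "increasing"),
      growth = dose_response_curve(concentrations, growth$mean,
                                   replicates = growth$reps,
                                   direction = "decreasing"),
      time_courses = tc,
      truth = list(ec50 = syn$ec50_true, ic50 = syn$ic50_true,
                   hill_n_yfp = syn$hill_n_yfp,
                   hill_n_growth = syn$hill_n_growth)
    )
  })
}

#' Generate a synthetic flow-cytometry sample
#'
#' Live events have lognormal side scatter and fluorescence proportional
#' to side scatter times the target expression level with lognormal
#' per-cell noise, so fluorescence/scatter is an unbiased readout of
#' expression. Dead events (the configured fraction) have attenuated
#' scatter and even more strongly attenuated fluorescence -- the artifact
#' that side-scatter normalization plus the median is meant to reject.
#'
#' @param mean_level Target normalized expression level (a.u.).
#' @param noise A [noise_spec()].
#' @param n_events Number of events (>= 100).
#' @param seed Integer seed.
#' @return A [flow_sample()] with attribute `truth` (the target level and
#'   dead fraction).
#' @export
gen_flow_sample <- function(mean_level, noise = noise_spec(),
                            n_events = 10000, seed = 1) {
  if (n_events < 100) stop("n_events must be >= 100")
  withr::with_seed(seed, {
    n_dead <- round(n_events * noise$dead_fraction)
    n_live <- n_events - n_dead
    ssc_live <- exp(stats::rnorm(n_live, log(100), noise$ssc_sigma))
    fluor_live <- mean_level * ssc_live *
      exp(stats::rnorm(n_live, 0, noise$cell_sigma))
    ssc_dead <- noise$dead_ssc_atten *
      exp(stats::rnorm(n_dead, log(100), noise$ssc_sigma))
    fluor_dead <- noise$dead_fluor_atten * mean_level * ssc_dead /
      noise$dead_ssc_atten *
      exp(stats::rnorm(n_dead, 0, noise$cell_sigma))
    idx <- sample.int(n_events)
    s <- flow_sample(c(fluor_live, fluor_dead)[idx],
                     c(ssc_live, ssc_dead)[idx])
    attr(s, "truth") <- list(mean_level = mean_level,
                             dead_fraction = noise$dead_fraction)
    s
  })
}

#' Generate synthetic two-phase growth curves
#'
#' OD600 follows a logistic within each temperature phase: a 30 C
#' pre-growth phase up to the shift time, then a 37 C phase whose
#' intrinsic rate is reduced per strain by its deficit. Sampling every 20
#' minutes over 24 hours, two replicates, multiplicative noise.
#'
#' @param deficits Named numeric vector of fractional reductions of the
#'   post-shift growth rate per strain (0 = wild-type-like).
#' @param seed Integer seed.
#' @param r30,r37 Intrinsic logistic rates (1/min) at 30 C and 37 C.
#' @param K Carrying capacity (OD600).
#' @param od0 Inoculation OD600.
#' @param shift_time Temperature shift time (min).
#' @param horizon Total assay length (min).
#' @param cv Multiplicative noise CV (0 for noiseless curves).
#' @param n_reps Replicates per strain.
#' @return Named list (per strain) of lists of [growth_series()], with
#'   attribute `truth` (per-strain post-shift rates).
#' @export
gen_growth_curves <- function(deficits = c(WT = 0), seed = 1,
                              r30 = 0.004, r37 = 0.008, K = 1.2,
                              od0 = 0.1, shift_time = 240,
                              horizon = 1440, cv = 0.02, n_reps = 2) {
  if (any(deficits < 0 | deficits >= 1)) stop("deficits must be in [0, 1)")
  times <- seq(0, horizon, by = 20)
  logistic_od <- function(od_start, r, t) {
    K / (1 + (K / od_start - 1) * exp(-r * t))
  }
  withr::with_seed(seed, {
    out <- lapply(names(deficits), function(strain) {
      r2 <- r37 * (1 - deficits[[strain]])
      od_shift <- logistic_od(od0, r30, shift_time)
      mu <- ifelse(times <= shift_time,
                   logistic_od(od0, r30, times),
                   logistic_od(od_shift, r2, times - shift_time))
      lapply(seq_len(n_reps), function(r) {
        od <- mu * exp(stats::rnorm(length(mu), 0, cv))
        growth_series(times, od, replicate = r)
      })
    })
    names(out) <- names(deficits)
    attr(out, "truth") <- list(
      post_shift_rate = r37 * (1 - deficits), K = K,
      shift_time = shift_time
    )
    out
  })
}
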