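test_that("rss sums squared deviations at observed times", {
  base <- hsr_base()
  proto <- heat_protocol()
  tj <- hsr_simulate(base, proto)

  obs_same <- observed_time_course("wt", proto$sample_times, tj$yfp_fold_change)
  expect_identical(rss(obs_same, tj), 0)

  # a uniform +1 offset at all 10 points (built directly, bypassing the
  # constructor's fold-change-is-1-at-t0 invariant, to test rss arithmetic)
  obs_shift <- structure(list(strain = "wt", times = proto$sample_times,
                              values = tj$yfp_fold_change + 1, sd = NULL,
                              n_reps = 3), class = "hsr_observed")
  expect_equal(rss(obs_shift, tj), 10)

  set.seed(5)
  eps <- c(0, stats::runif(9, -0.2, 0.2))
  obs_eps <- observed_time_course("wt", proto$sample_times,
                                  tj$yfp_fold_change + eps)
  expect_equal(rss(obs_eps, tj), sum(eps^2), tolerance = 1e-12)

  obs_bad <- observed_time_course("wt", c(0, 33, 77), c(1, 2, 3))
  expect_error(rss(obs_bad, tj), "subset")
})

test_that("release-scale fit recovers the generating scale", {
  base <- hsr_base()
  proto <- heat_protocol()
  gts <- list(strain_genotype("WT", "WT"),
              strain_genotype("fes1", "AUX_DHSE", release_scale = 0.3))
  panel <- gen_mutant_panel(gts, proto, noise_spec(replicate_cv = 0),
                            base, seed = 1)

  # wild-type data refit: optimum at the upper search bound
  f_wt <- fit_release_scale(panel$WT, base, proto)
  expect_gte(f_wt$release_scale, 0.97)
  expect_lt(f_wt$rss, 1e-6)

  # noiseless mutant data
  f03 <- fit_release_scale(panel$fes1, base, proto)
  expect_lt(abs(f03$release_scale - 0.3), 0.01)
  expect_equal(f03$convergence, "ok")

  # RSS profile is unimodal on the 40-point grid: monotone descent into
  # the global minimum and ascent out of it (up to solver jitter)
  r <- f03$profile$rss
  i_min <- which.min(r)
  slack <- abs(r) * 1e-4 + 1e-12
  expect_true(all(diff(r[1:i_min]) <= slack[1:(i_min - 1)]))
  expect_true(all(diff(r[i_min:length(r)]) >= -slack[i_min:(length(r) - 1)]))

  # noisy recovery, 5% replicate noise
  noisy <- gen_mutant_panel(gts[2], proto, noise_spec(replicate_cv = 0.05),
                            base, seed = 11)
  f11 <- fit_release_scale(noisy$fes1, base, proto)
  expect_gte(f11$release_scale, 0.24)
  expect_lte(f11$release_scale, 0.36)
})

test_that("early-time overshoot cannot be explained by release reduction", {
  base <- hsr_base()
  proto <- heat_protocol()
  gt <- list(strain_genotype("fes1", "AUX_DHSE", release_scale = 0.3))
  panel <- gen_mutant_panel(gt, proto, noise_spec(replicate_cv = 0),
                            base, seed = 1)
  f_clean <- fit_release_scale(panel$fes1, base, proto)

  vals <- panel$fes1$values
  early <- proto$sample_times > 0 & proto$sample_times <= 30
  vals[early] <- vals[early] * 2
  obs_over <- observed_time_course("hsp42", proto$sample_times, vals)
  f_over <- fit_release_scale(obs_over, base, proto)
  expect_gt(f_over$rss, 10 * max(f_clean$rss, 1e-8))
})

test_that("fitting never mutates its input parameter object", {
  base <- hsr_base()
  proto <- heat_protocol()
  snapshot <- unserialize(serialize(base, NULL))
  gt <- list(strain_genotype("m", "AUX_DHSE", release_scale = 0.5))
  panel <- gen_mutant_panel(gt, proto, noise_spec(replicate_cv = 0),
                            base, seed = 2)
  invisible(fit_release_scale(panel$m, base, proto))
  expect_identical(base, snapshot)
})

test_that("ethanol re-calibration recovers client parameters and leaves the
           core loop untouched", {
  base <- hsr_base()
  pe <- stress_protocol("ethanol", magnitude = 8.5)

  truthp <- base
  truthp$s_eth <- base$s_eth * 2
  truthp$k_bU <- base$k_bU * 0.5
  tj <- hsr_simulate(truthp, pe)
  obs <- observed_time_course("wt_etoh", pe$sample_times, tj$yfp_fold_change)

  fit <- fit_ethanol_baseline(obs, base, pe)
  info <- attr(fit, "fit")
  expect_lt(abs(info$s_eth_multiplier - 2) / 2, 0.1)
  expect_lt(abs(info$k_bU_multiplier - 0.5) / 0.5, 0.1)
  untouched <- setdiff(names(base), c("s_eth", "k_bU"))
  expect_identical(unclass(fit)[untouched], unclass(base)[untouched])

  # data generated at the baseline itself: multipliers near 1
  tj0 <- hsr_simulate(base, pe)
  obs0 <- observed_time_course("wt_etoh", pe$sample_times, tj0$yfp_fold_change)
  fit0 <- fit_ethanol_baseline(obs0, base, pe)
  info0 <- attr(fit0, "fit")
  expect_lt(abs(info0$s_eth_multiplier - 1), 0.05)
  expect_lt(abs(info0$k_bU_multiplier - 1), 0.05)

  # noisy data: the optimizer must improve on the starting parameters
  noisy_vals <- tj0$yfp_fold_change *
    withr::with_seed(7, exp(stats::rnorm(10, 0, 0.05)))
  noisy_vals[1] <- 1
  obs7 <- observed_time_course("wt_etoh", pe$sample_times, noisy_vals)
  fit7 <- fit_ethanol_baseline(obs7, base, pe)
  expect_lt(attr(fit7, "fit")$rss, rss(obs7, tj0))

  expect_error(fit_ethanol_baseline(obs, base, heat_protocol()), "ethanol")
})
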