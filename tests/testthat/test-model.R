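test_that("stress multiplier follows the protocol schedule", {
  base <- hsr_base()
  none <- stress_protocol("none")
  expect_equal(stress_multiplier(none, base, c(0, 10, 240)), c(1, 1, 1))

  heat <- stress_protocol("heat")
  expect_equal(stress_multiplier(heat, base, 10), base$s_heat)

  eth <- stress_protocol("ethanol", magnitude = 8.5)
  # onset is inclusive: t = t_on is already stressed
  expect_equal(stress_multiplier(eth, base, 0), base$s_eth)

  delayed <- stress_protocol("heat", t_on = 30)
  expect_equal(stress_multiplier(delayed, base, 10), 1)
  expect_equal(stress_multiplier(delayed, base, 30), base$s_heat)

  expect_error(stress_multiplier(heat, base, -1), "t must be")
})

test_that("genotype overrides map onto parameters", {
  base <- hsr_base()

  wt <- make_parameters(strain_genotype("wt", "WT"), base)
  expect_identical(unclass(wt), unclass(base))

  aux <- make_parameters(strain_genotype("fes1", "AUX_DHSE",
                                         release_scale = 0.3), base)
  expect_identical(aux$k_rel, 0.3 * base$k_rel)
  other <- setdiff(names(base), "k_rel")
  expect_identical(unclass(aux)[other], unclass(base)[other])

  dfbl <- make_parameters(strain_genotype("hsp70", "HSP70_DFBL"), base)
  expect_identical(dfbl$beta1, 0)
  tot_wt <- sum(basal_steady_state(base)[c("Hf", "HU", "HF")])
  tot_dfbl <- sum(basal_steady_state(dfbl)[c("Hf", "HU", "HF")])
  expect_lt(abs(tot_dfbl - tot_wt) / tot_wt, 0.01)

  expect_error(strain_genotype("bad", "WT", release_scale = 0.5), "WT")
  expect_error(strain_genotype("bad", "AUX_DHSE", release_scale = 0), "0, 1")
  expect_error(strain_genotype("bad", "AUX_DHSE", release_scale = 1.2), "0, 1")
  expect_error(make_parameters(list(kind = "WT"), base), "hsr_genotype")
})

test_that("derivatives vanish at steady state, conserve Hsf1, and lose
           Hsf1 affinity at extreme client load", {
  base <- hsr_base()
  ss <- basal_steady_state(base)
  expect_lt(max(abs(hsr_derivatives(ss, base, 1))), 1e-9)

  # Hsf1 conservation by construction, at arbitrary states
  set.seed(42)
  for (i in 1:20) {
    st <- ss * exp(stats::rnorm(length(ss), 0, 1))
    st["HF"] <- stats::runif(1) * base$F_tot
    st["Ff"] <- base$F_tot - st["HF"]
    d <- hsr_derivatives(st, base, sample(c(1, base$s_heat), 1))
    expect_equal(unname(d["Ff"] + d["HF"]), 0)
  }

  # U -> infinity: the affinity switch abolishes Hsp70-Hsf1 binding, so
  # the complex only decays
  st <- ss
  st["U"] <- 1e12
  d <- hsr_derivatives(st, base, 1)
  expect_equal(unname(d["HF"]),
               -(base$k_uF + base$gamma) * unname(st["HF"]),
               tolerance = 1e-9)
})

test_that("basal steady state converges, persists, and represses Hsf1", {
  base <- hsr_base()
  ss <- basal_steady_state(base)
  expect_lt(max(abs(hsr_derivatives(ss, base, 1))), 1e-8)
  expect_gt(ss[["Ym"]], 0)
  expect_lt(ss[["Ff"]] / base$F_tot, 0.5)

  # state reproduces itself under 100 further minutes of integration
  tj <- hsr_simulate(base, stress_protocol("none", sample_times = c(0, 50, 100)))
  drift <- abs(tj$states[3, ] - ss) / pmax(abs(ss), 1e-10)
  expect_lt(max(drift), 1e-6)
})

test_that("no-stress and delayed-onset simulations hold the pre-stress level", {
  base <- hsr_base()
  tj <- hsr_simulate(base, stress_protocol("none"))
  expect_true(all(tj$yfp_fold_change >= 0.999 & tj$yfp_fold_change <= 1.001))

  delayed <- stress_protocol("heat", t_on = 60,
                             sample_times = seq(0, 240, by = 30))
  tjd <- hsr_simulate(base, delayed)
  expect_true(all(abs(tjd$yfp_fold_change[tjd$times <= 60] - 1) < 1e-3))
  expect_gt(tjd$yfp_fold_change[length(tjd$times)], 1.5)
})

test_that("adaptive solution matches the fixed-step RK4 oracle", {
  base <- hsr_base()
  proto <- heat_protocol()
  ref <- rk4_simulate(base, proto, dt = 0.01)
  tj <- hsr_simulate(base, proto)
  rel <- abs(tj$states - ref) / pmax(abs(ref), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("trajectories conserve Hsf1 and stay non-negative", {
  base <- hsr_base()
  proto <- heat_protocol()
  strains <- list(
    base,
    make_parameters(strain_genotype("a", "AUX_DHSE", release_scale = 0.2), base),
    make_parameters(strain_genotype("d", "HSP70_DFBL"), base)
  )
  for (p in strains) {
    tj <- hsr_simulate(p, proto)
    cons <- abs(tj$states[, "Ff"] + tj$states[, "HF"] - p$F_tot) / p$F_tot
    expect_lt(max(cons), 1e-6)
    expect_true(all(tj$states >= 0))
    expect_identical(tj$yfp_fold_change[1], 1)
  }
})

test_that("reducing productive release elevates the reporter endpoint", {
  base <- hsr_base()
  proto <- heat_protocol()
  wt <- hsr_simulate(base, proto)
  slow <- base
  slow$k_rel <- base$k_rel / 5
  tj <- hsr_simulate(slow, proto)
  expect_gt(tj$yfp_fold_change[10], wt$yfp_fold_change[10])
})

test_that("trajectory export is tidy and matches the wide layout", {
  base <- hsr_base()
  tj <- hsr_simulate(base, stress_protocol("heat",
                                           sample_times = c(0, 120, 240)))
  long <- as.data.frame(tj)
  expect_setequal(names(long), c("time_min", "species", "value"))
  expect_equal(nrow(long), 3 * 8)
  ym <- long$value[long$species == "Ym"]
  expect_equal(ym, unname(tj$states[, "Ym"]))
  fc <- long$value[long$species == "yfp_fold_change"]
  expect_equal(fc, unname(tj$yfp_fold_change))
})
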