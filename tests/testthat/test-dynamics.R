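std_times <- seq(0, 240, length.out = 10)

test_that("logistic fit recovers exact parameters and flags degenerate
           series", {
  y <- logistic4(std_times, B = 100, M = 800, k = 0.05, t50 = 60)
  fit <- fit_logistic(gene_time_course("g1", std_times, y))
  expect_false(fit$degenerate)
  expect_equal(fit$B, 100, tolerance = 1e-6)
  expect_equal(fit$M, 800, tolerance = 1e-6)
  expect_equal(fit$k, 0.05, tolerance = 1e-6)
  expect_equal(fit$t50, 60, tolerance = 1e-6)

  flat <- fit_logistic(gene_time_course("g2", std_times, rep(50, 10)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$t50))
  expect_true(is.na(time_to_half_max(flat)))
  expect_true(is.na(max_induction_rate(flat)))

  declining <- fit_logistic(gene_time_course("g3", std_times,
                                             100 * exp(-0.01 * std_times)))
  expect_true(declining$degenerate)

  expect_error(fit_logistic(gene_time_course("g4", c(0, 60, 120),
                                             c(1, 2, 3))), "6 time points")
})

test_that("half-max time and maximal rate are the logistic closed forms", {
  y <- logistic4(std_times, B = 0, M = 1, k = 0.1, t50 = 75)
  fit <- fit_logistic(gene_time_course("g", std_times, y))
  expect_equal(time_to_half_max(fit), 75, tolerance = 1e-6)

  # the fitted curve reaches exactly the mid level at t50
  expect_equal(predict_logistic(fit, fit$t50) - fit$B,
               (fit$M - fit$B) / 2, tolerance = 1e-12)

  # bisection oracle for the half-level crossing
  half <- fit$B + (fit$M - fit$B) / 2
  lo <- 0; hi <- 240
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (predict_logistic(fit, mid) < half) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, fit$t50, tolerance = 1e-6)

  # maximal slope k (M - B) / 4, from the definition
  fit2 <- list(B = 0, M = 4, k = 1, t50 = 30, degenerate = FALSE)
  class(fit2) <- "logistic_fit"
  expect_identical(max_induction_rate(fit2), 1)

  # finite-difference oracle on a fine grid
  grid <- seq(0, 240, by = 0.01)
  fd <- max(diff(predict_logistic(fit, grid)) / 0.01)
  expect_equal(max_induction_rate(fit), fd, tolerance = 1e-4)

  # shifting baseline and plateau together leaves the rate unchanged
  fit3 <- fit2; fit3$B <- fit2$B + 10; fit3$M <- fit2$M + 10
  expect_identical(max_induction_rate(fit3), max_induction_rate(fit2))
})

test_that("fold-change normalization rescales rows to basal level", {
  courses <- list(
    gene_time_course("a", c(0, 60, 120), c(10, 20, 80)),
    gene_time_course("b", c(0, 60, 120), c(5, 5, 5))
  )
  m <- regulon_matrix(courses)
  fc <- fold_change_normalize(m)
  expect_equal(unname(fc["a", ]), c(1, 2, 8))
  expect_equal(unname(fc["b", ]), c(1, 1, 1))
  expect_true(all(fc[, 1] == 1))
  expect_identical(attr(fc, "kind"), "fold_change")
  expect_error(fold_change_normalize(fc), "raw")

  bad <- m
  bad[1, 1] <- 0
  expect_error(fold_change_normalize(bad), "basal")
})

test_that("PCA matches an eigendecomposition oracle with deterministic
           signs", {
  # exact rank-1 matrix: PC1 carries all variance
  m1 <- outer(c(1, 2, 5, 9), c(1, 1.5, 2, 4, 8))
  p1 <- run_pca(m1)
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-9)

  set.seed(3)
  m <- matrix(stats::rexp(50, 0.1), 10, 5)
  p <- run_pca(m)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-9)
  oracle <- pca_oracle(m)
  expect_equal(unname(p$scores), unname(oracle$scores), tolerance = 1e-8)
  expect_equal(p$variance_explained[1:4], oracle$variance_explained[1:4],
               tolerance = 1e-8)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }

  expect_error(run_pca(matrix(1, 5, 4)), "rank 0")
  expect_error(run_pca(matrix(1:4, 2, 2)), ">= 3")
})

test_that("tradeoff fit recovers an exact power law with bootstrap CI", {
  t_half <- c(10, 20, 40, 80, 160)
  rate <- 100 / t_half
  tf <- tradeoff_fit(t_half, rate, n_boot = 200, seed = 1)
  expect_equal(tf$slope, -1, tolerance = 1e-9)
  expect_equal(tf$intercept, 2, tolerance = 1e-9)
  expect_true(tf$slope_ci[1] <= tf$slope && tf$slope <= tf$slope_ci[2])
  expect_true(tf$intercept_ci[1] <= tf$intercept &&
                tf$intercept <= tf$intercept_ci[2])
  expect_error(tradeoff_fit(c(10, 20), c(5, 2)), "5 non-degenerate")
})

test_that("synthetic regulon shows the expected PCA structure and
           rate-timing tradeoff", {
  lib <- gen_regulon_library(regulon_spec(), seed = 1)
  truth <- attr(lib, "truth")
  m <- regulon_matrix(lib)

  # raw matrix: expression magnitude dominates PC1
  p_raw <- run_pca(m)
  expect_gte(p_raw$variance_explained[1], 0.95)
  expect_gt(abs(cor(p_raw$scores[, 1], log10(truth$basal),
                    method = "spearman")), 0.9)

  # fold-change matrix: leading PCs order genes by induction timing
  p_fc <- run_pca(fold_change_normalize(m))
  s12 <- p_fc$scores[, 1] + p_fc$scores[, 2]
  expect_gt(abs(cor(truth$t50, s12, method = "spearman")), 0.7)

  # normalization then PCA is invariant to rescaling a gene's raw row
  m2 <- m
  m2[7, ] <- m2[7, ] * 13.7
  p_fc2 <- run_pca(fold_change_normalize(m2))
  expect_equal(p_fc2$scores, p_fc$scores, tolerance = 1e-12)

  # slower genes induce at lower maximal rates
  fits <- lapply(lib, fit_logistic)
  ok <- !vapply(fits, `[[`, logical(1), "degenerate")
  expect_gte(sum(ok), 5)
  tf <- tradeoff_fit(vapply(fits[ok], time_to_half_max, numeric(1)),
                     vapply(fits[ok], max_induction_rate, numeric(1)),
                     n_boot = 200, seed = 1)
  expect_lt(tf$slope, 0)
})
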