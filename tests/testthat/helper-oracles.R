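# Shared fixtures and independent oracles for the test suite.

hsr_base <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_parameters()
    cache
  }
})

heat_protocol <- function() stress_protocol("heat")

# Brute-force fixed-step classical RK4 integration of the circuit; the
# independent oracle for the adaptive solver.
rk4_simulate <- function(params, protocol, dt = 0.01) {
  y <- basal_steady_state(params)
  times <- protocol$sample_times
  out <- matrix(NA_real_, length(times), length(y),
                dimnames = list(NULL, names(y)))
  out[1, ] <- y
  t <- times[1]
  for (i in 2:length(times)) {
    target <- times[i]
    while (t < target - 1e-9) {
      h <- min(dt, target - t)
      s <- stress_multiplier(protocol, params, t + h / 2)
      k1 <- hsr_derivatives(y, params, s)
      k2 <- hsr_derivatives(y + h / 2 * k1, params, s)
      k3 <- hsr_derivatives(y + h / 2 * k2, params, s)
      k4 <- hsr_derivatives(y + h * k3, params, s)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  out
}

# Evaluate the four-parameter logistic directly.
logistic4 <- function(t, B, M, k, t50) {
  B + (M - B) / (1 + exp(-k * (t - t50)))
}

# Eigendecomposition-of-covariance PCA oracle with the same deterministic
# sign convention as run_pca.
pca_oracle <- function(m) {
  centered <- scale(m, center = TRUE, scale = FALSE)
  cv <- crossprod(centered) / (nrow(m) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  vec <- eig$vectors
  for (j in seq_len(ncol(vec))) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  list(scores = centered %*% vec,
       variance_explained = eig$values / sum(eig$values))
}
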