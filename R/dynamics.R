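#' Construct a gene reporter time course
#'
#' Mean reporter level of a single regulon gene across a stress time
#' course, with per-replicate measurements retained.
#'
#' @param gene Gene label.
#' @param times Strictly increasing times (min).
#' @param means Mean reporter level at each time (a.u., > 0).
#' @param replicates Optional matrix (time x replicate) of replicate
#'   levels.
#' @return An object of class `gene_time_course`.
#' @export
gene_time_course <- function(gene, times, means, replicates = NULL) {
  times <- as.numeric(times)
  means <- as.numeric(means)
  if (length(times) != length(means)) stop("times and means lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(means <= 0)) stop("levels must be > 0")
  structure(list(gene = gene, times = times, means = means,
                 replicates = replicates),
            class = "gene_time_course")
}

#' Fit a four-parameter logistic induction curve
#'
#' Least-squares fit of `f(t) = B + (M - B) / (1 + exp(-k (t - t50)))` to
#' a gene's mean time course. The logistic is used because the two kinetic
#' statistics extracted downstream -- the time to half-maximal induction
#' and the maximal induction rate -- are closed-form in its parameters.
#' Starting values come from the data (baseline = min, plateau = max,
#' `t50` = time nearest mid-level, `k` = 4 / time range) and the fit is
#' bounded so that `M >= B >= 0`, `k > 0` and `t50` lies within twice the
#' horizon. Series with no induction signal (flat, or decreasing) are
#' returned as degenerate fits with `NA` parameters rather than errors, so
#' a library-wide sweep never aborts.
#'
#' @param tc A [gene_time_course()] (>= 6 time points).
#' @return An object of class `logistic_fit` with fields `B`, `M`, `k`,
#'   `t50`, `rss`, `degenerate` and `gene`.
#' @export
fit_logistic <- function(tc) {
  stopifnot(inherits(tc, "gene_time_course"))
  t <- tc$times
  yv <- tc$means
  if (length(t) < 6) stop("need at least 6 time points")

  degenerate <- function(reason) {
    structure(list(B = NA_real_, M = NA_real_, k = NA_real_,
                   t50 = NA_real_, rss = NA_real_, degenerate = TRUE,
                   reason = reason, gene = tc$gene),
              class = "logistic_fit")
  }
  rng <- max(yv) - min(yv)
  if (rng <= 1e-12 * max(yv)) return(degenerate("constant series"))
  # monotone decreasing: the rising logistic cannot represent it
  if (stats::cor(t, yv, method = "spearman") < -0.99) {
    return(degenerate("decreasing series"))
  }

  mid <- min(yv) + rng / 2
  start <- list(B = min(yv), M = max(yv),
                k = 4 / diff(range(t)),
                t50 = t[which.min(abs(yv - mid))])
  horizon <- max(t)
  # baseline/plateau left unbounded in the optimizer (a lower bound of 0
  # makes the Levenberg-Marquardt scaling singular when the start sits on
  # it); the type invariants B >= 0, M >= B are enforced on the result
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ B + (M - B) / (1 + exp(-k * (t - t50))),
      start = start,
      lower = c(B = -Inf, M = -Inf, k = 1e-6, t50 = 0),
      upper = c(B = Inf, M = Inf, k = Inf, t50 = 2 * horizon),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(degenerate("non-convergence"))
  cf <- stats::coef(fit)
  if (cf[["B"]] < 0 && cf[["B"]] > -1e-8 * cf[["M"]]) cf[["B"]] <- 0
  if (cf[["M"]] < cf[["B"]]) return(degenerate("k bound violated"))
  if (cf[["B"]] < 0) return(degenerate("negative baseline"))
  structure(list(B = cf[["B"]], M = cf[["M"]], k = cf[["k"]],
                 t50 = cf[["t50"]], rss = sum(stats::resid(fit)^2),
                 degenerate = FALSE, reason = NULL, gene = tc$gene),
            class = "logistic_fit")
}

#' Evaluate a fitted logistic at given times
#'
#' @param fit A non-degenerate `logistic_fit`.
#' @param t Times (min).
#' @return Fitted levels at `t`.
#' @export
predict_logistic <- function(fit, t) {
  if (isTRUE(fit$degenerate)) stop("degenerate fit")
  fit$B + (fit$M - fit$B) / (1 + exp(-fit$k * (t - fit$t50)))
}

#' Time to half-maximal induction
#'
#' For the logistic family this is exactly the inflection time `t50`,
#' where the level equals `B + (M - B) / 2`.
#'
#' @param fit A `logistic_fit`.
#' @return Minutes; `NA` for degenerate fits.
#' @export
time_to_half_max <- function(fit) {
  if (isTRUE(fit$degenerate)) return(NA_real_)
  fit$t50
}

#' Maximal induction rate
#'
#' The logistic's steepest slope, attained at its inflection:
#' `k (M - B) / 4` (a.u./min). Depends on the induction amplitude
#' `M - B` only, so it is unchanged by shifting baseline and plateau
#' together.
#'
#' @param fit A `logistic_fit`.
#' @return a.u./min; `NA` for degenerate fits.
#' @export
max_induction_rate <- function(fit) {
  if (isTRUE(fit$degenerate)) return(NA_real_)
  fit$k * (fit$M - fit$B) / 4
}

#' Assemble a regulon matrix from gene time courses
#'
#' @param courses List of [gene_time_course()] objects sharing one time
#'   grid.
#' @return A `regulon_matrix`: genes x time points matrix of mean levels
#'   with attribute `kind = "raw"` and the times as an attribute.
#' @export
regulon_matrix <- function(courses) {
  times <- courses[[1]]$times
  for (tc in courses) {
    if (!isTRUE(all.equal(tc$times, times))) {
      stop("all gene time courses must share the same time grid")
    }
  }
  m <- do.call(rbind, lapply(courses, function(tc) tc$means))
  rownames(m) <- vapply(courses, function(tc) tc$gene, character(1))
  colnames(m) <- paste0("t", times)
  if (anyNA(m)) stop("regulon matrix has missing cells")
  structure(m, kind = "raw", times = times, class = c("regulon_matrix", "matrix"))
}

#' Normalize a raw regulon matrix to fold change
#'
#' Divides each gene's row by its level at the first (pre-stress) time
#' point, so the first column becomes all ones and magnitude differences
#' between genes are removed while induction dynamics are preserved.
#'
#' @param m A raw `regulon_matrix` with a strictly positive first column.
#' @return A `regulon_matrix` flagged `fold_change`.
#' @export
fold_change_normalize <- function(m) {
  if (!identical(attr(m, "kind"), "raw")) stop("input must be a raw matrix")
  basal <- m[, 1]
  if (any(basal <= 0)) stop("zero or negative basal level")
  out <- m / basal
  attr(out, "kind") <- "fold_change"
  out
}

#' Principal component analysis of a regulon matrix
#'
#' Genes are observations and time points are variables. Columns are
#' mean-centered but NOT variance-scaled, so absolute expression magnitude
#' is allowed to dominate the leading component when the input is a raw
#' matrix; run on the fold-change matrix to study induction dynamics
#' instead. The sign of each component is fixed deterministically: the
#' largest-magnitude loading entry of each PC is made positive.
#'
#' @param m A `regulon_matrix` (>= 3 genes, >= 3 time points).
#' @return A list of class `hsr_pca`: `scores` (genes x PCs), `loadings`
#'   (time points x PCs), `variance_explained` (fractions summing to 1).
#' @export
run_pca <- function(m) {
  if (nrow(m) < 3 || ncol(m) < 3) stop("need >= 3 genes and >= 3 time points")
  centered <- scale(unclass(m), center = TRUE, scale = FALSE)
  if (max(abs(centered)) == 0) stop("matrix has rank 0 after centering")
  pc <- stats::prcomp(unclass(m), center = TRUE, scale. = FALSE)
  scores <- pc$x
  loadings <- pc$rotation
  for (j in seq_len(ncol(loadings))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve),
            class = "hsr_pca")
}

#' Fit the induction-rate versus timing tradeoff
#'
#' Across the regulon, genes that reach half-maximal induction later tend
#' to induce more slowly. This is quantified by ordinary least squares of
#' `log10(max_rate)` on `log10(t_half)` with a 95 percent confidence band
#' from bootstrap resampling of genes.
#'
#' @param t_half Per-gene times to half-max (min); must be positive.
#' @param max_rate Per-gene maximal induction rates (a.u./min); positive.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A list of class `tradeoff_fit`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci` (95 percent bootstrap percentile
#'   intervals), and the fitted `lm` object.
#' @export
tradeoff_fit <- function(t_half, max_rate, n_boot = 1000, seed = 1) {
  keep <- is.finite(t_half) & is.finite(max_rate) & t_half > 0 & max_rate > 0
  x <- log10(t_half[keep])
  y <- log10(max_rate[keep])
  if (length(x) < 5) stop("need at least 5 non-degenerate genes")
  fit <- stats::lm(y ~ x)
  coefs <- stats::coef(fit)
  boot <- withr::with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(length(x), replace = TRUE)
      stats::coef(stats::lm(y[idx] ~ x[idx]))
    })
  })
  slope_ci <- stats::quantile(boot[2, ], c(0.025, 0.975), names = FALSE,
                              na.rm = TRUE)
  int_ci <- stats::quantile(boot[1, ], c(0.025, 0.975), names = FALSE,
                            na.rm = TRUE)
  structure(list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
                 slope_ci = slope_ci, intercept_ci = int_ci, lm = fit),
            class = "tradeoff_fit")
}
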