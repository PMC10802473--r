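#' Write a trajectory to tidy or wide CSV
#'
#' @param traj An `hsr_trajectory`.
#' @param path Output CSV path.
#' @param format `"tidy"` (columns `time_min`, `species`, `value`) or
#'   `"wide"` (one column per species).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, format = c("tidy", "wide")) {
  format <- match.arg(format)
  df <- if (format == "tidy") {
    as.data.frame(traj)
  } else {
    data.frame(time_min = traj$times, traj$states,
               yfp_fold_change = traj$yfp_fold_change)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read observed reporter time courses from tidy CSV
#'
#' Expected columns: `strain`, `time_min`, `mean_fold_change`, and
#' optionally `sd` and `n_reps`.
#'
#' @param path CSV path.
#' @return Named list of [observed_time_course()] objects, one per strain.
#' @export
read_observed_csv <- function(path) {
  df <- utils::read.csv(path)
  required <- c("strain", "time_min", "mean_fold_change")
  if (!all(required %in% names(df))) {
    stop("observed CSV needs columns: ", paste(required, collapse = ", "))
  }
  out <- lapply(split(df, df$strain), function(d) {
    d <- d[order(d$time_min), ]
    observed_time_course(
      strain = d$strain[1], times = d$time_min, values = d$mean_fold_change,
      sd = if ("sd" %in% names(d)) d$sd else NULL,
      n_reps = if ("n_reps" %in% names(d)) d$n_reps[1] else 3
    )
  })
  out
}

#' Write observed time courses to tidy CSV
#'
#' @param panel List of [observed_time_course()] objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_observed_csv <- function(panel, path) {
  rows <- lapply(panel, function(obs) {
    data.frame(strain = obs$strain, time_min = obs$times,
               mean_fold_change = obs$values,
               sd = if (is.null(obs$sd)) NA_real_ else obs$sd,
               n_reps = obs$n_reps)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a gene reporter library from tidy CSV
#'
#' Expected columns: `gene`, `time_min`, `replicate`, `level`. Gene means
#' are computed across replicates at each time.
#'
#' @param path CSV path.
#' @return Named list of [gene_time_course()] objects.
#' @export
read_library_csv <- function(path) {
  df <- utils::read.csv(path)
  required <- c("gene", "time_min", "replicate", "level")
  if (!all(required %in% names(df))) {
    stop("library CSV needs columns: ", paste(required, collapse = ", "))
  }
  lapply(split(df, df$gene), function(d) {
    wide <- stats::reshape(d[, c("time_min", "replicate", "level")],
                           idvar = "time_min", timevar = "replicate",
                           direction = "wide")
    wide <- wide[order(wide$time_min), ]
    reps <- as.matrix(wide[, -1, drop = FALSE])
    gene_time_course(d$gene[1], wide$time_min, rowMeans(reps),
                     replicates = reps)
  })
}

#' Write a gene reporter library to tidy CSV
#'
#' @param courses List of [gene_time_course()] objects with replicate
#'   matrices.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(courses, path) {
  rows <- lapply(courses, function(tc) {
    reps <- tc$replicates
    if (is.null(reps)) reps <- matrix(tc$means, ncol = 1)
    do.call(rbind, lapply(seq_len(ncol(reps)), function(r) {
      data.frame(gene = tc$gene, time_min = tc$times, replicate = r,
                 level = reps[, r])
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read growth series from tidy CSV
#'
#' Expected columns: `strain`, `replicate`, `time_min`, `od600`.
#'
#' @param path CSV path.
#' @return Nested named list: per strain, a list of [growth_series()].
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path)
  required <- c("strain", "replicate", "time_min", "od600")
  if (!all(required %in% names(df))) {
    stop("growth CSV needs columns: ", paste(required, collapse = ", "))
  }
  lapply(split(df, df$strain), function(d) {
    lapply(split(d, d$replicate), function(r) {
      r <- r[order(r$time_min), ]
      growth_series(r$time_min, r$od600, replicate = r$replicate[1])
    })
  })
}

#' Read a flow sample from tidy CSV
#'
#' Expected columns: `fluor`, `ssc`, and optionally `sample`.
#'
#' @param path CSV path.
#' @return A [flow_sample()] (one sample per file).
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("fluor", "ssc") %in% names(df))) {
    stop("flow CSV needs columns: fluor, ssc")
  }
  label <- if ("sample" %in% names(df)) as.character(df$sample[1]) else "sample"
  flow_sample(df$fluor, df$ssc, label = label)
}
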