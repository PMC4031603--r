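# Regional loading metrics for one stance: peak pressure (PP, kPa),
# time-to-peak pressure (TPP, % of stance), pressure-time integral (PTI,
# kPa.s) and centre-of-pressure (COP) mean velocity (m/s), per region and
# for the whole foot, plus the across-step subject aggregate.

#' Per-region peak-pressure time series
#'
#' For each of the six anatomical regions, the regional curve is the
#' per-frame maximum pressure over the region's sensors (the convention
#' behind the "peak pressure temporal series" from which TPP is read). A
#' region with no sensors yields an all-zero, inactive series.
#'
#' @param rec A [pressure_recording()].
#' @param phase A single stance phase.
#' @param masks Region masks from [build_region_masks()].
#' @return Named list (one element per region) of `region_series` objects:
#'   `list(region, values, active)` where `values` is kPa per stance frame.
#' @export
regional_series <- function(rec, phase, masks) {
  fr <- phase_frames(phase, nrow(rec$frames))
  sub <- rec$frames[fr, , drop = FALSE]
  idx_of <- match(masks$sensor_id, rec$grid$sensor_id)
  out <- lapply(REGIONS, function(rg) {
    cols <- idx_of[masks$region == rg]
    vals <- if (length(cols)) {
      apply(sub[, cols, drop = FALSE], 1, max)
    } else {
      rep(0, length(fr))
    }
    structure(list(region = rg, values = as.numeric(vals),
                   active = length(cols) > 0 && any(vals > 0)),
              class = "region_series")
  })
  names(out) <- REGIONS
  out
}

series_values <- function(series) {
  if (inherits(series, "region_series")) series$values else as.numeric(series)
}

#' Peak pressure of a regional series
#'
#' @param series A `region_series` or numeric vector (kPa).
#' @return Maximum pressure in kPa.
#' @export
peak_pressure <- function(series) {
  v <- series_values(series)
  if (length(v) == 0) stop("empty series")
  max(v)
}

#' Time to peak pressure, as percent of stance
#'
#' The instant of the (first) maximum of the regional curve relative to
#' stance duration: `100 * (first argmax - 1) / (N - 1)` over the N stance
#' frames, so a peak in the first frame reads 0% and in the last frame
#' exactly 100%. Ties resolve to the first occurrence.
#'
#' @param series A `region_series` or numeric vector.
#' @return TPP in percent of stance duration, in `[0, 100]`.
#' @export
time_to_peak <- function(series) {
  v <- series_values(series)
  if (length(v) == 0) stop("empty series")
  if (length(v) == 1) return(0)
  100 * (which.max(v) - 1) / (length(v) - 1)
}

#' Pressure-time integral of a regional series
#'
#' Trapezoidal integral of the regional peak-pressure curve over stance
#' time, in kPa.s.
#'
#' @param series A `region_series` or numeric vector (kPa).
#' @param sampling_rate Sampling rate in Hz.
#' @return PTI in kPa.s.
#' @export
pressure_time_integral <- function(series, sampling_rate) {
  stopifnot(sampling_rate > 0)
  v <- series_values(series)
  if (length(v) < 2) return(0)
  (sum(v) - (v[1] + v[length(v)]) / 2) / sampling_rate
}

#' Centre-of-pressure trajectory, total and per region
#'
#' Per frame, the COP is the pressure-times-area weighted centroid of the
#' sensor positions. The total path uses all sensors over the whole stance;
#' each regional path uses that region's sensors over the region's active
#' (non-zero load) frames. Frames with zero load are excluded from a path.
#'
#' @inheritParams regional_series
#' @return List with `total` (data frame `frame`, `x`, `y`) and `regions`
#'   (named list of such data frames; zero rows when a region never loads).
#' @export
cop_trajectory <- function(rec, phase, masks) {
  fr <- phase_frames(phase, nrow(rec$frames))
  sub <- rec$frames[fr, , drop = FALSE]
  path_for <- function(cols) {
    wts <- sweep(sub[, cols, drop = FALSE], 2, rec$grid$area[cols], `*`)
    tot <- rowSums(wts)
    keep <- tot > 0
    data.frame(
      frame = fr[keep],
      x = as.numeric(wts[keep, , drop = FALSE] %*% rec$grid$x[cols]) / tot[keep],
      y = as.numeric(wts[keep, , drop = FALSE] %*% rec$grid$y[cols]) / tot[keep]
    )
  }
  if (nrow(sub) == 0 || max(sub) <= 0) stop("no loaded frame in stance")
  idx_of <- match(masks$sensor_id, rec$grid$sensor_id)
  regions <- lapply(REGIONS, function(rg) {
    cols <- idx_of[masks$region == rg]
    if (!length(cols)) {
      data.frame(frame = integer(0), x = numeric(0), y = numeric(0))
    } else {
      path_for(cols)
    }
  })
  names(regions) <- REGIONS
  list(total = path_for(seq_len(nrow(rec$grid))), regions = regions)
}

cop_path_length <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
}

#' Mean velocity along a COP path
#'
#' Total path length divided by the elapsed time spanned by the path's
#' frames.
#'
#' @param path Data frame with columns `frame`, `x`, `y` (m), as returned in
#'   [cop_trajectory()].
#' @param sampling_rate Sampling rate in Hz.
#' @return Mean COP velocity in m/s.
#' @export
cop_mean_velocity <- function(path, sampling_rate) {
  stopifnot(sampling_rate > 0)
  if (nrow(path) < 2) {
    stop("undefined velocity: COP path has fewer than 2 points")
  }
  elapsed <- (path$frame[nrow(path)] - path$frame[1]) / sampling_rate
  cop_path_length(path) / elapsed
}

#' Rollover metrics for one stance
#'
#' Computes PP, TPP and PTI per region from the regional peak-pressure
#' curves, regional and total COP mean velocities, and the stance duration.
#' A regional COP velocity is `NA` when the region's path has fewer than 2
#' points.
#'
#' @inheritParams regional_series
#' @return A `rollover_metrics` object: list with `regions` (data frame
#'   `region`, `pp`, `tpp`, `pti`, `cop_velocity`), `total_cop_velocity` and
#'   `stance_duration`.
#' @export
rollover_metrics <- function(rec, phase, masks) {
  fr <- phase_frames(phase, nrow(rec$frames))
  fs <- rec$sampling_rate
  series <- regional_series(rec, phase, masks)
  cop <- cop_trajectory(rec, phase, masks)
  regions <- do.call(rbind, lapply(REGIONS, function(rg) {
    s <- series[[rg]]
    pathv <- if (nrow(cop$regions[[rg]]) >= 2) {
      cop_mean_velocity(cop$regions[[rg]], fs)
    } else {
      NA_real_
    }
    data.frame(region = rg,
               pp = peak_pressure(s),
               tpp = time_to_peak(s),
               pti = pressure_time_integral(s, fs),
               cop_velocity = pathv)
  }))
  structure(
    list(regions = regions,
         total_cop_velocity = cop_mean_velocity(cop$total, fs),
         stance_duration = length(fr) / fs),
    class = "rollover_metrics"
  )
}

metric_vector <- function(m) {
  v <- c(with(m$regions, c(rbind(pp, tpp, pti, cop_velocity))),
         m$total_cop_velocity, m$stance_duration)
  names(v) <- c(t(outer(m$regions$region, c("pp", "tpp", "pti", "cop_velocity"),
                        paste, sep = ".")),
                "total_cop_velocity", "stance_duration")
  v
}

#' Aggregate rollover metrics across analysis steps
#'
#' Arithmetic mean and sample SD of every metric across the selected steps
#' of one subject/foot. With a single step the SD is 0 by convention.
#'
#' @param metrics_list List of [rollover_metrics()] objects (one per step).
#' @return A `subject_aggregate`: list with `mean` and `sd`, each a named
#'   numeric vector over all metric fields, plus `n_steps`.
#' @export
aggregate_steps <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1)
  M <- do.call(rbind, lapply(metrics_list, metric_vector))
  sds <- if (nrow(M) == 1) {
    stats::setNames(rep(0, ncol(M)), colnames(M))
  } else {
    apply(M, 2, stats::sd, na.rm = TRUE)
  }
  structure(list(mean = colMeans(M, na.rm = TRUE), sd = sds,
                 n_steps = nrow(M)),
            class = "subject_aggregate")
}

#' Tidy export of rollover metrics
#'
#' One row per (step, region, variable) plus the whole-foot variables, ready
#' for CSV export or statistics.
#'
#' @param metrics_list List of [rollover_metrics()] (one per step).
#' @param subject,side Identifier columns copied into the output.
#' @return A long data frame with columns `subject`, `side`, `step`,
#'   `region`, `variable`, `value`.
#' @export
tidy_rollover_metrics <- function(metrics_list, subject = NA, side = NA) {
  rows <- lapply(seq_along(metrics_list), function(i) {
    v <- metric_vector(metrics_list[[i]])
    nm <- strsplit(names(v), ".", fixed = TRUE)
    data.frame(subject = subject, side = side, step = i,
               region = vapply(nm, function(x)
                 if (length(x) == 2) x[1] else "total", character(1)),
               variable = vapply(nm, function(x) x[length(x)], character(1)),
               value = unname(v))
  })
  do.call(rbind, rows)
}
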