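# Stance-phase detection, analysis-step selection, and the six anatomical
# region masks (heel, midfoot, medial/lateral forefoot, hallux, toes) built
# from percentage divisions of the loaded footprint.

REGIONS <- c("heel", "midfoot", "medial_forefoot", "lateral_forefoot",
             "hallux", "toes")

#' Six anatomical plantar region labels
#'
#' Canonical ordering used throughout the package.
#' @return Character vector of the six region labels.
#' @export
foot_regions <- function() REGIONS

total_force <- function(rec) {
  # vertical force proxy per frame, N: kPa -> Pa times sensor area
  if (nrow(rec$frames) == 0) return(numeric(0))
  as.numeric(rec$frames %*% (rec$grid$area * 1000))
}

#' Detect stance phases in a pressure recording
#'
#' A stance phase is a maximal run of frames whose summed pressure-times-area
#' force exceeds `threshold_fraction` of the trial's maximum force and that
#' lasts at least `min_duration` seconds. Runs are returned in temporal
#' order, non-overlapping, with half-open frame intervals
#' `[start_frame, end_frame)`.
#'
#' @param rec A [pressure_recording()].
#' @param threshold_fraction Force threshold as a fraction of the trial
#'   maximum; default 0.05 (5%), common gait-event practice.
#' @param min_duration Minimum stance duration in seconds (default 0.2 s).
#' @return Data frame with columns `start_frame`, `end_frame`, `duration`
#'   (s); zero rows if no stance is found.
#' @export
detect_stance_phases <- function(rec, threshold_fraction = 0.05,
                                 min_duration = 0.2) {
  stopifnot(inherits(rec, "pressure_recording"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must be in (0, 1)")
  }
  empty <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration = numeric(0))
  f <- total_force(rec)
  if (length(f) == 0 || max(f) <= 0) return(empty)
  on <- f > threshold_fraction * max(f)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= min_duration * rec$sampling_rate)
  if (!any(keep)) return(empty)
  data.frame(
    start_frame = starts[keep],
    end_frame = ends[keep] + 1L,  # half-open
    duration = r$lengths[keep] / rec$sampling_rate
  )
}

#' Select the most central analysis steps across trials
#'
#' Mimics the "middle steps" selection used when a fixed number of valid
#' steps per foot is analysed: the first and last step of every trial are
#' dropped (they include gait initiation/termination), then the
#' `n_required` steps closest to their trial's midpoint are kept.
#'
#' @param phases_per_trial List of stance-phase data frames (one per trial),
#'   as returned by [detect_stance_phases()].
#' @param n_required Number of steps to select (default 25).
#' @return A single data frame of selected phases with columns `trial`,
#'   `step` (index within trial) plus the phase columns.
#' @export
select_analysis_steps <- function(phases_per_trial, n_required = 25) {
  stopifnot(is.list(phases_per_trial), n_required >= 1)
  pool <- list()
  for (ti in seq_along(phases_per_trial)) {
    ph <- phases_per_trial[[ti]]
    k <- nrow(ph)
    if (k <= 2) next  # dropping first and last leaves nothing
    mid <- (k + 1) / 2
    for (si in 2:(k - 1)) {
      pool[[length(pool) + 1L]] <- cbind(
        data.frame(trial = ti, step = si,
                   centrality = abs(si - mid)),
        ph[si, , drop = FALSE]
      )
    }
  }
  pool <- if (length(pool)) do.call(rbind, pool) else
    data.frame(trial = integer(0), step = integer(0), centrality = numeric(0))
  if (nrow(pool) < n_required) {
    counts <- vapply(phases_per_trial, nrow, integer(1))
    stop(sprintf(
      "insufficient steps: %d usable after dropping trial-boundary steps, %d required (steps per trial: %s)",
      nrow(pool), n_required, paste(counts, collapse = ", ")), call. = FALSE)
  }
  ord <- order(pool$centrality, pool$trial, pool$step)
  sel <- pool[ord[seq_len(n_required)], ]
  sel <- sel[order(sel$trial, sel$step), setdiff(names(sel), "centrality")]
  rownames(sel) <- NULL
  sel
}

rotate90 <- function(v) c(-v[2], v[1])

#' Build the six anatomical region masks for a stance
#'
#' The footprint (sensors with non-zero peak pressure during the stance) is
#' divided along its long axis into percentage bands measured from the heel:
#' heel `[0, 27)%`, midfoot `[27, 55)%`, forefoot `[55, 80)%` and the toe
#' band `[80, 100]%` of foot length. The forefoot band is split across its
#' width into a medial strip (55% of the forefoot width) and a lateral strip
#' (45%); the toe band into the hallux (medial 33% of width) and the
#' remaining toes (lateral 67%). The long axis is the area-weighted
#' principal axis of the loaded sensor cloud; the heel end is the end whose
#' sensors load earliest, falling back to the grid's posterior-to-anterior
#' `y` convention when loading carries no temporal signal. Which side is
#' medial follows `rec$side`.
#'
#' Each sensor belongs to the band containing its centre; band intervals are
#' half-open with the distal-most closed, so the partition is deterministic.
#'
#' @param rec A [pressure_recording()].
#' @param phase A single stance phase (one row of
#'   [detect_stance_phases()] output, or a list with `start_frame`,
#'   `end_frame`).
#' @return A `region_mask_set`: data frame with columns `sensor_id`,
#'   `region` covering exactly the footprint sensors, with attributes
#'   `foot_length`, `foot_width` (m) and `axis` (posterior-to-anterior unit
#'   vector).
#' @export
build_region_masks <- function(rec, phase) {
  stopifnot(inherits(rec, "pressure_recording"))
  fr <- phase_frames(phase, nrow(rec$frames))
  sub <- rec$frames[fr, , drop = FALSE]
  peak <- apply(sub, 2, max)
  loaded <- peak > 0
  if (!any(loaded)) stop("empty footprint: no sensor loaded during stance")
  P <- cbind(rec$grid$x[loaded], rec$grid$y[loaded])
  w <- rec$grid$area[loaded]
  ctr <- colSums(P * w) / sum(w)
  Pc <- sweep(P, 2, ctr)
  cov <- crossprod(Pc * sqrt(w)) / sum(w)
  e1 <- eigen(cov, symmetric = TRUE)$vectors[, 1]
  # orient e1 posterior->anterior: early-loading sensors sit at the heel
  onset <- apply(sub[, loaded, drop = FALSE], 2, function(p) {
    i <- which(p > 0)
    if (length(i)) i[1] else NA_integer_
  })
  u0 <- as.numeric(Pc %*% e1)
  ok <- !is.na(onset)
  cv <- if (sum(ok) > 1) stats::cov(u0[ok], as.numeric(onset[ok])) else 0
  if (cv < 0) {
    e1 <- -e1
  } else if (cv == 0 && sum(e1 * c(0, 1)) < 0) {
    e1 <- -e1  # no temporal signal: fall back to +y = anterior
  }
  u <- as.numeric(Pc %*% e1)
  L <- diff(range(u))
  # a point-like footprint has no length to divide: it all reads as heel
  rel <- if (L > 1e-12) (u - min(u)) / L * 100 else rep(0, length(u))
  # medial coordinate: +90-degree rotation of e1 is the left of travel,
  # which is medial for the right foot and lateral for the left
  e2 <- rotate90(e1)
  m <- as.numeric(Pc %*% e2) * if (rec$side == "right") 1 else -1
  region <- character(length(u))
  region[rel < 27] <- "heel"
  region[rel >= 27 & rel < 55] <- "midfoot"
  ff <- rel >= 55 & rel < 80
  tb <- rel >= 80
  split_width <- function(idx, medial_frac) {
    lab <- character(sum(idx))
    mm <- m[idx]
    W <- diff(range(mm))
    cut <- min(mm) + (1 - medial_frac) * W
    lab[mm >= cut] <- "medial"
    lab[mm < cut] <- "lateral"
    lab
  }
  if (any(ff)) {
    region[ff] <- ifelse(split_width(ff, 0.55) == "medial",
                         "medial_forefoot", "lateral_forefoot")
  }
  if (any(tb)) {
    region[tb] <- ifelse(split_width(tb, 0.33) == "medial", "hallux", "toes")
  }
  masks <- data.frame(sensor_id = rec$grid$sensor_id[loaded],
                      region = factor(region, levels = REGIONS))
  attr(masks, "foot_length") <- L
  attr(masks, "foot_width") <- diff(range(m))
  attr(masks, "axis") <- e1
  class(masks) <- c("region_mask_set", "data.frame")
  masks
}

# Normalize a phase argument (one-row data frame or list) to frame indices.
phase_frames <- function(phase, n_frames) {
  s <- phase$start_frame[1]
  e <- phase$end_frame[1]
  if (is.null(s) || is.null(e) || e <= s) stop("invalid stance phase")
  if (s < 1 || e - 1 > n_frames) stop("stance phase outside recording")
  seq.int(s, e - 1L)
}

#' Export a region mask set as CSV
#'
#' @param masks A `region_mask_set` from [build_region_masks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_masks <- function(masks, path) {
  utils::write.csv(as.data.frame(masks)[, c("sensor_id", "region")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
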