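# Shared fixtures and independent oracles, built in code at test time.

# small fully-specified recording: constant pressure on every sensor over a
# frame window, zeros elsewhere
pulse_recording <- function(n_frames = 120, on = 21:80, level = 50,
                            grid = rect_sensor_grid(4, 8), fs = 100,
                            side = "left", cadence = NULL) {
  frames <- matrix(0, n_frames, nrow(grid))
  frames[on, ] <- level
  pressure_recording(grid, frames, sampling_rate = fs, side = side,
                     cadence = cadence)
}

# heel-to-toe progressive loading on a rectangular grid: row i of the grid
# (ordered by y) is loaded from frame i onwards, giving an unambiguous
# posterior-to-anterior onset gradient
progressive_recording <- function(grid = rect_sensor_grid(), fs = 100,
                                  side = "left", level = 100) {
  ys <- sort(unique(grid$y))
  n <- length(ys) + 10
  frames <- matrix(0, n, nrow(grid))
  for (i in seq_along(ys)) {
    frames[i:n, grid$y == ys[i]] <- level
  }
  pressure_recording(grid, frames, sampling_rate = fs, side = side)
}

# Independent brute-force region classifier for an AXIS-ALIGNED grid
# (y posterior->anterior), applying the stated percentage scheme directly:
# 27/28/25/20% of foot length from the heel; medial 55% of the forefoot
# band width; medial 33% of the toe band width for the hallux.
brute_force_regions <- function(grid, loaded, side) {
  y <- grid$y[loaded]; x <- grid$x[loaded]
  rel <- (y - min(y)) / (max(y) - min(y)) * 100
  med <- if (side == "right") -x else x   # medial coordinate
  out <- character(sum(loaded))
  out[rel < 27] <- "heel"
  out[rel >= 27 & rel < 55] <- "midfoot"
  band <- function(sel, frac_med, lab_med, lab_lat) {
    mm <- med[sel]
    cut <- min(mm) + (1 - frac_med) * (max(mm) - min(mm))
    ifelse(mm >= cut, lab_med, lab_lat)
  }
  ff <- rel >= 55 & rel < 80
  tb <- rel >= 80
  out[ff] <- band(ff, 0.55, "medial_forefoot", "lateral_forefoot")
  out[tb] <- band(tb, 0.33, "hallux", "toes")
  out
}

# exact Mann-Whitney two-sided p by enumeration of all group assignments
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(sel) {
    x <- pooled[sel]; y <- pooled[-sel]
    sum(outer(x, y, ">"))
  }
  us <- apply(idx, 2, u_of)
  u_obs <- sum(outer(a, b, ">"))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# exact Wilcoxon signed-rank two-sided p by enumeration of sign patterns
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p_lo <- mean(vs <= v_obs)
  p_hi <- mean(vs >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# rotate a sensor grid rigidly about the origin (for mask invariance tests)
rotate_grid <- function(grid, angle_deg) {
  th <- angle_deg * pi / 180
  x2 <- grid$x * cos(th) - grid$y * sin(th)
  y2 <- grid$x * sin(th) + grid$y * cos(th)
  sensor_grid(x2, y2, grid$area, sensor_id = grid$sensor_id)
}
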