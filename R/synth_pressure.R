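# Synthetic barefoot rollover pressure recordings with closed-form ground
# truth. Each region carries an asymmetric raised-cosine pulse (half-Hann
# rise to the peak, half-Hann fall after it), whose maximum, peak time and
# time integral are exact, so PP/TPP/PTI recovery can be tested against
# analytic values.

#' Rollover scenario: per-region pulse parameters
#'
#' Defines one synthetic stance: for each of the six regions, the pulse
#' onset, peak time and offset (in % of stance; onset may be negative and
#' offset may exceed 100, in which case the pulse is truncated at foot
#' strike/lift, emulating the abrupt load at heel strike and the non-zero
#' pressure still under the toes at lift-off) and the peak amplitude in
#' kPa. The default scenario follows the heel, then midfoot, then lateral
#' before medial forefoot, then hallux/toes progression of barefoot
#' rollover at normal self-selected cadence, with amplitudes and peak times
#' in the ranges reported for adults with diabetic polyneuropathy (heel
#' around 300 kPa peaking near 18% stance, forefoot peaks above 300 kPa
#' near 80% stance).
#'
#' @param regions Data frame with columns `region`, `onset_pct`,
#'   `peak_pct`, `offset_pct`, `amplitude`; one row per region. Default as
#'   described.
#' @param stance_duration Stance duration in seconds (default 0.65 s).
#' @param cadence Steps/min metadata (default 106, mid normal band).
#' @param noise_sd Additive Gaussian sensor noise SD in kPa (default 0).
#' @param seed Integer seed for the noise (default 1).
#' @return A `rollover_scenario` list.
#' @export
rollover_scenario <- function(regions = NULL, stance_duration = 0.65,
                              cadence = 106, noise_sd = 0, seed = 1) {
  if (is.null(regions)) {
    regions <- data.frame(
      region = REGIONS,
      onset_pct = c(-10, 8, 28, 24, 55, 52),
      peak_pct = c(18, 52, 82, 80, 85, 83),
      offset_pct = c(48, 88, 108, 106, 112, 110),
      amplitude = c(300, 120, 350, 310, 210, 185)
    )
  }
  stopifnot(setequal(regions$region, REGIONS),
            all(regions$onset_pct < regions$peak_pct),
            all(regions$peak_pct < regions$offset_pct),
            all(regions$peak_pct >= 0), all(regions$peak_pct <= 100),
            all(regions$amplitude >= 0),
            stance_duration > 0, noise_sd >= 0)
  structure(list(regions = regions, stance_duration = stance_duration,
                 cadence = cadence, noise_sd = noise_sd, seed = seed),
            class = "rollover_scenario")
}

# pulse value at stance percentage u (vectorized over u)
pulse_value <- function(u, onset, peak, offset, amplitude) {
  v <- numeric(length(u))
  ris <- u >= onset & u <= peak
  fal <- u > peak & u <= offset
  v[ris] <- amplitude / 2 * (1 - cos(pi * (u[ris] - onset) / (peak - onset)))
  v[fal] <- amplitude / 2 * (1 + cos(pi * (u[fal] - peak) / (offset - peak)))
  v
}

# exact integral of the pulse over stance [0, 100]%, in (kPa * % units)
pulse_integral <- function(onset, peak, offset, amplitude) {
  # antiderivative of the rise lobe A/2 (1 - cos(pi (u-o)/(p-o)))
  Fr <- function(u) amplitude / 2 *
    ((u - onset) - (peak - onset) / pi * sin(pi * (u - onset) / (peak - onset)))
  # antiderivative of the fall lobe A/2 (1 + cos(pi (u-p)/(q-p)))
  Ff <- function(u) amplitude / 2 *
    ((u - peak) + (offset - peak) / pi * sin(pi * (u - peak) / (offset - peak)))
  lo <- max(onset, 0); hi <- min(offset, 100)
  rise <- if (peak > lo) Fr(min(peak, hi)) - Fr(lo) else 0
  fall <- if (hi > peak) Ff(hi) - Ff(max(peak, lo)) else 0
  rise + fall
}

# axis-aligned band classifier used by the generator to place pulses;
# mirrors the documented percentage scheme on the grid's own y axis
grid_region_bands <- function(grid, side) {
  yr <- range(grid$y)
  if (diff(yr) <= 0) {
    stop("geometry error: grid has no posterior-anterior extent")
  }
  rel <- (grid$y - yr[1]) / diff(yr) * 100
  m <- if (side == "right") -grid$x else grid$x  # medial coordinate
  region <- character(nrow(grid))
  region[rel < 27] <- "heel"
  region[rel >= 27 & rel < 55] <- "midfoot"
  band_split <- function(sel, medial_frac, med_lab, lat_lab) {
    mm <- m[sel]
    cut <- min(mm) + (1 - medial_frac) * diff(range(mm))
    ifelse(mm >= cut, med_lab, lat_lab)
  }
  ff <- rel >= 55 & rel < 80
  tb <- rel >= 80
  region[ff] <- band_split(ff, 0.55, "medial_forefoot", "lateral_forefoot")
  region[tb] <- band_split(tb, 0.33, "hallux", "toes")
  region
}

#' Generate a synthetic rollover pressure recording
#'
#' Builds a recording in which every sensor of a region carries the
#' region's pulse (plus optional noise), padded with zero-pressure frames
#' before and after each stance, together with the analytic ground truth
#' (PP, TPP, PTI per region) and the true stance window(s).
#'
#' @param scenario A [rollover_scenario()].
#' @param grid A [sensor_grid()]; default [rect_sensor_grid()]. The grid's
#'   `y` axis is posterior-to-anterior.
#' @param side Foot side (default "left").
#' @param sampling_rate Hz (default 100).
#' @param n_steps Number of stances in the trial (default 1).
#' @param pad Zero-load padding between/around stances in seconds
#'   (default 0.3).
#' @return List with `recording` ([pressure_recording()]), `truth` (data
#'   frame `region`, `pp`, `tpp`, `pti`) and `stances` (data frame of true
#'   `start_frame`, `end_frame`).
#' @export
generate_rollover_recording <- function(scenario = rollover_scenario(),
                                        grid = rect_sensor_grid(),
                                        side = "left", sampling_rate = 100,
                                        n_steps = 1, pad = 0.3) {
  stopifnot(inherits(scenario, "rollover_scenario"))
  region_of <- grid_region_bands(grid, side)
  if (!all(REGIONS %in% region_of)) {
    stop("geometry error: grid does not cover all six region bands")
  }
  n_st <- round(scenario$stance_duration * sampling_rate) + 1L
  n_pad <- round(pad * sampling_rate)
  u <- 100 * (seq_len(n_st) - 1) / (n_st - 1)
  stance_block <- matrix(0, n_st, nrow(grid))
  for (i in seq_len(nrow(scenario$regions))) {
    rg <- scenario$regions[i, ]
    cols <- which(region_of == rg$region)
    pv <- pulse_value(u, rg$onset_pct, rg$peak_pct, rg$offset_pct, rg$amplitude)
    stance_block[, cols] <- matrix(pv, n_st, length(cols))
  }
  zeros <- matrix(0, n_pad, nrow(grid))
  frames <- zeros
  starts <- integer(n_steps)
  for (s in seq_len(n_steps)) {
    starts[s] <- nrow(frames) + 1L
    frames <- rbind(frames, stance_block, zeros)
  }
  if (scenario$noise_sd > 0) {
    local_rng(scenario$seed, {
      frames <- pmax(frames + matrix(
        stats::rnorm(length(frames), 0, scenario$noise_sd),
        nrow(frames)), 0)
    })
  }
  rec <- pressure_recording(grid, frames, sampling_rate = sampling_rate,
                            side = side, cadence = scenario$cadence)
  truth <- data.frame(
    region = scenario$regions$region,
    pp = scenario$regions$amplitude,
    tpp = scenario$regions$peak_pct,
    pti = mapply(pulse_integral, scenario$regions$onset_pct,
                 scenario$regions$peak_pct, scenario$regions$offset_pct,
                 scenario$regions$amplitude) / 100 * scenario$stance_duration
  )
  list(recording = rec, truth = truth,
       stances = data.frame(start_frame = starts, end_frame = starts + n_st))
}
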