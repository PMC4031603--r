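# a tiny hand-built recording for the metric arithmetic: 4x8 grid, known
# per-sensor series
mini_setup <- function(series_by_sensor) {
  g <- rect_sensor_grid(4, 8, foot_length = 0.24, foot_width = 0.08)
  n <- length(series_by_sensor[[1]])
  fr <- matrix(0, n, nrow(g))
  for (s in seq_along(series_by_sensor)) fr[, s] <- series_by_sensor[[s]]
  rec <- pressure_recording(g, fr)
  list(rec = rec, phase = list(start_frame = 1L, end_frame = n + 1L))
}

test_that("regional series is the per-frame max over region sensors", {
  rec <- progressive_recording(grid = rect_sensor_grid(4, 20))
  ph <- detect_stance_phases(rec)
  masks <- build_region_masks(rec, ph[1, ])
  ser <- regional_series(rec, ph[1, ], masks)
  # brute force: per frame, max over that region's sensor columns
  fr <- rec$frames[ph$start_frame[1]:(ph$end_frame[1] - 1), ]
  for (rg in foot_regions()) {
    cols <- match(masks$sensor_id[masks$region == rg], rec$grid$sensor_id)
    want <- if (length(cols)) apply(fr[, cols, drop = FALSE], 1, max)
            else rep(0, nrow(fr))
    expect_equal(ser[[rg]]$values, want)
  }
  # two-sensor worked example: [10,30] and [20,5] -> max [20,30]
  expect_equal(pmax(c(10, 30), c(20, 5)), c(20, 30))
})

test_that("peak pressure and time-to-peak follow the series", {
  expect_equal(peak_pressure(rep(100, 10)), 100)
  tri <- c(seq(0, 250, by = 50), seq(200, 0, by = -50))
  expect_equal(peak_pressure(tri), 250)
  expect_equal(peak_pressure(rep(0, 5)), 0)
  expect_equal(time_to_peak(seq(0, 90, by = 10)), 100)  # peak at end
  expect_equal(time_to_peak(c(9, 5, 1)), 0)             # peak at start
  # two equal maxima at 30% and 60% of an 11-frame series -> first one
  v <- rep(1, 11); v[c(4, 7)] <- 9
  expect_equal(time_to_peak(v), 30)
  expect_equal(which(v == max(v))[1], 4L)  # argmax-scan oracle
})

test_that("pressure-time integral is the trapezoidal area", {
  fs <- 100
  expect_equal(pressure_time_integral(rep(100, 101), fs), 100)  # 1 s plateau
  # symmetric triangle, peak 200, base 0.5 s: area = b*h/2 = 50
  tri <- c(seq(0, 200, length.out = 26), seq(200, 0, length.out = 26)[-1])
  expect_equal(pressure_time_integral(tri, fs), 50)
  expect_equal(pressure_time_integral(rep(0, 30), fs), 0)
})

test_that("COP is the load-weighted centroid with excluded empty frames", {
  # single loaded sensor: fixed COP, zero path length
  ser <- c(list(c(0, 40, 40, 10)), rep(list(rep(0, 4)), 31))
  ms <- mini_setup(ser)
  masks <- build_region_masks(ms$rec, ms$phase)
  cop <- cop_trajectory(ms$rec, ms$phase, masks)
  expect_identical(cop$total$frame, 2:4)  # zero-load frame excluded
  expect_equal(cop$total$x, rep(ms$rec$grid$x[1], 3))
  expect_equal(cop$total$y, rep(ms$rec$grid$y[1], 3))
  expect_equal(footroll:::cop_path_length(cop$total), 0)
  # two equal sensors 0.2 m apart (same x): COP at midpoint
  g <- sensor_grid(c(0, 0, 1, 1), c(0, 0.2, 0, 0.2), rep(1e-4, 4))
  rec <- pressure_recording(g, matrix(c(50, 50, 0, 0), 3, 4, byrow = TRUE))
  cop2 <- cop_trajectory(rec, list(start_frame = 1L, end_frame = 4L),
                         build_region_masks(rec, list(start_frame = 1L,
                                                      end_frame = 4L)))
  expect_equal(cop2$total$y, rep(0.1, 3))
})

test_that("a linear heel-to-toe roll gives a straight COP path", {
  g <- rect_sensor_grid(4, 30)
  ys <- sort(unique(g$y))
  fr <- matrix(0, length(ys), nrow(g))
  for (i in seq_along(ys)) fr[i, g$y == ys[i]] <- 150
  rec <- pressure_recording(g, fr)
  ph <- list(start_frame = 1L, end_frame = length(ys) + 1L)
  masks <- build_region_masks(rec, ph)
  cop <- cop_trajectory(rec, ph, masks)
  plen <- footroll:::cop_path_length(cop$total)
  chord <- sqrt(diff(range(cop$total$x))^2 + diff(range(cop$total$y))^2)
  expect_lt(abs(plen - chord) / chord, 0.01)
  expect_equal(chord, max(g$y) - min(g$y))
})

test_that("COP mean velocity is path length over elapsed time", {
  path <- data.frame(frame = 1:66, x = 0, y = seq(0, 0.20, length.out = 66))
  expect_equal(cop_mean_velocity(path, 100), 0.20 / 0.65)
  still <- data.frame(frame = 1:10, x = 1, y = 1)
  expect_equal(cop_mean_velocity(still, 100), 0)
  expect_error(cop_mean_velocity(still[1, ], 100), "fewer than 2")
  # zig-zag never beats the chord
  zig <- data.frame(frame = 1:20, x = rep(c(0, 0.01), 10),
                    y = seq(0, 0.19, by = 0.01))
  v_zig <- cop_mean_velocity(zig, 100)
  chord_v <- sqrt(0.01^2 + 0.19^2) / (19 / 100)
  expect_gte(v_zig, chord_v)
})

test_that("total COP path length is invariant under translation/rotation", {
  gen <- generate_rollover_recording(rollover_scenario(seed = 5))
  rec <- gen$recording
  ph <- detect_stance_phases(rec)[1, ]
  base <- cop_trajectory(rec, ph, build_region_masks(rec, ph))
  l0 <- footroll:::cop_path_length(base$total)
  g2 <- rotate_grid(rec$grid, 33)
  g2$x <- g2$x + 0.4; g2$y <- g2$y - 0.1
  rec2 <- pressure_recording(g2, rec$frames, side = rec$side)
  l1 <- footroll:::cop_path_length(
    cop_trajectory(rec2, ph, build_region_masks(rec2, ph))$total)
  expect_equal(l1, l0, tolerance = 1e-10)
})

test_that("metric invariants hold on random synthetic recordings", {
  for (seed in 1:25) {
    sc <- rollover_scenario(noise_sd = runif(1, 0, 6), seed = seed)
    gen <- generate_rollover_recording(sc)
    ph <- detect_stance_phases(gen$recording)
    masks <- build_region_masks(gen$recording, ph[1, ])
    met <- rollover_metrics(gen$recording, ph[1, ], masks)
    expect_true(all(met$regions$pp >= 0))
    expect_true(all(met$regions$tpp >= 0 & met$regions$tpp <= 100))
    expect_true(all(met$regions$pti <=
                      met$regions$pp * met$stance_duration + 1e-9))
    expect_true(all(met$regions$cop_velocity >= 0, na.rm = TRUE))
    expect_gte(met$total_cop_velocity, 0)
  }
})

test_that("step aggregation gives mean and sample SD per field", {
  gen <- generate_rollover_recording(rollover_scenario(seed = 2))
  ph <- detect_stance_phases(gen$recording)[1, ]
  masks <- build_region_masks(gen$recording, ph)
  met <- rollover_metrics(gen$recording, ph, masks)
  # 25 identical steps: mean = the step, SD = 0
  agg <- aggregate_steps(rep(list(met), 25))
  expect_equal(agg$mean[["heel.pp"]],
               met$regions$pp[met$regions$region == "heel"])
  expect_true(all(agg$sd == 0))
  # hand arithmetic: PP 200 and 300 -> mean 250, SD 70.71
  m1 <- met; m1$regions$pp[1] <- 200
  m2 <- met; m2$regions$pp[1] <- 300
  agg2 <- aggregate_steps(list(m1, m2))
  expect_equal(agg2$mean[[paste0(met$regions$region[1], ".pp")]], 250)
  expect_equal(agg2$sd[[paste0(met$regions$region[1], ".pp")]], 70.71,
               tolerance = 1e-3)
  # single step: SD 0 by convention
  expect_true(all(aggregate_steps(list(met))$sd == 0))
})

test_that("tidy export has one row per step, region and variable", {
  gen <- generate_rollover_recording(rollover_scenario(seed = 3))
  ph <- detect_stance_phases(gen$recording)[1, ]
  masks <- build_region_masks(gen$recording, ph)
  met <- rollover_metrics(gen$recording, ph, masks)
  td <- tidy_rollover_metrics(list(met, met), subject = "S1", side = "left")
  expect_identical(nrow(td), 2L * (6L * 4L + 2L))
  expect_setequal(unique(td$variable),
                  c("pp", "tpp", "pti", "cop_velocity",
                    "total_cop_velocity", "stance_duration"))
})
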