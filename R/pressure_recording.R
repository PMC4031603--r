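#' Construct an insole sensor grid
#'
#' A sensor grid describes the geometry of a pressure insole: one row per
#' sensor with its centre coordinates and active area. Coordinates follow the
#' package convention: `x` medio-lateral, `y` posterior-to-anterior (heel at
#' low `y`), both in metres.
#'
#' @param x,y Numeric vectors of sensor centre coordinates in metres.
#' @param area Numeric vector of per-sensor active areas in square metres.
#' @param sensor_id Integer sensor identifiers; must be unique.
#' @return A `sensor_grid` object (a data frame with columns `sensor_id`,
#'   `x`, `y`, `area`).
#' @examples
#' g <- rect_sensor_grid(4, 8)
#' nrow(g)
#' @export
sensor_grid <- function(x, y, area, sensor_id = seq_along(x)) {
  if (length(x) != length(y) || length(x) != length(area) ||
      length(x) != length(sensor_id)) {
    stop("x, y, area and sensor_id must have equal length")
  }
  if (length(x) < 4L) stop("a sensor grid needs at least 4 sensors")
  if (anyDuplicated(sensor_id)) stop("sensor ids must be unique")
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("sensor areas must be positive and finite")
  }
  g <- data.frame(
    sensor_id = as.integer(sensor_id),
    x = as.numeric(x), y = as.numeric(y), area = as.numeric(area)
  )
  class(g) <- c("sensor_grid", "data.frame")
  g
}

#' Rectangular synthetic sensor grid
#'
#' Builds an `n_x` by `n_y` rectangular grid of equal-area sensors covering a
#' nominal foot length (along `y`) and width (along `x`), the default layout
#' used by the synthetic-data generators. Sensors sit at cell centres.
#'
#' @param n_x,n_y Number of sensor columns (width) and rows (length).
#' @param foot_length,foot_width Overall extent covered, in metres.
#' @return A [sensor_grid()].
#' @export
rect_sensor_grid <- function(n_x = 10, n_y = 30,
                             foot_length = 0.26, foot_width = 0.09) {
  cx <- (seq_len(n_x) - 0.5) * foot_width / n_x
  cy <- (seq_len(n_y) - 0.5) * foot_length / n_y
  pts <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  cell_area <- (foot_width / n_x) * (foot_length / n_y)
  sensor_grid(pts$x, pts$y, rep(cell_area, nrow(pts)))
}

#' Construct a plantar pressure recording
#'
#' One walking trial recorded by a pressure insole: a sensor grid plus a
#' frames-by-sensors matrix of pressures in kPa sampled at `sampling_rate`.
#'
#' @param grid A [sensor_grid()].
#' @param frames Numeric matrix, one row per time frame, one column per
#'   sensor (kPa, non-negative). A zero-row matrix is a valid (empty)
#'   recording.
#' @param sampling_rate Sampling rate in Hz (default 100, the conventional
#'   insole rate).
#' @param side `"left"` or `"right"`.
#' @param cadence Optional walking cadence metadata in steps/min.
#' @return A `pressure_recording` object.
#' @export
pressure_recording <- function(grid, frames, sampling_rate = 100,
                               side = c("left", "right"), cadence = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(grid, "sensor_grid"))
  frames <- as.matrix(frames)
  if (nrow(frames) > 0 && ncol(frames) != nrow(grid)) {
    stop("each frame must have one pressure per sensor (",
         ncol(frames), " != ", nrow(grid), ")")
  }
  if (nrow(frames) == 0) frames <- matrix(numeric(0), 0, nrow(grid))
  if (any(!is.finite(frames))) stop("pressures must be finite")
  if (any(frames < 0)) stop("pressures must be non-negative")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar (Hz)")
  }
  if (!is.null(cadence)) {
    stopifnot(is.numeric(cadence), length(cadence) == 1, cadence > 0)
    cadence <- as.numeric(cadence)
  }
  structure(
    list(grid = grid, frames = unname(frames),
         sampling_rate = as.numeric(sampling_rate),
         side = side, cadence = cadence),
    class = "pressure_recording"
  )
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat("<pressure_recording> ", x$side, " foot, ",
      nrow(x$frames), " frames x ", nrow(x$grid), " sensors @ ",
      x$sampling_rate, " Hz",
      if (!is.null(x$cadence)) paste0(", cadence ", x$cadence, " steps/min"),
      "\n", sep = "")
  invisible(x)
}

#' Validate a pressure recording against acquisition conventions
#'
#' Pure check that never mutates its input. Flags a cadence outside the
#' 96--116 steps/min self-selected walking band and a sampling rate other
#' than the conventional 100 Hz.
#'
#' @param rec A [pressure_recording()].
#' @return Character vector of warnings (empty if none).
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "pressure_recording"))
  warnings <- character(0)
  if (!is.null(rec$cadence) && (rec$cadence < 96 || rec$cadence > 116)) {
    warnings <- c(warnings, sprintf(
      "cadence %g steps/min outside the expected 96-116 steps/min range",
      rec$cadence))
  }
  if (rec$sampling_rate != 100) {
    warnings <- c(warnings, sprintf(
      "sampling rate %g Hz differs from the conventional 100 Hz",
      rec$sampling_rate))
  }
  warnings
}
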