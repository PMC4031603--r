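# Sagittal ankle kinematics and bottom-up inverse dynamics. The sagittal
# plane is (x anterior, z up); moments are taken about the medio-lateral
# axis with plantarflexion positive, so the late-stance push-off moment is
# positive and the early-stance (extensor/dorsiflexor) peak is negative.

GRAVITY <- 9.81  # m/s^2

#' Dempster anthropometric segment parameters
#'
#' Standard Dempster-derived table for the three linked segments of the
#' bottom-up model: segment mass as a fraction of body mass, centre-of-mass
#' position as a fraction of segment length from the proximal end (for the
#' foot: from heel toward toe), and radius of gyration about the segment COM
#' as a fraction of segment length.
#'
#' @return Data frame with rows foot, shank, thigh and columns
#'   `mass_fraction`, `com_fraction`, `gyration_fraction`.
#' @export
dempster_model <- function() {
  m <- data.frame(
    segment = c("foot", "shank", "thigh"),
    mass_fraction = c(0.0145, 0.0465, 0.100),
    com_fraction = c(0.500, 0.433, 0.433),
    gyration_fraction = c(0.475, 0.302, 0.323)
  )
  class(m) <- c("anthropometric_model", "data.frame")
  m
}

validate_anthropometric_model <- function(model) {
  stopifnot(is.data.frame(model),
            all(c("segment", "mass_fraction", "com_fraction",
                  "gyration_fraction") %in% names(model)))
  if (nrow(model) != 3 || !setequal(model$segment, c("foot", "shank", "thigh"))) {
    stop("anthropometric model must have exactly the foot, shank and thigh segments")
  }
  fr <- unlist(model[, c("mass_fraction", "com_fraction", "gyration_fraction")])
  if (any(fr <= 0) || any(fr >= 1)) stop("anthropometric fractions must lie in (0, 1)")
  invisible(model)
}

#' Construct a synchronized gait mechanics record
#'
#' Marker trajectories, ground reaction force and plate centre of pressure
#' for one trial, all sampled on the same clock. Markers are n-by-3
#' matrices in metres with columns (x anterior, y medio-lateral, z up);
#' the GRF is n-by-3 in newtons with the same axes; the plate COP is n-by-3
#' with z = 0 on the plate surface.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param markers Named list of n-by-3 matrices; `heel`, `toe`, `ankle`,
#'   `knee` are required (`hip` optional, used only for completeness of the
#'   three-segment chain).
#' @param grf n-by-3 ground reaction force matrix (N).
#' @param cop n-by-3 plate centre-of-pressure matrix (m).
#' @param body_mass Body mass in kg.
#' @param height Body height in m.
#' @return A `gait_mechanics` object.
#' @export
gait_mechanics <- function(sampling_rate, markers, grf, cop,
                           body_mass, height) {
  stopifnot(sampling_rate > 0, body_mass > 0, height > 0)
  need <- c("heel", "toe", "ankle", "knee")
  if (!all(need %in% names(markers))) {
    stop("markers must include: ", paste(need, collapse = ", "))
  }
  markers <- lapply(markers, as.matrix)
  grf <- as.matrix(grf)
  cop <- as.matrix(cop)
  n <- nrow(grf)
  lens <- c(vapply(markers, nrow, integer(1)), nrow(cop))
  if (any(lens != n)) stop("marker, GRF and COP streams must have equal length")
  if (any(vapply(markers, ncol, integer(1)) != 3) || ncol(grf) != 3 ||
      ncol(cop) != 3) {
    stop("markers, GRF and COP must have 3 columns (x, y, z)")
  }
  structure(list(sampling_rate = sampling_rate, markers = markers,
                 grf = grf, cop = cop, body_mass = body_mass,
                 height = height),
            class = "gait_mechanics")
}

#' Sagittal ankle angle series
#'
#' Signed angle between the shank long axis (ankle to knee) and the foot
#' long axis (heel to toe) projected on the sagittal plane, referenced so
#' that neutral standing (foot flat, shank vertical) reads 0 degrees, with
#' dorsiflexion positive and plantarflexion negative.
#'
#' @param mech A [gait_mechanics()].
#' @return Numeric vector of angles in degrees, one per frame.
#' @export
sagittal_ankle_angle <- function(mech) {
  stopifnot(inherits(mech, "gait_mechanics"))
  heel <- mech$markers$heel; toe <- mech$markers$toe
  ankle <- mech$markers$ankle; knee <- mech$markers$knee
  fvx <- toe[, 1] - heel[, 1]; fvz <- toe[, 3] - heel[, 3]
  svx <- knee[, 1] - ankle[, 1]; svz <- knee[, 3] - ankle[, 3]
  if (any(fvx^2 + fvz^2 < 1e-12) || any(svx^2 + svz^2 < 1e-12)) {
    stop("degenerate (zero-length) segment in sagittal projection")
  }
  theta_f <- atan2(-fvz, fvx)      # foot pitch, plantarflexion positive
  theta_s <- atan2(svx, svz)       # shank forward lean
  (theta_s - theta_f) * 180 / pi
}

# central-difference derivative at uniform sampling
num_deriv <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Net sagittal ankle moment by bottom-up inverse dynamics
#'
#' Newton-Euler balance of the foot segment: the ground reaction force
#' applied at the plate COP, the foot's weight and inertial terms (mass,
#' COM and moment of inertia from the anthropometric model and the
#' marker-derived foot length), and the resulting ankle joint reaction give
#' the net ankle moment. The moment is normalized to percent body weight
#' times height, `100 * M / (body_mass * g * height)`, plantarflexion
#' positive. Frames whose vertical force falls below `stance_threshold` of
#' the trial maximum are returned as `NA`.
#'
#' Input signals are low-pass filtered before differentiation
#' (Butterworth, zero phase) at `cutoff_force` for the GRF/COP and
#' `cutoff_kin` for the markers, the conventional 20/6 Hz split.
#'
#' @param mech A [gait_mechanics()].
#' @param model An anthropometric model (default [dempster_model()]).
#' @param cutoff_force,cutoff_kin Low-pass cutoffs in Hz.
#' @param stance_threshold Vertical-force fraction below which frames are
#'   excluded (default 0.05).
#' @param filter Logical; set `FALSE` to skip filtering (e.g. for
#'   analytically clean synthetic inputs in oracles).
#' @return Numeric vector of normalized ankle moments (%BW.h) per frame,
#'   `NA` outside stance.
#' @export
inverse_dynamics_ankle_moment <- function(mech, model = dempster_model(),
                                          cutoff_force = 20, cutoff_kin = 6,
                                          stance_threshold = 0.05,
                                          filter = TRUE) {
  stopifnot(inherits(mech, "gait_mechanics"))
  validate_anthropometric_model(model)
  fs <- mech$sampling_rate
  lp <- function(m, cutoff) {
    if (!filter) return(m)
    apply(m, 2, butterworth_lowpass, sampling_rate = fs, cutoff = cutoff)
  }
  heel <- lp(mech$markers$heel, cutoff_kin)
  toe <- lp(mech$markers$toe, cutoff_kin)
  ankle <- lp(mech$markers$ankle, cutoff_kin)
  grf <- lp(mech$grf, cutoff_force)
  cop <- lp(mech$cop, cutoff_force)

  foot <- model[model$segment == "foot", ]
  m_f <- foot$mass_fraction * mech$body_mass
  ell <- mean(sqrt((toe[, 1] - heel[, 1])^2 + (toe[, 3] - heel[, 3])^2))
  I_f <- m_f * (foot$gyration_fraction * ell)^2

  com_x <- heel[, 1] + foot$com_fraction * (toe[, 1] - heel[, 1])
  com_z <- heel[, 3] + foot$com_fraction * (toe[, 3] - heel[, 3])
  ax <- num_deriv(num_deriv(com_x, fs), fs)
  az <- num_deriv(num_deriv(com_z, fs), fs)
  theta <- atan2(heel[, 3] - toe[, 3], toe[, 1] - heel[, 1])  # plantarflexion +
  alpha <- num_deriv(num_deriv(theta, fs), fs)

  # ankle joint reaction on the foot
  Fa_x <- m_f * ax - grf[, 1]
  Fa_z <- m_f * az - grf[, 3] + m_f * GRAVITY
  # moments about the foot COM on the plantarflexion-positive axis:
  # m_y(r, F) = r_z * F_x - r_x * F_z, the same axis as theta above
  m_y <- function(rx, rz, Fx, Fz) rz * Fx - rx * Fz
  M <- I_f * alpha -
    m_y(cop[, 1] - com_x, cop[, 3] - com_z, grf[, 1], grf[, 3]) -
    m_y(ankle[, 1] - com_x, ankle[, 3] - com_z, Fa_x, Fa_z)
  fz <- grf[, 3]
  M[fz < stance_threshold * max(fz)] <- NA_real_
  100 * M / (mech$body_mass * GRAVITY * mech$height)
}

#' Extract the four sagittal ankle outcomes
#'
#' From the stance-phase windows of the angle and moment series: the total
#' sagittal range of motion (degrees), the ankle angle at the end of the
#' propulsion phase (last stance frame, degrees), the peak extensor
#' (dorsiflexor, negative) moment near 20% stance taken as the minimum over
#' the 5--40% window, and the peak flexor (plantarflexor, positive) moment
#' near 80% stance taken as the maximum over the 60--95% window (%BW.h).
#'
#' @param angles Angle series (degrees) covering the recording.
#' @param moments Normalized moment series (%BW.h), `NA` allowed outside
#'   stance.
#' @param stance A single stance phase (list or one-row data frame with
#'   `start_frame`, `end_frame`).
#' @return An `ankle_summary`: list with `rom`, `end_propulsion_angle`,
#'   `peak_extensor_moment`, `peak_flexor_moment`.
#' @export
extract_ankle_outcomes <- function(angles, moments, stance) {
  fr <- phase_frames(stance, length(angles))
  if (length(fr) < 10) stop("insufficient data: stance shorter than 10 frames")
  a <- angles[fr]
  m <- moments[fr]
  pct <- 100 * (seq_along(fr) - 1) / (length(fr) - 1)
  ext_w <- m[pct >= 5 & pct <= 40]
  flex_w <- m[pct >= 60 & pct <= 95]
  structure(list(
    rom = max(a) - min(a),
    end_propulsion_angle = a[length(a)],
    peak_extensor_moment = min(ext_w, na.rm = TRUE),
    peak_flexor_moment = max(flex_w, na.rm = TRUE)
  ), class = "ankle_summary")
}
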