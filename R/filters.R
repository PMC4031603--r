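# Zero-phase low-pass filtering of gait signals. Coefficients come from
# signal::butter; the forward-backward pass is implemented here with odd
# reflection padding and steady-state initial conditions (direct form II
# transposed), which keeps constants exact and removes boundary transients.

iir_zi <- function(b, a) {
  # steady-state filter state for unit step input (lfilter_zi construction)
  n <- length(a) - 1L
  Acomp <- rbind(-a[-1], cbind(diag(n - 1), 0))[seq_len(n), seq_len(n), drop = FALSE]
  B <- b[-1] - b[1] * a[-1]
  solve(diag(n) - t(Acomp), B)
}

iir_filter <- function(b, a, x, zi) {
  # direct form II transposed with initial state zi
  n <- length(x)
  nz <- length(zi)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1) {
      for (k in seq_len(nz - 1)) {
        z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
      }
    }
    z[nz] <- b[nz + 1] * xi - a[nz + 1] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a signal forward and backward so the net response has the stated
#' order and zero phase lag, the standard treatment of marker and force
#' signals before differentiation. A 4th-order request is realised as a
#' forward-backward pass of a 2nd-order Butterworth filter.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist. Conventional
#'   gait values are 20 Hz for force-plate data and 6 Hz for kinematics.
#' @param order Net filter order (even; default 4).
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, sampling_rate, cutoff, order = 4) {
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    stop("cutoff must lie in (0, Nyquist) = (0, ", sampling_rate / 2, ") Hz")
  }
  if (order < 2 || order %% 2 != 0) stop("order must be a positive even number")
  n <- length(x)
  if (n < 2) return(x)
  bf <- signal::butter(order / 2, cutoff / (sampling_rate / 2), type = "low")
  b <- bf$b
  a <- bf$a
  zi <- iir_zi(b, a)
  p <- min(n - 1L, max(12L, ceiling(3 * sampling_rate / cutoff)))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(p + 1):(p + n)]
}
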