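#' Construct a sampled pulsatile flow waveform
#'
#' A waveform is one cardiac cycle of volumetric flow sampled on a
#' strictly increasing time grid starting at 0 and ending at the
#' period, with periodic closure (first and last flow samples equal).
#'
#' @param time sample times in s; strictly increasing, `time[1] == 0`.
#' @param flow flow samples in cm^3/s; finite, same length as `time`.
#' @return An object of class `waveform` with elements `time`, `flow`
#'   and `period` (= `time[length(time)]`).
#' @seealso [make_waveform()] to synthesize one parametrically.
#' @export
waveform <- function(time, flow) {
  if (length(time) < 2L || length(time) != length(flow)) {
    stop("`time` and `flow` must be equal-length vectors (>= 2 samples)",
         call. = FALSE)
  }
  if (any(!is.finite(time)) || any(!is.finite(flow))) {
    stop("waveform samples must be finite", call. = FALSE)
  }
  if (time[1L] != 0) stop("waveform time grid must start at 0", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("waveform time grid must be strictly increasing", call. = FALSE)
  }
  period <- time[length(time)]
  closure <- abs(flow[1L] - flow[length(flow)])
  if (closure > 1e-9 * max(abs(flow))) {
    stop("waveform is not periodically closed: |flow(0) - flow(T)| too large",
         call. = FALSE)
  }
  structure(list(time = time, flow = flow, period = period),
            class = "waveform")
}

#' Synthesize an arterial inflow waveform
#'
#' Builds one cardiac cycle of pulsatile flow as a truncated Fourier
#' series with a fast systolic upstroke and slow diastolic decay,
#' qualitatively matching internal-carotid / basilar inflow shapes.
#' The sampled cycle is normalized so that its trapezoidal cycle mean
#' equals `mean_flow` exactly and its pulsatility index
#' (max - min) / mean equals `pulsatility_index` exactly (both up to
#' floating-point rounding).
#'
#' @param mean_flow cycle-averaged flow in cm^3/s; must be > 0.
#' @param pulsatility_index (max - min)/mean of the cycle; >= 0.
#'   0 gives a constant waveform.
#' @param heart_rate heart rate in beats/min (default 60).
#' @param n_harmonics number of Fourier harmonics in the base shape.
#' @param n_samples number of samples including both endpoints.
#' @return A [waveform()] object.
#' @examples
#' wf <- make_waveform(4, 1.0, 60)
#' waveform_mean(wf)          # 4
#' waveform_pulsatility(wf)   # 1
#' @export
make_waveform <- function(mean_flow, pulsatility_index, heart_rate = 60,
                          n_harmonics = 4L, n_samples = 201L) {
  if (!is.numeric(mean_flow) || length(mean_flow) != 1L ||
      !is.finite(mean_flow) || mean_flow <= 0) {
    stop("`mean_flow` must be a single positive number (cm^3/s)",
         call. = FALSE)
  }
  if (!is.numeric(pulsatility_index) || length(pulsatility_index) != 1L ||
      !is.finite(pulsatility_index) || pulsatility_index < 0) {
    stop("`pulsatility_index` must be a single number >= 0", call. = FALSE)
  }
  if (heart_rate <= 0) stop("`heart_rate` must be > 0 (1/min)", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (n_samples < 8L) stop("`n_samples` must be at least 8", call. = FALSE)
  period <- 60 / heart_rate
  t <- seq(0, period, length.out = n_samples)

  if (pulsatility_index == 0) {
    return(waveform(t, rep(mean_flow, n_samples)))
  }
  if (n_harmonics < 1L) {
    stop("`n_harmonics` must be >= 1 for a pulsatile waveform",
         call. = FALSE)
  }

  # Decaying harmonics with phase lead growing per harmonic: steep
  # early-systolic rise, gentle diastolic runoff.
  theta <- 2 * pi * t / period
  s <- rep(0, n_samples)
  for (k in seq_len(n_harmonics)) {
    s <- s + sin(k * theta + (k - 1) * pi / 4) / k
  }
  # Exact discrete normalization: zero trapezoid mean, unit range.
  # With a uniform periodic grid the trapezoid mean is the arithmetic
  # mean of the first n - 1 samples.
  s <- s - mean(s[-n_samples])
  s <- s / (max(s) - min(s))
  flow <- mean_flow * (1 + pulsatility_index * s)
  waveform(t, flow)
}

#' Cycle statistics of a waveform
#'
#' `waveform_mean()` is the trapezoidal integral over one period
#' divided by the period; `waveform_pulsatility()` is
#' (max - min) / mean.
#'
#' @param wf a [waveform()] object.
#' @return A single number.
#' @export
waveform_mean <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  trapz_scalar(wf$time, wf$flow) / wf$period
}

#' @rdname waveform_mean
#' @export
waveform_pulsatility <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  (max(wf$flow) - min(wf$flow)) / waveform_mean(wf)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "Flow waveform: period %.3g s, %d samples, mean %.4g cm^3/s, PI %.3g\n",
    x$period, length(x$time), waveform_mean(x), waveform_pulsatility(x)))
  invisible(x)
}

# Periodic linear interpolant Q(t) of a waveform, usable at any t >= 0.
waveform_interpolant <- function(wf) {
  force(wf)
  function(t) {
    tt <- t %% wf$period
    stats::approx(wf$time, wf$flow, xout = tt, rule = 2)$y
  }
}

# Trapezoid rule on a (possibly non-uniform) grid.
trapz_scalar <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-n] + y[-1L]) / 2)
}

# Trapezoid weights: t(w) %*% y == trapz_scalar(t, y).
trapz_weights <- function(t) {
  n <- length(t)
  dt <- diff(t)
  w <- numeric(n)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dt[-(n - 1L)] + dt[-1L]) / 2
  w
}
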