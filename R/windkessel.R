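#' Outlet cross-section set
#'
#' Outlet areas of a vascular model. The total area is always
#' recomputed as the sum of the per-outlet areas.
#'
#' @param areas per-outlet cross-sectional areas in cm^2; all > 0.
#' @return An object of class `outlet_set` with `areas` and `total`.
#' @export
outlet_set <- function(areas) {
  if (length(areas) < 1L || any(!is.finite(areas)) || any(areas <= 0)) {
    stop("outlet areas must be positive and finite (cm^2)", call. = FALSE)
  }
  structure(list(areas = as.numeric(areas), total = sum(areas)),
            class = "outlet_set")
}

#' Split a total resistance over outlets inversely to area
#'
#' Distributes a net downstream resistance over outlets so that larger
#' outlets receive proportionally more flow: R_i = R_total * A_total /
#' A_i. The parallel combination of the returned resistances equals
#' `R_total` by algebraic identity.
#'
#' @param outlets an [outlet_set()].
#' @param R_total net resistance of all outlets in parallel,
#'   dyne s/cm^5; > 0.
#' @return Numeric vector of per-outlet total resistances.
#' @examples
#' split_resistances(outlet_set(c(1, 3)), 1000)
#' @export
split_resistances <- function(outlets, R_total) {
  stopifnot(inherits(outlets, "outlet_set"))
  if (!is.numeric(R_total) || length(R_total) != 1L ||
      !is.finite(R_total) || R_total <= 0) {
    stop("`R_total` must be a single positive number", call. = FALSE)
  }
  R_total * outlets$total / outlets$areas
}

#' Three-element Windkessel parameter set
#'
#' Per-outlet proximal resistance, capacitance and distal resistance,
#' with a shared distal reference pressure. All outlets must share the
#' same proximal fraction R_p / (R_p + R_d).
#'
#' @param R_p proximal resistances, dyne s/cm^5.
#' @param C capacitances, cm^5/dyne.
#' @param R_d distal resistances, dyne s/cm^5.
#' @param P_ref distal reference pressure, dyne/cm^2 (default 0).
#' @return An object of class `rcr_set`.
#' @export
rcr_set <- function(R_p, C, R_d, P_ref = 0) {
  n <- length(R_p)
  if (length(C) != n || length(R_d) != n || n < 1L) {
    stop("R_p, C, R_d must be equal-length (>= 1) vectors", call. = FALSE)
  }
  if (any(!is.finite(c(R_p, C, R_d, P_ref))) ||
      any(c(R_p, C, R_d) <= 0)) {
    stop("R_p, C, R_d must be positive and finite", call. = FALSE)
  }
  frac <- R_p / (R_p + R_d)
  if (diff(range(frac)) > 1e-12) {
    stop("all outlets must share the same proximal fraction R_p/(R_p+R_d)",
         call. = FALSE)
  }
  structure(list(R_p = as.numeric(R_p), C = as.numeric(C),
                 R_d = as.numeric(R_d), P_ref = P_ref,
                 proximal_fraction = frac[1L]),
            class = "rcr_set")
}

#' @export
print.rcr_set <- function(x, ...) {
  cat(sprintf(
    "RCR set: %d outlet(s), proximal fraction %.3g, P_ref %.4g barye\n",
    length(x$R_p), x$proximal_fraction, x$P_ref))
  invisible(x)
}

# Parallel-equivalent single RCR of a multi-outlet set (shared
# capacitor node assumption used for global pressure tuning).
reduce_rcr <- function(rcr) {
  list(R_p = 1 / sum(1 / rcr$R_p), C = sum(rcr$C),
       R_d = 1 / sum(1 / rcr$R_d), P_ref = rcr$P_ref)
}

#' Simulate the pressure response of an RCR outlet set
#'
#' Integrates the three-element Windkessel ODE
#' \eqn{C dP_c/dt = Q(t) - (P_c - P_{ref})/R_d} with inlet-equivalent
#' pressure \eqn{P(t) = P_c + R_p Q(t)}, driven by a periodic inflow
#' waveform. Multi-outlet sets are collapsed to their parallel
#' equivalent. Integration uses a stiff-capable adaptive solver with
#' maximum internal step period/200.
#'
#' @param wf a [waveform()] (cm^3/s).
#' @param rcr an [rcr_set()].
#' @param n_cycles number of cardiac cycles to integrate (>= 1).
#' @param dt output sampling step in s; must be <= period/200.
#' @param P_c0 initial capacitor pressure (barye); defaults to the
#'   steady mean-flow pressure.
#' @return A `pressure_trace` data.frame with columns `time` (s),
#'   `pressure` (barye), `flow` (cm^3/s) and `cycle` (1-based index),
#'   with the period stored as attribute `period`.
#' @export
simulate_rcr <- function(wf, rcr, n_cycles = 10L, dt = wf$period / 400,
                         P_c0 = NULL) {
  stopifnot(inherits(wf, "waveform"), inherits(rcr, "rcr_set"))
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("`n_cycles` must be >= 1", call. = FALSE)
  if (dt > wf$period / 200) {
    stop("`dt` must be at most period/200", call. = FALSE)
  }
  eq <- reduce_rcr(rcr)
  qf <- waveform_interpolant(wf)
  if (is.null(P_c0)) P_c0 <- eq$P_ref + waveform_mean(wf) * eq$R_d
  times <- seq(0, n_cycles * wf$period, by = dt)
  rhs <- function(t, y, p) {
    list((qf(t) - (y - eq$P_ref) / eq$R_d) / eq$C)
  }
  sol <- deSolve::lsoda(c(Pc = P_c0), times, rhs, parms = NULL,
                        hmax = wf$period / 200,
                        rtol = 1e-8, atol = 1e-6 * max(abs(P_c0), 1))
  pc <- sol[, "Pc"]
  if (any(!is.finite(pc))) {
    stop(sprintf(
      "unstable RCR integration (non-finite pressure); R_p=%g C=%g R_d=%g",
      eq$R_p, eq$C, eq$R_d), call. = FALSE)
  }
  q <- qf(times)
  p <- pc + eq$R_p * q
  cyc <- pmin(floor(times / wf$period * (1 - 1e-12)) + 1L, n_cycles)
  out <- data.frame(time = times, pressure = p, flow = q, cycle = cyc)
  attr(out, "period") <- wf$period
  class(out) <- c("pressure_trace", "data.frame")
  out
}

#' Per-cycle systolic and diastolic pressures of a trace
#'
#' @param trace a `pressure_trace` from [simulate_rcr()].
#' @return data.frame with columns `cycle`, `systolic`, `diastolic`
#'   (barye).
#' @export
cycle_extrema <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  sys <- tapply(trace$pressure, trace$cycle, max)
  dia <- tapply(trace$pressure, trace$cycle, min)
  data.frame(cycle = as.integer(names(sys)),
             systolic = as.numeric(sys), diastolic = as.numeric(dia))
}

#' Limit-cycle convergence check
#'
#' A pulsatile pressure trace has reached its limit cycle when the
#' relative change of both the systolic and the diastolic pressure
#' between the last two cycles is at most `tol` (default 5%).
#'
#' @param trace a `pressure_trace` with at least 2 complete cycles.
#' @param tol relative tolerance (fraction).
#' @return A list with `converged` (logical) and `table`, the
#'   per-cycle systolic/diastolic table with relative changes.
#' @export
limit_cycle_converged <- function(trace, tol = 0.05) {
  ext <- cycle_extrema(trace)
  if (nrow(ext) < 2L) {
    stop("limit-cycle check needs at least 2 complete cycles",
         call. = FALSE)
  }
  ext$d_systolic <- c(NA, abs(diff(ext$systolic)) /
                        abs(ext$systolic[-nrow(ext)]))
  ext$d_diastolic <- c(NA, abs(diff(ext$diastolic)) /
                         abs(ext$diastolic[-nrow(ext)]))
  last <- nrow(ext)
  conv <- ext$d_systolic[last] <= tol && ext$d_diastolic[last] <= tol
  list(converged = conv, table = ext)
}

# Simulate until the limit cycle (cycle-to-cycle change <= tol_cycle on
# systolic and diastolic), returning the final trace.
simulate_to_limit_cycle <- function(wf, rcr, tol_cycle = 0.005,
                                    max_cycles = 60L, dt = wf$period / 400) {
  eq <- reduce_rcr(rcr)
  n <- 4L
  repeat {
    tr <- simulate_rcr(wf, rcr, n_cycles = n, dt = dt)
    lc <- limit_cycle_converged(tr, tol = tol_cycle)
    if (lc$converged || n >= max_cycles) {
      return(list(trace = tr, check = lc, n_cycles = n))
    }
    n <- min(max_cycles, n * 2L)
  }
}

#' Tune RCR outlet boundary conditions to target pressures
#'
#' Two-stage tuner for the lumped outlet model under a pulsatile
#' inflow: the total resistance is set from the mean-pressure identity
#' (cycle-mean pressure = Q_mean (R_p + R_d) + P_ref, using
#' (systolic + 2 diastolic)/3 as the mean-pressure estimate) and the
#' capacitance follows by secant iteration on the limit-cycle pulse
#' pressure; the resistance stage is re-entered until both targets are
#' met. Per-outlet resistances follow the inverse-area split; the
#' equivalent capacitance is redistributed proportionally to 1/R_i.
#'
#' @param wf pulsatile inflow [waveform()]; pulsatility must be > 0.
#' @param outlets an [outlet_set()].
#' @param systolic_mmHg,diastolic_mmHg target pressures in mmHg;
#'   systolic > diastolic > 0.
#' @param tol acceptable relative deviation of each achieved pressure
#'   from its target (default 0.05). The internal iteration aims for
#'   `tol/5` so the returned set sits comfortably inside `tol`.
#' @param proximal_fraction R_p / (R_p + R_d) per outlet (default 0.1,
#'   i.e. a 1:9 proximal:distal split).
#' @param P_ref distal reference pressure in barye.
#' @param max_iter iteration cap over all stages.
#' @return A list of class `rcr_tuning`: `rcr` (tuned [rcr_set()]),
#'   `trace` (final limit-cycle `pressure_trace`), `systolic_mmHg`,
#'   `diastolic_mmHg` (achieved), `converged`, and `audit`, a
#'   data.frame logging every iteration.
#' @export
tune_rcr <- function(wf, outlets, systolic_mmHg = 120, diastolic_mmHg = 80,
                     tol = 0.05, proximal_fraction = 0.1, P_ref = 0,
                     max_iter = 100L) {
  stopifnot(inherits(wf, "waveform"), inherits(outlets, "outlet_set"))
  if (!(systolic_mmHg > diastolic_mmHg && diastolic_mmHg > 0)) {
    stop("targets must satisfy systolic > diastolic > 0", call. = FALSE)
  }
  if (proximal_fraction <= 0 || proximal_fraction >= 1) {
    stop("`proximal_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (waveform_pulsatility(wf) <= 0) {
    stop("tuning infeasible: constant inflow cannot produce a nonzero pulse pressure",
         call. = FALSE)
  }
  q_mean <- waveform_mean(wf)
  s_t <- mmHg_to_barye(systolic_mmHg)
  d_t <- mmHg_to_barye(diastolic_mmHg)
  pp_t <- s_t - d_t
  inner_tol <- tol / 5

  build <- function(R_total, C_total) {
    R_i <- split_resistances(outlets, R_total)
    C_i <- C_total * R_total / R_i
    rcr_set(R_p = proximal_fraction * R_i, C = C_i,
            R_d = (1 - proximal_fraction) * R_i, P_ref = P_ref)
  }
  audit <- list()
  log_iter <- function(stage, R_total, C_total, sys, dia) {
    audit[[length(audit) + 1L]] <<- data.frame(
      iter = length(audit) + 1L, stage = stage, R_total = R_total,
      C_total = C_total, systolic_mmHg = barye_to_mmHg(sys),
      diastolic_mmHg = barye_to_mmHg(dia))
  }
  evaluate <- function(R_total, C_total, stage) {
    sim <- simulate_to_limit_cycle(wf, build(R_total, C_total))
    ext <- sim$check$table
    sys <- ext$systolic[nrow(ext)]
    dia <- ext$diastolic[nrow(ext)]
    log_iter(stage, R_total, C_total, sys, dia)
    list(sys = sys, dia = dia, sim = sim)
  }

  mean_t <- (s_t + 2 * d_t) / 3
  R_total <- (mean_t - P_ref) / q_mean
  # Initial capacitances around a distal time constant of one period.
  omega <- 2 * pi / wf$period
  C0 <- 1 / (omega * (1 - proximal_fraction) * R_total)
  C1 <- 2 * C0
  best <- NULL
  n_eval <- 0L

  e0 <- evaluate(R_total, C0, "C-init"); n_eval <- n_eval + 1L
  e1 <- evaluate(R_total, C1, "C-init"); n_eval <- n_eval + 1L
  repeat {
    # Secant stage on pulse pressure vs C (monotone decreasing in C).
    g0 <- (e0$sys - e0$dia) - pp_t
    g1 <- (e1$sys - e1$dia) - pp_t
    while (abs(g1) > inner_tol * pp_t && n_eval < max_iter) {
      if (g1 == g0) break
      C2 <- C1 - g1 * (C1 - C0) / (g1 - g0)
      if (!is.finite(C2) || C2 <= 0) C2 <- C1 / 2
      C0 <- C1; g0 <- g1; e0 <- e1
      C1 <- C2
      e1 <- evaluate(R_total, C1, "C-secant"); n_eval <- n_eval + 1L
      g1 <- (e1$sys - e1$dia) - pp_t
    }
    err_s <- (e1$sys - s_t) / s_t
    err_d <- (e1$dia - d_t) / d_t
    if (is.null(best) || max(abs(err_s), abs(err_d)) < best$score) {
      best <- list(score = max(abs(err_s), abs(err_d)), R_total = R_total,
                   C = C1, eval = e1)
    }
    if ((abs(err_s) <= inner_tol && abs(err_d) <= inner_tol) ||
        n_eval >= max_iter) {
      break
    }
    # Resistance stage: shift the mean pressure by the observed error.
    d_mean <- ((s_t - e1$sys) + 2 * (d_t - e1$dia)) / 3
    R_total <- R_total + d_mean / q_mean
    if (R_total <= 0) R_total <- best$R_total
    e0 <- evaluate(R_total, C1, "R-update"); n_eval <- n_eval + 1L
    C0 <- C1; C1 <- C1 * 1.2
    e1 <- evaluate(R_total, C1, "R-update"); n_eval <- n_eval + 1L
  }

  audit <- do.call(rbind, audit)
  final <- best$eval
  sys_mmHg <- barye_to_mmHg(final$sys)
  dia_mmHg <- barye_to_mmHg(final$dia)
  within <- abs(sys_mmHg - systolic_mmHg) / systolic_mmHg <= tol &&
    abs(dia_mmHg - diastolic_mmHg) / diastolic_mmHg <= tol
  if (!within && n_eval >= max_iter) {
    stop(sprintf(
      "RCR tuning did not converge in %d evaluations; best systolic %.1f, diastolic %.1f mmHg",
      n_eval, sys_mmHg, dia_mmHg), call. = FALSE)
  }
  structure(list(rcr = build(best$R_total, best$C),
                 trace = final$sim$trace,
                 limit_cycle = final$sim$check,
                 systolic_mmHg = sys_mmHg, diastolic_mmHg = dia_mmHg,
                 R_total = best$R_total, C_total = best$C,
                 converged = within, audit = audit),
            class = "rcr_tuning")
}

#' @export
print.rcr_tuning <- function(x, ...) {
  cat(sprintf(
    "Tuned RCR set: %d outlet(s), R_total %.5g dyne s/cm^5, C_total %.5g cm^5/dyne\n",
    length(x$rcr$R_p), x$R_total, x$C_total))
  cat(sprintf("  limit-cycle pressures: %.1f / %.1f mmHg (%s)\n",
              x$systolic_mmHg, x$diastolic_mmHg,
              if (x$converged) "converged" else "NOT within tolerance"))
  invisible(x)
}
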