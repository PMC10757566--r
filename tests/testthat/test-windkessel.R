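test_that("inverse-area resistance split preserves the parallel total", {
  expect_equal(split_resistances(outlet_set(2.5), 1234), 1234)
  r <- split_resistances(outlet_set(c(1, 3)), 1000)
  expect_equal(r, c(4000, 4000 / 3))
  expect_equal(1 / sum(1 / r), 1000, tolerance = 1e-12)
  r4 <- split_resistances(outlet_set(rep(0.7, 4)), 500)
  expect_equal(r4, rep(2000, 4))
  set.seed(7)
  for (i in 1:100) {
    areas <- runif(sample(1:6, 1), 0.01, 2)
    Rt <- runif(1, 100, 1e5)
    ri <- split_resistances(outlet_set(areas), Rt)
    expect_equal(1 / sum(1 / ri), Rt, tolerance = 1e-12)
  }
  expect_error(outlet_set(c(1, -2)), "positive")
})

test_that("constant inflow settles to the resistive steady state", {
  wf <- make_waveform(4.0, 0, 60)
  rcr <- rcr_set(R_p = 1000, C = 1e-4, R_d = 9000, P_ref = 2000)
  tau <- 9000 * 1e-4
  tr <- simulate_rcr(wf, rcr, n_cycles = ceiling(10 * tau) + 1L)
  p_inf <- 4.0 * (1000 + 9000) + 2000
  late <- tr$pressure[tr$time >= 10 * tau]
  expect_equal(max(abs(late - p_inf)) / p_inf, 0, tolerance = 1e-3)
})

test_that("sinusoidal forcing matches the impedance closed form", {
  hr <- 60
  Tp <- 1
  t <- seq(0, Tp, length.out = 401)
  q0 <- 4; q1 <- 1.5
  wf <- waveform(t, q0 + q1 * sin(2 * pi * t / Tp))
  rp <- 3000; rd <- 27000; cc <- 2e-5
  rcr <- rcr_set(rp, cc, rd)
  tr <- simulate_rcr(wf, rcr, n_cycles = 20)
  ext <- cycle_extrema(tr)
  amp <- (ext$systolic[20] - ext$diastolic[20]) / 2
  z <- abs(rp + rd / (1 + 1i * 2 * pi / Tp * rd * cc))
  expect_equal(amp, q1 * z, tolerance = 5e-3)
})

test_that("large capacitance shrinks the pulse toward the proximal drop", {
  Tp <- 1
  t <- seq(0, Tp, length.out = 401)
  q1 <- 2
  wf <- waveform(t, 5 + q1 * sin(2 * pi * t / Tp))
  rp <- 2000
  rcr <- rcr_set(rp, 5e-3, 18000)
  tr <- simulate_rcr(wf, rcr, n_cycles = 12)
  ext <- cycle_extrema(tr)
  pulse <- ext$systolic[12] - ext$diastolic[12]
  expect_equal(pulse, 2 * q1 * rp, tolerance = 0.02)
})

test_that("adaptive integration agrees with a fine-step RK4 oracle", {
  set.seed(21)
  for (i in 1:5) {
    wf <- make_waveform(runif(1, 2, 6), runif(1, 0.5, 1.5), 60)
    Rt <- runif(1, 1e4, 5e4)
    rcr <- rcr_set(0.1 * Rt, runif(1, 5e-6, 5e-5), 0.9 * Rt)
    tr <- simulate_rcr(wf, rcr, n_cycles = 8)
    ora <- rk4_windkessel(wf, rcr, 8, wf$period / 4000)
    s1 <- max(tr$pressure[tr$cycle == 8])
    d1 <- min(tr$pressure[tr$cycle == 8])
    s2 <- max(ora$pressure[ora$cycle == 8])
    d2 <- min(ora$pressure[ora$cycle == 8])
    expect_equal(s1, s2, tolerance = 1e-3)
    expect_equal(d1, d2, tolerance = 1e-3)
  }
})

test_that("limit-cycle detection applies the last-two-cycles rule", {
  Tp <- 1
  t_all <- seq(0, 4, by = 1 / 200)
  p <- 10 + sin(2 * pi * t_all)
  tr <- data.frame(time = t_all, pressure = p,
                   cycle = pmin(floor(t_all * (1 - 1e-12)) + 1L, 4L))
  class(tr) <- c("pressure_trace", "data.frame")
  attr(tr, "period") <- Tp
  expect_true(limit_cycle_converged(tr, tol = 0)$converged)

  sys <- c(150, 130, 124, 121)
  mk <- function(sys) {
    tt <- unlist(lapply(seq_along(sys), function(k) k - 1 + c(0.25, 0.75)))
    pp <- as.vector(rbind(sys, sys - 40))
    out <- data.frame(time = tt, pressure = pp,
                      cycle = rep(seq_along(sys), each = 2))
    class(out) <- c("pressure_trace", "data.frame")
    out
  }
  expect_true(limit_cycle_converged(mk(sys), tol = 0.05)$converged)
  drift <- 150 * 0.9^(0:3)
  expect_false(limit_cycle_converged(mk(drift), tol = 0.05)$converged)
  one <- mk(c(120))
  expect_error(limit_cycle_converged(one), "2 complete cycles")
})

test_that("tuning hits 120/80 within tolerance and respects the 1:9 split", {
  wf <- make_waveform(4.0, 1.0, 60)
  tn <- tune_rcr(wf, outlet_set(c(0.05, 0.03)))
  expect_true(tn$converged)
  expect_lt(abs(tn$systolic_mmHg - 120) / 120, 0.05)
  expect_lt(abs(tn$diastolic_mmHg - 80) / 80, 0.05)
  expect_equal(unname(tn$rcr$R_p / (tn$rcr$R_p + tn$rcr$R_d)),
               rep(0.1, 2), tolerance = 1e-12)
  expect_true(limit_cycle_converged(tn$trace, 0.05)$converged)
  expect_gt(nrow(tn$audit), 0)

  # mean-pressure identity on the limit cycle
  eq <- aneushear:::reduce_rcr(tn$rcr)
  last <- tn$trace[tn$trace$cycle == max(tn$trace$cycle), ]
  pm <- aneushear:::trapz_scalar(last$time, last$pressure) /
    (max(last$time) - min(last$time))
  expect_equal(pm, waveform_mean(wf) * (eq$R_p + eq$R_d) + eq$P_ref,
               tolerance = 0.02)
})

test_that("tuning is deterministic and refuses constant inflow", {
  wf <- make_waveform(4.0, 1.0, 60)
  a <- tune_rcr(wf, outlet_set(0.05))
  b <- tune_rcr(wf, outlet_set(0.05))
  expect_identical(a$rcr, b$rcr)
  expect_identical(a$audit, b$audit)
  expect_error(tune_rcr(make_waveform(4, 0, 60), outlet_set(0.05)),
               "infeasible")
})
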