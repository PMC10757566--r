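# Independent oracles and small fixture builders used across tests.
# Oracles deliberately use different code paths (dense resampling,
# explicit enumeration, fixed-step integration) from the package.

# Random labeled surface with a smooth random WSS time series.
random_field <- function(seed, n_times = 9L) {
  set.seed(seed)
  # small structured sheet so triangles are valid and non-degenerate
  nx <- 4L; ny <- 3L
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  pts <- cbind(g$x + rnorm(nx * ny, 0, 0.05),
               g$y + rnorm(nx * ny, 0, 0.05),
               rnorm(nx * ny, 0, 0.1))
  idx <- function(i, j) (j - 1L) * nx + i
  tris <- NULL
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      tris <- rbind(tris,
                    c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L)),
                    c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
    }
  }
  n <- nrow(pts)
  region <- rep(2L, n)
  region[g$y == ny] <- 1L              # top row is the "dome"
  times <- seq(0, 0.8, length.out = n_times)
  wss <- array(0, dim = c(n, 3L, n_times))
  for (p in seq_len(n)) {
    amp <- runif(3L, 0.5, 30)
    ph <- runif(3L, 0, 2 * pi)
    off <- rnorm(3L, 0, 5)
    for (d in 1:3) {
      wss[p, d, ] <- off[d] + amp[d] * sin(2 * pi * times / 0.8 + ph[d])
    }
  }
  tri_surface_field(pts, tris, region, times, wss)
}

# TAWSS/OSI by brute force: each sampled integrand (the per-sample
# |WSS| magnitudes and the three vector components) is resampled on a
# 10x finer grid and integrated by a plain scalar trapezoid loop.
# Checks the package's weight-based integration on non-uniform grids.
tawss_osi_oracle <- function(field, refine = 10L) {
  t0 <- field$times
  tf <- seq(t0[1L], t0[length(t0)], length.out = refine * (length(t0) - 1L) + 1L)
  Tp <- t0[length(t0)]
  n <- nrow(field$points)
  tawss <- osi <- numeric(n)
  trapz <- function(t, y) sum(diff(t) * (y[-length(y)] + y[-1L]) / 2)
  for (p in seq_len(n)) {
    mag0 <- sqrt(colSums(field$wss[p, , ]^2))
    S <- trapz(tf, approx(t0, mag0, xout = tf)$y)
    V <- sapply(1:3, function(d) {
      trapz(tf, approx(t0, field$wss[p, d, ], xout = tf)$y)
    })
    tawss[p] <- S / Tp
    osi[p] <- if (S > 0) 0.5 * (1 - sqrt(sum(V^2)) / S) else 0
  }
  list(tawss = tawss, osi = osi)
}

# Fixed-step RK4 integration of the reduced Windkessel ODE.
rk4_windkessel <- function(wf, rcr, n_cycles, dt) {
  eq <- aneushear:::reduce_rcr(rcr)
  qf <- function(t) approx(wf$time, wf$flow, xout = t %% wf$period,
                           rule = 2)$y
  f <- function(t, pc) (qf(t) - (pc - eq$P_ref) / eq$R_d) / eq$C
  times <- seq(0, n_cycles * wf$period, by = dt)
  pc <- numeric(length(times))
  pc[1L] <- eq$P_ref + aneushear::waveform_mean(wf) * eq$R_d
  for (i in seq_len(length(times) - 1L)) {
    t <- times[i]; y <- pc[i]
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    pc[i + 1L] <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  p <- pc + eq$R_p * qf(times)
  data.frame(time = times, pressure = p,
             cycle = pmin(floor(times / wf$period * (1 - 1e-12)) + 1L,
                          n_cycles))
}

# Exact two-sided signed-rank p by explicit enumeration of all 2^n
# sign vectors (mid-ranks, zeros dropped).
signed_rank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  M <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p <- mean(abs(Ws - M / 2) >= abs(W - M / 2) - 1e-9)
  list(W = W, p = p)
}

# Coarse patient spec used where geometry detail is irrelevant.
coarse_spec <- function(...) {
  patient_spec(mesh_edge_size = 0.12, n_time_samples = 11L, ...)
}
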