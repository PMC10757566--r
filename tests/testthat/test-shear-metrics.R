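# Minimal two-triangle flat mesh with prescribed areas 1 and 3:
# right triangles with legs (2, 1) and (2, 3).
two_triangle_field <- function(v1 = 10, v2 = 20) {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0),      # dome, area 1
               c(4, 0, 0), c(6, 0, 0), c(4, 3, 0),      # dome, area 3
               c(10, 0, 0), c(11, 0, 0), c(10, 1, 0))   # parent
  tris <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  region <- c(rep(1L, 6), rep(2L, 3))
  times <- c(0, 0.5, 1)
  vals <- c(rep(v1, 3), rep(v2, 3), rep(5, 3))
  wss <- array(0, dim = c(9, 3, 3))
  for (k in 1:3) wss[, 1, k] <- vals
  tri_surface_field(pts, tris, region, times, wss)
}

test_that("constant and sinusoidal fields hit the analytic TAWSS/OSI limits", {
  n <- 3L
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  tris <- rbind(c(1, 2, 3))
  times <- seq(0, 1, length.out = 2001)
  w <- 7.5
  wss <- array(0, dim = c(n, 3, length(times)))
  wss[, 2, ] <- w
  f <- tri_surface_field(pts, tris, c(1L, 2L, 2L), times, wss)
  pw <- pointwise_tawss_osi(f)
  expect_equal(pw$tawss, rep(w, 3), tolerance = 1e-12)
  expect_equal(pw$osi, rep(0, 3), tolerance = 1e-12)

  v <- 12
  wss2 <- array(0, dim = c(n, 3, length(times)))
  wss2[, 1, ] <- matrix(v * sin(2 * pi * times), n, length(times),
                        byrow = TRUE)
  f2 <- tri_surface_field(pts, tris, c(1L, 2L, 2L), times, wss2)
  pw2 <- pointwise_tawss_osi(f2)
  expect_equal(pw2$tawss, rep(2 * v / pi, 3), tolerance = 1e-6)
  expect_equal(pw2$osi, rep(0.5, 3), tolerance = 1e-9)
})

test_that("random fields agree with the dense-resampling oracle", {
  for (seed in 1:10) {
    f <- random_field(seed)
    got <- pointwise_tawss_osi(f)
    ora <- tawss_osi_oracle(f)
    expect_equal(got$tawss, ora$tawss, tolerance = 1e-6)
    expect_equal(got$osi, ora$osi, tolerance = 1e-6)
    expect_true(all(got$osi >= 0 & got$osi <= 0.5))
  }
})

test_that("regional means are area-weighted over triangles", {
  f <- two_triangle_field(10, 20)
  s <- region_summary(f)
  expect_equal(s$dome$tawss_mean, (1 * 10 + 3 * 20) / 4)  # 17.5
  expect_equal(s$dome$tawss_min, 10)
  expect_equal(s$dome$tawss_max, 20)
  expect_equal(s$dome$area, 4)
  expect_equal(s$parent$tawss_mean, 5)

  u <- two_triangle_field(8, 8)
  su <- region_summary(u)
  expect_equal(su$dome$tawss_mean, 8)
  expect_equal(su$dome$tawss_min, 8)
  expect_equal(su$dome$tawss_max, 8)
})

test_that("low-shear areas follow their threshold definitions", {
  pat <- make_patient(coarse_spec(dome_low_fraction = 0.3,
                                  dome_low_level = 0.1,
                                  parent_tawss_cv = 0.2))
  s <- region_summary(pat$field)
  expect_equal(s$mtlsa[["70"]], 30, tolerance = 1e-10)
  expect_true(s$mtlsa[["50"]] <= s$mtlsa[["70"]])
  expect_true(s$mtlsa[["70"]] <= s$mtlsa[["90"]])

  # dome uniformly at the parent mean: nothing is below 70%
  flat <- make_patient(coarse_spec(dome_low_fraction = 0,
                                   parent_tawss_cv = 0))
  sf <- region_summary(flat$field)
  expect_equal(unname(sf$mtlsa), c(0, 0, 0))
  expect_equal(sf$lsa, 0)

  # dome at zero shear: everything is low
  zero <- make_patient(coarse_spec(dome_low_fraction = 1,
                                   dome_low_level = 0))
  sz <- region_summary(zero$field)
  expect_equal(unname(sz$mtlsa), c(100, 100, 100))
  expect_equal(sz$lsa, 100)
})

test_that("summaries are invariant to point order and rigid motion", {
  pat <- make_patient(coarse_spec())
  f <- pat$field
  s0 <- region_summary(f)

  set.seed(5)
  perm <- sample(nrow(f$points))
  inv <- order(perm)
  f_perm <- tri_surface_field(f$points[perm, ],
                              matrix(inv[f$triangles], ncol = 3),
                              f$region[perm], f$times, f$wss[perm, , ])
  s1 <- region_summary(f_perm)
  expect_equal(s1$dome$tawss_mean, s0$dome$tawss_mean, tolerance = 1e-12)
  expect_equal(s1$mtlsa, s0$mtlsa, tolerance = 1e-12)
  expect_equal(s1$lsa, s0$lsa, tolerance = 1e-12)

  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  f_rot <- tri_surface_field(f$points %*% t(R) + 5, f$triangles,
                             f$region, f$times, f$wss)
  s2 <- region_summary(f_rot)
  expect_equal(s2$dome$tawss_mean, s0$dome$tawss_mean, tolerance = 1e-9)
  expect_equal(s2$dome$area, s0$dome$area, tolerance = 1e-9)
  expect_equal(s2$mtlsa, s0$mtlsa, tolerance = 1e-9)
})

test_that("summaries are stable under mesh refinement", {
  s1 <- region_summary(make_patient(patient_spec(mesh_edge_size = 0.1))$field)
  s2 <- region_summary(make_patient(patient_spec(mesh_edge_size = 0.05))$field)
  rel <- function(a, b) abs(a - b) / abs(b)
  expect_lt(rel(s1$dome$tawss_mean, s2$dome$tawss_mean), 0.01)
  expect_lt(rel(s1$parent$tawss_mean, s2$parent$tawss_mean), 0.01)
  expect_lt(abs(s1$mtlsa[["70"]] - s2$mtlsa[["70"]]), 1)
  expect_lt(abs(s1$lsa - s2$lsa), 1)
})

test_that("non-finite WSS values are reported with their location", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  wss <- array(1, dim = c(3, 3, 2))
  wss[2, 1, 2] <- NaN
  expect_error(
    tri_surface_field(pts, rbind(c(1, 2, 3)), c(1L, 2L, 2L), c(0, 1), wss),
    "point 2, time index 2")
})
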