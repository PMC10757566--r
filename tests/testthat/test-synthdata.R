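test_that("Poiseuille wall shear stress follows the closed form", {
  props <- fluid_properties()
  expect_equal(poiseuille_wss(props, 4.0, 0.2), 0.64 / (pi * 0.008),
               tolerance = 1e-12)
  expect_equal(poiseuille_wss(props, 4.0, 0.2), 25.46479,
               tolerance = 1e-6)
  expect_equal(poiseuille_wss(props, 0, 0.2), 0)
  expect_equal(poiseuille_wss(props, 8.0, 0.2),
               2 * poiseuille_wss(props, 4.0, 0.2))
  expect_error(poiseuille_wss(props, 4.0, 0), "positive")
})

test_that("generator ground truth matches the measured region summaries", {
  cases <- list(
    list(f = 0.3, osi = 0.25, cv = 0.2),
    list(f = 0.0, osi = 0.0, cv = 0.0),
    list(f = 0.62, osi = 0.5, cv = 0.35),
    list(f = 1.0, osi = 0.1, cv = 0.15))
  for (cs in cases) {
    pat <- make_patient(coarse_spec(dome_low_fraction = cs$f,
                                    osi_target = cs$osi,
                                    parent_tawss_cv = cs$cv,
                                    seed = 11L))
    s <- region_summary(pat$field)
    expect_equal(s$parent$tawss_mean, pat$truth$parent_mean_tawss,
                 tolerance = 1e-10)
    expect_equal(s$dome$tawss_mean, pat$truth$dome_mean_tawss,
                 tolerance = 1e-10)
    expect_equal(unname(s$mtlsa), unname(pat$truth$mtlsa),
                 tolerance = 1e-10)
    expect_equal(s$lsa, pat$truth$lsa, tolerance = 1e-10)
    expect_equal(s$dome$osi_mean, cs$osi, tolerance = 1e-9)
  }
})

test_that("two-level dome construction yields exact area fractions", {
  pat <- make_patient(coarse_spec(dome_low_fraction = 0.3,
                                  dome_low_level = 0.1))
  expect_equal(pat$truth$mtlsa[["70"]], 30.0, tolerance = 1e-10)
  s <- region_summary(pat$field)
  expect_equal(s$mtlsa[["70"]], 30.0, tolerance = 1e-10)
  # analytic two-level mean
  m <- pat$truth$parent_mean_tawss
  expect_equal(pat$truth$dome_mean_tawss, 0.3 * 0.1 * m + 0.7 * m,
               tolerance = 1e-9)

  none <- make_patient(coarse_spec(dome_low_fraction = 0))
  expect_true(all(none$truth$mtlsa == 0))
})

test_that("full reversal makes every dome WSS series integrate to zero", {
  pat <- make_patient(coarse_spec(osi_target = 0.5))
  f <- pat$field
  w <- aneushear:::trapz_weights(f$times)
  dome <- which(f$region == 1L)
  for (d in 1:3) {
    v <- as.vector(f$wss[dome, d, ] %*% w)
    expect_lt(max(abs(v)), 1e-10 * max(abs(f$wss)))
  }
  pw <- pointwise_tawss_osi(f)
  expect_equal(unname(range(pw$osi[dome])), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("degenerate and invalid patient specs are refused", {
  expect_error(patient_spec(mesh_edge_size = 0.5, dome_radius = 0.35),
               "degenerate")
  expect_error(patient_spec(dome_low_fraction = 1.2), "0, 1")
  expect_error(patient_spec(osi_target = 0.6), "0, 0.5")
  expect_error(patient_spec(osi_target = 0.001, n_time_samples = 11),
               "smallest nonzero")
})

test_that("cohort generator honours effect, noise and seed contracts", {
  z <- make_cohort(5, effect = 0, noise_sd = 0)
  for (m in shear_metric_names()) {
    pr <- aneushear:::cohort_pairs(z, m)
    expect_equal(pr$growing - pr$stable, rep(0, 5))
  }
  eff <- make_cohort(11, effect = 17.56, effect_metric = "MTLSA_70",
                     noise_sd = 0)
  pr <- aneushear:::cohort_pairs(eff, "MTLSA_70")
  expect_equal(pr$growing - pr$stable, rep(17.56, 11))
  pr2 <- aneushear:::cohort_pairs(eff, "MTLSA_50")
  expect_equal(pr2$growing - pr2$stable, rep(0, 11))

  a <- make_cohort(8, effect = 5, noise_sd = 10, seed = 99)
  b <- make_cohort(8, effect = 5, noise_sd = 10, seed = 99)
  expect_identical(a, b)

  expect_error(make_cohort(5, effect_metric = "NotAMetric"),
               "Mean_TAWSS")
  fracs <- make_cohort(6, noise_sd = 500, seed = 3)
  expect_true(all(fracs$MTLSA_70 >= 0 & fracs$MTLSA_70 <= 100))
  expect_true(all(fracs$Mean_OSI >= 0 & fracs$Mean_OSI <= 0.5))
})
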