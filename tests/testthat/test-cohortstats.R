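test_that("growth classification applies the two-of-three 1 mm rule", {
  expect_equal(classify_growth(c(5, 5, 5), c(6.2, 6.1, 5.0)), "growing")
  expect_equal(classify_growth(c(5, 5, 5), c(5.9, 5.9, 5.9)), "stable")
  expect_equal(classify_growth(c(5, 5, 5), c(5, 5, 5)), "stable")
  expect_equal(classify_growth(c(5, 5, 5), c(6.0, 6.0, 5.0)), "growing")
  expect_equal(classify_growth(c(5, 5, 5), c(7.0, 5.2, 5.0)), "stable")
  expect_error(classify_growth(c(5, 5), c(6, 6)), "missing dimension")
  expect_error(classify_growth(
    aneurysm_measurement(c(5, 5, 5), date = as.Date("2020-01-01")),
    aneurysm_measurement(c(6, 6, 6), date = as.Date("2019-01-01"))),
    "later than baseline")
  m <- aneurysm_measurement(c(2, 3, 4))
  expect_equal(m$volume, pi / 6 * 24)
})

test_that("exact signed-rank p matches hand-enumerated references", {
  r <- wilcoxon_paired_exact(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r$p_value, 2 / 32)
  expect_equal(r$statistic, 15)
  expect_equal(r$n_effective, 5L)

  sym <- wilcoxon_paired_exact(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(sym$p_value, 1)

  one <- wilcoxon_paired_exact(5, 3)
  expect_equal(one$p_value, 1)

  zeros <- wilcoxon_paired_exact(c(1, 2, 3), c(1, 2, 3))
  expect_true(zeros$degenerate)
  expect_equal(zeros$p_value, 1)
  expect_equal(zeros$n_effective, 0L)
})

test_that("exact signed-rank p matches the enumeration oracle on random inputs", {
  set.seed(314)
  for (i in 1:25) {
    n <- sample(2:10, 1)
    d <- round(rnorm(n, sd = 3), sample(0:1, 1))  # induces ties and zeros
    got <- wilcoxon_paired_exact(d, rep(0, n))
    ora <- signed_rank_enum(d)
    if (all(d == 0)) {
      expect_equal(got$p_value, 1)
    } else {
      expect_equal(got$statistic, ora$W)
      expect_equal(got$p_value, ora$p, tolerance = 1e-12)
    }
  }
})

test_that("exact signed-rank p matches wilcox.test for tie-free data", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    d <- rnorm(n)  # continuous: no ties, no zeros a.s.
    got <- wilcoxon_paired_exact(d, rep(0, n))
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("p-values are invariant to scaling and pair order", {
  set.seed(4)
  g <- rnorm(9, 1)
  s <- rnorm(9)
  p0 <- wilcoxon_paired_exact(g, s)$p_value
  expect_equal(wilcoxon_paired_exact(3.7 * g, 3.7 * s)$p_value, p0)
  perm <- sample(9)
  expect_equal(wilcoxon_paired_exact(g[perm], s[perm])$p_value, p0)
})

test_that("normal approximation is consistent with the exact path", {
  set.seed(11)
  d <- rnorm(18, 0.4)
  ex <- wilcoxon_paired_exact(d, rep(0, 18))
  ap <- wilcoxon_paired_exact(d, rep(0, 18), exact_max = 5L)
  expect_equal(ap$method, "normal-approximation")
  expect_equal(ap$p_value, ex$p_value, tolerance = 0.15)
})

test_that("Shapiro-Wilk gate flags non-normal and degenerate metrics", {
  set.seed(8)
  coh <- make_cohort(20, noise_sd = 10)
  gate <- shapiro_wilk_gate(coh)
  expect_equal(nrow(gate$table), length(shear_metric_names()))

  # lognormal differences: heavily skewed, should reject for most seeds
  rej <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    d <- exp(rnorm(20, 0, 1))
    rej <- rej + (stats::shapiro.test(d)$p.value < 0.05)
  }
  expect_gt(rej, 15)

  flat <- make_cohort(5, noise_sd = 0)
  g2 <- shapiro_wilk_gate(flat)
  expect_true(all(g2$table$degenerate))
  expect_equal(g2$recommendation, "nonparametric")
})

test_that("null Shapiro-Wilk rejection rate is near the nominal level", {
  set.seed(123)
  rej <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    rej <- rej + (stats::shapiro.test(rnorm(50))$p.value < 0.05)
  }
  rate <- rej / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-9)
})

test_that("cohort report flags only the metric carrying the effect", {
  coh <- make_cohort(11, effect = 40, effect_metric = "MTLSA_70",
                     noise_sd = 10, seed = 5)
  rep_ <- cohort_report(coh, alpha = 0.1)
  expect_equal(rep_$metric, intersect(shear_metric_names(), names(coh)))
  row70 <- rep_[rep_$metric == "MTLSA_70", ]
  expect_true(row70$significant)
  expect_gt(row70$growing_mean, row70$stable_mean)

  single <- make_cohort(1, noise_sd = 10, seed = 2)
  rep1 <- cohort_report(single)
  expect_true(all(rep1$p_value == 1))

  broken <- coh
  broken$MTLSA_70[3] <- NA
  expect_error(cohort_report(broken), "MTLSA_70.*pair|pair.*MTLSA_70")
})
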