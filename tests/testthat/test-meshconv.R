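test_that("convergence uses the previous-refinement 5% rule", {
  tr <- convergence_trace(c(0.30, 0.27, 0.243) * 10, c(10.0, 8.5, 8.6))
  chk <- check_converged(tr, tol = 0.05)
  expect_true(chk$converged)
  expect_equal(chk$index, 3L)         # |8.6 - 8.5| / 8.5 = 1.18%
  expect_false(check_converged(tr, tol = 0.01)$converged)

  one <- convergence_trace(0.3, 12.0)
  expect_false(check_converged(one)$converged)

  expect_error(convergence_trace(c(0.3, 0.3), c(1, 1)),
               "strictly decreasing")
  expect_error(convergence_trace(c(0.3, 0.4), c(1, 1)),
               "strictly decreasing")
})

test_that("residual conventions match their definitions", {
  # initial vs final dome mean TAWSS of a strongly refining case
  tr <- convergence_trace(c(0.40, 0.36, 0.324, 0.2915),
                          c(8.518, 12.2, 15.1, 15.754))
  expect_equal(tr$residual_final[1], (8.518 - 15.754) / 15.754,
               tolerance = 1e-12)
  expect_equal(tr$residual_final[1], -0.459, tolerance = 1e-3)
  expect_equal(tr$residual_final[4], 0)
  expect_equal(tr$normalized_size[4], 1)
  expect_equal(tr$normalized_size[1], 0.40 / 0.2915, tolerance = 1e-12)
  # the change from initial to final exceeds 80% of the final value
  expect_gt(abs(tr$residual_final[1]), 0.45)
})

test_that("convergence decision is scale invariant", {
  tawss <- c(20, 14, 13.8, 13.7)
  tr1 <- convergence_trace(c(4, 3, 2, 1), tawss)
  tr2 <- convergence_trace(c(4, 3, 2, 1), tawss * 123.4)
  expect_identical(check_converged(tr1), check_converged(tr2))
})

test_that("edge-size refinement decrements by the given factor", {
  expect_equal(next_edge_size(0.30), 0.27)
  x <- 0.30
  for (i in 1:7) x <- next_edge_size(x)
  expect_equal(x, 0.30 * 0.9^7, tolerance = 1e-12)
  expect_equal(x, 0.1435, tolerance = 1e-3)
  expect_true(x > 0.144 * 0.99 && x < 0.32)  # plausible final edge range
  expect_error(next_edge_size(0.3, factor = 1), "between 0 and 1")
  expect_error(next_edge_size(-1), "positive")
})
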