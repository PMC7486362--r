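test_that("transfer function and its inverse behave as a logistic pair", {
  expect_equal(transfer(0), 0.5)
  expect_equal(inverse_transfer(0.5), 0)
  expect_equal(transfer(inverse_transfer(0.9)), 0.9, tolerance = 1e-12)
  expect_equal(transfer(-5), 1 / (1 + exp(5)))
  # monotone increasing onto (0,1)
  xs <- seq(-30, 30, length.out = 200)
  expect_true(all(diff(transfer(xs)) > 0))
  expect_true(all(transfer(xs) > 0 & transfer(xs) < 1))
  expect_error(inverse_transfer(0), "strictly inside")
  expect_error(inverse_transfer(1), "strictly inside")
})

test_that("steady synaptic activation and depression match their closed forms", {
  expect_equal(steady_synapse(0, 6.25, 1.25), 0)
  expect_equal(steady_synapse(1, 6.25, 1.25), 1.25 / 8.5)
  expect_equal(steady_depression(0, 6.25), 1)
  expect_equal(steady_depression(1, 6.25), 1 / 7.25)
  expect_equal(steady_depression(0.7, 0), 1)  # no depression recovers fully
  # without depression s reduces to br/(1+br)
  r <- seq(0, 1, by = 0.1)
  expect_equal(steady_synapse(r, 6.25, 1.25, depression = FALSE),
               1.25 * r / (1 + 1.25 * r))
})

test_that("steady values jointly zero the synapse and depression equations", {
  p <- std_params()
  r <- seq(0.01, 0.99, length.out = 23)
  s <- steady_synapse(r, p$a, p$b)
  d <- steady_depression(r, p$a)
  ds <- p$alpha * (-s + p$b * r * d * (1 - s))
  dd <- p$beta * (1 - d - p$a * r * d)
  expect_equal(max(abs(ds)), 0, tolerance = 1e-14)
  expect_equal(max(abs(dd)), 0, tolerance = 1e-14)
  # s(r) and 1 - d(r) strictly increasing on [0, 1]
  rr <- seq(0, 1, length.out = 101)
  expect_true(all(diff(steady_synapse(rr, p$a, p$b)) > 0))
  expect_true(all(diff(1 - steady_depression(rr, p$a)) > 0))
})

test_that("nondimensionalization reproduces the standard dimensionless set", {
  nd <- nondimensionalize(physical_params(tau_d = 250, p0 = 0.5, r_max = 50))
  expect_equal(nd$params$a, 6.25)
  expect_equal(nd$params$b, 1.25)
  expect_equal(nd$params$alpha, 0.2)
  expect_equal(nd$params$beta, 0.04)
  # Delta = 1 leaves couplings and thresholds unchanged
  ph <- physical_params(Theta = 3.7, Delta = 1, W = matrix(c(12, -1, 2, 8), 2))
  nd2 <- nondimensionalize(ph)
  expect_equal(nd2$params$theta, 3.7)
  expect_equal(nd2$weights, ph$W)
  expect_error(physical_params(tau_r = -1), "positive")
  expect_error(physical_params(Delta = 0), "positive")
})

test_that("parameter bundles enforce the depression flag consistently", {
  expect_equal(dim_params(depression = FALSE)$a, 0)
  expect_false(dim_params(a = 0)$depression)
  expect_true(is_slow_depression(dim_params()))
  expect_false(is_slow_depression(dim_params(a = 1.0, b = 1.25)))
  expect_error(dim_params(b = -1), "positive")
})
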