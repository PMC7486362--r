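test_that("the right-hand side matches direct evaluation of the equations", {
  p <- std_params()
  # single unit at rest with no input: rate pulled toward f(-theta)
  dv <- network_rhs(network_state(0, 0, 1), p, weights = 40)
  expect_equal(dv$dr, transfer(-5))
  expect_equal(dv$ds, 0)
  expect_equal(dv$dd, 0)
  # saturated synapse: (1 - s) = 0 leaves only the decay term
  dv2 <- network_rhs(network_state(1, 1, 1), p, weights = 40)
  expect_equal(dv2$ds, -p$alpha)
  # any exact fixed point with steady s, d has zero derivative
  for (r_star in oracle_unit_roots()) {
    dv3 <- network_rhs(steady_state(r_star, p), p, weights = 40)
    expect_equal(max(abs(c(dv3$dr, dv3$ds, dv3$dd))), 0, tolerance = 1e-12)
  }
  expect_error(network_rhs(network_state(c(0, 0), c(0, 0), c(1, 1)), p,
                           weights = 40), "units")
})

test_that("disabling depression equals the a = 0 limit with d pinned at 1", {
  p0 <- dim_params(a = 0, depression = TRUE)  # constructor forces the flag off
  pn <- nodep_params()
  w <- sym_pair(0.3)
  set.seed(42)
  for (k in 1:10) {
    st <- network_state(runif(2), runif(2), rep(1, 2))
    dv_a0 <- network_rhs(st, p0, w, input = c(0.5, -0.2))
    dv_off <- network_rhs(st, pn, w, input = c(0.5, -0.2))
    expect_equal(dv_a0, dv_off)
  }
})

test_that("trajectories stay inside the unit cube under bounded input", {
  p <- std_params()
  w <- sym_pair(0.5)
  tr <- pulse_train(square_pulse(20, 30, 2), n_pulses = 2, tau_isi = 100)
  set.seed(7)
  for (k in 1:5) {
    st <- steady_state(runif(2), p)
    traj <- simulate_network(st, p, w, tr, t_span = c(0, 320), sample_dt = 5)
    expect_true(all(traj$r >= -1e-7 & traj$r <= 1 + 1e-7))
    expect_true(all(traj$s >= -1e-7 & traj$s <= 1 + 1e-7))
    expect_true(all(traj$d >= -1e-7 & traj$d <= 1 + 1e-7))
  }
})

test_that("analytic Jacobian of the rhs agrees with finite differences", {
  p <- std_params()
  set.seed(11)
  for (N in 1:3) {
    w <- random_network(N, mu = 0, sigma = 0.4, seed = N)
    for (k in 1:7) {
      st <- network_state(runif(N), runif(N), runif(N))
      J <- rhs_jacobian(st, p, w, input = 0.3)
      Jfd <- fd_jacobian(st, p, w, input = 0.3)
      expect_lt(max(abs(J - Jfd)), 1e-5)
    }
  }
})

test_that("the blocked fixed-point Jacobian is the rhs Jacobian at a root", {
  p <- std_params()
  for (r_star in oracle_unit_roots()) {
    J_blocked <- fp_jacobian(r_star, p, weights = 40)
    J_general <- rhs_jacobian(steady_state(r_star, p), p, weights = 40)
    expect_equal(J_blocked, J_general, tolerance = 1e-9)
  }
  # at the quiescent state the block form is lower-triangular with
  # eigenvalues given by the three relaxation rates
  J0 <- fp_jacobian(0, p, weights = 40)
  expect_equal(J0[upper.tri(J0)], rep(0, 3))
  expect_equal(sort(eigen(J0, only.values = TRUE)$values),
               sort(c(-1, -p$alpha, -p$beta)))
  # without depression the matrix drops to the (r, s) block
  expect_equal(dim(fp_jacobian(c(0.1, 0.2), nodep_params(), sym_pair(0))),
               c(4, 4))
})
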