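test_that("equilibria are invariant and settling recovers phase-line limits", {
  p <- std_params()
  roots <- oracle_unit_roots()            # OFF, saddle, ON from the 1-D oracle
  on_state <- steady_state(roots[3], p)
  traj <- simulate_network(on_state, p, 40, t_span = c(0, 400), sample_dt = 50)
  expect_lt(max(abs(traj$r - roots[3])), 1e-6)
  # settling from a fixed point is immediate
  out0 <- settle_network(on_state, p, 40)
  expect_true(out0$settled)
  expect_equal(out0$time, 0)
  # just above the saddle the phase line flows to the ON state
  out_up <- settle_network(steady_state(roots[2] + 0.01, p), p, 40)
  expect_true(out_up$settled)
  expect_equal(out_up$state$r, roots[3], tolerance = 1e-3)
  # just below, to the OFF state
  out_dn <- settle_network(steady_state(roots[2] - 0.01, p), p, 40)
  expect_equal(out_dn$state$r, roots[1], tolerance = 1e-3)
})

test_that("settled states satisfy the fixed-point equation residual", {
  p <- std_params()
  w <- sym_pair(0.5)
  set.seed(5)
  for (k in 1:4) {
    out <- settle_network(steady_state(runif(2), p), p, w)
    expect_true(out$settled)
    r <- out$state$r
    resid <- max(abs(inverse_transfer(r) -
                       drop(w %*% steady_synapse(r, p$a, p$b)) +
                       expand_theta_test(p, 2)))
    expect_lt(resid, 1e-3)   # residual in the input scale at settle_tol 1e-6
  }
})

test_that("a single pulse switches the unit according to its starting state", {
  # the maximal-history-dependence stimulus flips OFF to ON and ON to OFF
  p <- std_params()
  roots <- oracle_unit_roots()
  tr <- pulse_train(square_pulse(t0 = 0, tau_dur = 20, amplitude = 1),
                    n_pulses = 1, tau_isi = 1000)
  traj_off <- simulate_network(steady_state(roots[1], p), p, 40, tr,
                               t_span = c(0, 1020), sample_dt = 20)
  final_off <- dplyr::filter(traj_off, t == max(t))$r
  expect_gt(final_off, 0.5)    # OFF -> ON
  traj_on <- simulate_network(steady_state(roots[3], p), p, 40, tr,
                              t_span = c(0, 1020), sample_dt = 20)
  final_on <- dplyr::filter(traj_on, t == max(t))$r
  expect_lt(final_on, 0.5)     # ON -> OFF, same stimulus
})

test_that("binarization thresholds rates into ON/OFF strings", {
  expect_equal(binarize(c(0.99, 0.003, 0.7)), "101")
  expect_equal(binarize(c(0.1, 0.2)), "00")
  roots <- oracle_unit_roots()
  expect_equal(binarize(roots[1]), "0")
  expect_equal(binarize(roots[3]), "1")
  cfg <- integration_config(binarize_threshold = 0.8)
  expect_equal(binarize(0.7, cfg), "0")
})

test_that("settled outcomes are robust to 10x tighter integrator tolerances", {
  p <- std_params()
  cfg1 <- integration_config()
  cfg2 <- integration_config(rel_tol = cfg1$rel_tol / 10,
                             abs_tol = cfg1$abs_tol / 10)
  battery <- list(
    list(w = 40, r0 = 0.3), list(w = 40, r0 = 0.05),
    list(w = sym_pair(0.5), r0 = c(0.2, 0.8)),
    list(w = sym_pair(-1), r0 = c(0.7, 0.75)),
    list(w = sym_pair(-1), r0 = c(0.95, 0.9))
  )
  for (case in battery) {
    p1 <- settle_network(steady_state(case$r0, p), p, case$w, cfg1)
    p2 <- settle_network(steady_state(case$r0, p), p, case$w, cfg2)
    expect_equal(binarize(p1$state, cfg1), binarize(p2$state, cfg2))
    expect_equal(p1$state$r, p2$state$r, tolerance = 1e-3)
  }
})

test_that("without depression any pulse outcome is a no-depression attractor", {
  pn <- nodep_params()
  stable <- find_fixed_points(pn, 40)
  stable_r <- unlist(stable$r[stable$stable])
  tr <- pulse_train(square_pulse(0, 40, 2), n_pulses = 1, tau_isi = 1000)
  out <- simulate_network(steady_state(stable_r[1], pn), pn, 40, tr,
                          t_span = c(0, 1040), sample_dt = 40)
  final <- dplyr::filter(out, t == max(t))$r
  expect_lt(min(abs(final - stable_r)), 1e-3)
})
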