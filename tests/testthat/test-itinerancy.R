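test_that("null and weak stimuli leave the response map unchanged", {
  p <- std_params()
  rm_off <- single_pulse_map(p, 40, from = "0", tau_dur = c(0, 20, 40),
                             I_app = c(0, 0.25, 1))
  # zero amplitude or zero duration never changes the state
  null_cells <- dplyr::filter(rm_off, I_app == 0 | tau_dur == 0)
  expect_true(all(!null_cells$changed))
  # half the switching amplitude: no state change from either start
  expect_false(dplyr::filter(rm_off, tau_dur == 20, I_app == 0.25)$changed)
  rm_on <- single_pulse_map(p, 40, from = "1", tau_dur = c(20),
                            I_app = c(0.25, 1))
  expect_false(dplyr::filter(rm_on, I_app == 0.25)$changed)
  expect_true(dplyr::filter(rm_on, I_app == 1)$changed)
})

test_that("two identical pulses switch twice only with depression", {
  p <- std_params()
  dm <- double_pulse_map(p, 40, from = "0", tau_dur = c(10, 20),
                         I_app = c(0, 1, 2))
  expect_true(all(dplyr::filter(dm, I_app == 0)$n_switches == 0))
  cell <- dplyr::filter(dm, tau_dur == 20, I_app == 1)
  expect_equal(cell$n_switches, 2)          # OFF -> ON -> OFF
  expect_equal(cell$pattern_1, "1")
  expect_equal(cell$pattern_2, "0")
  # the same protocol without depression never switches twice
  dmn <- double_pulse_map(nodep_params(), 40, from = "0",
                          tau_dur = c(10, 20, 60), I_app = c(0, 1, 2))
  expect_true(all(dmn$n_switches < 2))
})

test_that("reachable-state counts are bounded by the stable catalog", {
  p <- std_params()
  # a null grid reaches only the initial attractor
  rs0 <- count_reachable_states(p, uncoupled_weights(2), from = "01",
                                tau_dur = c(0, 10), I_app = 0)
  expect_equal(rs0$count, 1)
  expect_equal(rs0$patterns$pattern, "01")
  # a weakly coupled five-unit network reaches several distinct states
  w5 <- random_network(5, mu = 0, sigma = 0.1, seed = 3)
  rs <- count_reachable_states(p, w5, from = "01001",
                               tau_dur = seq(10, 90, 20),
                               I_app = seq(0.5, 3, 0.5))
  expect_gte(rs$count, 2)
  cat5 <- find_fixed_points(p, w5)
  expect_lte(rs$count, sum(cat5$stable))
})

test_that("cycle detection matches brute-force iteration of a known map", {
  # deterministic 5-state map with a 3-cycle: 1 -> 2 -> 3 -> 4 -> 2
  transition <- c(2, 3, 4, 2, 1)
  iterate <- function(start, steps) {
    out <- start
    for (i in seq_len(steps)) out <- c(out, transition[out[length(out)]])
    out
  }
  seq1 <- iterate(1, 10)
  # brute force: first position whose state appeared before
  first_rep <- which(duplicated(seq1))[1]
  prev <- match(seq1[first_rep], seq1)
  det <- itinerant:::detect_cycle(seq1)
  expect_equal(det$cycle_start, prev)
  expect_equal(det$cycle_length, first_rep - prev)
  expect_equal(det$cycle_length, 3)
  # a fixed state registers as a cycle of length 1
  expect_equal(itinerant:::detect_cycle(c(5, 5))$cycle_length, 1)
  # no repeat: nothing detected
  expect_equal(itinerant:::detect_cycle(c(1, 2, 3))$cycle_length, 0)
})

test_that("a null train holds the network at its starting attractor", {
  p <- std_params()
  cat1 <- find_fixed_points(p, 40)
  tr0 <- pulse_train(square_pulse(0, 20, 0), n_pulses = 5, tau_isi = 200)
  rec <- run_train(cat1, start_index = 1, train = tr0)
  expect_equal(unique(rec$visited), cat1$index[1])
  expect_equal(rec$ell, 1)
  expect_equal(rec$cycle_length, 1)
  expect_true(all(rec$settled))
})

test_that("the single-unit flip-flop closes into a two-cycle", {
  p <- std_params()
  cat1 <- find_fixed_points(p, 40)
  off_idx <- cat1$index[cat1$pattern == "0" & cat1$stable]
  tr <- pulse_train(square_pulse(0, 20, 1), n_pulses = 10, tau_isi = 1000)
  rec <- run_train(cat1, off_idx, tr)
  expect_equal(rec$cycle_length, 2)
  expect_equal(rec$ell, 2)
  pats <- cat1$pattern[match(rec$visited, cat1$index)]
  expect_equal(pats[1:3], c("0", "1", "0"))
})

test_that("trains without depression terminate in a fixed state", {
  pn <- nodep_params()
  w <- random_network(10, mu = -0.2, sigma = 1, seed = 101)
  cat10 <- suppressMessages(estimate_frequencies(
    find_fixed_points(pn, w, max_seeds = 100, seed = 1),
    n_samples = 60, seed = 2))
  starts <- head(cat10$index[cat10$stable], 3)
  tr <- pulse_train(square_pulse(0, 20, 1), n_pulses = 12, tau_isi = 1000)
  for (i0 in starts) {
    rec <- suppressWarnings(run_train(cat10, i0, tr))
    expect_equal(rec$cycle_length, 1)
  }
})

test_that("uncoupled bistable units give trivial sequence statistics", {
  p <- std_params()
  ens <- network_ensemble(2, n = 2, mu = 0, sigma = 0, seed = 5)
  # amplitude in the trivial-history region: too weak to switch anything
  st <- sequence_stats(p, ens, tau_dur = 20, I_app = 0.25, n_pulses = 4,
                       n_freq_samples = 40)
  expect_true(all(st$ell_mean <= 2))
  expect_true(all(st$ell_max <= 2))
})

test_that("itinerancy outputs are deterministic given seeds", {
  p <- std_params()
  dm1 <- double_pulse_map(p, 40, from = "0", tau_dur = c(15, 20),
                          I_app = c(1, 1.5))
  dm2 <- double_pulse_map(p, 40, from = "0", tau_dur = c(15, 20),
                          I_app = c(1, 1.5))
  expect_identical(as.data.frame(dm1), as.data.frame(dm2))
  ens <- network_ensemble(2, n = 5, mu = 0, sigma = 0.1, seed = 12)
  s1 <- sequence_stats(p, ens, tau_dur = 20, I_app = 1, n_pulses = 5,
                       max_starts = 3, n_freq_samples = 40)
  s2 <- sequence_stats(p, ens, tau_dur = 20, I_app = 1, n_pulses = 5,
                       max_starts = 3, n_freq_samples = 40)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("targeted-subset and exponential-amplitude protocols are honored", {
  p <- std_params()
  ens <- network_ensemble(2, n = 5, mu = 0, sigma = 0.1, seed = 77)
  st <- suppressMessages(suppressWarnings(sequence_stats(
    p, ens, tau_dur = 25, I_app = 1.5, n_pulses = 4, target_fraction = 0.5,
    amplitude_draw = "exponential", max_starts = 2, n_freq_samples = 40
  )))
  expect_equal(nrow(st), 2)
  expect_true(all(st$ell_mean >= 1))
  st2 <- suppressMessages(suppressWarnings(sequence_stats(
    p, ens, tau_dur = 25, I_app = 1.5, n_pulses = 4, target_fraction = 0.5,
    amplitude_draw = "exponential", max_starts = 2, n_freq_samples = 40
  )))
  expect_identical(as.data.frame(st), as.data.frame(st2))
})
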