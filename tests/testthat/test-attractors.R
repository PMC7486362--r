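test_that("a strongly self-excited unit is bistable with one saddle", {
  cat1 <- find_fixed_points(std_params(), weights = 40)
  expect_equal(nrow(cat1), 3)
  expect_equal(sum(cat1$stable), 2)
  expect_equal(sum(cat1$degree == 1), 1)
  # roots agree with the independent bracketing oracle
  expect_equal(sort(unlist(cat1$r)), oracle_unit_roots(), tolerance = 1e-9)
  expect_true(all(cat1$residual < 1e-9))
  # the two stable states binarize to distinct labels
  expect_setequal(cat1$pattern[cat1$stable], c("0", "1"))
})

test_that("uncoupled units multiply into the combinatorial catalog", {
  p <- std_params()
  for (N in 1:3) {
    catN <- find_fixed_points(p, uncoupled_weights(N))
    expect_equal(nrow(catN), 3^N)
    for (k in 0:N) {
      expect_equal(sum(catN$degree == k), expected_saddle_count(N, k))
    }
    expect_equal(sum(catN$stable), 2^N)
  }
})

test_that("spectrum classification counts positive real parts only", {
  p <- std_params()
  expect_identical(classify_spectrum(c(-1, -p$alpha, -p$beta)),
                   list(degree = 0L, stable = TRUE, marginal = FALSE))
  cls1 <- classify_spectrum(c(0.16, -1.4, -0.03))
  expect_equal(cls1$degree, 1L)
  expect_false(cls1$stable)
  # a complex pair with negative real part is a stable spiral
  cls2 <- classify_spectrum(c(-0.01 + 0.3i, -0.01 - 0.3i, -1))
  expect_equal(cls2$degree, 0L)
  expect_true(cls2$stable)
  # near-zero real parts are flagged marginal and never counted stable
  cls3 <- classify_spectrum(c(-1, 1e-12))
  expect_true(cls3$marginal)
  expect_false(cls3$stable)
  # a diagonal test matrix: degree equals its positive diagonal entries
  eig <- eigen(diag(c(2, -1, 0.5, -3)), only.values = TRUE)$values
  expect_equal(classify_spectrum(eig)$degree, 2L)
})

test_that("depression weakens the stability of the fully active state", {
  w <- sym_pair(0)
  p <- std_params(); pn <- nodep_params()
  on_dep <- max(unlist(find_fixed_points(p, w)$r))
  on_nodep <- max(unlist(find_fixed_points(pn, w)$r))
  lead <- function(params, r_on) {
    max(Re(eigen(fp_jacobian(rep(r_on, 2), params, w),
                 only.values = TRUE)$values))
  }
  expect_gt(lead(p, on_dep), lead(pn, on_nodep))
})

test_that("stable catalog entries attract perturbed states back", {
  p <- std_params()
  w <- sym_pair(0.5)
  cat2 <- find_fixed_points(p, w)
  stable <- cat2[cat2$stable, ]
  set.seed(9)
  for (i in seq_len(nrow(stable))) {
    r0 <- stable$r[[i]]
    pert <- network_state(r0 + runif(2, -1e-4, 1e-4),
                          stable$s[[i]], stable$d[[i]])
    traj <- simulate_network(pert, p, w, t_span = c(0, 800), sample_dt = 800)
    final <- dplyr::filter(traj, t == max(t))
    expect_lt(max(abs(final$r - r0)), 1e-6)
  }
})

test_that("occurrence frequencies partition the sampled state space", {
  p <- std_params()
  cat1 <- estimate_frequencies(find_fixed_points(p, 40), n_samples = 60,
                               seed = 21)
  expect_true(all(cat1$frequency[cat1$stable] > 0))
  expect_equal(sum(cat1$frequency) + attr(cat1, "unsettled_fraction"), 1)
  expect_equal(cat1$frequency[!cat1$stable], 0)  # saddles collect no samples
  # a monostable unit funnels every sample into its only attractor
  mono <- estimate_frequencies(find_fixed_points(p, weights = 10),
                               n_samples = 25, seed = 3)
  expect_equal(sum(mono$stable), 1)
  expect_equal(mono$frequency[mono$stable], 1)
})

test_that("basin maps respect the exchange symmetry of identical units", {
  p <- std_params()
  bm <- map_basins(p, sym_pair(0), resolution = 41)
  expect_equal(sum(basin_areas(bm)$area), 1)
  # swapping (r1, r2) swaps the pattern labels
  swapped <- dplyr::mutate(
    bm,
    pattern_swapped = paste0(substr(pattern, 2, 2), substr(pattern, 1, 1))
  )
  merged <- dplyr::inner_join(
    dplyr::select(bm, r1, r2, pattern),
    dplyr::select(swapped, r1 = r2, r2 = r1, pattern_swapped),
    by = c("r1", "r2")
  )
  expect_true(all(merged$pattern == merged$pattern_swapped, na.rm = TRUE))
})

test_that("basin areas are stable under grid refinement without depression", {
  pn <- nodep_params()
  a1 <- basin_areas(map_basins(pn, sym_pair(-1), resolution = 31))
  a2 <- basin_areas(map_basins(pn, sym_pair(-1), resolution = 62))
  joined <- dplyr::inner_join(a1, a2, by = "pattern")
  expect_equal(nrow(joined), nrow(a1))
  expect_lt(max(abs(joined$area.x - joined$area.y)), 0.02)
})
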