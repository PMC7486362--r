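# initial attractor whose binarized pattern matches `pattern`; the rate
# vector is assembled from each unit's isolated ON/OFF roots and settled.
pattern_attractor <- function(pattern, params, weights,
                              cfg = integration_config()) {
  w <- as_weight_matrix(weights)
  n <- nrow(w)
  bits <- as.integer(strsplit(pattern, "")[[1]])
  if (length(bits) != n) {
    abort(sprintf("pattern '%s' has %d units but the network has %d.",
                  pattern, length(bits), n))
  }
  theta <- expand_theta(params, n)
  r0 <- vapply(seq_len(n), function(i) {
    xr <- sort(transfer(single_unit_roots_x(w[i, i], theta[i], 0, params)))
    if (bits[i] == 1) xr[length(xr)] else xr[1]
  }, numeric(1))
  out <- settle_network(steady_state(r0, params), params, w, cfg)
  if (!out$settled) {
    warn(sprintf("initial pattern %s did not settle within the cutoff.",
                 pattern))
  }
  out$state
}

# run a grid of (tau_dur, I_app) cells through `n_pulses` pulses from a
# common initial state, batching cells that share a duration. Returns a
# tibble with per-cell binarized settled patterns after each pulse.
pulse_grid_run <- function(state0, params, w, tau_dur, I_app, n_pulses,
                           tau_isi, cfg) {
  n <- ncol(as_weight_matrix(w))
  w <- as_weight_matrix(w)
  grid <- tidyr::expand_grid(tau_dur = tau_dur, I_app = I_app)
  sv <- state_vectors(state0)
  out <- purrr::map(tau_dur, function(dur) {
    m <- length(I_app)
    R <- matrix(sv$r, m, n, byrow = TRUE)
    S <- matrix(sv$s, m, n, byrow = TRUE)
    D <- matrix(sv$d, m, n, byrow = TRUE)
    pat <- matrix(NA_character_, m, n_pulses)
    settled <- matrix(TRUE, m, n_pulses)
    for (p in seq_len(n_pulses)) {
      if (dur > 0) {
        sol <- integrate_batch(R, S, D, params, w,
                               input = matrix(I_app, m, n), dur, cfg)
        R <- sol$R; S <- sol$S; D <- sol$D
      }
      st <- settle_batch(R, S, D, params, w, cfg, max_time = tau_isi)
      R <- st$R; S <- st$S; D <- st$D
      settled[, p] <- st$settled
      pat[, p] <- apply(R, 1, binarize, cfg = cfg)
    }
    tibble(tau_dur = dur, I_app = I_app,
           pattern_by_pulse = lapply(seq_len(m), function(i) pat[i, ]),
           settled = apply(settled, 1, all))
  })
  dplyr::bind_rows(out)
}

#' Single-pulse stimulus-response map
#'
#' For every combination of pulse duration and amplitude, the network is
#' prepared in the settled attractor with binary pattern `from`, given one
#' square pulse applied to all units, allowed to relax, and the final
#' binarized pattern recorded.  For a single unit this is the
#' history-dependence diagram: the same pulse can switch the unit ON from OFF
#' and OFF from ON in different regions of the (duration, amplitude) plane.
#'
#' @inheritParams simulate_network
#' @param from Initial binary pattern (e.g. `"0"` or `"1"` for one unit).
#' @param tau_dur Numeric vector of pulse durations.
#' @param I_app Numeric vector of pulse amplitudes.
#' @param settle_time Relaxation time allowed after the pulse (the
#'   inter-stimulus interval of the corresponding train protocol).
#' @return A `response_map` tibble with columns `tau_dur`, `I_app`,
#'   `final_pattern`, `changed`, `settled`; attributes `from`, `params`.
#' @examples
#' \donttest{
#' rm1 <- single_pulse_map(dim_params(), weights = 40, from = "0",
#'                         tau_dur = c(10, 20), I_app = c(0, 1, 2))
#' }
#' @export
single_pulse_map <- function(params, weights, from = "0",
                             tau_dur = seq(0, 100, length.out = 26),
                             I_app = seq(0, 4, length.out = 21),
                             settle_time = 1000,
                             cfg = integration_config()) {
  w <- as_weight_matrix(weights)
  state0 <- pattern_attractor(from, params, w, cfg)
  res <- pulse_grid_run(state0, params, w, tau_dur, I_app, n_pulses = 1,
                        tau_isi = settle_time, cfg = cfg)
  res <- dplyr::mutate(
    res,
    final_pattern = purrr::map_chr(.data$pattern_by_pulse, 1),
    changed = .data$final_pattern != from
  )
  structure(dplyr::select(res, -"pattern_by_pulse"),
            class = c("response_map", class(res)),
            from = from, params = params, protocol = "single_pulse")
}

#' Two-pulse history-dependence map
#'
#' Applies two identical pulses separated by `tau_isi` and counts binarized
#' state changes across the settled states (initial, after pulse 1, after
#' pulse 2).  Cells with 2 changes are the maximally history-dependent
#' regime in which the same stimulus repeatedly switches the state back and
#' forth; without synaptic depression no such cell exists.
#'
#' @inheritParams single_pulse_map
#' @param tau_isi Offset-to-onset interval between the two pulses.
#' @return A `response_map` tibble with columns `tau_dur`, `I_app`,
#'   `pattern_1`, `pattern_2`, `n_switches` (0, 1, or 2), `settled`.
#' @export
double_pulse_map <- function(params, weights, from = "0",
                             tau_dur = seq(0, 100, length.out = 26),
                             I_app = seq(0, 4, length.out = 21),
                             tau_isi = 1000,
                             cfg = integration_config()) {
  w <- as_weight_matrix(weights)
  state0 <- pattern_attractor(from, params, w, cfg)
  res <- pulse_grid_run(state0, params, w, tau_dur, I_app, n_pulses = 2,
                        tau_isi = tau_isi, cfg = cfg)
  res <- dplyr::mutate(
    res,
    pattern_1 = purrr::map_chr(.data$pattern_by_pulse, 1),
    pattern_2 = purrr::map_chr(.data$pattern_by_pulse, 2),
    n_switches = (from != .data$pattern_1) + (.data$pattern_1 != .data$pattern_2)
  )
  structure(dplyr::select(res, -"pattern_by_pulse"),
            class = c("response_map", class(res)),
            from = from, params = params, protocol = "double_pulse")
}

#' Count final states reachable by a uniform pulse
#'
#' Starting every run from the same settled attractor (`from`), applies a
#' single square pulse uniformly to all units for every (duration,
#' amplitude) combination and counts the distinct settled binary patterns.
#' This measures the network's capacity to encode stimulus duration and
#' amplitude in its final state; synaptic depression typically enlarges it.
#'
#' @inheritParams single_pulse_map
#' @param from Initial binary pattern (default the five-unit example
#'   `"01001"`).
#' @return A list of class `reachable_states`: `count` (distinct settled
#'   patterns), `patterns` (tibble pattern/n), `map` (the per-cell grid),
#'   `n_unsettled`.
#' @export
count_reachable_states <- function(params, weights, from = "01001",
                                   tau_dur = seq(4, 100, length.out = 13),
                                   I_app = seq(0.25, 4, length.out = 16),
                                   settle_time = 1000,
                                   cfg = integration_config()) {
  rm1 <- single_pulse_map(params, weights, from = from, tau_dur = tau_dur,
                          I_app = I_app, settle_time = settle_time, cfg = cfg)
  ok <- dplyr::filter(rm1, .data$settled)
  pats <- dplyr::count(ok, pattern = .data$final_pattern, sort = TRUE)
  structure(
    list(count = nrow(pats), patterns = pats, map = rm1,
         n_unsettled = sum(!rm1$settled), from = from),
    class = "reachable_states"
  )
}

#' @export
print.reachable_states <- function(x, ...) {
  cat(sprintf("<reachable_states> %d distinct final states from %s (%d unsettled cells)\n",
              x$count, x$from, x$n_unsettled))
  print(x$patterns)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.reachable_states <- function(x, ...) x$patterns

#' @exportS3Method generics::glance
glance.reachable_states <- function(x, ...) {
  tibble(n_reachable = x$count, n_unsettled = x$n_unsettled, from = x$from)
}

#' Drive a network through a train of repeated stimuli
#'
#' Starting at a catalogued attractor, applies a train of identical square
#' pulses; after each pulse the network relaxes for the inter-stimulus
#' interval and the settled state is matched to the catalog (states matching
#' no entry are polished and appended with a warning).  Because the map from
#' settled state to settled state is deterministic, the visited sequence is
#' eventually periodic; the record is closed at the first repeated catalog
#' index and the cycle reported.
#'
#' @param catalog An [find_fixed_points()] catalog for the network.
#' @param start_index Catalog index of the initial attractor.
#' @param train A [pulse_train()]; its `n_pulses` bounds the record length.
#' @param cfg An [integration_config()].
#' @return A list of class `transition_record`: `visited` (catalog indices,
#'   initial first), `ell` (number of distinct states visited),
#'   `cycle_start`, `cycle_length` (1 for a terminal fixed state; 0 if no
#'   repeat occurred within the train), `settled` (per-pulse flags),
#'   `catalog` (possibly extended).
#' @examples
#' \donttest{
#' cat1 <- find_fixed_points(dim_params(), weights = 40)
#' tr <- pulse_train(square_pulse(0, 20, 1), n_pulses = 10, tau_isi = 1000)
#' run_train(cat1, start_index = 1, train = tr)$visited
#' }
#' @export
run_train <- function(catalog, start_index, train,
                      cfg = integration_config()) {
  ctx <- catalog_context(catalog)
  params <- ctx$params; w <- ctx$weights
  n <- nrow(w)
  train <- as_pulse_train(train)
  amps <- pulse_amplitudes(train, n)
  if (!start_index %in% catalog$index) {
    abort(sprintf("start_index %d is not in the catalog.", start_index))
  }
  row0 <- which(catalog$index == start_index)
  state <- list(r = catalog$r[[row0]], s = catalog$s[[row0]],
                d = catalog$d[[row0]])
  visited <- start_index
  settled <- logical(0)
  cycle_start <- 0L; cycle_length <- 0L
  fn <- packed_rhs(params, w, n)
  for (p in seq_len(train$n_pulses)) {
    y <- c(state$r, state$s, state$d)
    if (train$pulse$tau_dur > 0) {
      out <- ode_segment(y, c(0, train$pulse$tau_dur), fn, amps[p, ], cfg)
      y <- as.numeric(out[nrow(out), -1])
    }
    rootfn <- function(t, yy, parms) {
      max(abs(fn(t, yy, parms)[[1]])) - cfg$settle_tol
    }
    out <- deSolve::ode(y = y, times = c(0, train$tau_isi), func = fn,
                        parms = list(input = numeric(n)),
                        rtol = cfg$rel_tol, atol = cfg$abs_tol,
                        method = "lsodar", rootfunc = rootfn)
    y <- as.numeric(out[nrow(out), -1])
    res <- max(abs(fn(0, y, list(input = numeric(n)))[[1]]))
    settled[p] <- res <= cfg$settle_tol * 1.01
    r_now <- pmin(pmax(y[seq_len(n)], 0), 1)
    idx <- match_catalog(catalog, r_now, cfg$match_tol)
    if (is.na(idx)) {
      ext <- extend_catalog(catalog, r_now, sprintf("post-pulse state %d", p))
      catalog <- ext$catalog
      idx <- ext$index
    }
    state <- list(r = y[seq_len(n)], s = y[n + seq_len(n)],
                  d = if (params$depression) y[2 * n + seq_len(n)]
                      else rep(1, n))
    prev <- match(idx, visited)
    visited <- c(visited, idx)
    if (!is.na(prev)) {
      cycle_start <- prev
      cycle_length <- length(visited) - prev
      break
    }
  }
  structure(
    list(visited = visited, ell = length(unique(visited)),
         cycle_start = cycle_start, cycle_length = cycle_length,
         settled = settled, start_index = start_index, catalog = catalog),
    class = "transition_record"
  )
}

#' @export
print.transition_record <- function(x, ...) {
  cyc <- if (x$cycle_length > 0) {
    sprintf(" cycle of length %d from position %d", x$cycle_length, x$cycle_start)
  } else " no cycle detected"
  cat(sprintf("<transition_record> %s; ell=%d;%s\n",
              paste(x$visited, collapse = " -> "), x$ell, cyc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.transition_record <- function(x, ...) {
  tibble(
    step = seq_along(x$visited) - 1L,
    index = x$visited,
    pattern = x$catalog$pattern[match(x$visited, x$catalog$index)],
    settled = c(NA, x$settled)[seq_along(x$visited)]
  )
}

#' @exportS3Method generics::glance
glance.transition_record <- function(x, ...) {
  tibble(ell = x$ell, n_steps = length(x$visited) - 1L,
         cycle_start = x$cycle_start, cycle_length = x$cycle_length,
         all_settled = all(x$settled))
}

# detect the first cycle in an integer sequence (oracle-friendly helper):
# returns list(cycle_start, cycle_length), 0/0 if no repeat
detect_cycle <- function(indices) {
  seen <- integer(0)
  for (i in seq_along(indices)) {
    prev <- match(indices[i], seen)
    if (!is.na(prev)) {
      return(list(cycle_start = prev, cycle_length = i - prev))
    }
    seen <- c(seen, indices[i])
  }
  list(cycle_start = 0L, cycle_length = 0L)
}

#' Sequence-length statistics over an ensemble of random networks
#'
#' For each network in a seeded ensemble, enumerates the attractor catalog,
#' runs a repeated-stimulus train from stable fixed points, and summarizes
#' the number of distinct states visited: the per-network mean sequence
#' length and the per-network maximum.  Conditions differing in depression,
#' targeting fraction, or amplitude protocol can be compared by calling this
#' with different `params`/`target_fraction`/`amplitude_draw`.
#'
#' The targeted unit subset is drawn once per network (seeded) and reused
#' for every pulse.  With `max_starts` below the stable count, a seeded
#' random subset of stable fixed points is used as starting states.
#'
#' @inheritParams simulate_network
#' @param networks A [network_ensemble()] tibble (columns `network`, `seed`,
#'   `w`).
#' @param tau_dur,I_app Pulse duration and amplitude.
#' @param n_pulses Train length bound (records close early at a repeat).
#' @param tau_isi Inter-stimulus interval.
#' @param target_fraction Fraction of units receiving the stimulus (1 = all).
#' @param amplitude_draw `"fixed"` or `"exponential"` per-pulse amplitudes.
#' @param max_starts Cap on starting attractors per network; when the stable
#'   count exceeds it, the most frequently occurring attractors are used.
#' @param max_seeds Newton-start cap per catalog ([find_fixed_points()]).
#' @param n_freq_samples Random initial conditions settled per network to
#'   discover attractors missed by Newton seeding and estimate their
#'   occurrence frequencies (see [estimate_frequencies()]); 0 skips this.
#' @return A `sequence_stats` tibble with one row per network: `network`,
#'   `seed`, `n_stable`, `n_starts`, `ell_mean`, `ell_max`,
#'   `all_settled`.
#' @examples
#' \donttest{
#' ens <- network_ensemble(2, n = 5, mu = 0, sigma = 0.1, seed = 7)
#' sequence_stats(dim_params(), ens, n_pulses = 6, max_starts = 3)
#' }
#' @export
sequence_stats <- function(params, networks, tau_dur = 20, I_app = 1,
                           n_pulses = 30, tau_isi = 1000,
                           target_fraction = 1,
                           amplitude_draw = c("fixed", "exponential"),
                           max_starts = Inf, max_seeds = 300,
                           n_freq_samples = 150,
                           cfg = integration_config()) {
  amplitude_draw <- match.arg(amplitude_draw)
  rows <- purrr::pmap(networks, function(network, seed, w, ...) {
    n <- nrow(w)
    catalog <- find_fixed_points(params, w, max_seeds = max_seeds,
                                 seed = seed, cfg = cfg)
    if (n_freq_samples > 0) {
      catalog <- estimate_frequencies(catalog, n_samples = n_freq_samples,
                                      seed = seed + 40000L, cfg = cfg)
    }
    stable <- catalog[catalog$stable, ]
    if (nrow(stable) == 0) {
      warn(sprintf("network %d has no stable fixed points; dropped.", network))
      return(NULL)
    }
    stable_idx <- stable$index[order(-(stable$frequency %||% 0),
                                     stable$index)]
    if (all(is.na(stable$frequency))) stable_idx <- stable$index
    target <- if (target_fraction >= 1) NULL else withr::with_seed(
      seed + 10000L,
      sort(sample.int(n, max(1, round(target_fraction * n))))
    )
    starts <- head(stable_idx, max_starts)
    train <- pulse_train(
      square_pulse(t0 = 0, tau_dur = tau_dur, amplitude = I_app,
                   target = target),
      n_pulses = n_pulses, tau_isi = tau_isi,
      amplitude_draw = amplitude_draw, seed = seed + 30000L
    )
    recs <- purrr::map(starts, function(i0) {
      run_train(catalog, i0, train, cfg = cfg)
    })
    ells <- vapply(recs, function(x) x$ell, numeric(1))
    tibble(
      network = network, seed = seed, n_stable = length(stable_idx),
      n_starts = length(starts), ell_mean = mean(ells), ell_max = max(ells),
      all_settled = all(vapply(recs, function(x) all(x$settled), logical(1)))
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sequence_stats", class(out)),
            params = params, tau_dur = tau_dur, I_app = I_app,
            target_fraction = target_fraction,
            amplitude_draw = amplitude_draw)
}

#' @exportS3Method generics::glance
glance.sequence_stats <- function(x, ...) {
  tibble(
    n_networks = nrow(x),
    ell_mean = mean(x$ell_mean),
    ell_max_mean = mean(x$ell_max),
    ell_mean_sd = stats::sd(x$ell_mean),
    ell_max_sd = stats::sd(x$ell_max)
  )
}
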