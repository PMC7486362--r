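#' Integration and settling configuration
#'
#' Numerical knobs shared by the simulation and analysis routines.
#'
#' `settle_tol` is the threshold on the max-norm of the right-hand side below
#' which a trajectory is declared settled.  The slowest linear mode at an
#' active (ON) fixed point of the standard parameter set has a real part of
#' about -0.012, so residuals shrink by only ~e^-12 per 1000 time units;
#' `settle_tol = 1e-6` together with an attractor-matching tolerance of
#' `match_tol = 1e-3` on the rate vector identifies final states reliably
#' without demanding the unreachable tail of that slow decay.
#'
#' @param rel_tol,abs_tol Integrator relative/absolute tolerances.
#' @param settle_tol Max-norm derivative threshold for steady state.
#' @param max_settle_time Settling cutoff in dimensionless time.
#' @param match_tol Max-norm tolerance on `r` for matching a settled state to
#'   a catalogued attractor.
#' @param binarize_threshold Rate cut separating ON from OFF, in (0, 1).
#' @return An object of class `integration_config` (a named list).
#' @export
integration_config <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                               settle_tol = 1e-6, max_settle_time = 2000,
                               match_tol = 1e-3, binarize_threshold = 0.5) {
  if (any(c(rel_tol, abs_tol, settle_tol, max_settle_time, match_tol) <= 0)) {
    abort("tolerances and the settling cutoff must be positive.")
  }
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    abort("`binarize_threshold` must lie in (0, 1).")
  }
  structure(
    list(rel_tol = rel_tol, abs_tol = abs_tol, settle_tol = settle_tol,
         max_settle_time = max_settle_time, match_tol = match_tol,
         binarize_threshold = binarize_threshold),
    class = "integration_config"
  )
}

# deSolve-facing rhs on the packed vector c(r, s, d)
packed_rhs <- function(params, w, n) {
  force(params); force(w); force(n)
  th <- expand_theta(params, n)
  a <- params$a; b <- params$b; al <- params$alpha; be <- params$beta
  dep <- params$depression
  function(t, y, parms) {
    r <- y[seq_len(n)]; s <- y[n + seq_len(n)]; d <- y[2 * n + seq_len(n)]
    u <- drop(w %*% s) - th + parms$input
    dr <- -r + transfer(u)
    if (dep) {
      ds <- al * (-s + b * r * d * (1 - s))
      dd <- be * (1 - d - a * r * d)
    } else {
      ds <- al * (-s + b * r * (1 - s))
      dd <- numeric(n)
    }
    list(c(dr, ds, dd))
  }
}

pack_state <- function(state) {
  sv <- state_vectors(state)
  c(sv$r, sv$s, sv$d)
}

unpack_state <- function(y, n) {
  network_state(pmin(pmax(y[seq_len(n)], 0), 1),
                pmin(pmax(y[n + seq_len(n)], 0), 1),
                pmin(pmax(y[2 * n + seq_len(n)], 0), 1))
}

ode_segment <- function(y0, times, fn, input, cfg) {
  out <- deSolve::ode(y = y0, times = times, func = fn,
                      parms = list(input = input),
                      rtol = cfg$rel_tol, atol = cfg$abs_tol, method = "lsoda")
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf(
      "integrator failed on segment [%g, %g] (rtol=%g, atol=%g).",
      times[1], times[length(times)], cfg$rel_tol, cfg$abs_tol))
  }
  out
}

#' Integrate the network through a stimulus protocol
#'
#' Integrates the model from `state0` over `t_span`, splitting the
#' integration at every pulse onset/offset so the solver never steps across a
#' current discontinuity.  The trajectory is returned in tidy long form.
#'
#' @param state0 Initial state tibble ([network_state()] / [steady_state()]).
#' @param params A [dim_params()] bundle.
#' @param weights Coupling matrix (or scalar for N = 1).
#' @param train Optional [pulse_train()] or [square_pulse()]; `NULL` means no
#'   applied current.
#' @param t_span Length-2 numeric: start and end times.
#' @param sample_dt Spacing of returned sample times.
#' @param cfg An [integration_config()].
#' @return A tibble of class `rate_trajectory` with columns `t`, `unit`, `r`,
#'   `s`, `d`.
#' @examples
#' p <- dim_params()
#' tr <- pulse_train(square_pulse(50, 20, 1), n_pulses = 1)
#' traj <- simulate_network(steady_state(0.0111, p), p, 40, tr,
#'                          t_span = c(0, 300))
#' @export
simulate_network <- function(state0, params, weights, train = NULL,
                             t_span = c(0, 1000), sample_dt = 1,
                             cfg = integration_config()) {
  sv <- state_vectors(state0)
  n <- length(sv$r)
  w <- as_weight_matrix(weights, n)
  fn <- packed_rhs(params, w, n)
  breaks <- if (is.null(train)) numeric(0) else stim_breaks(train)
  breaks <- breaks[breaks > t_span[1] & breaks < t_span[2]]
  edges <- unique(c(t_span[1], breaks, t_span[2]))
  y <- pack_state(state0)
  rows <- list()
  for (k in seq_len(length(edges) - 1)) {
    t0 <- edges[k]; t1 <- edges[k + 1]
    times <- unique(c(seq(t0, t1, by = sample_dt), t1))
    input <- if (is.null(train)) numeric(n) else {
      stim_current(train, (t0 + t1) / 2, n)
    }
    out <- ode_segment(y, times, fn, input, cfg)
    y <- as.numeric(out[nrow(out), -1])
    keep <- if (k < length(edges) - 1) -nrow(out) else TRUE  # drop duplicated edge
    rows[[k]] <- out[keep, , drop = FALSE]
  }
  raw <- do.call(rbind, rows)
  traj <- tibble(
    t = rep(raw[, 1], times = n),
    unit = rep(seq_len(n), each = nrow(raw)),
    r = as.numeric(raw[, 1 + seq_len(n)]),
    s = as.numeric(raw[, 1 + n + seq_len(n)]),
    d = if (params$depression) as.numeric(raw[, 1 + 2 * n + seq_len(n)])
        else rep(1, nrow(raw) * n)
  )
  structure(dplyr::arrange(traj, .data$t, .data$unit),
            class = c("rate_trajectory", class(traj)))
}

# residual of the autonomous rhs at a packed state
packed_residual <- function(y, fn) {
  max(abs(fn(0, y, list(input = 0))[[1]]))
}

#' Relax the network to a steady state
#'
#' Integrates the autonomous system (zero applied current) until the max-norm
#' of the right-hand side drops below `cfg$settle_tol` (detected by the
#' solver's root-finding, so integration stops at the crossing) or until
#' `max_time` is reached, whichever comes first.  Timing out is reported as
#' `settled = FALSE`, not an error: long transients are an expected regime in
#' larger random networks.
#'
#' @inheritParams simulate_network
#' @param max_time Settling cutoff; defaults to `cfg$max_settle_time`.
#' @return A list of class `settled_state` with elements `state` (tibble),
#'   `settled` (logical), `time` (time at which settling was detected, or the
#'   cutoff), and `residual`.
#' @examples
#' p <- dim_params()
#' settle_network(steady_state(0.3, p), p, 40)$state$r
#' @export
settle_network <- function(state0, params, weights,
                           cfg = integration_config(), max_time = NULL) {
  sv <- state_vectors(state0)
  n <- length(sv$r)
  w <- as_weight_matrix(weights, n)
  fn <- packed_rhs(params, w, n)
  max_time <- max_time %||% cfg$max_settle_time
  y0 <- pack_state(state0)
  if (packed_residual(y0, fn) < cfg$settle_tol) {
    return(structure(list(state = unpack_state(y0, n), settled = TRUE,
                          time = 0, residual = packed_residual(y0, fn)),
                     class = "settled_state"))
  }
  rootfn <- function(t, y, parms) {
    max(abs(fn(t, y, parms)[[1]])) - cfg$settle_tol
  }
  out <- deSolve::ode(y = y0, times = c(0, max_time), func = fn,
                      parms = list(input = numeric(n)),
                      rtol = cfg$rel_tol, atol = cfg$abs_tol,
                      method = "lsodar", rootfunc = rootfn)
  t_end <- out[nrow(out), 1]
  y <- as.numeric(out[nrow(out), -1])
  res <- packed_residual(y, fn)
  structure(
    list(state = unpack_state(y, n), settled = res <= cfg$settle_tol * 1.01,
         time = t_end, residual = res),
    class = "settled_state"
  )
}

#' @export
print.settled_state <- function(x, ...) {
  cat(sprintf("<settled_state> settled=%s t=%.1f residual=%.2e\n",
              x$settled, x$time, x$residual))
  print(x$state)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.settled_state <- function(x, ...) {
  dplyr::mutate(x$state, settled = x$settled, settle_time = x$time)
}

# ---- batched ensemble integration ------------------------------------------
# Many independent copies of the same network are stacked into one block
# ODE system (matrices M x N); converged rows are frozen and pruned between
# chunks. Used by basin maps, frequency estimation, and response-map grids.

batch_rhs <- function(params, w, n, m) {
  th <- expand_theta(params, n)
  a <- params$a; b <- params$b; al <- params$alpha; be <- params$beta
  dep <- params$depression
  wt <- t(w)
  function(t, y, parms) {
    R <- matrix(y[seq_len(m * n)], m, n)
    S <- matrix(y[m * n + seq_len(m * n)], m, n)
    D <- matrix(y[2 * m * n + seq_len(m * n)], m, n)
    U <- S %*% wt - matrix(th, m, n, byrow = TRUE) + parms$input
    dR <- -R + transfer(U)
    if (dep) {
      dS <- al * (-S + b * R * D * (1 - S))
      dD <- be * (1 - D - a * R * D)
    } else {
      dS <- al * (-S + b * R * (1 - S))
      dD <- matrix(0, m, n)
    }
    list(c(dR, dS, dD))
  }
}

# integrate a batch for a fixed duration under constant per-row input
# R, S, D: M x N matrices; input: M x N matrix (or scalar)
integrate_batch <- function(R, S, D, params, w, input, t_len, cfg) {
  m <- nrow(R); n <- ncol(R)
  if (t_len <= 0) return(list(R = R, S = S, D = D))
  if (length(input) == 1) input <- matrix(input, m, n)
  fn <- batch_rhs(params, w, n, m)
  # explicit Adams: the stacked system is non-stiff, and the implicit
  # stiff path would factor a dense Jacobian across all 3*m*n states
  out <- deSolve::ode(y = c(R, S, D), times = c(0, t_len), func = fn,
                      parms = list(input = input),
                      rtol = cfg$rel_tol, atol = cfg$abs_tol,
                      method = "adams")
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf("batch integrator failed (m=%d, n=%d, t=%g).", m, n, t_len))
  }
  y <- as.numeric(out[nrow(out), -1])
  list(R = matrix(y[seq_len(m * n)], m, n),
       S = matrix(y[m * n + seq_len(m * n)], m, n),
       D = matrix(y[2 * m * n + seq_len(m * n)], m, n))
}

# settle a batch of initial conditions (autonomous), chunked with pruning.
# Returns R/S/D at the final time plus per-row settled flags and times.
settle_batch <- function(R, S, D, params, w, cfg = integration_config(),
                         max_time = NULL, chunk = 250) {
  m <- nrow(R); n <- ncol(R)
  max_time <- max_time %||% cfg$max_settle_time
  th <- expand_theta(params, n)
  residual_rows <- function(R, S, D) {
    U <- S %*% t(w) - matrix(th, m0 <- nrow(R), n, byrow = TRUE)
    dR <- -R + transfer(U)
    if (params$depression) {
      dS <- params$alpha * (-S + params$b * R * D * (1 - S))
      dD <- params$beta * (1 - D - params$a * R * D)
    } else {
      dS <- params$alpha * (-S + params$b * R * (1 - S))
      dD <- matrix(0, nrow(R), n)
    }
    pmax(apply(abs(dR), 1, max), apply(abs(dS), 1, max), apply(abs(dD), 1, max))
  }
  settled <- rep(FALSE, m)
  settle_time <- rep(NA_real_, m)
  active <- seq_len(m)
  t_now <- 0
  res <- residual_rows(R, S, D)
  settled[res < cfg$settle_tol] <- TRUE
  settle_time[settled] <- 0
  active <- which(!settled)
  while (length(active) > 0 && t_now < max_time) {
    step <- min(chunk, max_time - t_now)
    sol <- integrate_batch(R[active, , drop = FALSE], S[active, , drop = FALSE],
                           D[active, , drop = FALSE], params, w, 0, step, cfg)
    R[active, ] <- sol$R; S[active, ] <- sol$S; D[active, ] <- sol$D
    t_now <- t_now + step
    res <- residual_rows(sol$R, sol$S, sol$D)
    done <- res < cfg$settle_tol
    settled[active[done]] <- TRUE
    settle_time[active[done]] <- t_now
    active <- active[!done]
  }
  list(R = R, S = S, D = D, settled = settled, time = settle_time)
}

#' Binarize a network state into an ON/OFF pattern
#'
#' Unit i is labeled ON (1) when its rate exceeds the binarization threshold,
#' OFF (0) otherwise; the result is rendered as a 0/1 string with unit 1
#' leftmost (e.g. `"01001"`).
#'
#' @param state A state tibble, or a numeric rate vector.
#' @param cfg An [integration_config()] (supplies the threshold).
#' @return A character scalar of 0/1 labels.
#' @examples
#' binarize(c(0.99, 0.003))
#' @export
binarize <- function(state, cfg = integration_config()) {
  r <- if (is.numeric(state)) state else state_vectors(state)$r
  paste(as.integer(r > cfg$binarize_threshold), collapse = "")
}

#' Fraction of random initial states that fail to settle
#'
#' Draws `n_samples` initial rate vectors uniformly from \[0, 1\]^N (with
#' synapse and depression at their conditional steady values), relaxes each,
#' and reports the fraction not within `tol` (max-norm of the right-hand
#' side) of a steady state by the cutoff.  Used to probe the growth of long
#' transients with network size: the cutoff default of 500 time units
#' corresponds to five seconds at a 10 ms rate time constant.
#'
#' @inheritParams simulate_network
#' @param n_samples Number of random initial conditions.
#' @param cutoff Settling cutoff (dimensionless time).
#' @param tol Residual threshold defining "reached a steady state"; looser
#'   than `settle_tol` because the question is whether the trajectory is
#'   still wandering, not whether the linear tail has fully decayed.
#' @param seed Integer seed.
#' @return A one-row tibble with columns `n`, `n_samples`, `unsettled_fraction`,
#'   and `mean_settle_time` (settled runs only; `NA` if none settled).
#' @export
settling_fraction <- function(params, weights, n_samples = 100, cutoff = 500,
                              tol = 1e-3, seed = 1,
                              cfg = integration_config()) {
  w <- as_weight_matrix(weights)
  n <- nrow(w)
  R <- withr::with_seed(seed, matrix(runif(n_samples * n), n_samples, n))
  S <- matrix(steady_synapse(as.numeric(R), params$a, params$b,
                             params$depression), n_samples, n)
  D <- matrix(steady_depression(as.numeric(R), params$a, params$depression),
              n_samples, n)
  cfg_loose <- integration_config(
    rel_tol = cfg$rel_tol, abs_tol = cfg$abs_tol, settle_tol = tol,
    max_settle_time = cutoff, match_tol = cfg$match_tol,
    binarize_threshold = cfg$binarize_threshold
  )
  out <- settle_batch(R, S, D, params, w, cfg_loose, max_time = cutoff,
                      chunk = 100)
  tibble(
    n = n, n_samples = n_samples,
    unsettled_fraction = mean(!out$settled),
    mean_settle_time = if (any(out$settled)) mean(out$time[out$settled])
                       else NA_real_
  )
}
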