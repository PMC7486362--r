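#' Square-pulse stimuli and pulse trains
#'
#' `square_pulse()` describes one rectangular current pulse
#' \eqn{I(t) = I_{app} [H(t - t_0) - H(t - t_0 - \tau_{dur})]} delivered to a
#' subset of units; `pulse_train()` repeats it `n_pulses` times with a fixed
#' offset-to-next-onset interval `tau_isi`.  Pulse windows are half-open
#' `[onset, offset)`, so a query exactly at the offset returns zero.
#'
#' Amplitudes may be fixed or redrawn per pulse (and per targeted unit) from
#' an exponential distribution with the configured mean, the randomized
#' protocol used in network-size scaling experiments.
#'
#' @param t0 Onset time (dimensionless, time in units of the rate time
#'   constant).
#' @param tau_dur Pulse duration (>= 0).
#' @param amplitude Scalar applied current `I_app`.
#' @param target Integer vector of targeted unit indices, or `NULL` for all
#'   units.
#' @param pulse A `square_pulse` template for the first pulse of a train.
#' @param n_pulses Number of pulses (>= 1).
#' @param tau_isi Interval from each pulse offset to the next onset (> 0).
#' @param amplitude_draw `"fixed"` or `"exponential"`; with `"exponential"`
#'   each pulse's amplitude is drawn per targeted unit from an exponential
#'   distribution whose mean is `amplitude`.
#' @param seed Integer seed for exponential draws (required for
#'   reproducibility of randomized trains).
#'
#' @return `square_pulse()` returns a `square_pulse` object; `pulse_train()`
#'   a `pulse_train` object.  Both are lists.
#'
#' @examples
#' tr <- pulse_train(square_pulse(t0 = 500, tau_dur = 20, amplitude = 0.8),
#'                   n_pulses = 3, tau_isi = 1000)
#' stim_breaks(tr)
#' @export
square_pulse <- function(t0 = 500, tau_dur = 20, amplitude = 1,
                         target = NULL) {
  if (tau_dur < 0) abort("`tau_dur` must be non-negative.")
  if (!is.numeric(amplitude) || any(!is.finite(amplitude))) {
    abort("`amplitude` must be finite numeric.")
  }
  if (!is.null(target)) {
    target <- as.integer(target)
    if (any(target < 1)) abort("`target` indices must be positive.")
  }
  structure(
    list(t0 = t0, tau_dur = tau_dur, amplitude = amplitude, target = target),
    class = "square_pulse"
  )
}

#' @rdname square_pulse
#' @export
pulse_train <- function(pulse, n_pulses = 1, tau_isi = 1000,
                        amplitude_draw = c("fixed", "exponential"),
                        seed = NULL) {
  amplitude_draw <- match.arg(amplitude_draw)
  stopifnot(inherits(pulse, "square_pulse"))
  if (n_pulses < 1) abort("`n_pulses` must be at least 1.")
  if (tau_isi <= 0) abort("`tau_isi` must be positive.")
  structure(
    list(pulse = pulse, n_pulses = n_pulses, tau_isi = tau_isi,
         amplitude_draw = amplitude_draw, seed = seed),
    class = "pulse_train"
  )
}

as_pulse_train <- function(x) {
  if (inherits(x, "pulse_train")) x
  else if (inherits(x, "square_pulse")) pulse_train(x, n_pulses = 1)
  else abort("expected a `square_pulse` or `pulse_train`.")
}

# onset times of every pulse in a train
pulse_onsets <- function(train) {
  train <- as_pulse_train(train)
  p <- train$pulse
  p$t0 + (seq_len(train$n_pulses) - 1) * (p$tau_dur + train$tau_isi)
}

# per-pulse amplitude matrix (n_pulses x N), honoring exponential draws;
# rows are pulses, columns units (zero for untargeted units)
pulse_amplitudes <- function(train, n) {
  train <- as_pulse_train(train)
  p <- train$pulse
  target <- p$target %||% seq_len(n)
  if (any(target > n)) abort("`target` contains unit indices beyond N.")
  amps <- matrix(0, train$n_pulses, n)
  if (train$amplitude_draw == "exponential") {
    draw <- function() matrix(rexp(train$n_pulses * length(target),
                                   rate = 1 / p$amplitude),
                              train$n_pulses, length(target))
    vals <- if (is.null(train$seed)) draw() else withr::with_seed(train$seed, draw())
    amps[, target] <- vals
  } else {
    amps[, target] <- p$amplitude
  }
  amps
}

#' Applied current at a given time
#'
#' Evaluates the train's per-unit applied current at time `t`: the pulse
#' amplitude on targeted units inside any half-open pulse window
#' `[onset, onset + tau_dur)`, zero elsewhere and for untargeted units.
#'
#' @param train A [pulse_train()] (or a single [square_pulse()]).
#' @param t Time (finite scalar).
#' @param n Number of units.
#' @return Numeric vector of length `n`.
#' @examples
#' tr <- pulse_train(square_pulse(500, 60, 0.8), n_pulses = 2, tau_isi = 1000)
#' stim_current(tr, 510, n = 3)
#' @export
stim_current <- function(train, t, n) {
  if (!is.finite(t)) abort("`t` must be finite.")
  train <- as_pulse_train(train)
  onsets <- pulse_onsets(train)
  k <- which(t >= onsets & t < onsets + train$pulse$tau_dur)
  if (length(k) == 0) return(numeric(n))
  pulse_amplitudes(train, n)[k[1], ]
}

#' Stimulus discontinuity times
#'
#' Sorted onset and offset times of every pulse in the train.  Integration is
#' split at these times so that the solver never steps across a current
#' discontinuity.  A zero-duration pulse contributes nothing.
#'
#' @inheritParams stim_current
#' @return Increasing numeric vector (possibly empty).
#' @export
stim_breaks <- function(train) {
  train <- as_pulse_train(train)
  if (train$pulse$tau_dur == 0) return(numeric(0))
  onsets <- pulse_onsets(train)
  sort(c(onsets, onsets + train$pulse$tau_dur))
}

#' @exportS3Method generics::tidy
tidy.pulse_train <- function(x, ...) {
  onsets <- pulse_onsets(x)
  tibble(
    pulse = seq_len(x$n_pulses),
    onset = onsets,
    offset = onsets + x$pulse$tau_dur,
    amplitude = if (x$amplitude_draw == "fixed") x$pulse$amplitude else NA_real_
  )
}
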