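#' Logistic rate transfer function and its inverse
#'
#' `transfer()` maps net input current to a normalized firing rate through the
#' logistic sigmoid \eqn{f(x) = (1 + e^{-x})^{-1}}; `inverse_transfer()` is the
#' logit \eqn{g(r) = \ln[r / (1 - r)]}, defined for rates strictly inside
#' (0, 1).  Both are vectorized.
#'
#' @param x Numeric vector of net input currents (dimensionless).
#' @param r Numeric vector of normalized rates, each in the open interval (0, 1).
#'
#' @return Numeric vector: rates in (0, 1) for `transfer()`, currents for
#'   `inverse_transfer()`.
#'
#' @examples
#' transfer(0)                 # 0.5
#' inverse_transfer(0.5)       # 0
#' transfer(inverse_transfer(0.9))
#' @export
transfer <- function(x) {
  stats::plogis(x)
}

#' @rdname transfer
#' @export
inverse_transfer <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 1)) {
    abort("`r` must lie strictly inside (0, 1) for inverse_transfer().")
  }
  stats::qlogis(r)
}

#' Steady-state synaptic activation and depression
#'
#' At a constant rate \eqn{r}, the synaptic activation and depression variables
#' relax to \eqn{s(r) = br / (1 + (a + b) r)} and \eqn{d(r) = 1 / (1 + a r)}.
#' With depression disabled (`a = 0`, `d = 1`) the activation reduces to
#' \eqn{br / (1 + br)}.
#'
#' @param r Numeric vector of normalized rates in \[0, 1\].
#' @param a Depression strength (dimensionless, \eqn{\ge 0}).
#' @param b Synaptic amplitude (dimensionless, \eqn{> 0}).
#' @param depression Logical; if `FALSE`, `a` is treated as 0.
#'
#' @return Numeric vector of steady values in \[0, 1\].
#'
#' @examples
#' steady_synapse(1, a = 6.25, b = 1.25)   # 1.25 / 8.5
#' steady_depression(1, a = 6.25)          # 1 / 7.25
#' @export
steady_synapse <- function(r, a, b, depression = TRUE) {
  if (any(r < 0 | r > 1)) abort("`r` must lie in [0, 1].")
  if (!depression) a <- 0
  b * r / (1 + (a + b) * r)
}

#' @rdname steady_synapse
#' @export
steady_depression <- function(r, a, depression = TRUE) {
  if (any(r < 0 | r > 1)) abort("`r` must lie in [0, 1].")
  if (any(a < 0)) abort("`a` must be non-negative.")
  if (!depression) a <- 0
  1 / (1 + a * r)
}

# derivative of steady_synapse wrt r, used by the Newton solver
steady_synapse_prime <- function(r, a, b) {
  b / (1 + (a + b) * r)^2
}
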