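#' Dimensionless model parameters
#'
#' Bundles the parameters of the dimensionless rate model with short-term
#' synaptic depression.  Time is measured in units of the rate time constant,
#' rates are normalized to \[0, 1\], and the two slow timescales enter through
#' `alpha` (rate/synapse) and `beta` (rate/depression).
#'
#' The defaults are the standard parameter set used throughout the package:
#' `a = 6.25`, `b = 1.25`, `alpha = 0.2`, `beta = 0.04`, `theta = 5`,
#' corresponding to physical constants `tau_r = 10` ms, `tau_s = 50` ms,
#' `tau_d = 250` ms, `p0 = 0.5`, `r_max = 50` Hz, `rho = 1`.  With the
#' standard self-coupling `w_self = 40` each isolated population is bistable.
#'
#' @param a Depression strength (dimensionless, \eqn{\ge 0}).  Forced to 0
#'   when `depression = FALSE`; conversely `a = 0` implies depression is
#'   disabled.
#' @param b Synaptic amplitude (dimensionless, \eqn{> 0}).
#' @param alpha Ratio of the rate to the synaptic time constant
#'   (\eqn{\tau_r/\tau_s > 0}).
#' @param beta Ratio of the rate to the depression time constant
#'   (\eqn{\tau_r/\tau_d > 0}).
#' @param theta Activation threshold; a scalar (shared by all units) or a
#'   vector with one entry per unit.
#' @param depression Logical flag; `FALSE` models the no-depression control
#'   in which the depression variable is pinned at 1.
#'
#' @return An object of class `dim_params`: a list with elements `a`, `b`,
#'   `alpha`, `beta`, `theta`, `depression`.
#'
#' @examples
#' p <- dim_params()
#' p$a
#' dim_params(depression = FALSE)$a   # 0
#' @seealso [physical_params()], [nondimensionalize()]
#' @export
dim_params <- function(a = 6.25, b = 1.25, alpha = 0.2, beta = 0.04,
                       theta = 5, depression = TRUE) {
  if (!depression) a <- 0
  if (a == 0) depression <- FALSE
  if (a < 0) abort("`a` must be non-negative.")
  if (b <= 0) abort("`b` must be positive.")
  if (alpha <= 0 || beta <= 0) abort("`alpha` and `beta` must be positive.")
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    abort("`theta` must be finite numeric.")
  }
  structure(
    list(a = a, b = b, alpha = alpha, beta = beta, theta = theta,
         depression = depression),
    class = "dim_params"
  )
}

#' @export
print.dim_params <- function(x, ...) {
  cat("<dim_params>\n")
  cat(sprintf("  a = %g, b = %g, alpha = %g, beta = %g\n",
              x$a, x$b, x$alpha, x$beta))
  cat(sprintf("  theta = %s\n", paste(format(x$theta), collapse = ", ")))
  cat(sprintf("  depression: %s\n", if (x$depression) "enabled" else "disabled"))
  if (x$depression && !(x$a > x$b && x$beta < x$alpha)) {
    cat("  note: outside the slow-depression regime (a > b, beta < alpha)\n")
  }
  invisible(x)
}

#' Check the slow-depression regime
#'
#' The separation-of-timescales analysis assumes depression is both strong and
#' slow relative to synaptic activation: `a > b` and `beta < alpha`.
#'
#' @param params A [dim_params()] object.
#' @return Logical scalar.
#' @export
is_slow_depression <- function(params) {
  stopifnot(inherits(params, "dim_params"))
  isTRUE(params$a > params$b && params$beta < params$alpha)
}

#' Physical (dimensional) model parameters
#'
#' The dimensional form of the model, from which the dimensionless bundle is
#' obtained by [nondimensionalize()].  Times are in milliseconds and rates in
#' Hz (so `r_max * tau_d` is computed with `tau_d` in seconds internally).
#'
#' @param tau_r,tau_s,tau_d Time constants (ms) of the rate, synaptic
#'   activation, and depression variables; all positive.
#' @param p0 Fraction of docked vesicles released per spike, in (0, 1\].
#' @param rho Fraction of receptors bound at maximal release, in (0, 1\].
#' @param r_max Maximum firing rate (Hz), positive.
#' @param Theta Input threshold for half-maximum rate (current units); scalar
#'   or per-unit vector.
#' @param Delta Inverse slope of the input-output curve (current units);
#'   scalar or per-unit vector, positive.
#' @param W Coupling matrix in current units (N x N), or a scalar for a single
#'   population.
#'
#' @return An object of class `physical_params` (a named list).
#' @examples
#' ph <- physical_params()
#' nondimensionalize(ph)$params$a   # 6.25
#' @export
physical_params <- function(tau_r = 10, tau_s = 50, tau_d = 250,
                            p0 = 0.5, rho = 1, r_max = 50,
                            Theta = 5, Delta = 1, W = 40) {
  if (any(c(tau_r, tau_s, tau_d) <= 0)) {
    abort("time constants `tau_r`, `tau_s`, `tau_d` must be positive.")
  }
  if (p0 <= 0 || p0 > 1 || rho <= 0 || rho > 1) {
    abort("`p0` and `rho` must lie in (0, 1].")
  }
  if (r_max <= 0) abort("`r_max` must be positive.")
  if (any(Delta <= 0)) abort("`Delta` must be positive.")
  W <- if (is.matrix(W)) W else matrix(W, 1, 1)
  if (nrow(W) != ncol(W) || any(!is.finite(W))) {
    abort("`W` must be a square matrix of finite couplings.")
  }
  structure(
    list(tau_r = tau_r, tau_s = tau_s, tau_d = tau_d, p0 = p0, rho = rho,
         r_max = r_max, Theta = Theta, Delta = Delta, W = W),
    class = "physical_params"
  )
}

#' Nondimensionalize physical parameters
#'
#' Rescales time by `tau_r`, normalizes rates by `r_max`, and divides inputs,
#' thresholds, and couplings by `Delta`.  The resulting depression strength
#' and synaptic amplitude are `a = p0 * r_max * tau_d` and
#' `b = rho * p0 * r_max * tau_s` (with the time constants converted to
#' seconds, since `r_max` is in Hz).
#'
#' @param phys A [physical_params()] object.
#' @return A list with elements `params` (a [dim_params()] bundle) and
#'   `weights` (the dimensionless coupling matrix).
#' @examples
#' nd <- nondimensionalize(physical_params(tau_d = 250, p0 = 0.5, r_max = 50))
#' nd$params$a     # 6.25
#' nd$params$beta  # 0.04
#' @export
nondimensionalize <- function(phys) {
  stopifnot(inherits(phys, "physical_params"))
  a <- phys$p0 * phys$r_max * phys$tau_d / 1000
  b <- phys$rho * phys$p0 * phys$r_max * phys$tau_s / 1000
  params <- dim_params(
    a = a, b = b,
    alpha = phys$tau_r / phys$tau_s,
    beta = phys$tau_r / phys$tau_d,
    theta = phys$Theta / phys$Delta,
    depression = a > 0
  )
  list(params = params, weights = phys$W / phys$Delta)
}

# expand theta (scalar or vector) to length N
expand_theta <- function(params, n) {
  th <- params$theta
  if (length(th) == 1) rep(th, n)
  else if (length(th) == n) th
  else abort(sprintf("`theta` has length %d but the network has %d units.",
                     length(th), n))
}
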