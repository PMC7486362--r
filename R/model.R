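#' Network state constructors
#'
#' A network state holds, for each of N units, the normalized firing rate `r`,
#' the synaptic activation `s`, and the depression variable `d`, all in
#' \[0, 1\].  `network_state()` builds one from explicit vectors;
#' `steady_state()` lifts a rate vector to the state in which `s` and `d` sit
#' at their conditional steady values `s(r)`, `d(r)` (the convention used for
#' basin grids and fixed points).  When depression is disabled `d` is pinned
#' at 1.
#'
#' @param r,s,d Numeric vectors of equal length with entries in \[0, 1\].
#' @param params A [dim_params()] bundle (used by `steady_state()`).
#' @return A tibble with columns `unit`, `r`, `s`, `d`.
#' @examples
#' steady_state(c(0.02, 0.6), dim_params())
#' @export
network_state <- function(r, s, d) {
  n <- length(r)
  if (length(s) != n || length(d) != n) {
    abort("`r`, `s`, `d` must have equal lengths.")
  }
  if (any(c(r, s, d) < -1e-9) || any(c(r, s, d) > 1 + 1e-9)) {
    abort("state components must lie in [0, 1].")
  }
  tibble(unit = seq_len(n), r = as.numeric(r), s = as.numeric(s),
         d = as.numeric(d))
}

#' @rdname network_state
#' @export
steady_state <- function(r, params) {
  stopifnot(inherits(params, "dim_params"))
  network_state(
    r,
    steady_synapse(r, params$a, params$b, params$depression),
    steady_depression(r, params$a, params$depression)
  )
}

# coerce a state tibble (or a list with r/s/d) to plain vectors
state_vectors <- function(state) {
  if (is.data.frame(state)) {
    list(r = state$r, s = state$s, d = state$d)
  } else {
    state[c("r", "s", "d")]
  }
}

# fast internal right-hand side on plain vectors; returns list(dr, ds, dd)
rhs_core <- function(r, s, d, params, w, input) {
  u <- drop(w %*% s) - expand_theta(params, length(r)) + input
  dr <- -r + transfer(u)
  if (params$depression) {
    ds <- params$alpha * (-s + params$b * r * d * (1 - s))
    dd <- params$beta * (1 - d - params$a * r * d)
  } else {
    ds <- params$alpha * (-s + params$b * r * (1 - s))
    dd <- numeric(length(r))
  }
  list(dr = dr, ds = ds, dd = dd)
}

#' Model right-hand side
#'
#' Time derivatives of the dimensionless model at a given state: the rate
#' relaxes toward the logistic transfer of its net input
#' \eqn{\sum_j w_{ij} s_j - \theta_i + I_i}, the synaptic activation follows
#' \eqn{\dot s_i = \alpha(-s_i + b r_i d_i (1 - s_i))}, and depression follows
#' \eqn{\dot d_i = \beta(1 - d_i - a r_i d_i)}.  With depression disabled,
#' `d` is treated as 1 and its derivative is 0.
#'
#' @param state A state tibble from [network_state()] or [steady_state()].
#' @param params A [dim_params()] bundle.
#' @param weights N x N coupling matrix (or scalar for N = 1).
#' @param input Applied current: scalar or per-unit vector (default 0).
#' @return A tibble with columns `unit`, `dr`, `ds`, `dd`.
#' @examples
#' p <- dim_params()
#' network_rhs(steady_state(0.01, p), p, weights = 40)
#' @export
network_rhs <- function(state, params, weights, input = 0) {
  sv <- state_vectors(state)
  n <- length(sv$r)
  w <- as_weight_matrix(weights, n)
  input <- expand_input(input, n)
  dv <- rhs_core(sv$r, sv$s, sv$d, params, w, input)
  tibble(unit = seq_len(n), dr = dv$dr, ds = dv$ds, dd = dv$dd)
}

as_weight_matrix <- function(weights, n = NULL) {
  w <- if (is.matrix(weights)) weights else {
    if (length(weights) != 1) abort("`weights` must be a square matrix or scalar.")
    matrix(weights, 1, 1)
  }
  if (nrow(w) != ncol(w)) abort("`weights` must be square.")
  if (any(!is.finite(w))) abort("`weights` must be finite.")
  if (!is.null(n) && nrow(w) != n) {
    abort(sprintf("weight matrix is %d x %d but the state has %d units.",
                  nrow(w), ncol(w), n))
  }
  w
}

expand_input <- function(input, n) {
  if (length(input) == 1) rep(input, n)
  else if (length(input) == n) as.numeric(input)
  else abort(sprintf("`input` has length %d but the network has %d units.",
                     length(input), n))
}

#' Analytic Jacobian of the right-hand side at an arbitrary state
#'
#' Exact derivative matrix of the model equations with respect to the full
#' state, valid anywhere in state space (not only at fixed points).  With
#' depression enabled it is 3N x 3N with variables ordered
#' (r_1..r_N, s_1..s_N, d_1..d_N); without depression the depression variable
#' is pinned and the Jacobian is the 2N x 2N matrix over (r, s).
#'
#' @inheritParams network_rhs
#' @return A square numeric matrix.
#' @seealso [fp_jacobian()] for the closed block form valid at fixed points.
#' @export
rhs_jacobian <- function(state, params, weights, input = 0) {
  sv <- state_vectors(state)
  n <- length(sv$r)
  w <- as_weight_matrix(weights, n)
  input <- expand_input(input, n)
  u <- drop(w %*% sv$s) - expand_theta(params, n) + input
  fp <- transfer(u) * (1 - transfer(u))   # f'(u)
  a <- params$a; b <- params$b; al <- params$alpha; be <- params$beta
  r <- sv$r; s <- sv$s
  d <- if (params$depression) sv$d else rep(1, n)
  if (params$depression) {
    J <- matrix(0, 3 * n, 3 * n)
    ir <- seq_len(n); is <- n + ir; id <- 2 * n + ir
    J[ir, ir] <- diag(-1, n)
    J[ir, is] <- fp * w            # row-scales w by f'(u_i)
    J[cbind(is, ir)] <- al * b * d * (1 - s)
    J[cbind(is, is)] <- -al * (1 + b * r * d)
    J[cbind(is, id)] <- al * b * r * (1 - s)
    J[cbind(id, ir)] <- -be * a * d
    J[cbind(id, id)] <- -be * (1 + a * r)
  } else {
    J <- matrix(0, 2 * n, 2 * n)
    ir <- seq_len(n); is <- n + ir
    J[ir, ir] <- diag(-1, n)
    J[ir, is] <- fp * w
    J[cbind(is, ir)] <- al * b * (1 - s)
    J[cbind(is, is)] <- -al * (1 + b * r)
  }
  J
}

#' Blocked Jacobian at a fixed point
#'
#' The closed-form linearization at a root of the fixed-point equation, as a
#' function of the rate vector alone: the steady values `s(r)`, `d(r)` and the
#' fixed-point identity \eqn{f'(u_i) = r_i(1 - r_i)} are substituted, giving
#' per-unit 3 x 3 diagonal blocks coupled across units only through the
#' rate-to-synapse entry \eqn{w_{ij} r_i (1 - r_i)}.  Without depression the
#' corresponding 2N x 2N form is returned.
#'
#' @param r Rate vector at the fixed point.
#' @inheritParams network_rhs
#' @return A square numeric matrix (3N x 3N, or 2N x 2N without depression).
#' @export
fp_jacobian <- function(r, params, weights) {
  n <- length(r)
  w <- as_weight_matrix(weights, n)
  a <- params$a; b <- params$b; al <- params$alpha; be <- params$beta
  if (params$depression) {
    J <- matrix(0, 3 * n, 3 * n)
    ir <- seq_len(n); is <- n + ir; id <- 2 * n + ir
    J[ir, ir] <- diag(-1, n)
    J[ir, is] <- (r * (1 - r)) * w
    J[cbind(is, ir)] <- al * b / (1 + (a + b) * r)
    J[cbind(is, is)] <- -al * (1 + (a + b) * r) / (1 + a * r)
    J[cbind(is, id)] <- al * b * r * (1 + a * r) / (1 + (a + b) * r)
    J[cbind(id, ir)] <- -be * a / (1 + a * r)
    J[cbind(id, id)] <- -be * (1 + a * r)
  } else {
    J <- matrix(0, 2 * n, 2 * n)
    ir <- seq_len(n); is <- n + ir
    J[ir, ir] <- diag(-1, n)
    J[ir, is] <- (r * (1 - r)) * w
    J[cbind(is, ir)] <- al * b / (1 + b * r)
    J[cbind(is, is)] <- -al * (1 + b * r)
  }
  J
}
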