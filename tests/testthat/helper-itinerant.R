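# Shared fixtures and independent oracles for the test suite.

std_params <- function() dim_params()                      # a=6.25, b=1.25, ...
nodep_params <- function() dim_params(depression = FALSE)

sym_pair <- function(w_cross, w_self = 40) {
  matrix(c(w_self, w_cross, w_cross, w_self), 2)
}

# Independent 1-D oracle for the single-unit fixed-point equation
# g(r) - w s(r) + theta = I: dense bracketing grid + stats::uniroot,
# a completely separate path from the package's Newton solver.
oracle_unit_roots <- function(w = 40, theta = 5, input = 0,
                              a = 6.25, b = 1.25) {
  fun <- function(r) {
    log(r / (1 - r)) - w * b * r / (1 + (a + b) * r) + theta - input
  }
  # bracket in logit space to resolve roots exponentially close to 0 or 1
  xs <- seq(-60, 60, length.out = 40001)
  rs <- stats::plogis(xs)
  vals <- fun(rs)
  idx <- which(diff(sign(vals)) != 0)
  sort(vapply(idx, function(i) {
    stats::uniroot(fun, c(rs[i], rs[i + 1]), tol = 1e-14)$root
  }, numeric(1)))
}

# central finite-difference Jacobian of the model rhs at a state
fd_jacobian <- function(state, params, weights, input = 0, h = 1e-6) {
  sv <- itinerant:::state_vectors(state)
  n <- length(sv$r)
  y0 <- c(sv$r, sv$s, sv$d)
  n_var <- if (params$depression) 3 * n else 2 * n
  rhs_at <- function(y) {
    st <- network_state(y[1:n], y[n + 1:n],
                        if (params$depression) y[2 * n + 1:n] else rep(1, n))
    dv <- network_rhs(st, params, weights, input)
    if (params$depression) c(dv$dr, dv$ds, dv$dd) else c(dv$dr, dv$ds)
  }
  J <- matrix(0, n_var, n_var)
  for (j in seq_len(n_var)) {
    yp <- y0; ym <- y0
    yp[j] <- yp[j] + h; ym[j] <- ym[j] - h
    J[, j] <- (rhs_at(yp) - rhs_at(ym)) / (2 * h)
  }
  J
}

# number of saddles of degree k among N uncoupled bistable units
expected_saddle_count <- function(N, k) choose(N, k) * 2^(N - k)

# diagonal block matrix of n copies of the standard single-unit weight
uncoupled_weights <- function(n, w_self = 40) {
  diag(w_self, n)
}

expand_theta_test <- function(params, n) itinerant:::expand_theta(params, n)
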