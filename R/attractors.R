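#' Classify a Jacobian spectrum
#'
#' A hyperbolic fixed point is a saddle of degree k when exactly k
#' eigenvalues of its Jacobian have positive real part; it is stable when
#' k = 0.  Imaginary parts indicate spiral approach but do not affect
#' stability, so only real parts are compared.  Eigenvalues whose real part
#' lies within `tol` of zero are flagged marginal and excluded from the
#' stable count.
#'
#' @param eigenvalues Complex (or numeric) vector: the full spectrum.
#' @param tol Stability tolerance on the real part.
#' @return A list with elements `degree`, `stable`, `marginal`.
#' @examples
#' classify_spectrum(c(-1, -0.2, -0.04))
#' classify_spectrum(c(0.16, -1.4, -0.03))
#' @export
classify_spectrum <- function(eigenvalues, tol = 1e-8) {
  re <- Re(eigenvalues)
  marginal <- any(abs(re) <= tol)
  degree <- sum(re > tol)
  list(degree = degree, stable = degree == 0 && !marginal, marginal = marginal)
}

# roots of the isolated single-unit fixed-point equation for unit i, in logit
# coordinates: x + theta_i - I_i - w_ii * s(f(x)) = 0.  Bracketing grid plus
# uniroot; the ON root without depression can sit at x ~ w_ii*b/(1+b), hence
# the wide grid.
single_unit_roots_x <- function(w_self, theta_i, input_i, params) {
  a_eff <- if (params$depression) params$a else 0
  fun <- function(x) {
    x + theta_i - input_i -
      w_self * steady_synapse(transfer(x), a_eff, params$b)
  }
  hi <- max(abs(w_self) * params$b / (1 + a_eff + params$b), 1) +
    abs(theta_i) + abs(input_i) + 5
  xs <- seq(-hi, hi, length.out = 4001)
  vals <- fun(xs)
  idx <- which(diff(sign(vals)) != 0)
  vapply(idx, function(i) {
    stats::uniroot(fun, c(xs[i], xs[i + 1]), tol = 1e-14)$root
  }, numeric(1))
}

# damped Newton in logit coordinates for the N-unit fixed-point system
# F(x) = x + theta - I - w %*% s(f(x)).  Returns r vector or NULL.
newton_fixed_point <- function(x0, params, w, theta, input,
                               tol = 1e-11, max_iter = 60) {
  a_eff <- if (params$depression) params$a else 0
  b <- params$b
  n <- length(x0)
  x <- x0
  Fx <- function(x) {
    r <- transfer(x)
    x + theta - input - drop(w %*% steady_synapse(r, a_eff, b))
  }
  fx <- Fx(x)
  for (iter in seq_len(max_iter)) {
    if (max(abs(fx)) < tol) {
      return(transfer(x))
    }
    r <- transfer(x)
    J <- diag(n) - w * rep(steady_synapse_prime(r, a_eff, b) * r * (1 - r),
                           each = n)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      if (max(abs(x_new)) > 200) x_new <- pmin(pmax(x_new, -200), 200)
      fx_new <- Fx(x_new)
      if (max(abs(fx_new)) < max(abs(fx)) || lambda < 1 / 256) break
      lambda <- lambda / 2
    }
    x <- x_new; fx <- fx_new
  }
  if (max(abs(fx)) < tol) transfer(x) else NULL
}

#' Enumerate and classify the fixed points of a network
#'
#' Solves the fixed-point condition
#' \eqn{g(r_i) - \sum_j w_{ij} s(r_j) = I_i - \theta_i} by damped Newton
#' iteration in logit coordinates from many starting points, then classifies
#' every distinct root through the eigenvalues of its blocked Jacobian.
#'
#' Starting points are all combinations of each unit's isolated single-unit
#' roots (at most 3 per bistable unit, hence 3^N seeds), which enumerates the
#' complete catalog in the weak-cross-coupling regime.  When 3^N exceeds
#' `max_seeds` a random subset of combinations, jittered in logit space, is
#' used instead (`seed` controls the draw), so catalogs for larger networks
#' are stochastic samples; [estimate_frequencies()] and [run_train()] append
#' any attractor discovered later by settling.
#'
#' @inheritParams simulate_network
#' @param input Constant applied current (scalar or per-unit).
#' @param max_seeds Cap on the number of Newton starts.
#' @param seed Seed for the random starts used when 3^N > `max_seeds`.
#' @param stability_tol Tolerance on eigenvalue real parts
#'   ([classify_spectrum()]).
#' @param dedup_tol Max-norm tolerance on `r` below which two roots are the
#'   same fixed point.
#' @return An `attractor_catalog`: a tibble with one row per fixed point and
#'   columns `index`, `pattern`, `stable`, `degree`, `marginal`, `residual`,
#'   `frequency` (`NA` until estimated), and list-columns `r`, `s`, `d`,
#'   `eigenvalues`.  Stable points come first, then saddles by degree.
#'   Attributes `params`, `weights`, `input`, and `cfg` carry the defining
#'   context.
#' @examples
#' cat1 <- find_fixed_points(dim_params(), weights = 40)
#' cat1$pattern          # "0" saddle "1": 2 stable, 1 saddle
#' @export
find_fixed_points <- function(params, weights, input = 0,
                              max_seeds = 6561, seed = 1,
                              stability_tol = 1e-8, dedup_tol = 1e-6,
                              cfg = integration_config()) {
  w <- as_weight_matrix(weights)
  n <- nrow(w)
  theta <- expand_theta(params, n)
  input <- expand_input(input, n)
  unit_roots <- lapply(seq_len(n), function(i) {
    xr <- single_unit_roots_x(w[i, i], theta[i], input[i], params)
    if (length(xr) == 0) 0 else xr
  })
  counts <- vapply(unit_roots, length, integer(1))
  n_combo <- prod(counts)
  seeds <- if (n_combo <= max_seeds) {
    as.matrix(do.call(expand.grid, unit_roots))
  } else {
    withr::with_seed(seed, {
      picks <- vapply(seq_len(max_seeds), function(k) {
        vapply(unit_roots, function(xr) xr[sample.int(length(xr), 1)],
               numeric(1))
      }, numeric(n))
      t(picks) + matrix(rnorm(max_seeds * n, sd = 0.5), max_seeds, n)
    })
  }
  roots <- list()
  for (k in seq_len(nrow(seeds))) {
    r <- newton_fixed_point(as.numeric(seeds[k, ]), params, w, theta, input)
    if (is.null(r)) next
    dup <- any(vapply(roots, function(r0) max(abs(r0 - r)) < dedup_tol,
                      logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  build_catalog(roots, params, w, input, stability_tol, cfg)
}

# residual of the fixed-point equation at r (Inf if r touches {0,1})
fp_residual <- function(r, params, w, theta, input) {
  a_eff <- if (params$depression) params$a else 0
  g <- stats::qlogis(r)
  if (any(!is.finite(g))) return(Inf)
  max(abs(g - drop(w %*% steady_synapse(r, a_eff, params$b)) - input + theta))
}

build_catalog <- function(roots, params, w, input, stability_tol, cfg) {
  n <- nrow(w)
  theta <- expand_theta(params, n)
  rows <- purrr::map(roots, function(r_star) {
    eig <- eigen(fp_jacobian(r_star, params, w), only.values = TRUE)$values
    cls <- classify_spectrum(eig, stability_tol)
    s_star <- steady_synapse(r_star, params$a, params$b, params$depression)
    d_star <- steady_depression(r_star, params$a, params$depression)
    tibble(
      pattern = binarize(r_star, cfg),
      stable = cls$stable, degree = cls$degree, marginal = cls$marginal,
      residual = fp_residual(r_star, params, w, theta, input),
      frequency = NA_real_,
      r = list(r_star), s = list(s_star), d = list(d_star),
      eigenvalues = list(eig)
    )
  })
  cat_tbl <- if (length(rows)) dplyr::bind_rows(rows) else tibble(
    pattern = character(), stable = logical(), degree = integer(),
    marginal = logical(), residual = numeric(), frequency = numeric(),
    r = list(), s = list(), d = list(), eigenvalues = list()
  )
  cat_tbl <- dplyr::arrange(cat_tbl, .data$degree, .data$pattern)
  cat_tbl <- dplyr::mutate(cat_tbl, index = dplyr::row_number(),
                           .before = 1)
  structure(cat_tbl,
            class = c("attractor_catalog", class(cat_tbl)),
            params = params, weights = w, input = input, cfg = cfg)
}

catalog_context <- function(catalog) {
  list(params = attr(catalog, "params"), weights = attr(catalog, "weights"),
       input = attr(catalog, "input"),
       cfg = attr(catalog, "cfg") %||% integration_config())
}

# index of the catalog entry whose r is within match_tol of `r`, else NA
match_catalog <- function(catalog, r, match_tol) {
  if (nrow(catalog) == 0) return(NA_integer_)
  dists <- vapply(catalog$r, function(r0) max(abs(r0 - r)), numeric(1))
  i <- which.min(dists)
  if (dists[i] <= match_tol) catalog$index[i] else NA_integer_
}

# polish a settled rate vector into an exact root and append it as a new row
# with a fresh index (existing rows and indices are untouched, so records
# that reference them stay valid); returns the extended catalog and index
extend_catalog <- function(catalog, r_settled, warn_context = "settled state",
                           quiet = FALSE) {
  ctx <- catalog_context(catalog)
  n <- length(r_settled)
  theta <- expand_theta(ctx$params, n)
  r_clip <- pmin(pmax(r_settled, 1e-12), 1 - 1e-12)
  r <- newton_fixed_point(stats::qlogis(r_clip), ctx$params, ctx$weights,
                          theta, ctx$input)
  # keep the raw settled vector if Newton failed or wandered to a distant root
  cfg <- ctx$cfg
  if (is.null(r) || max(abs(r - r_settled)) > 10 * cfg$match_tol) {
    r <- r_settled
  }
  msg <- sprintf("catalog extended: %s at pattern %s was not in the catalog.",
                 warn_context, binarize(r))
  if (quiet) inform(msg) else warn(msg)
  params <- ctx$params
  eig <- eigen(fp_jacobian(r, params, ctx$weights), only.values = TRUE)$values
  cls <- classify_spectrum(eig)
  new_index <- if (nrow(catalog)) max(catalog$index) + 1L else 1L
  s_star <- steady_synapse(r, params$a, params$b, params$depression)
  d_star <- steady_depression(r, params$a, params$depression)
  new_row <- tibble(
    index = new_index,
    pattern = binarize(r, ctx$cfg),
    stable = cls$stable, degree = cls$degree, marginal = cls$marginal,
    residual = fp_residual(r, params, ctx$weights, theta, ctx$input),
    frequency = NA_real_,
    r = list(r), s = list(s_star), d = list(d_star),
    eigenvalues = list(eig)
  )
  new_cat <- dplyr::bind_rows(as_tibble(catalog), new_row)
  new_cat <- structure(new_cat,
                       class = c("attractor_catalog", class(new_cat)),
                       params = params, weights = ctx$weights,
                       input = ctx$input, cfg = ctx$cfg)
  list(catalog = new_cat, index = new_index)
}

#' @export
print.attractor_catalog <- function(x, ...) {
  cat(sprintf("<attractor_catalog> %d fixed points (%d stable) in %d units\n",
              nrow(x), sum(x$stable), length(x$r[[1]] %||% numeric(0))))
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.attractor_catalog <- function(x, ...) {
  dplyr::select(
    tidyr::unnest_longer(as_tibble(x), col = "r", indices_to = "unit"),
    "index", "pattern", "unit", "r", "stable", "degree", "frequency"
  )
}

#' @exportS3Method generics::glance
glance.attractor_catalog <- function(x, ...) {
  tibble(
    n_fixed_points = nrow(x),
    n_stable = sum(x$stable),
    n_saddle = sum(!x$stable),
    max_degree = if (nrow(x)) max(x$degree) else NA_integer_,
    n_marginal = sum(x$marginal),
    unsettled_fraction = attr(x, "unsettled_fraction") %||% NA_real_
  )
}

#' Estimate attractor occurrence frequencies by random sampling
#'
#' Draws `n_samples` rate vectors uniformly from \[0, 1\]^N (synapse and
#' depression lifted to their conditional steady values), relaxes each to a
#' steady state, and assigns it to the nearest catalogued attractor within
#' the matching tolerance.  A settled state matching no entry is polished
#' into an exact root and appended (with a warning) rather than discarded.
#' Frequencies are convergence fractions over all samples; the unsettled
#' fraction is reported separately so frequencies sum to at most 1.
#'
#' @param catalog An [find_fixed_points()] catalog.
#' @param n_samples Number of random initial conditions.
#' @param seed Integer seed.
#' @param cfg An [integration_config()].
#' @return The catalog, reordered by decreasing frequency (stable entries
#'   first), with the `frequency` column filled and attribute
#'   `unsettled_fraction` set.
#' @examples
#' cat1 <- find_fixed_points(dim_params(), weights = 40)
#' cat1 <- estimate_frequencies(cat1, n_samples = 40, seed = 1)
#' cat1$frequency
#' @export
estimate_frequencies <- function(catalog, n_samples = 200, seed = 1,
                                 cfg = NULL) {
  ctx <- catalog_context(catalog)
  cfg <- cfg %||% ctx$cfg
  params <- ctx$params; w <- ctx$weights
  n <- nrow(w)
  R <- withr::with_seed(seed, matrix(runif(n_samples * n), n_samples, n))
  S <- matrix(steady_synapse(as.numeric(R), params$a, params$b,
                             params$depression), n_samples, n)
  D <- matrix(steady_depression(as.numeric(R), params$a, params$depression),
              n_samples, n)
  out <- settle_batch(R, S, D, params, w, cfg)
  tally <- rep(0L, nrow(catalog))
  for (i in seq_len(n_samples)) {
    if (!out$settled[i]) next
    idx <- match_catalog(catalog, out$R[i, ], cfg$match_tol)
    if (is.na(idx)) {
      ext <- extend_catalog(catalog, out$R[i, ], "sampled steady state",
                            quiet = TRUE)
      catalog <- ext$catalog
      idx <- ext$index
      tally <- c(tally, 0L)
    }
    pos <- match(idx, catalog$index)
    tally[pos] <- tally[pos] + 1L
  }
  catalog$frequency <- tally / n_samples
  ord <- order(-catalog$stable, -catalog$frequency, catalog$degree)
  catalog <- catalog[ord, ]
  catalog$index <- seq_len(nrow(catalog))
  attr(catalog, "unsettled_fraction") <- mean(!out$settled)
  catalog
}

#' Map basins of attraction of a two-unit circuit
#'
#' Lays a regular grid over the (r1, r2) rate plane, lifts each grid point to
#' the state with synapse and depression at their conditional steady values
#' (the projection convention for visualizing basins), relaxes it, and labels
#' it by the stable attractor it reaches.  Cells that fail to settle, or
#' settle to a state matching no attractor, are labeled `NA` and excluded
#' from area normalization.
#'
#' @inheritParams simulate_network
#' @param resolution Grid points per axis.
#' @param catalog Optional precomputed [find_fixed_points()] catalog.
#' @return A `basin_map`: tibble with columns `r1`, `r2`, `label` (catalog
#'   index), `pattern`; attributes `areas` (normalized area per stable
#'   attractor), `catalog`, `resolution`.
#' @examples
#' \donttest{
#' bm <- map_basins(dim_params(), weights = matrix(c(40, 0.5, 0.5, 40), 2),
#'                  resolution = 41)
#' basin_areas(bm)
#' }
#' @export
map_basins <- function(params, weights, resolution = 101,
                       cfg = integration_config(), catalog = NULL) {
  w <- as_weight_matrix(weights)
  if (nrow(w) != 2) abort("basin mapping is defined for two-unit circuits.")
  catalog <- catalog %||% find_fixed_points(params, w, cfg = cfg)
  grid_r <- seq(0, 1, length.out = resolution)
  cells <- tidyr::expand_grid(r1 = grid_r, r2 = grid_r)
  R <- as.matrix(cells)
  S <- matrix(steady_synapse(as.numeric(R), params$a, params$b,
                             params$depression), nrow(R), 2)
  D <- matrix(steady_depression(as.numeric(R), params$a, params$depression),
              nrow(R), 2)
  out <- settle_batch(R, S, D, params, w, cfg)
  label <- rep(NA_integer_, nrow(R))
  stable_cat <- catalog[catalog$stable, ]
  for (i in seq_len(nrow(R))) {
    if (!out$settled[i]) next
    label[i] <- match_catalog(stable_cat, out$R[i, ], cfg$match_tol)
  }
  pattern <- ifelse(is.na(label), NA_character_,
                    catalog$pattern[match(label, catalog$index)])
  bm <- dplyr::mutate(cells, label = label, pattern = pattern)
  areas <- dplyr::count(dplyr::filter(bm, !is.na(.data$label)),
                        .data$label, .data$pattern)
  areas <- dplyr::mutate(areas, area = .data$n / sum(.data$n))
  structure(bm,
            class = c("basin_map", class(bm)),
            areas = dplyr::select(areas, "label", "pattern", "area"),
            catalog = catalog, resolution = resolution)
}

#' Normalized basin areas
#'
#' @param bm A [map_basins()] result.
#' @return A tibble with columns `label`, `pattern`, `area` (areas sum to 1
#'   over labeled cells).
#' @export
basin_areas <- function(bm) {
  stopifnot(inherits(bm, "basin_map"))
  attr(bm, "areas")
}

#' @exportS3Method generics::glance
glance.basin_map <- function(x, ...) {
  ar <- basin_areas(x)
  tibble(
    n_basins = nrow(ar),
    resolution = attr(x, "resolution"),
    unlabeled_fraction = mean(is.na(x$label))
  )
}

# connected components (8-neighbor, so diagonal bands count as one region)
# of each basin label on the grid; used to check that basins are simple
# regions. Returns a tibble label -> n_components.
basin_components <- function(bm) {
  res <- attr(bm, "resolution")
  lab <- matrix(bm$label, nrow = res, byrow = TRUE)  # rows follow r1 of expand_grid
  comp <- matrix(0L, res, res)
  n_comp <- stats::setNames(integer(0), character(0))
  cur <- 0L
  for (i in seq_len(res)) for (j in seq_len(res)) {
    if (is.na(lab[i, j]) || comp[i, j] > 0L) next
    cur <- cur + 1L
    lbl <- as.character(lab[i, j])
    n_comp[lbl] <- if (lbl %in% names(n_comp)) n_comp[[lbl]] + 1L else 1L
    queue <- matrix(c(i, j), ncol = 2)
    comp[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (dij in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                       c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
        q <- p + dij
        if (q[1] < 1 || q[1] > res || q[2] < 1 || q[2] > res) next
        if (comp[q[1], q[2]] > 0L || is.na(lab[q[1], q[2]])) next
        if (lab[q[1], q[2]] != lbl) next
        comp[q[1], q[2]] <- cur
        queue <- rbind(queue, q)
      }
    }
  }
  tibble(label = as.integer(names(n_comp)), n_components = as.integer(n_comp))
}
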