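#' Generate a random coupling matrix
#'
#' Off-diagonal (cross-population) couplings are drawn i.i.d. from a Gaussian
#' with mean `mu` and standard deviation `sigma`; the diagonal
#' (self-coupling) is then overwritten with `w_self`, since self- and
#' cross-couplings play distinct roles (strong self-excitation makes a unit
#' bistable, weak cross-coupling deforms basins).  Under
#' `scaling = "inverse_sqrt_N"` the standard deviation is replaced by
#' \eqn{N^{-1/2}}, the scaling used when comparing networks of different
#' sizes.
#'
#' @param n Number of units (N >= 1).
#' @param w_self Diagonal self-coupling (default 40, the standard bistable
#'   setting).
#' @param mu Mean of the cross-couplings.
#' @param sigma Standard deviation of the cross-couplings (>= 0); ignored
#'   under `scaling = "inverse_sqrt_N"`.
#' @param scaling `"none"` or `"inverse_sqrt_N"`.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return An N x N numeric matrix with attribute `"seed"` recording the seed
#'   used (or `NA` if none was given).
#'
#' @examples
#' w <- random_network(5, mu = 0, sigma = 0.1, seed = 1)
#' diag(w)          # all 40
#' @export
random_network <- function(n, w_self = 40, mu = 0, sigma = 0.1,
                           scaling = c("none", "inverse_sqrt_N"),
                           seed = NULL) {
  scaling <- match.arg(scaling)
  if (n < 1) abort("`n` must be at least 1.")
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (scaling == "inverse_sqrt_N") sigma <- 1 / sqrt(n)
  draw <- function() {
    w <- matrix(rnorm(n * n, mean = mu, sd = sigma), n, n)
    diag(w) <- w_self
    w
  }
  w <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(w, "seed") <- seed %||% NA_integer_
  w
}

#' Generate an ensemble of random networks
#'
#' Draws `n_networks` coupling matrices with per-network seeds derived from
#' one ensemble seed (`seed + index`), so ensembles are reproducible and any
#' member can be regenerated in isolation.
#'
#' @inheritParams random_network
#' @param n_networks Ensemble size.
#' @param seed Integer ensemble seed.
#' @return A tibble with columns `network` (index), `seed` (per-network
#'   seed), and `w` (list-column of matrices).
#' @examples
#' ens <- network_ensemble(3, n = 5, sigma = 0.1, seed = 42)
#' ens$w[[2]]
#' @export
network_ensemble <- function(n_networks, n, w_self = 40, mu = 0, sigma = 0.1,
                             scaling = c("none", "inverse_sqrt_N"), seed = 1) {
  scaling <- match.arg(scaling)
  seeds <- seed + seq_len(n_networks)
  tibble(
    network = seq_len(n_networks),
    seed = seeds,
    w = purrr::map(seeds, function(s) {
      random_network(n, w_self = w_self, mu = mu, sigma = sigma,
                     scaling = scaling, seed = s)
    })
  )
}

#' Read and write coupling matrices as delimited text
#'
#' The format is a single header line with N followed by N rows of N
#' whitespace-separated values, written at full double precision.
#'
#' @param w An N x N coupling matrix.
#' @param path File path.
#' @return `write_weight_matrix()` returns `path` invisibly;
#'   `read_weight_matrix()` returns the matrix.
#' @export
write_weight_matrix <- function(w, path) {
  w <- as_weight_matrix(w)
  lines <- c(
    as.character(nrow(w)),
    apply(w, 1, function(row) paste(format(row, digits = 17), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 1) {
    abort(sprintf("malformed weight-matrix file '%s'.", path))
  }
  w <- do.call(rbind, lapply(lines[1 + seq_len(n)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  as_weight_matrix(w, n)
}
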