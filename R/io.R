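#' Read and write the experiment configuration document
#'
#' Experiments are declared in a flat YAML document with sections `model`,
#' `network`, `stimulus`, `integration`, and `experiment`.  The `model`
#' section is required and uses the keys `a`, `b`, `alpha`, `beta`, `theta`,
#' `w_self`, `depression_enabled`; the other sections are optional and fall
#' back to package defaults.  Numeric values round-trip at full double
#' precision.
#'
#' @param path File path of the YAML config.
#' @param config A config list (as returned by `read_model_config()`).
#' @return `read_model_config()` returns a validated list of class
#'   `itinerant_config`; `write_model_config()` returns `path` invisibly.
#' @examples
#' cfg <- default_config()
#' path <- tempfile(fileext = ".yaml")
#' write_model_config(cfg, path)
#' identical(read_model_config(path)$model$a, cfg$model$a)
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found.", path))
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
  invisible(path)
}

#' @rdname read_model_config
#' @export
default_config <- function() {
  validate_config(list(
    model = list(a = 6.25, b = 1.25, alpha = 0.2, beta = 0.04, theta = 5,
                 w_self = 40, depression_enabled = TRUE),
    network = list(n_units = 1, mu = 0, sigma = 0.1, scaling = "none", seed = 1,
                   n_networks = 1),
    stimulus = list(t0 = 500, tau_dur = 20, I_app = 1, n_pulses = 1,
                    tau_isi = 1000, target_fraction = 1,
                    amplitude_draw = "fixed"),
    integration = list(rel_tol = 1e-8, abs_tol = 1e-10, settle_tol = 1e-6,
                       max_settle_time = 2000, match_tol = 1e-3,
                       binarize_threshold = 0.5),
    experiment = list(type = "fixed-points")
  ))
}

required_model_keys <- c("a", "b", "alpha", "beta", "theta", "w_self",
                         "depression_enabled")

validate_config <- function(raw) {
  if (is.null(raw$model)) abort("config is missing the `model` section.")
  missing <- setdiff(required_model_keys, names(raw$model))
  if (length(missing)) {
    abort(sprintf("config `model` section is missing key(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  defaults <- list(
    network = list(n_units = 1, mu = 0, sigma = 0.1, scaling = "none", seed = 1,
                   n_networks = 1),
    stimulus = list(t0 = 500, tau_dur = 20, I_app = 1, n_pulses = 1,
                    tau_isi = 1000, target_fraction = 1,
                    amplitude_draw = "fixed"),
    integration = list(rel_tol = 1e-8, abs_tol = 1e-10, settle_tol = 1e-6,
                       max_settle_time = 2000, match_tol = 1e-3,
                       binarize_threshold = 0.5),
    experiment = list(type = "fixed-points")
  )
  for (sec in names(defaults)) {
    raw[[sec]] <- utils::modifyList(defaults[[sec]], raw[[sec]] %||% list())
  }
  n <- raw$network$n_units
  theta <- raw$model$theta
  if (length(theta) > 1 && length(theta) != n) {
    abort(sprintf(
      "config key `model.theta` has length %d but `network.n_units` is %d.",
      length(theta), n))
  }
  structure(raw, class = "itinerant_config")
}

config_params <- function(config) {
  m <- config$model
  dim_params(a = if (isTRUE(m$depression_enabled)) m$a else 0,
             b = m$b, alpha = m$alpha, beta = m$beta,
             theta = unlist(m$theta),
             depression = isTRUE(m$depression_enabled))
}

config_integration <- function(config) {
  i <- config$integration
  integration_config(rel_tol = i$rel_tol, abs_tol = i$abs_tol,
                     settle_tol = i$settle_tol,
                     max_settle_time = i$max_settle_time,
                     match_tol = i$match_tol,
                     binarize_threshold = i$binarize_threshold)
}

config_weights <- function(config) {
  nw <- config$network
  if (!is.null(nw$weight_file)) return(read_weight_matrix(nw$weight_file))
  if (nw$n_units == 1) {
    matrix(config$model$w_self, 1, 1)
  } else {
    random_network(nw$n_units, w_self = config$model$w_self, mu = nw$mu,
                   sigma = nw$sigma, scaling = nw$scaling, seed = nw$seed)
  }
}

#' Write a run manifest
#'
#' Records the full configuration snapshot, seeds, package version, per-stage
#' runtimes, and warning counts alongside an experiment's outputs, so any run
#' can be reproduced bit-identically by re-running from the manifest's
#' embedded config.
#'
#' @param path Output file path (YAML).
#' @param config The `itinerant_config` used.
#' @param runtimes Named numeric vector of per-stage runtimes (seconds).
#' @param warnings Character vector of warning messages raised by the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, runtimes = numeric(0),
                           warnings = character(0)) {
  manifest <- list(
    package = "itinerant",
    version = as.character(utils::packageVersion("itinerant")),
    config = unclass(config),
    runtimes = as.list(runtimes),
    n_warnings = length(warnings),
    warnings = as.list(warnings)
  )
  yaml::write_yaml(manifest, path, precision = 17)
  invisible(path)
}

# write a result table as TSV at full precision
write_result_table <- function(x, path) {
  is_listcol <- vapply(x, is.list, logical(1))
  readr::write_tsv(as_tibble(x)[!is_listcol], path)
  invisible(path)
}

#' Export an attractor catalog as a delimited table
#'
#' One row per fixed point with the binary pattern, per-unit rates, saddle
#' degree, and occurrence frequency.
#'
#' @param catalog An [find_fixed_points()] catalog.
#' @param path Optional file path; when `NULL` the table is returned only.
#' @return The flat tibble, invisibly when written.
#' @export
export_catalog <- function(catalog, path = NULL) {
  flat <- dplyr::mutate(
    dplyr::select(as_tibble(catalog), "index", "pattern", "stable", "degree",
                  "marginal", "residual", "frequency"),
    r = vapply(catalog$r, function(v) paste(format(v, digits = 17),
                                            collapse = ","), character(1))
  )
  if (!is.null(path)) {
    readr::write_tsv(flat, path)
    return(invisible(flat))
  }
  flat
}
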