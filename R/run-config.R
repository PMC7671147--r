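#' Analysis run configuration
#'
#' Bundles the tunable constants of the pipeline. Every analysis function
#' that needs more than one of them takes a `run_config`; single-purpose
#' functions take plain arguments.
#'
#' @param kinematic_viscosity kinematic viscosity of the medium, m^2 s^-1.
#'   Default 9.5e-7, seawater at 25 degrees C and 33 psu.
#' @param area_of_influence_threshold flow-speed cutoff (m s^-1) defining the
#'   hydrodynamic area of influence — the region a rheotactic predator could
#'   sense. Default 0.0005.
#' @param n_permutations permutation count for [perm_t_test()]; default 9999.
#' @param attenuation_bins number of log-spaced speed thresholds used by
#'   [attenuation_fit()]; default 15.
#' @param attenuation_noise_floor lowest speed threshold (m s^-1) considered
#'   above PIV noise in [attenuation_fit()]; default 1e-5.
#' @param vorticity_threshold_fraction fraction of peak |vorticity| delimiting
#'   a vortex region in [find_vortices()]; default 0.1.
#' @param body_length carapace length in micrometres used to normalize
#'   swimming speed and form the Reynolds number. `NULL` (default) falls back
#'   to the measured mean frontal-horn-midpoint-to-Dts distance.
#' @param power_stroke_decreasing logical; `TRUE` (default) defines the power
#'   stroke as the interval where the antenna angle to the tail vector
#'   decreases (appendage sweeping toward the tail).
#' @param speed_mode `"path"` (default): average swimming speed U is total
#'   path length over elapsed time; `"net"`: net displacement over elapsed
#'   time.
#' @param amplitude_mode `"cycle_mean"` (default): beat amplitude is the
#'   per-cycle angular range averaged across cycles; `"grand_max"`: range
#'   over the whole record.
#' @param rng_seed integer seed used by stochastic operations; default 1.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(kinematic_viscosity = 9.5e-7,
                       area_of_influence_threshold = 5e-4,
                       n_permutations = 9999,
                       attenuation_bins = 15,
                       attenuation_noise_floor = 1e-5,
                       vorticity_threshold_fraction = 0.1,
                       body_length = NULL,
                       power_stroke_decreasing = TRUE,
                       speed_mode = c("path", "net"),
                       amplitude_mode = c("cycle_mean", "grand_max"),
                       rng_seed = 1L) {
  speed_mode <- match.arg(speed_mode)
  amplitude_mode <- match.arg(amplitude_mode)
  num_pos <- c(kinematic_viscosity = kinematic_viscosity,
               area_of_influence_threshold = area_of_influence_threshold,
               attenuation_noise_floor = attenuation_noise_floor)
  bad <- names(num_pos)[!is.finite(num_pos) | num_pos <= 0]
  if (length(bad)) stopf("%s must be > 0", paste(bad, collapse = ", "))
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (attenuation_bins < 3) stopf("attenuation_bins must be >= 3")
  if (vorticity_threshold_fraction <= 0 || vorticity_threshold_fraction >= 1)
    stopf("vorticity_threshold_fraction must lie in (0, 1)")
  if (!is.null(body_length) && body_length <= 0) stopf("body_length must be > 0")
  structure(list(
    kinematic_viscosity = kinematic_viscosity,
    area_of_influence_threshold = area_of_influence_threshold,
    n_permutations = as.integer(n_permutations),
    attenuation_bins = as.integer(attenuation_bins),
    attenuation_noise_floor = attenuation_noise_floor,
    vorticity_threshold_fraction = vorticity_threshold_fraction,
    body_length = body_length,
    power_stroke_decreasing = isTRUE(power_stroke_decreasing),
    speed_mode = speed_mode,
    amplitude_mode = amplitude_mode,
    rng_seed = as.integer(rng_seed)), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults; absent keys take the [run_config()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
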