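#' Specification for a synthetic velocity field
#'
#' Ground-truth flow structures for validating the hydrodynamic operators:
#'
#' \describe{
#'   \item{`power_decay`}{radial flow whose speed at distance r from
#'     `source` is `amplitude * (r / r_ref)^n` with decay power `n < 0` —
#'     the structure the attenuation fit measures. The cell containing the
#'     source (r = 0) is masked.}
#'   \item{`vortex_pair`}{two opposite-signed Lamb-Oseen vortices with
#'     circulations `+/- circulation` and core radius `core_radius`,
#'     centred at `centers` (2 x 2 matrix, one row per vortex).}
#'   \item{`solid_rotation`}{rigid-body rotation at angular rate
#'     `omega0` inside a disc of radius `patch_radius` about `center`.
#'     The vorticity inside the patch is exactly `2 * omega0`, so the patch
#'     circulation is `2 * omega0 * pi * patch_radius^2`. By default the
#'     exterior is the irrotational `omega0 * R^2 / r` azimuthal flow of a
#'     Rankine vortex, keeping the velocity continuous and all vorticity
#'     inside the patch; `exterior = "still"` instead sets the outside to
#'     zero, which places an unresolvable shear sheet at the patch edge
#'     (useful for stress-testing, but the discrete vorticity of that
#'     sheet cancels the patch circulation).}
#'   \item{`uniform`}{constant velocity `(v1, v2)`.}
#'   \item{`comoving`}{uniform flow equal to a supplied body velocity —
#'     fluid moving exactly with the larva, the null case of relative
#'     flux.}
#' }
#'
#' Geometry defaults mirror a typical micro-PIV export: an 80 x 64 cell
#' grid with 25 micrometre pitch (16-pixel cells at about 1.56 um/px).
#'
#' @param kind one of `"power_decay"`, `"vortex_pair"`, `"uniform"`,
#'   `"solid_rotation"`, `"comoving"`.
#' @param ... kind-specific parameters, see Details.
#' @param grid_shape grid shape `c(n_x, n_y)` in cells.
#' @param cell_pitch cell size, metres.
#' @param mask_center,mask_radii optional ellipse (centre and semi-axes, m)
#'   marked as larval body in the mask.
#' @param rng_seed integer seed (reserved for stochastic variants; the
#'   analytic kinds are deterministic).
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(kind = c("power_decay", "vortex_pair", "uniform",
                                "solid_rotation", "comoving"),
                       ...,
                       grid_shape = c(80L, 64L), cell_pitch = 25e-6,
                       mask_center = NULL, mask_radii = NULL,
                       rng_seed = 1L) {
  kind <- match.arg(kind)
  n_x <- grid_shape[1]; n_y <- grid_shape[2]
  if (n_x < 2 || n_y < 2) stopf("grid must be at least 2 x 2")
  if (cell_pitch <= 0) stopf("cell_pitch must be > 0")
  pars <- list(...)
  defaults <- switch(kind,
    power_decay = list(n = -2, amplitude = 5e-3, r_ref = 1e-4,
                       source = NULL),
    vortex_pair = list(circulation = 2e-6, core_radius = 1.5e-4,
                       centers = NULL),
    uniform = list(v1 = 1e-3, v2 = 0),
    solid_rotation = list(omega0 = 10, patch_radius = 3e-4, center = NULL,
                          exterior = "irrotational"),
    comoving = list(body_velocity = c(1e-3, 0)))
  unknown <- setdiff(names(pars), names(defaults))
  if (length(unknown))
    stopf("unknown parameter(s) for kind '%s': %s", kind,
          paste(unknown, collapse = ", "))
  defaults[names(pars)] <- pars
  if (kind == "power_decay" && defaults$n >= 0)
    stopf("power_decay requires a decay power n < 0")
  structure(list(kind = kind, n_x = as.integer(n_x), n_y = as.integer(n_y),
                 cell_pitch = cell_pitch, mask_center = mask_center,
                 mask_radii = mask_radii, parameters = defaults,
                 rng_seed = as.integer(rng_seed)),
            class = "field_spec")
}

cell_pitch_half <- function(pitch) c(pitch, pitch) / 2

#' Realize a synthetic velocity field
#'
#' @param spec a [field_spec()].
#' @param time frame time recorded on the output field, seconds.
#' @return a [velocity_field()]; ground-truth parameters are attached as
#'   `attr(x, "truth")`.
#' @export
make_field <- function(spec, time = 0) {
  stopifnot(inherits(spec, "field_spec"))
  p <- spec$parameters
  pitch <- spec$cell_pitch
  cx <- (seq_len(spec$n_x) - 0.5) * pitch
  cy <- (seq_len(spec$n_y) - 0.5) * pitch
  X <- matrix(cx, spec$n_x, spec$n_y)
  Y <- matrix(cy, spec$n_x, spec$n_y, byrow = TRUE)
  center_default <- c(spec$n_x, spec$n_y) / 2 * pitch
  mask <- matrix(FALSE, spec$n_x, spec$n_y)
  if (!is.null(spec$mask_center)) {
    mask <- ((X - spec$mask_center[1]) / spec$mask_radii[1])^2 +
      ((Y - spec$mask_center[2]) / spec$mask_radii[2])^2 <= 1
  }
  if (spec$kind == "uniform") {
    v1 <- matrix(p$v1, spec$n_x, spec$n_y)
    v2 <- matrix(p$v2, spec$n_x, spec$n_y)
  } else if (spec$kind == "comoving") {
    v1 <- matrix(p$body_velocity[1], spec$n_x, spec$n_y)
    v2 <- matrix(p$body_velocity[2], spec$n_x, spec$n_y)
  } else if (spec$kind == "power_decay") {
    # default source sits on a cell centre so the r = 0 singularity is a
    # real cell (which gets masked)
    src <- p$source %||% (center_default - cell_pitch_half(pitch))
    dx <- X - src[1]; dy <- Y - src[2]
    r <- sqrt(dx^2 + dy^2)
    at_source <- r < pitch / 2
    speed <- p$amplitude * (r / p$r_ref)^p$n
    speed[at_source] <- 0
    r[at_source] <- Inf
    v1 <- speed * dx / r
    v2 <- speed * dy / r
    mask <- mask | at_source
  } else if (spec$kind == "solid_rotation") {
    ctr <- p$center %||% center_default
    dx <- X - ctr[1]; dy <- Y - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    inside <- r <= p$patch_radius
    # angular rate: omega0 inside; Rankine (irrotational) or still outside
    rate <- ifelse(inside, p$omega0,
                   if (identical(p$exterior, "still")) 0
                   else p$omega0 * p$patch_radius^2 / pmax(r, 1e-12)^2)
    v1 <- -rate * dy
    v2 <- rate * dx
  } else { # vortex_pair
    ctrs <- p$centers %||% rbind(center_default - c(0.8e-3, 0),
                                 center_default + c(0.8e-3, 0))
    v1 <- matrix(0, spec$n_x, spec$n_y)
    v2 <- matrix(0, spec$n_x, spec$n_y)
    signs <- c(1, -1)
    for (k in 1:2) {
      dx <- X - ctrs[k, 1]; dy <- Y - ctrs[k, 2]
      r2 <- dx^2 + dy^2
      r <- sqrt(r2)
      # Lamb-Oseen azimuthal profile; finite at the core centre
      vt <- signs[k] * p$circulation / (2 * pi * pmax(r, 1e-12)) *
        (1 - exp(-r2 / p$core_radius^2))
      v1 <- v1 - vt * dy / pmax(r, 1e-12)
      v2 <- v2 + vt * dx / pmax(r, 1e-12)
    }
  }
  out <- velocity_field(v1, v2, cell_pitch = pitch, mask = mask, time = time)
  truth <- switch(spec$kind,
    power_decay = list(n = p$n, amplitude = p$amplitude, r_ref = p$r_ref,
                       source = p$source %||%
                         (center_default - cell_pitch_half(pitch))),
    solid_rotation = list(omega0 = p$omega0, patch_radius = p$patch_radius,
                          circulation = 2 * p$omega0 * pi * p$patch_radius^2,
                          center = p$center %||% center_default),
    vortex_pair = list(circulation = p$circulation,
                       core_radius = p$core_radius),
    uniform = list(v = c(p$v1, p$v2)),
    comoving = list(body_velocity = p$body_velocity))
  attr(out, "truth") <- truth
  out
}
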