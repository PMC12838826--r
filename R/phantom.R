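#' Elastic tissue phantom under the indenter
#'
#' Geometric, elastic and acoustic description of the sample: thickness `h`
#' (m), longitudinal sound speed `v` (m/s), Young's modulus `E` (Pa),
#' Poisson's ratio `nu` (default 0.5, incompressible soft tissue),
#' frequency-linear attenuation `alpha` (dB/(cm MHz), default 0.5, a
#' textbook soft-tissue value), and an optional strain-stiffening
#' coefficient `beta` >= 0 making the load-deformation law
#' `P = 2 a E w (1 + beta w / h) / (1 - nu^2)` progressively harder to
#' compress. An optional stiff embedded inclusion (a lesion analogue) is a
#' layer of relative depth and thickness with its own modulus; it changes
#' the phantom's compressive compliance (see [effective_modulus()]) but not
#' its acoustics.
#'
#' @param thickness_h Resting thickness in m.
#' @param sound_speed_v Sound speed in m/s.
#' @param youngs_modulus_E Young's modulus in Pa.
#' @param poisson_ratio_nu Poisson's ratio in `[0, 0.5]`.
#' @param attenuation_alpha Attenuation coefficient in dB/(cm MHz).
#' @param stiffening_beta Dimensionless strain-stiffening coefficient >= 0;
#'   0 gives the linear-elastic law.
#' @param inclusion `NULL`, or a list with `depth_fraction` and
#'   `thickness_fraction` in (0, 1) (summing to at most 1) and
#'   `youngs_modulus_E_inc` in Pa.
#' @return An object of class `tissue_phantom`.
#' @examples
#' ph <- tissue_phantom(30e-3, 1540, 10e3)
#' @export
tissue_phantom <- function(thickness_h, sound_speed_v, youngs_modulus_E,
                           poisson_ratio_nu = 0.5, attenuation_alpha = 0.5,
                           stiffening_beta = 0, inclusion = NULL) {
  if (thickness_h <= 0) stop("`thickness_h` must be positive", call. = FALSE)
  if (sound_speed_v <= 0) stop("`sound_speed_v` must be positive", call. = FALSE)
  if (youngs_modulus_E <= 0) stop("`youngs_modulus_E` must be positive", call. = FALSE)
  if (poisson_ratio_nu < 0 || poisson_ratio_nu > 0.5)
    stop("`poisson_ratio_nu` must be in [0, 0.5]", call. = FALSE)
  if (attenuation_alpha < 0) stop("`attenuation_alpha` must be >= 0", call. = FALSE)
  if (stiffening_beta < 0) stop("`stiffening_beta` must be >= 0", call. = FALSE)
  if (!is.null(inclusion)) {
    req <- c("depth_fraction", "thickness_fraction", "youngs_modulus_E_inc")
    if (!all(req %in% names(inclusion)))
      stop("`inclusion` needs depth_fraction, thickness_fraction, youngs_modulus_E_inc",
           call. = FALSE)
    if (inclusion$depth_fraction <= 0 || inclusion$thickness_fraction <= 0 ||
        inclusion$depth_fraction + inclusion$thickness_fraction > 1)
      stop("inclusion fractions must be positive with depth + thickness <= 1",
           call. = FALSE)
    if (inclusion$youngs_modulus_E_inc <= 0)
      stop("`youngs_modulus_E_inc` must be positive", call. = FALSE)
  }
  structure(
    list(thickness_h = thickness_h, sound_speed_v = sound_speed_v,
         youngs_modulus_E = youngs_modulus_E,
         poisson_ratio_nu = poisson_ratio_nu,
         attenuation_alpha = attenuation_alpha,
         stiffening_beta = stiffening_beta, inclusion = inclusion),
    class = "tissue_phantom"
  )
}

#' Cylindrical flat-punch indenter
#'
#' @param contact_radius_a Radius of the flat contact surface in m.
#' @return An object of class `indenter` with the derived `contact_area`
#'   (`pi * a^2`, m^2).
#' @examples
#' ind <- indenter(10e-3)
#' ind$contact_area
#' @export
indenter <- function(contact_radius_a = 10e-3) {
  if (contact_radius_a <= 0)
    stop("`contact_radius_a` must be positive", call. = FALSE)
  structure(
    list(contact_radius_a = contact_radius_a,
         contact_area = pi * contact_radius_a^2),
    class = "indenter"
  )
}

#' One step of an indentation load protocol
#'
#' Loads can be stated as an indentation force (N) or an applied cuff
#' pressure (Pa); at least one must be given. A pressure is converted to
#' force through the indenter contact area (`P = pressure * pi * a^2`) by
#' [resolve_force()].
#'
#' @param label Text label, e.g. `"5N"` or `"3kPa"`.
#' @param applied_pressure Pressure in Pa, or `NULL`.
#' @param applied_force Force in N, or `NULL`.
#' @return An object of class `load_step`.
#' @export
load_step <- function(label, applied_pressure = NULL, applied_force = NULL) {
  if (is.null(applied_pressure) && is.null(applied_force))
    stop("a load step needs `applied_pressure` or `applied_force`", call. = FALSE)
  if (!is.null(applied_force) && applied_force < 0)
    stop("invalid load: `applied_force` must be >= 0", call. = FALSE)
  if (!is.null(applied_pressure) && applied_pressure < 0)
    stop("invalid load: `applied_pressure` must be >= 0", call. = FALSE)
  structure(
    list(label = as.character(label), applied_pressure = applied_pressure,
         applied_force = applied_force),
    class = "load_step"
  )
}

#' Resolve a load step to an indentation force
#'
#' Uses the stated force when present; otherwise maps pressure to force via
#' the indenter contact area. When both are present they must agree through
#' that same mapping.
#'
#' @param load A [load_step()].
#' @param ind An [indenter()].
#' @return Force in N.
#' @export
resolve_force <- function(load, ind) {
  stopifnot(inherits(load, "load_step"), inherits(ind, "indenter"))
  if (!is.null(load$applied_force) && !is.null(load$applied_pressure)) {
    implied <- load$applied_pressure * ind$contact_area
    if (abs(load$applied_force - implied) >
        1e-9 * max(1, abs(load$applied_force)))
      stop("invalid load: force and pressure disagree through the contact area",
           call. = FALSE)
  }
  load$applied_force %||% (load$applied_pressure * ind$contact_area)
}

#' Build force- or pressure-stepped load protocols
#'
#' @param forces_N,pressures_kPa Numeric vectors of levels; the first is
#'   the baseline.
#' @return List of [load_step()] objects.
#' @rdname load_protocols
#' @export
force_steps <- function(forces_N) {
  lapply(forces_N, function(f) load_step(sprintf("%gN", f), applied_force = f))
}

#' @rdname load_protocols
#' @export
pressure_steps <- function(pressures_kPa) {
  lapply(pressures_kPa, function(p)
    load_step(sprintf("%gkPa", p), applied_pressure = p * 1e3))
}

#' Series-composite modulus of a phantom with an embedded inclusion
#'
#' The host layer and the inclusion layer deform in series under the punch,
#' so their compliances add in proportion to thickness:
#' `E_eff = 1 / (f_host / E + f_inc / E_inc)` with `f_inc` the inclusion
#' thickness fraction. A stiffer inclusion always raises `E_eff`.
#'
#' @param phantom A [tissue_phantom()] with an inclusion.
#' @return Effective Young's modulus in Pa.
#' @examples
#' ph <- tissue_phantom(30e-3, 1540, 10e3,
#'   inclusion = list(depth_fraction = 0.3, thickness_fraction = 0.3,
#'                    youngs_modulus_E_inc = 1e6))
#' effective_modulus(ph) # ~ 14.2 kPa
#' @export
effective_modulus <- function(phantom) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (is.null(phantom$inclusion))
    stop("invalid input: phantom has no inclusion", call. = FALSE)
  f_inc <- phantom$inclusion$thickness_fraction
  1 / ((1 - f_inc) / phantom$youngs_modulus_E +
         f_inc / phantom$inclusion$youngs_modulus_E_inc)
}

# Modulus governing compression: composite when an inclusion is present.
mechanical_modulus <- function(phantom) {
  if (is.null(phantom$inclusion)) phantom$youngs_modulus_E
  else effective_modulus(phantom)
}

#' Quasi-static deformation under a load step
#'
#' Inverts the flat-punch contact law. With `stiffening_beta = 0` the
#' deformation is linear, `w = (1 - nu^2) P / (2 a E)`; with `beta > 0` it
#' solves `P = 2 a E w (1 + beta w / h) / (1 - nu^2)` by bisection on
#' `[0, 0.95 h]` to a relative tolerance of 1e-10. Deformation is capped at
#' 95% of the resting thickness; a cap marks the state as bottomed out and
#' raises a warning.
#'
#' @param phantom A [tissue_phantom()]. With an inclusion present, the
#'   series-composite modulus governs.
#' @param ind An [indenter()].
#' @param load A [load_step()].
#' @return A list of class `deformation_state` with `deformation_w`,
#'   `compressed_thickness_hi` and logical `bottomed_out`.
#' @examples
#' ph <- tissue_phantom(30e-3, 1540, 10e3)
#' deform(ph, indenter(10e-3), load_step("1N", applied_force = 1))
#' @export
deform <- function(phantom, ind, load) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(ind, "indenter"))
  P <- resolve_force(load, ind)
  if (P < 0) stop("invalid load: force must be >= 0", call. = FALSE)
  h <- phantom$thickness_h
  E <- mechanical_modulus(phantom)
  nu <- phantom$poisson_ratio_nu
  a <- ind$contact_radius_a
  beta <- phantom$stiffening_beta
  w_cap <- 0.95 * h
  bottomed <- FALSE

  if (P == 0) {
    w <- 0
  } else if (beta == 0) {
    w <- (1 - nu^2) * P / (2 * a * E)
    if (w >= h) bottomed <- TRUE
    w <- min(w, w_cap)
  } else {
    load_at <- function(w) 2 * a * E * w * (1 + beta * w / h) / (1 - nu^2)
    if (load_at(w_cap) < P) {
      bottomed <- TRUE
      w <- w_cap
    } else {
      lo <- 0
      hi <- w_cap
      while ((hi - lo) > 1e-10 * max(hi, .Machine$double.eps)) {
        mid <- (lo + hi) / 2
        if (load_at(mid) < P) lo <- mid else hi <- mid
      }
      w <- (lo + hi) / 2
    }
  }
  if (bottomed)
    warning("phantom bottomed out: deformation capped at 0.95 * thickness",
            call. = FALSE)
  structure(
    list(deformation_w = w, compressed_thickness_hi = h - w,
         bottomed_out = bottomed),
    class = "deformation_state"
  )
}

#' Convert Shore A hardness to Young's modulus (Gent relation)
#'
#' Parameterizes silicone-like calibration phantoms from durometer
#' readings: `E(MPa) = 0.0981 (56 + 7.62336 S) / (0.137505 (254 - 2.54 S))`.
#' Strictly increasing in S; singular at S = 100.
#'
#' @param shore_HA Shore A hardness, `0 <= S < 100`.
#' @return Young's modulus in Pa.
#' @examples
#' shore_to_young(30) # ~ 1.14 MPa
#' @export
shore_to_young <- function(shore_HA) {
  if (any(shore_HA < 0) || any(shore_HA >= 100))
    stop("invalid input: `shore_HA` must satisfy 0 <= S < 100", call. = FALSE)
  e_mpa <- 0.0981 * (56 + 7.62336 * shore_HA) /
    (0.137505 * (254 - 2.54 * shore_HA))
  e_mpa * 1e6
}
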