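#' Flat-punch contact model: modulus from load and deformation
#'
#' For a rigid cylindrical punch of contact radius `a` on an elastic
#' half-space, `E = (1 - nu^2) P / (2 a w)`.
#'
#' @param P Indentation force in N.
#' @param w Deformation in m; must be positive.
#' @param a Contact radius in m.
#' @param nu Poisson's ratio in `[0, 0.5]`.
#' @return Young's modulus in Pa.
#' @export
hertz_modulus <- function(P, w, a, nu = 0.5) {
  if (any(w <= 0)) stop("invalid deformation: `w` must be positive", call. = FALSE)
  stopifnot(a > 0, nu >= 0, nu <= 0.5)
  (1 - nu^2) / (2 * a) * P / w
}

#' Flat-punch contact model: deformation from load and modulus
#'
#' Exact algebraic inverse of [hertz_modulus()]:
#' `w = (1 - nu^2) P / (2 a E)`.
#'
#' @inheritParams hertz_modulus
#' @param E Young's modulus in Pa.
#' @return Deformation in m.
#' @export
hertz_deformation <- function(P, E, a, nu = 0.5) {
  stopifnot(E > 0, a > 0, nu >= 0, nu <= 0.5)
  (1 - nu^2) * P / (2 * a * E)
}

#' Convert between ToF difference and deformation
#'
#' The round-trip relation `w = v tau / 2`: a compression of `w` shortens
#' the echo path by `2 w`, advancing arrival by `tau = 2 w / v`.
#'
#' @param tau ToF difference in s; must be >= 0 (positive tau means the
#'   loaded echo arrives earlier).
#' @param w Deformation in m.
#' @param v Sound speed in m/s.
#' @return Deformation in m, or ToF difference in s.
#' @rdname tof_deformation
#' @export
tof_to_deformation <- function(tau, v) {
  if (any(tau < 0))
    stop("invalid input: negative tau violates the sign convention", call. = FALSE)
  stopifnot(v > 0)
  v * tau / 2
}

#' @rdname tof_deformation
#' @export
deformation_to_tof <- function(w, v) {
  stopifnot(v > 0)
  2 * w / v
}

#' Estimate Young's modulus from a ToF sweep
#'
#' Converts each ToF difference to a deformation (`w = v tau / 2`), fits
#' `w` against force `P` through the origin by least squares — the contact
#' law forces a zero intercept — and inverts the slope:
#' `E = (1 - nu^2) / (2 a slope)`. Regressing the whole sweep averages
#' measurement noise; single-point inversion is available via
#' [hertz_modulus()] + [tof_to_deformation()].
#'
#' @param measurements `data.frame` with columns `force_N` and `tau_s`
#'   (e.g. from [tof_table()]); needs >= 2 nonzero-load rows.
#' @param v Sound speed in m/s.
#' @param ind An [indenter()].
#' @param nu Poisson's ratio.
#' @return List with `youngs_modulus_E` (Pa) and `fit`
#'   (`slope` m/N, through-origin `r_squared`, `n_points`).
#' @export
estimate_modulus_from_sweep <- function(measurements, v, ind, nu = 0.5) {
  stopifnot(is.data.frame(measurements),
            all(c("force_N", "tau_s") %in% names(measurements)),
            inherits(ind, "indenter"))
  if (sum(measurements$force_N > 0) < 2)
    stop("need at least 2 nonzero-load measurements", call. = FALSE)
  P <- measurements$force_N
  w <- tof_to_deformation(pmax(measurements$tau_s, 0), v)
  slope <- sum(P * w) / sum(P^2)
  if (slope <= 0)
    stop("degenerate sweep: fitted deformation-per-force slope is not positive",
         call. = FALSE)
  ss_res <- sum((w - slope * P)^2)
  ss_tot <- sum(w^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(
    youngs_modulus_E = (1 - nu^2) / (2 * ind$contact_radius_a * slope),
    fit = list(slope = slope, r_squared = r2, n_points = length(P))
  )
}

#' Ordinary least-squares calibration fits
#'
#' `fit_tof_vs_load` fits tau against applied load (the force- or
#' pressure-sweep calibration line); `fit_tof_vs_hardness` fits tau
#' against Shore hardness across a phantom series at fixed load, where the
#' expected slope is negative (harder samples deform less). Both are
#' affine OLS fits; a response with zero variance yields slope 0 and
#' R^2 = 0.
#'
#' @param loads Numeric loads (N or kPa).
#' @param hardness_HA Numeric Shore A hardness values.
#' @param taus Numeric ToF differences (s), same length.
#' @return An object of class `linear_fit`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @rdname calibration_fits
#' @export
fit_tof_vs_load <- function(loads, taus) {
  linear_fit(loads, taus)
}

#' @rdname calibration_fits
#' @export
fit_tof_vs_hardness <- function(hardness_HA, taus) {
  linear_fit(hardness_HA, taus)
}

linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need >= 2 (x, y) points of equal length", call. = FALSE)
  if (sd(y) == 0) {
    fit <- list(slope = 0, intercept = mean(y), r_squared = 0,
                n_points = length(x))
  } else {
    m <- lm(y ~ x)
    r2 <- suppressWarnings(summary(m)$r.squared)
    fit <- list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
                r_squared = r2, n_points = length(x))
  }
  structure(fit, class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.4g, intercept %.4g, R^2 %.4f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Rank samples by stiffness from ToF differences at a fixed load differential
#'
#' Under the same pressure differential a smaller tau means less
#' deformation, hence a stiffer sample. Labels are ordered stiffest first
#' (ascending tau); exactly tied taus are reported as one tie group rather
#' than broken silently.
#'
#' @param named_taus Named numeric vector of tau values (s), all >= 0.
#' @return An object of class `stiffness_ranking`: `labels` (stiffest
#'   first) and `groups` (list of tie groups in rank order).
#' @examples
#' rank_stiffness(c(beef = 1.0e-6, pork = 2.0e-6, fat = 3.0e-6))
#' @export
rank_stiffness <- function(named_taus) {
  if (length(named_taus) < 1 || is.null(names(named_taus)))
    stop("`named_taus` must be a non-empty named vector", call. = FALSE)
  if (any(named_taus < 0)) stop("tau values must be >= 0", call. = FALSE)
  ord <- order(named_taus)
  sorted <- named_taus[ord]
  groups <- split(names(sorted), factor(sorted, levels = unique(sorted)))
  names(groups) <- NULL
  structure(list(labels = names(sorted), groups = groups),
            class = "stiffness_ranking")
}

#' @export
print.stiffness_ranking <- function(x, ...) {
  txt <- vapply(x$groups, function(g)
    if (length(g) > 1) paste0("{", paste(g, collapse = " = "), "}") else g,
    character(1))
  cat("stiffest ", paste(txt, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Sensitivity curve of ToF difference against applied pressure
#'
#' Collects tau relative to the lowest-pressure baseline and its rate of
#' change per pressure step. `rate_of_change[i]` is
#' `(tau[i+1] - tau[i]) / (p[i+1] - p[i])`, the incoming rate of pressure
#' level `i + 1` (so it has one fewer element than `pressures`).
#'
#' @param pressures Strictly increasing pressures in kPa; the first is the
#'   baseline.
#' @param taus_vs_baseline Tau (s) at each pressure relative to the
#'   baseline; the first must be 0.
#' @return An object of class `sensitivity_curve`: `pressures`,
#'   `tau_vs_baseline`, `rate_of_change` (s/kPa, named by the pressure
#'   each step ends at).
#' @export
sensitivity_curve <- function(pressures, taus_vs_baseline) {
  if (length(pressures) != length(taus_vs_baseline))
    stop("`pressures` and `taus_vs_baseline` must have equal length", call. = FALSE)
  if (any(diff(pressures) <= 0))
    stop("`pressures` must be strictly increasing", call. = FALSE)
  if (taus_vs_baseline[1] != 0)
    stop("the first tau is the baseline and must be 0", call. = FALSE)
  rates <- diff(taus_vs_baseline) / diff(pressures)
  names(rates) <- pressures[-1]
  structure(
    list(pressures = pressures, tau_vs_baseline = taus_vs_baseline,
         rate_of_change = rates),
    class = "sensitivity_curve"
  )
}

#' Select the operating pressure at the knee of a sensitivity curve
#'
#' Returns the largest pressure whose incoming rate of ToF-difference
#' change is still at least `plateau_fraction` of the maximum rate — the
#' knee where the curve flattens. Measuring beyond it adds discomfort
#' without discriminability; the rule formalizes picking the last steep
#' step before the plateau.
#'
#' @param curve A [sensitivity_curve()] with >= 3 pressure levels.
#' @param plateau_fraction Fraction of the maximum rate below which a step
#'   counts as plateaued; default 0.25.
#' @return Operating pressure, in the units of `curve$pressures`.
#' @export
select_operating_pressure <- function(curve, plateau_fraction = 0.25) {
  stopifnot(inherits(curve, "sensitivity_curve"))
  if (length(curve$pressures) < 3)
    stop("need at least 3 pressure levels", call. = FALSE)
  rates <- curve$rate_of_change
  if (all(rates == 0))
    stop("no sensitivity: all rates are zero", call. = FALSE)
  keep <- rates >= plateau_fraction * max(rates)
  max(curve$pressures[-1][keep])
}
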