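#' Cell-line parameter set for the IMK model
#'
#' The fitted state of the model for one cell line: the intrinsic
#' linear-quadratic coefficients (alpha0, beta0) for lethal-lesion
#' induction, the sublethal-damage repair rate (a+c), the domain radius
#' r_d, and the micronucleus-formation probability h (the probability that
#' the misrepair transformation of a lethal lesion yields an MN).
#'
#' @param alpha0 Gy^-1, >= 0.
#' @param beta0 Gy^-2, >= 0.
#' @param a_plus_c 1/h, > 0.
#' @param r_d Domain radius, um (> 0).
#' @param h_mn MN-formation probability in [0, 1].
#' @param label Cell-line name.
#' @return An object of class `cell_params`.
#' @examples
#' hsg <- cell_parameters(0.150, 0.0467, 2.19, r_d = 0.42, h_mn = 0.275, label = "HSG")
#' @export
cell_parameters <- function(alpha0, beta0, a_plus_c, r_d = 0.42,
                            h_mn = 0.275, label = "") {
  if (alpha0 < 0 || beta0 < 0) stop("alpha0 and beta0 must be >= 0", call. = FALSE)
  if (a_plus_c <= 0) stop("a_plus_c must be > 0", call. = FALSE)
  if (r_d <= 0) stop("r_d must be > 0", call. = FALSE)
  if (h_mn < 0 || h_mn > 1) stop("h_mn must lie in [0, 1]", call. = FALSE)
  structure(list(alpha0 = alpha0, beta0 = beta0, a_plus_c = a_plus_c,
                 r_d = r_d, h_mn = h_mn, label = label),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("IMK cell parameters", if (nzchar(x$label)) paste0("[", x$label, "]"), "\n",
      sprintf("  alpha0 = %.4g Gy^-1, beta0 = %.4g Gy^-2, (a+c) = %.4g /h, r_d = %.3g um, h = %.4g\n",
              x$alpha0, x$beta0, x$a_plus_c, x$r_d, x$h_mn), sep = "")
  invisible(x)
}

#' Radiation quality
#'
#' Wraps the saturation-corrected dose-mean specific energy z1D* (Gy) that
#' enters the effective linear coefficient alpha = alpha0 + z1D* beta0.
#'
#' @param z1dstar z1D*, Gy (>= 0). 0 is the idealized low-LET photon
#'   reference.
#' @param label Free-text label.
#' @return An object of class `rad_quality`.
#' @seealso [quality_from_spectrum()]
#' @export
radiation_quality <- function(z1dstar = 0, label = "") {
  if (!is.numeric(z1dstar) || length(z1dstar) != 1L || !is.finite(z1dstar) ||
      z1dstar < 0)
    stop("z1dstar must be a single non-negative number", call. = FALSE)
  structure(list(z1dstar = z1dstar, label = label), class = "rad_quality")
}

#' Radiation quality from a lineal-energy spectrum
#'
#' @param spectrum An [mds_spectrum()].
#' @param geometry A [domain_geometry()] supplying r_d, rho and y0.
#' @return A [radiation_quality()] with z1D* computed via [compute_ystar()]
#'   and [compute_z1dstar()].
#' @export
quality_from_spectrum <- function(spectrum, geometry = domain_geometry()) {
  ys <- compute_ystar(spectrum, geometry$y0)
  radiation_quality(compute_z1dstar(ys, geometry),
                    label = spectrum$meta)
}

#' Mean number of lethal lesions per nucleus
#'
#' The IMK dose response: <w> = (alpha0 + z1D* beta0) D + F beta0 D^2,
#' where F is the Lea-Catcheside protraction factor of the delivery.
#'
#' @param params A [cell_parameters()].
#' @param quality A [radiation_quality()].
#' @param dose Absorbed dose, Gy (>= 0). Vectorized.
#' @param F Protraction factor in (0, 1]; 1 for acute exposure.
#' @return <w>, lethal lesions per nucleus.
#' @export
mean_lethal_lesions <- function(params, quality, dose, F = 1) {
  stopifnot(inherits(params, "cell_params"), inherits(quality, "rad_quality"))
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  if (any(F <= 0) || any(F > 1)) stop("F must lie in (0, 1]", call. = FALSE)
  (params$alpha0 + quality$z1dstar * params$beta0) * dose +
    F * params$beta0 * dose^2
}

#' Surviving fraction
#'
#' S = exp(-<w>) with <w> from [mean_lethal_lesions()].
#'
#' @inheritParams mean_lethal_lesions
#' @return S in (0, 1].
#' @export
surviving_fraction <- function(params, quality, dose, F = 1) {
  exp(-mean_lethal_lesions(params, quality, dose, F))
}

#' Micronucleus frequency
#'
#' F_MN = h <w>: micronuclei per cell, proportional to the mean
#' lethal-lesion number with the MN-formation probability h. Equivalently
#' F_MN = (alpha_m0 + z1D* beta_m0) D + F beta_m0 D^2 with
#' alpha_m0 = h alpha0 and beta_m0 = h beta0.
#'
#' @inheritParams mean_lethal_lesions
#' @return Expected MN per cell.
#' @export
mn_frequency <- function(params, quality, dose, F = 1) {
  params$h_mn * mean_lethal_lesions(params, quality, dose, F)
}

#' Dose at a given survival level (D10 by default)
#'
#' Inverts the acute LQ relation alpha D + beta D^2 = -log(level). For
#' beta below the cancellation threshold the linear limit -log(level)/alpha
#' is used.
#'
#' @param alpha Effective linear coefficient, Gy^-1 (>= 0).
#' @param beta Effective quadratic coefficient, Gy^-2 (>= 0). Not both zero.
#' @param level Survival level; default 0.10 (D10).
#' @return Dose in Gy such that exp(-(alpha D + beta D^2)) = level.
#' @export
d10 <- function(alpha, beta, level = 0.10) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (alpha == 0 && beta == 0)
    stop("undefined-dose error: alpha and beta are both zero", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  sstar <- -log(level)
  if (beta < 1e-12 * max(alpha^2, 1e-300))
    return(sstar / alpha)
  (sqrt(alpha^2 + 4 * beta * sstar) - alpha) / (2 * beta)
}

#' RBE for cell survival
#'
#' Ratio of the photon-reference D10 to the test-radiation D10, each
#' computed under the acute assumption (beta = beta0) with
#' alpha = alpha0 + z1D* beta0.
#'
#' @param params A [cell_parameters()].
#' @param quality_test,quality_photon [radiation_quality()] objects for the
#'   test radiation and the photon reference.
#' @param level Survival level defining the iso-effect dose; default 0.10.
#' @return RBE_SF (dimensionless); 1 for identical qualities.
#' @export
rbe_sf <- function(params, quality_test, quality_photon = radiation_quality(0),
                   level = 0.10) {
  stopifnot(inherits(params, "cell_params"))
  a_t <- params$alpha0 + quality_test$z1dstar * params$beta0
  a_p <- params$alpha0 + quality_photon$z1dstar * params$beta0
  d10(a_p, params$beta0, level) / d10(a_t, params$beta0, level)
}

#' RBE for micronucleus frequency
#'
#' Ratio of the linear MN coefficients alpha_m of the test radiation and
#' the photon reference. The MN-formation probability h cancels, so
#' RBE_MN = (alpha0 + z1D*_test beta0) / (alpha0 + z1D*_photon beta0);
#' this is the low-dose (maximum) RBE.
#'
#' @inheritParams rbe_sf
#' @return RBE_MN (dimensionless); 1 for identical qualities.
#' @export
rbe_mn <- function(params, quality_test, quality_photon = radiation_quality(0)) {
  stopifnot(inherits(params, "cell_params"))
  a_p <- params$alpha0 + quality_photon$z1dstar * params$beta0
  if (a_p <= 0)
    stop("undefined-ratio error: photon alpha_m is zero", call. = FALSE)
  (params$alpha0 + quality_test$z1dstar * params$beta0) / a_p
}

#' Relative MN frequency across dose-rate schedules
#'
#' Evaluates the MN frequency for each schedule at a fixed total dose and
#' normalizes by the reference (high-dose-rate) schedule; this is the
#' quantity measured in split/protracted dose-rate experiments.
#'
#' @param params A [cell_parameters()].
#' @param quality A [radiation_quality()].
#' @param total_dose Total dose each schedule must deliver, Gy.
#' @param schedules List of [irradiation_schedule()] objects.
#' @param reference_schedule The normalizing schedule (same total dose).
#' @param tol Relative tolerance for the dose check.
#' @return Numeric vector of F_MN(schedule)/F_MN(reference), one per
#'   schedule; the reference itself maps to 1.
#' @export
relative_mn_vs_doserate <- function(params, quality, total_dose, schedules,
                                    reference_schedule, tol = 1e-9) {
  stopifnot(inherits(params, "cell_params"))
  fmn_of <- function(sch) {
    stopifnot(inherits(sch, "irr_schedule"))
    if (abs(sch$D - total_dose) > tol * max(total_dose, 1))
      stop("schedule error: schedule dose does not match total_dose",
           call. = FALSE)
    Fv <- protraction_factor_schedule(sch, params$a_plus_c)
    mn_frequency(params, quality, total_dose, Fv)
  }
  ref <- fmn_of(reference_schedule)
  if (ref <= 0)
    stop("reference MN frequency is zero; cannot normalize", call. = FALSE)
  vapply(schedules, fmn_of, numeric(1)) / ref
}
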