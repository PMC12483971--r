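#' Dose-response dataset
#'
#' Observations of a radiobiological endpoint versus absorbed dose for one
#' radiation quality and one delivery schedule. Survival values are
#' fractions in (0, 1]; MN endpoints are non-negative counts per cell
#' (`mn_per_cell`) or MN-bearing-cell fractions (`mn_fraction`).
#'
#' @param dose Doses, Gy (>= 0).
#' @param value Endpoint values (same length as `dose`).
#' @param sd Optional per-point standard deviation across replicates.
#' @param n_rep Optional replicate count per point (scalar or vector); used
#'   to convert `sd` into a standard error of the recorded mean.
#' @param endpoint One of `"survival"`, `"mn_per_cell"`, `"mn_fraction"`.
#' @param quality A [radiation_quality()] (default: idealized photon,
#'   z1D* = 0).
#' @param schedule An [irradiation_schedule()], or `NULL` for acute
#'   delivery (protraction factor 1).
#' @param spectrum Optional [mds_spectrum()] attached for domain-radius
#'   calibration, where z1D* must be recomputed as r_d varies.
#' @param label Free-text dataset label.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(dose, value, sd = NULL, n_rep = NULL,
                          endpoint = c("survival", "mn_per_cell", "mn_fraction"),
                          quality = radiation_quality(0), schedule = NULL,
                          spectrum = NULL, label = "") {
  endpoint <- match.arg(endpoint)
  n <- length(dose)
  if (n < 1L || length(value) != n)
    stop("dose and value must be non-empty and of equal length", call. = FALSE)
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("validation error: doses must be finite and >= 0", call. = FALSE)
  bad <- if (endpoint == "survival") {
    which(!is.finite(value) | value <= 0 | value > 1)
  } else {
    which(!is.finite(value) | value < 0)
  }
  if (length(bad))
    stop(sprintf("validation error: invalid %s value(s) at row(s) %s",
                 endpoint, paste(bad, collapse = ", ")), call. = FALSE)
  if (!is.null(sd)) {
    if (length(sd) == 1L) sd <- rep(sd, n)
    if (length(sd) != n || any(sd[!is.na(sd)] < 0))
      stop("validation error: sd must be length-matched and >= 0", call. = FALSE)
  }
  if (!is.null(n_rep)) {
    if (length(n_rep) == 1L) n_rep <- rep(n_rep, n)
    if (length(n_rep) != n || any(n_rep < 1))
      stop("validation error: n_rep must be >= 1", call. = FALSE)
  }
  if (!is.null(schedule)) stopifnot(inherits(schedule, "irr_schedule"))
  if (!is.null(spectrum)) stopifnot(inherits(spectrum, "mds_spectrum"))
  stopifnot(inherits(quality, "rad_quality"))
  structure(list(
    records = data.frame(dose = dose, value = value,
                         sd = if (is.null(sd)) NA_real_ else sd,
                         n_rep = if (is.null(n_rep)) NA_real_ else n_rep),
    endpoint = endpoint, quality = quality, schedule = schedule,
    spectrum = spectrum, label = label
  ), class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose-response dataset", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n  endpoint: ", x$endpoint, ", ", nrow(x$records), " records, doses ",
      format(min(x$records$dose), digits = 3), "-",
      format(max(x$records$dose), digits = 3), " Gy, z1D* = ",
      format(x$quality$z1dstar, digits = 4), " Gy",
      if (is.null(x$schedule)) ", acute" else
        paste0(", schedule T = ", format(x$schedule$T, digits = 4), " h"),
      "\n", sep = "")
  invisible(x)
}
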