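#' Unit constant: joules per keV
#'
#' CODATA value of the elementary charge times 1e3, used to convert lineal
#' energy (keV/um) into specific energy (Gy = J/kg) in [compute_z1dstar()].
#'
#' @format A length-one numeric, 1.602176634e-16 J/keV.
#' @export
KEV_TO_JOULE <- 1.602176634e-16

# trapezoidal rule on a tabulated grid; spectra arrive as tables, no
# functional form is assumed anywhere downstream
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Microdosimetric lineal-energy spectrum
#'
#' Container for a discretized probability density f(y) of lineal energy y
#' (keV/um), the carrier of radiation quality in the IMK model. The density
#' is renormalized on construction so that its trapezoidal integral is 1.
#'
#' @param y_grid Strictly increasing lineal-energy values, keV/um, all > 0.
#' @param density Non-negative probability density f(y) on `y_grid`
#'   (per keV/um). Need not be normalized; it is renormalized internally.
#' @param meta Free-text label for the radiation (ion, energy, LET).
#' @param dialect Either `"fy"` (frequency density, the default) or `"dy"`
#'   (dose-weighted density d(y)); a `"dy"` input is converted through
#'   f(y) proportional to d(y)/y and renormalized. Both conventions
#'   circulate in microdosimetry.
#'
#' @return An object of class `mds_spectrum` with elements `y_grid`,
#'   `density` (normalized) and `meta`.
#' @examples
#' sp <- mds_spectrum(seq(1, 200, by = 0.5), dlnorm(seq(1, 200, by = 0.5), log(50), 0.3))
#' ystar(sp)
#' @seealso [compute_ystar()], [generate_spectrum()], [read_spectrum()]
#' @export
mds_spectrum <- function(y_grid, density, meta = "", dialect = c("fy", "dy")) {
  dialect <- match.arg(dialect)
  if (length(y_grid) < 2L || length(y_grid) != length(density))
    stop("invalid-spectrum: need >= 2 grid points and matching density length",
         call. = FALSE)
  if (any(!is.finite(y_grid)) || any(y_grid <= 0))
    stop("invalid-spectrum: all lineal energies must be finite and > 0",
         call. = FALSE)
  if (any(diff(y_grid) <= 0))
    stop("invalid-spectrum: y grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(density)) || any(density < 0))
    stop("invalid-spectrum: density must be finite and non-negative",
         call. = FALSE)
  if (dialect == "dy") density <- density / y_grid
  norm <- trapz(y_grid, density)
  if (!is.finite(norm) || norm <= 0)
    stop("invalid-spectrum: density integrates to zero, cannot normalize",
         call. = FALSE)
  structure(list(y_grid = y_grid, density = density / norm, meta = meta),
            class = "mds_spectrum")
}

#' @export
print.mds_spectrum <- function(x, ...) {
  cat("Microdosimetric spectrum", if (nzchar(x$meta)) paste0("[", x$meta, "]"),
      "\n  ", length(x$y_grid), " points, y in [",
      format(min(x$y_grid), digits = 4), ", ",
      format(max(x$y_grid), digits = 4), "] keV/um, y_F = ",
      format(y_frequency_mean(x), digits = 5), " keV/um\n", sep = "")
  invisible(x)
}

#' Frequency-mean lineal energy
#'
#' @param spectrum An [mds_spectrum()].
#' @return y_F = integral of y f(y) dy, keV/um.
#' @export
y_frequency_mean <- function(spectrum) {
  stopifnot(inherits(spectrum, "mds_spectrum"))
  trapz(spectrum$y_grid, spectrum$y_grid * spectrum$density)
}

#' Domain geometry for specific-energy conversion
#'
#' @param r_d Domain radius, um (> 0). Cell-line specific; 0.42 um is a
#'   typical fitted value for HSG-like cells.
#' @param rho Domain density, kg/m^3; default liquid water.
#' @param y0 Saturation parameter, keV/um; default 150, the conventional
#'   scale at which overkill saturates the effectiveness per unit dose.
#' @return An object of class `domain_geometry`.
#' @export
domain_geometry <- function(r_d = 0.42, rho = 1000, y0 = 150) {
  if (!is.numeric(r_d) || length(r_d) != 1L || !is.finite(r_d) || r_d <= 0)
    stop("geometry error: r_d must be a single positive number", call. = FALSE)
  if (rho <= 0 || y0 <= 0)
    stop("geometry error: rho and y0 must be positive", call. = FALSE)
  structure(list(r_d = r_d, rho = rho, y0 = y0), class = "domain_geometry")
}

#' Saturation-corrected lineal energy y*
#'
#' Computes the saturation-corrected (dose-mean-like) lineal energy
#' \deqn{y^* = y_0^2 \int [1 - e^{-y^2/y_0^2}] f(y)\,dy \; / \; \int y f(y)\,dy,}
#' the radiation-quality summary that caps effectiveness at high lineal
#' energy (the overkill effect). Quadrature is trapezoidal on the supplied
#' grid.
#'
#' @param spectrum An [mds_spectrum()].
#' @param y0 Saturation parameter, keV/um (> 0). Default 150.
#' @return y*, keV/um. For a single-line spectrum at y this equals
#'   y0^2 (1 - exp(-y^2/y0^2)) / y; for y much smaller than y0, y* ~ y.
#' @export
compute_ystar <- function(spectrum, y0 = 150) {
  stopifnot(inherits(spectrum, "mds_spectrum"))
  if (!is.numeric(y0) || length(y0) != 1L || !is.finite(y0) || y0 <= 0)
    stop("invalid saturation parameter y0", call. = FALSE)
  y <- spectrum$y_grid
  f <- spectrum$density
  yf <- trapz(y, y * f)
  if (!is.finite(yf) || yf <= 0)
    stop("invalid-spectrum: frequency-mean lineal energy is not positive",
         call. = FALSE)
  num <- y0^2 * trapz(y, -expm1(-(y / y0)^2) * f)
  num / yf
}

#' @rdname compute_ystar
#' @export
ystar <- compute_ystar

#' Saturation-corrected dose-mean specific energy z1D*
#'
#' Converts y* (keV/um) to the dose-mean saturation-corrected specific
#' energy per event in a spherical domain,
#' z1D* = y* / (rho pi r_d^2), expressed in Gy via [KEV_TO_JOULE].
#'
#' @param ystar Saturation-corrected lineal energy, keV/um (>= 0).
#' @param geometry A [domain_geometry()].
#' @return z1D* in Gy. Scales linearly in y* and as r_d^-2.
#' @examples
#' compute_z1dstar(100, domain_geometry(r_d = 0.42))  # ~28.9 Gy
#' @export
compute_z1dstar <- function(ystar, geometry = domain_geometry()) {
  stopifnot(inherits(geometry, "domain_geometry"))
  if (any(!is.finite(ystar)) || any(ystar < 0))
    stop("ystar must be finite and non-negative", call. = FALSE)
  # y* [keV/um] -> [J/m]; mass per unit chord length rho*pi*r_d^2 [kg/m]
  (ystar * KEV_TO_JOULE * 1e6) / (geometry$rho * pi * (geometry$r_d * 1e-6)^2)
}

#' Parametric lineal-energy spectrum generator
#'
#' Emits a normalized lognormal spectrum standing in for a Monte Carlo
#' transport tally: the median lineal energy is tied to the nominal LET and
#' the log-scale spread to `width`. `width = 0` yields a single-line
#' (numerically, a very narrow triangular) spectrum at `let`, whose y_F
#' equals `let` exactly by symmetry. An optional seeded multiplicative
#' jitter emulates tally counting noise. This is test scaffolding, not
#' transport physics: only spectral moments enter the model.
#'
#' @param kind `"photon"` or `"ion"`; sets the label and the default width
#'   (photon spectra are broader in y relative to their median).
#' @param let Nominal LET, keV/um (> 0), used as the lognormal median.
#' @param width Relative (log-scale) spread; >= 0. Defaults to 0.5 for
#'   photon-like and 0.25 for ion-like spectra.
#' @param n Number of grid points for width > 0.
#' @param noise Relative amplitude of seeded lognormal bin jitter (default 0).
#' @param seed Integer seed controlling the jitter; the result is
#'   deterministic given (`let`, `width`, `noise`, `seed`).
#' @return An [mds_spectrum()].
#' @export
generate_spectrum <- function(kind = c("ion", "photon"), let, width = NULL,
                              n = 400, noise = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(let) || length(let) != 1L || !is.finite(let) || let <= 0)
    stop("let must be a single positive number", call. = FALSE)
  if (is.null(width)) width <- if (kind == "photon") 0.5 else 0.25
  if (width < 0) stop("width must be >= 0", call. = FALSE)
  label <- sprintf("%s-like, LET %.4g keV/um", kind, let)
  if (width == 0) {
    # narrow symmetric triangle: y_F = let exactly, moments to O(eps^2)
    eps <- 1e-5 * let
    return(mds_spectrum(c(let - eps, let, let + eps), c(0, 1, 0), meta = label))
  }
  lo <- max(log(let) - 6 * width, log(1e-3))
  y <- exp(seq(lo, log(let) + 6 * width, length.out = n))
  f <- stats::dlnorm(y, meanlog = log(let), sdlog = width)
  if (noise > 0) {
    rs <- local_rng(seed)
    f <- f * exp(rs$rnorm(length(f), 0, noise))
  }
  mds_spectrum(y, f, meta = label)
}

# private RNG stream that never disturbs the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
  list(
    rnorm = function(...) draw(stats::rnorm, ...),
    runif = function(...) draw(stats::runif, ...),
    rpois = function(...) draw(stats::rpois, ...),
    rlnorm = function(...) draw(stats::rlnorm, ...)
  )
}
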