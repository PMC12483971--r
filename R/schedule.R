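#' Irradiation schedule
#'
#' Piecewise-constant dose-rate time course. Segments must be chronological
#' and non-overlapping; gaps (beam-off intervals) are allowed and matter for
#' the Lea-Catcheside protraction factor.
#'
#' @param start_h Segment start times, h.
#' @param duration_h Segment durations, h (> 0).
#' @param rate_Gy_h Dose rates, Gy/h (>= 0).
#' @param label Free-text schedule label.
#' @return An object of class `irr_schedule` with the segment table and the
#'   derived total dose `D` (Gy) and overall delivery time `T` (h, start of
#'   first to end of last segment).
#' @seealso [continuous_schedule()], [fractionated_schedule()],
#'   [protraction_factor_schedule()]
#' @export
irradiation_schedule <- function(start_h, duration_h, rate_Gy_h, label = "") {
  n <- length(start_h)
  if (n == 0L || length(duration_h) != n || length(rate_Gy_h) != n)
    stop("schedule error: segment vectors must be non-empty and equal length",
         call. = FALSE)
  if (any(!is.finite(start_h)) || any(!is.finite(duration_h)) ||
      any(!is.finite(rate_Gy_h)))
    stop("schedule error: non-finite segment values", call. = FALSE)
  if (any(duration_h <= 0)) stop("schedule error: durations must be > 0",
                                 call. = FALSE)
  if (any(rate_Gy_h < 0)) stop("schedule error: dose rates must be >= 0",
                               call. = FALSE)
  o <- order(start_h)
  start_h <- start_h[o]; duration_h <- duration_h[o]; rate_Gy_h <- rate_Gy_h[o]
  ends <- start_h + duration_h
  if (n > 1L && any(start_h[-1] < ends[-n] - 1e-12))
    stop("schedule error: segments overlap", call. = FALSE)
  structure(list(
    segments = data.frame(start_h = start_h, duration_h = duration_h,
                          rate_Gy_h = rate_Gy_h),
    D = sum(duration_h * rate_Gy_h),
    T = ends[n] - start_h[1],
    label = label
  ), class = "irr_schedule")
}

#' @export
print.irr_schedule <- function(x, ...) {
  cat("Irradiation schedule", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n  ", nrow(x$segments), " segment(s), D = ", format(x$D, digits = 5),
      " Gy over T = ", format(x$T, digits = 5), " h\n", sep = "")
  invisible(x)
}

#' Single continuous exposure
#'
#' @param dose Total dose, Gy (> 0).
#' @param time_h Delivery time, h (> 0).
#' @param label Label.
#' @return An [irradiation_schedule()] with one segment at rate `dose/time_h`.
#' @export
continuous_schedule <- function(dose, time_h, label = "") {
  if (dose <= 0 || time_h <= 0)
    stop("schedule error: dose and time must be > 0", call. = FALSE)
  if (!nzchar(label))
    label <- sprintf("continuous %.3g Gy over %.3g h", dose, time_h)
  irradiation_schedule(0, time_h, dose / time_h, label)
}

#' Equal-fraction schedule
#'
#' `n_fractions` equal fractions, each delivered over `delivery_h` at
#' constant rate, separated by beam-off intervals of `interval_h`.
#'
#' @param dose_per_fraction Gy per fraction (> 0).
#' @param n_fractions Number of fractions (>= 1).
#' @param delivery_h Per-fraction delivery time, h.
#' @param interval_h Beam-off interval between consecutive fractions, h.
#' @param label Label.
#' @return An [irradiation_schedule()]. The nominal average dose rate over
#'   whole fraction cycles (delivery + interval) is stored as attribute
#'   `avg_rate_Gy_h`.
#' @export
fractionated_schedule <- function(dose_per_fraction, n_fractions, delivery_h,
                                  interval_h, label = "") {
  if (dose_per_fraction <= 0 || n_fractions < 1 || delivery_h <= 0 ||
      interval_h < 0)
    stop("schedule error: invalid fractionation parameters", call. = FALSE)
  starts <- (seq_len(n_fractions) - 1) * (delivery_h + interval_h)
  if (!nzchar(label))
    label <- sprintf("%d x %.3g Gy/Fr", n_fractions, dose_per_fraction)
  sch <- irradiation_schedule(starts, rep(delivery_h, n_fractions),
                              rep(dose_per_fraction / delivery_h, n_fractions),
                              label)
  attr(sch, "avg_rate_Gy_h") <-
    (n_fractions * dose_per_fraction) / (n_fractions * (delivery_h + interval_h))
  sch
}

# x + expm1(-x), guarded against cancellation at small x; equals
# x^2/2 - x^3/6 + ... for small x
protraction_g <- function(x) {
  out <- x + expm1(-x)
  small <- x < 1e-4
  if (any(small)) {
    xs <- x[small]
    out[small] <- xs^2 / 2 - xs^3 / 6 + xs^4 / 24
  }
  out
}

#' Lea-Catcheside factor for a single continuous exposure
#'
#' F = 2 [ (a+c)T + exp(-(a+c)T) - 1 ] / ((a+c)T)^2, the dose-protraction
#' factor multiplying the beta (dose-squared) term. F -> 1 in the acute
#' limit T -> 0 (evaluated by series to avoid cancellation) and
#' F ~ 2/((a+c)T) for long exposures.
#'
#' @param a_plus_c Sublethal-damage repair rate constant (a+c), 1/h (> 0).
#' @param T Delivery time, h (>= 0). Vectorized.
#' @return F in (0, 1].
#' @export
protraction_factor_continuous <- function(a_plus_c, T) {
  if (!is.numeric(a_plus_c) || any(a_plus_c <= 0))
    stop("a_plus_c must be > 0", call. = FALSE)
  if (any(T < 0)) stop("schedule error: negative delivery time", call. = FALSE)
  x <- a_plus_c * T
  out <- rep(1, length(x))
  nz <- x >= 1e-9
  out[nz] <- 2 * protraction_g(x[nz]) / x[nz]^2
  out
}

#' Lea-Catcheside factor for an arbitrary piecewise-constant schedule
#'
#' Evaluates the generalized dose-protraction factor
#' \deqn{F = \frac{2}{D^2} \int\!\!\int_{t'<t} \dot D(t)\dot D(t')
#'   e^{-(a+c)(t-t')}\,dt'\,dt}
#' in closed form per pair of constant-rate segments. A single-segment
#' schedule reproduces [protraction_factor_continuous()]; two short
#' fractions of D/2 separated by a gap dt reproduce the split-dose form
#' (1 + exp(-(a+c) dt))/2.
#'
#' @param schedule An [irradiation_schedule()] with total dose > 0.
#' @param a_plus_c Repair rate constant (a+c), 1/h (> 0).
#' @return F in (0, 1].
#' @export
protraction_factor_schedule <- function(schedule, a_plus_c) {
  stopifnot(inherits(schedule, "irr_schedule"))
  if (!is.numeric(a_plus_c) || length(a_plus_c) != 1L || a_plus_c <= 0)
    stop("a_plus_c must be a single positive number", call. = FALSE)
  if (schedule$D <= 0)
    stop("schedule error: zero-dose schedule", call. = FALSE)
  seg <- schedule$segments
  mu <- a_plus_c
  R <- seg$rate_Gy_h
  s <- seg$start_h
  tau <- seg$duration_h
  # same-segment contributions: R^2 * g(mu tau) / mu^2
  G <- sum(R^2 * protraction_g(mu * tau)) / mu^2
  n <- nrow(seg)
  if (n > 1L) {
    # cross terms for ordered pairs i < j:
    # R_i R_j (1-e^{-mu tau_i})(1-e^{-mu tau_j}) e^{-mu gap_ij} / mu^2
    e <- -expm1(-mu * tau)
    ends <- s + tau
    gap <- outer(s, ends, "-")          # gap[a, b] = start_a - end_b
    # lower triangle: row index a (later segment) > col index b (earlier),
    # so gap >= 0 for chronological non-overlapping segments
    ix <- which(lower.tri(gap), arr.ind = TRUE)
    i <- ix[, 1]; j <- ix[, 2]
    G <- G + sum(R[i] * R[j] * e[i] * e[j] * exp(-mu * gap[ix])) / mu^2
  }
  2 * G / schedule$D^2
}
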