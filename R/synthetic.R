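#' Assay noise model for synthetic dose-response data
#'
#' @param kind Noise mechanism: `"lognormal_s"` (multiplicative lognormal
#'   scatter on the surviving fraction, the default clonogenic-assay
#'   model), `"gaussian_lns"` (additive Gaussian on -ln S),
#'   `"gaussian_mn"` (Gaussian with SD proportional to the mean MN
#'   frequency) or `"poisson_mn"` (Poisson MN counts over a finite number
#'   of scored cells).
#' @param cv_or_sd Relative scale (CV) for the multiplicative kinds, or the
#'   absolute SD for `"gaussian_lns"`. >= 0; 0 reproduces the model curve
#'   exactly.
#' @param replicates Replicate measurements per dose point (>= 1).
#' @param cells_per_point Scored cells per replicate for `"poisson_mn"`
#'   (default 200, a typical MN-assay scoring depth).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("lognormal_s", "gaussian_lns", "gaussian_mn",
                                 "poisson_mn"),
                        cv_or_sd = 0.15, replicates = 3L,
                        cells_per_point = 200L, seed = 1L) {
  kind <- match.arg(kind)
  if (cv_or_sd < 0) stop("noise scale must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(kind = kind, cv_or_sd = cv_or_sd,
                 replicates = as.integer(replicates),
                 cells_per_point = as.integer(cells_per_point),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a noisy clonogenic-survival dataset
#'
#' Draws replicate surviving fractions around the IMK model curve and
#' records the per-dose mean, SD and replicate count. Noisy survival is
#' clamped at 1 (as when normalizing to an unirradiated control), so the
#' dataset always satisfies the S in (0, 1] invariant; because the model
#' curve passes through S(0) = 1 regardless of the parameters, the clamp
#' does not influence fitting.
#'
#' @param params A [cell_parameters()].
#' @param quality A [radiation_quality()]; default idealized photon.
#' @param schedule [irradiation_schedule()] or `NULL` for acute delivery.
#' @param doses Dose grid, Gy; default 0-8 Gy in 1-Gy steps (the range that
#'   identifies both LQ coefficients).
#' @param noise A [noise_model()] of kind `"lognormal_s"` or
#'   `"gaussian_lns"`.
#' @return A [dose_response()] with endpoint `"survival"`.
#' @export
simulate_survival_dataset <- function(params, quality = radiation_quality(0),
                                      schedule = NULL, doses = 0:8,
                                      noise = noise_model("lognormal_s", 0.15)) {
  stopifnot(inherits(params, "cell_params"), inherits(noise, "noise_model"))
  if (!noise$kind %in% c("lognormal_s", "gaussian_lns"))
    stop("survival noise must be lognormal_s or gaussian_lns", call. = FALSE)
  Fv <- if (is.null(schedule)) 1 else
    protraction_factor_schedule(schedule, params$a_plus_c)
  s_true <- surviving_fraction(params, quality, doses, Fv)
  if (noise$cv_or_sd == 0) {
    return(dose_response(doses, s_true, endpoint = "survival",
                         quality = quality, schedule = schedule,
                         label = paste0(params$label, " survival (noise-free)")))
  }
  rs <- local_rng(noise$seed)
  nrep <- noise$replicates
  sdlog <- if (noise$kind == "lognormal_s")
    sqrt(log1p(noise$cv_or_sd^2)) else noise$cv_or_sd
  reps <- vapply(s_true, function(s) {
    eps <- rs$rnorm(nrep, 0, sdlog)
    pmin(pmax(s * exp(eps), 1e-12), 1)
  }, numeric(nrep))
  reps <- matrix(reps, nrow = nrep)
  dose_response(doses, colMeans(reps),
                sd = apply(reps, 2, stats::sd), n_rep = nrep,
                endpoint = "survival", quality = quality, schedule = schedule,
                label = paste0(params$label, " survival (synthetic)"))
}

#' Simulate a noisy micronucleus dataset
#'
#' Replicate MN-per-cell measurements around the IMK MN curve, either with
#' Gaussian scatter proportional to the mean or as Poisson counts over a
#' finite number of scored cells.
#'
#' @inheritParams simulate_survival_dataset
#' @param noise A [noise_model()] of kind `"gaussian_mn"` or
#'   `"poisson_mn"`.
#' @return A [dose_response()] with endpoint `"mn_per_cell"`.
#' @export
simulate_mn_dataset <- function(params, quality = radiation_quality(0),
                                schedule = NULL, doses = 0:8,
                                noise = noise_model("gaussian_mn", 0.10)) {
  stopifnot(inherits(params, "cell_params"), inherits(noise, "noise_model"))
  if (!noise$kind %in% c("gaussian_mn", "poisson_mn"))
    stop("MN noise must be gaussian_mn or poisson_mn", call. = FALSE)
  Fv <- if (is.null(schedule)) 1 else
    protraction_factor_schedule(schedule, params$a_plus_c)
  mn_true <- mn_frequency(params, quality, doses, Fv)
  if (noise$kind == "gaussian_mn" && noise$cv_or_sd == 0) {
    return(dose_response(doses, mn_true, endpoint = "mn_per_cell",
                         quality = quality, schedule = schedule,
                         label = paste0(params$label, " MN (noise-free)")))
  }
  rs <- local_rng(noise$seed)
  nrep <- noise$replicates
  reps <- vapply(mn_true, function(m) {
    if (noise$kind == "poisson_mn")
      rs$rpois(nrep, m * noise$cells_per_point) / noise$cells_per_point
    else
      pmax(m + rs$rnorm(nrep, 0, noise$cv_or_sd * m), 0)
  }, numeric(nrep))
  reps <- matrix(reps, nrow = nrep)
  dose_response(doses, colMeans(reps),
                sd = apply(reps, 2, stats::sd), n_rep = nrep,
                endpoint = "mn_per_cell", quality = quality,
                schedule = schedule,
                label = paste0(params$label, " MN (synthetic)"))
}

#' Standard dose-rate study regimens
#'
#' The four X-ray delivery regimens of the dose-rate experiment: continuous
#' delivery at 1.0 Gy/min, and fractionated deliveries of 0.5 Gy/fraction
#' (30 s beam-on at 1 Gy/min, 30 s intervals), 0.1 Gy/fraction (6 s beam-on,
#' 54 s intervals) and 0.05 Gy/fraction (3 s beam-on, 57 s intervals). Each
#' sums to `total_dose`, and the nominal average dose rates over whole
#' fraction cycles are 1.0, 0.5, 0.1 and 0.05 Gy/min.
#'
#' @param total_dose Total dose per regimen, Gy (> 0); default 4 Gy.
#' @return Named list of four [irradiation_schedule()] objects
#'   (`"1.0"`, `"0.5"`, `"0.1"`, `"0.05"`, by average Gy/min), each with
#'   attribute `avg_rate_Gy_h`.
#' @export
doserate_schedules <- function(total_dose = 4) {
  if (total_dose <= 0) stop("total_dose must be > 0", call. = FALSE)
  cont <- continuous_schedule(total_dose, total_dose / 60,
                              label = "continuous 1.0 Gy/min")
  attr(cont, "avg_rate_Gy_h") <- 60
  frac <- function(dpf, beam_s, gap_s, lab) {
    n <- round(total_dose / dpf)
    if (abs(n * dpf - total_dose) > 1e-9)
      stop("total_dose must be a multiple of ", dpf, " Gy", call. = FALSE)
    fractionated_schedule(dpf, n, beam_s / 3600, gap_s / 3600, label = lab)
  }
  list(
    "1.0"  = cont,
    "0.5"  = frac(0.5, 30, 30, "0.5 Gy/Fr @ 0.5 Gy/min"),
    "0.1"  = frac(0.1, 6, 54, "0.1 Gy/Fr @ 0.1 Gy/min"),
    "0.05" = frac(0.05, 3, 57, "0.05 Gy/Fr @ 0.05 Gy/min")
  )
}

#' Synthetic survival-MN pairs for h estimation
#'
#' Generates (-ln S, MN per cell) pairs spanning a lethal-lesion range,
#' applies proportional Gaussian noise to the MN values, and returns the
#' data frame expected by [estimate_h()].
#'
#' @param h Generating MN-formation probability.
#' @param n Number of pairs.
#' @param w_range Range of -ln S covered (uniform spacing).
#' @param cv Relative Gaussian noise on MN (default 0.10).
#' @param seed Integer seed.
#' @return Data frame with columns `w` and `mn`.
#' @export
simulate_survival_mn_pairs <- function(h = 0.275, n = 50,
                                       w_range = c(0.1, 4), cv = 0.10,
                                       seed = 1L) {
  if (h < 0 || h > 1) stop("h must lie in [0, 1]", call. = FALSE)
  w <- seq(w_range[1], w_range[2], length.out = n)
  mn <- h * w
  if (cv > 0) {
    rs <- local_rng(seed)
    mn <- pmax(mn + rs$rnorm(n, 0, cv * mn), 0)
  }
  data.frame(w = w, mn = mn)
}
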