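# Independent numerical oracle for the generalized Lea-Catcheside factor:
# midpoint-rule discretization of the double integral
#   F = 2/D^2 * int int_{t'<t} R(t) R(t') exp(-mu (t - t')) dt' dt
# with the exponential kernel evaluated exactly between grid cells.
# O(dt^2) accurate; entirely independent of the closed-form
# per-segment-pair implementation in the package.
num_protraction_factor <- function(schedule, mu, m = NULL) {
  # midpoint-rule value on cell size dt has O(dt^2) error; Richardson
  # extrapolation over the halved grid removes it
  if (is.null(m)) m <- max(4L, min(250L, 3000L %/% nrow(schedule$segments)))
  (4 * num_pf_grid(schedule, mu, 2L * m) - num_pf_grid(schedule, mu, m)) / 3
}

num_pf_grid <- function(schedule, mu, m) {
  seg <- schedule$segments
  # midpoint cells aligned to segment boundaries, so the piecewise-constant
  # rate is represented exactly; cross-cell kernels use the O(dt^2)
  # midpoint value and within-cell triangles the elementary exact integral
  tm <- numeric(0); wt <- numeric(0); dts <- numeric(0)
  for (k in seq_len(nrow(seg))) {
    dt <- seg$duration_h[k] / m
    tm <- c(tm, seg$start_h[k] + (seq_len(m) - 0.5) * dt)
    wt <- c(wt, rep(seg$rate_Gy_h[k] * dt, m))
    dts <- c(dts, rep(dt, m))
  }
  K <- exp(-mu * abs(outer(tm, tm, "-")))
  cross <- sum(wt * (K %*% wt)) - sum(wt^2)   # ordered pairs, both orders
  x <- mu * dts
  within <- sum((wt / x)^2 * (x + exp(-x) - 1))
  G <- cross / 2 + within
  D <- sum(seg$duration_h * seg$rate_Gy_h)
  2 * G / D^2
}

# random piecewise schedule with up to max_seg segments and gaps
random_schedule <- function(max_seg = 6L) {
  n <- sample.int(max_seg, 1L)
  dur <- stats::runif(n, 0.02, 1.5)
  gap <- stats::runif(n, 0, 2)
  starts <- cumsum(c(0, (dur + gap)[-n]))
  irradiation_schedule(starts, dur, stats::runif(n, 0.2, 30))
}

# reference cell-line parameter sets used across tests
params_hsg <- function() cell_parameters(0.150, 0.0467, 2.19, r_d = 0.42,
                                         h_mn = 0.275, label = "HSG")
params_wi38 <- function() cell_parameters(0.590, 0.0163, 0.371, r_d = 0.50,
                                          h_mn = 0.275, label = "WI-38")
params_du145 <- function() cell_parameters(0.0774, 0.0380, 2.10, r_d = 0.50,
                                           h_mn = 0.275, label = "DU145")
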