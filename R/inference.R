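#' MCMC fit configuration
#'
#' Settings for the Metropolis sampler used throughout the package:
#' uniform prior bounds per parameter, noise-model policy, chain lengths
#' and the proposal mechanism.
#'
#' @param priors Named list of length-2 numeric bounds (lower, upper) for
#'   any of `alpha0`, `beta0`, `alpha_m0`, `beta_m0`, `a_plus_c`, `h`.
#'   Missing entries fall back to the defaults `alpha0 = c(0, 2)` Gy^-1,
#'   `beta0 = c(0, 0.5)` Gy^-2, `a_plus_c = c(0.05, 10)` 1/h,
#'   `h = c(0, 1)`; the MN coefficients share the survival bounds.
#' @param n_burn Burn-in iterations (default 1e3).
#' @param n_samples Retained post-burn-in iterations (default 1e4).
#' @param seed Integer seed; chains are bit-reproducible given the seed.
#' @param proposal `"independence"` (candidates drawn afresh from the
#'   uniform prior, the literal reading of a prior-based candidate
#'   generator) or `"walk"` (Gaussian random walk, more efficient for
#'   joint fits of three or more parameters).
#' @param walk_scale Optional named vector of random-walk SDs; defaults to
#'   5 percent of each prior range.
#' @param adapt For `"walk"`: tune scales toward ~30 percent acceptance
#'   during burn-in only (frozen afterwards, so the retained chain is a
#'   valid Metropolis chain). Default TRUE.
#' @param sigma Optional fixed noise SD (on the -ln S scale for survival,
#'   on the MN scale for MN fits); overrides `sigma_policy`.
#' @param sigma_policy `"fit"` (default: one common noise SD sampled
#'   jointly with the model parameters under a Jeffreys-type prior, uniform
#'   in log sigma around a preliminary least-squares estimate, so that
#'   credible bands carry the noise-scale uncertainty), `"pooled"` (plug in
#'   the preliminary least-squares residual SD as a constant) or
#'   `"per_point"` (use recorded per-point SDs, converted to standard
#'   errors via the replicate count, with unstable or missing entries
#'   floored at a fraction of the pooled estimate). Replicate SDs from very
#'   small replicate counts are noisy, and inverse-variance weighting by
#'   them yields overconfident posteriors; the `"fit"` default keeps
#'   credible intervals calibrated.
#' @param a_plus_c Optional fixed (a+c) value, 1/h. When supplied, (a+c)
#'   is not sampled even if protracted datasets are present.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(priors = list(), n_burn = 1000L, n_samples = 10000L,
                       seed = 1L, proposal = c("independence", "walk"),
                       walk_scale = NULL, adapt = TRUE, sigma = NULL,
                       sigma_policy = c("fit", "pooled", "per_point"),
                       a_plus_c = NULL) {
  proposal <- match.arg(proposal)
  sigma_policy <- match.arg(sigma_policy)
  if (n_burn < 1 || n_samples < 1)
    stop("config error: n_burn and n_samples must be positive", call. = FALSE)
  if (!is.null(sigma) && sigma <= 0)
    stop("config error: sigma must be positive", call. = FALSE)
  defaults <- list(alpha0 = c(0, 2), beta0 = c(0, 0.5),
                   alpha_m0 = c(0, 2), beta_m0 = c(0, 0.5),
                   a_plus_c = c(0.05, 10), h = c(0, 1))
  for (nm in names(priors)) {
    b <- priors[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("config error: prior bounds must be finite with lower < upper",
           call. = FALSE)
    defaults[[nm]] <- b
  }
  structure(list(priors = defaults, n_burn = as.integer(n_burn),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 proposal = proposal, walk_scale = walk_scale, adapt = adapt,
                 sigma = sigma, sigma_policy = sigma_policy,
                 a_plus_c = a_plus_c),
            class = "fit_config")
}

# normalize data argument to a list of dose_response objects
as_dataset_list <- function(data) {
  if (inherits(data, "dose_response")) data <- list(data)
  if (!is.list(data) || !length(data) ||
      !all(vapply(data, inherits, logical(1), "dose_response")))
    stop("data must be a dose_response or a list of them", call. = FALSE)
  data
}

# residual-scale view of a dataset: y (fit scale), dose, z1D*, schedule,
# standard error of y where derivable from recorded sd/n_rep
fit_view <- function(ds, model_kind) {
  rec <- ds$records
  if (model_kind == "survival") {
    if (ds$endpoint != "survival")
      stop("dataset endpoint does not match survival model", call. = FALSE)
    y <- -log(rec$value)
    se <- rec$sd / rec$value        # delta method onto -ln S
  } else {
    if (!ds$endpoint %in% c("mn_per_cell", "mn_fraction"))
      stop("dataset endpoint does not match MN model", call. = FALSE)
    y <- rec$value
    if (ds$endpoint == "mn_fraction") {
      # Poisson link: fraction of MN-bearing cells = 1 - exp(-F_MN)
      if (any(rec$value >= 1))
        stop("mn_fraction values must be < 1 for the Poisson link",
             call. = FALSE)
      y <- -log1p(-rec$value)
      se <- rec$sd / (1 - rec$value)
    } else se <- rec$sd
  }
  nr <- ifelse(is.na(rec$n_rep), 1, rec$n_rep)
  list(dose = rec$dose, y = y, se = se / sqrt(nr),
       z = ds$quality$z1dstar, schedule = ds$schedule)
}

# pooled residual SD from a linear least-squares fit (the model is linear
# in (alpha, beta) once F is fixed); ac0 fixes F for protracted data
pooled_sigma <- function(views, ac0) {
  x1 <- numeric(0); x2 <- numeric(0); yy <- numeric(0)
  for (v in views) {
    Fv <- if (is.null(v$schedule)) 1 else
      protraction_factor_schedule(v$schedule, ac0)
    x1 <- c(x1, v$dose)
    x2 <- c(x2, v$z * v$dose + Fv * v$dose^2)
    yy <- c(yy, v$y)
  }
  keep <- x1 > 0
  if (sum(keep) < 3L) return(max(stats::sd(yy), 1e-3))
  fit <- stats::lm.fit(cbind(x1[keep], x2[keep]), yy[keep])
  sqrt(sum(fit$residuals^2) / max(1L, sum(keep) - 2L))
}

# per-view sigma vectors under the configured policy
build_sigmas <- function(views, config, ac0) {
  if (!is.null(config$sigma))
    return(lapply(views, function(v) rep(config$sigma, length(v$y))))
  pool <- pooled_sigma(views, ac0)
  lapply(views, function(v) {
    if (config$sigma_policy == "pooled") return(rep(pool, length(v$y)))
    s <- v$se
    # replicate SDs from small replicate counts are unstable; floor them
    # at a fraction of the pooled scale and fill missing entries
    s[!is.finite(s) | s <= 0] <- pool
    pmax(s, 0.25 * pool)
  })
}

#' Gaussian log-likelihood of a dose-response dataset
#'
#' The fit criterion used by the sampler: independent Gaussian residuals
#' on -ln S for survival data (or on the MN frequency for MN data) between
#' the observations and the model curve.
#'
#' @param dataset A [dose_response()] (or list of them).
#' @param theta Named parameter vector containing `alpha0`/`beta0` (or
#'   `alpha_m0`/`beta_m0` for MN data) and optionally `a_plus_c`.
#' @param sigma Noise SD (scalar, recycled).
#' @param model_kind `"survival"` or `"mn"`; default chosen from the first
#'   dataset's endpoint.
#' @return Total log-likelihood (finite for positive sigma).
#' @export
log_likelihood <- function(dataset, theta, sigma, model_kind = NULL) {
  if (missing(sigma) || !is.numeric(sigma) || any(sigma <= 0))
    stop("config error: sigma must be positive", call. = FALSE)
  data <- as_dataset_list(dataset)
  if (is.null(model_kind))
    model_kind <- if (data[[1]]$endpoint == "survival") "survival" else "mn"
  views <- lapply(data, fit_view, model_kind = model_kind)
  a <- theta[[if (model_kind == "survival") "alpha0" else "alpha_m0"]]
  b <- theta[[if (model_kind == "survival") "beta0" else "beta_m0"]]
  ac <- if ("a_plus_c" %in% names(theta)) theta[["a_plus_c"]] else NULL
  ll <- 0
  for (v in views) {
    Fv <- if (is.null(v$schedule)) 1 else {
      if (is.null(ac))
        stop("a_plus_c required for protracted datasets", call. = FALSE)
      protraction_factor_schedule(v$schedule, ac)
    }
    pred <- (a + v$z * b) * v$dose + Fv * b * v$dose^2
    ll <- ll + sum(stats::dnorm(v$y, pred, sigma, log = TRUE))
  }
  ll
}

#' Metropolis MCMC fit of the IMK dose-response model
#'
#' Samples (alpha0, beta0) -- or (alpha_m0, beta_m0) for MN data -- and,
#' when protracted datasets are present and no fixed value is supplied,
#' the repair rate (a+c), from the posterior under uniform priors and a
#' Gaussian likelihood on -ln S (survival) or on the MN frequency.
#' Candidates are accepted with probability min(1, posterior ratio).
#'
#' @param data A [dose_response()] or a list of them (e.g. several
#'   schedules or qualities fitted jointly). At least 3 records in total.
#' @param config A [fit_config()].
#' @param model_kind `"survival"` or `"mn"`; default inferred from the
#'   first dataset.
#' @return An object of class `posterior_samples`: `draws` (n_samples x p
#'   matrix), `param_names`, `acceptance_rate`, `config`, `sigma` (the
#'   noise SDs used), and `lp` (log-posterior trace).
#' @examples
#' hsg <- cell_parameters(0.150, 0.0467, 2.19, label = "HSG")
#' ds <- simulate_survival_dataset(hsg, doses = 0:8,
#'   noise = noise_model("lognormal_s", 0.15, replicates = 3, seed = 7))
#' fit <- mcmc_fit(ds, fit_config(n_burn = 200, n_samples = 500, seed = 1))
#' summary(fit)
#' @export
mcmc_fit <- function(data, config = fit_config(), model_kind = NULL) {
  data <- as_dataset_list(data)
  stopifnot(inherits(config, "fit_config"))
  if (is.null(model_kind))
    model_kind <- if (data[[1]]$endpoint == "survival") "survival" else "mn"
  model_kind <- match.arg(model_kind, c("survival", "mn"))
  views <- lapply(data, fit_view, model_kind = model_kind)
  if (sum(vapply(views, function(v) length(v$y), integer(1))) < 3L)
    stop("validation error: at least 3 records are required for fitting",
         call. = FALSE)
  protracted <- any(!vapply(views, function(v) is.null(v$schedule), logical(1)))
  fit_ac <- protracted && is.null(config$a_plus_c)
  names_ab <- if (model_kind == "survival") c("alpha0", "beta0") else
    c("alpha_m0", "beta_m0")
  fit_sigma <- is.null(config$sigma) && config$sigma_policy == "fit"
  pnames <- c(names_ab, if (fit_ac) "a_plus_c", if (fit_sigma) "log_sigma")
  ac_prior_mid <- mean(config$priors[["a_plus_c"]])
  ac0 <- if (!is.null(config$a_plus_c)) config$a_plus_c else
    if (protracted) ac_prior_mid else 1
  pool <- pooled_sigma(views, ac0)
  sigmas <- build_sigmas(views, config, ac0)
  lo <- hi <- numeric(length(pnames))
  for (k in seq_along(pnames)) {
    if (pnames[k] == "log_sigma") {
      # Jeffreys-type prior: uniform in log sigma, generous bounds around
      # the preliminary least-squares scale
      lo[k] <- log(pool) - log(20); hi[k] <- log(pool) + log(20)
    } else {
      lo[k] <- config$priors[[pnames[k]]][1]
      hi[k] <- config$priors[[pnames[k]]][2]
    }
  }
  i_sig <- if (fit_sigma) length(pnames) else 0L

  logpost <- function(th) {
    if (any(th < lo) || any(th > hi)) return(-Inf)
    a <- th[1]; b <- th[2]
    ac <- if (fit_ac) th[3] else ac0
    ll <- 0
    for (k in seq_along(views)) {
      v <- views[[k]]
      Fv <- if (is.null(v$schedule)) 1 else
        protraction_factor_schedule(v$schedule, ac)
      pred <- (a + v$z * b) * v$dose + Fv * b * v$dose^2
      sig <- if (fit_sigma) exp(th[i_sig]) else sigmas[[k]]
      ll <- ll + sum(stats::dnorm(v$y, pred, sig, log = TRUE))
    }
    ll
  }

  p <- length(pnames)
  n_total <- config$n_burn + config$n_samples
  set.seed(config$seed)
  scale <- config$walk_scale
  if (is.null(scale)) scale <- 0.05 * (hi - lo)
  if (length(scale) == 1L) scale <- rep(scale, p)
  # start at a prior draw with finite posterior
  theta <- lo + stats::runif(p) * (hi - lo)
  lp <- logpost(theta)
  tries <- 0L
  while (!is.finite(lp) && tries < 100L) {
    theta <- lo + stats::runif(p) * (hi - lo)
    lp <- logpost(theta)
    tries <- tries + 1L
  }
  if (!is.finite(lp))
    stop("numerical failure: could not find a starting point with finite posterior",
         call. = FALSE)
  draws <- matrix(NA_real_, config$n_samples, p,
                  dimnames = list(NULL, pnames))
  lptrace <- numeric(config$n_samples)
  burn_store <- matrix(NA_real_, config$n_burn, p)
  chol_prop <- NULL   # covariance-shaped proposal, learned in burn-in only
  gscale <- 1
  acc_post <- 0L
  win_acc <- 0L
  for (it in seq_len(n_total)) {
    cand <- if (config$proposal == "independence")
      lo + stats::runif(p) * (hi - lo)
    else if (is.null(chol_prop))
      theta + stats::rnorm(p, 0, scale)
    else
      theta + gscale * drop(stats::rnorm(p) %*% chol_prop)
    lpc <- logpost(cand)
    if (is.finite(lpc) && log(stats::runif(1)) < lpc - lp) {
      theta <- cand; lp <- lpc
      if (it > config$n_burn) acc_post <- acc_post + 1L
      win_acc <- win_acc + 1L
    }
    if (it <= config$n_burn) {
      burn_store[it, ] <- theta
      if (config$proposal == "walk" && config$adapt) {
        if (it %% 50L == 0L) {
          # global acceptance tuning runs through the whole burn-in, both
          # before and after the covariance shape is learned
          adj <- exp(win_acc / 50 - 0.3)
          if (is.null(chol_prop)) scale <- scale * adj else
            gscale <- gscale * adj
          win_acc <- 0L
        }
        if (it >= max(200L, config$n_burn %/% 2L) &&
            (it == max(200L, config$n_burn %/% 2L) || it == config$n_burn)) {
          # adaptive-Metropolis shape from the recent half of the burn-in
          # history, after the chain has localized; frozen once sampling
          # starts so the retained chain is a valid Metropolis chain
          win <- burn_store[seq(it %/% 2L, it), , drop = FALSE]
          C <- 2.38^2 / p * stats::cov(win) + diag((1e-4 * (hi - lo))^2, p)
          chol_prop <- chol(C)
          gscale <- 1
        }
      }
    } else {
      draws[it - config$n_burn, ] <- theta
      lptrace[it - config$n_burn] <- lp
    }
  }
  if (acc_post == 0L)
    stop(paste("diagnostics error: no accepted moves after burn-in.",
               "Widen walk_scale, narrow the priors toward the data, or",
               "switch proposal type."), call. = FALSE)
  structure(list(draws = draws, param_names = pnames,
                 acceptance_rate = acc_post / config$n_samples,
                 config = config, model_kind = model_kind,
                 sigma = sigmas, lp = lptrace),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("Metropolis posterior:", nrow(x$draws), "draws of (",
      paste(x$param_names, collapse = ", "), "), acceptance rate",
      format(x$acceptance_rate, digits = 3), "\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.posterior_samples <- function(object, probs = c(0.16, 0.5, 0.84), ...) {
  d <- object$draws
  out <- data.frame(mean = colMeans(d), sd = apply(d, 2, stats::sd))
  q <- t(apply(d, 2, stats::quantile, probs = probs))
  colnames(q) <- paste0("q", format(100 * probs, trim = TRUE))
  cbind(out, q)
}

#' MN-formation probability h from survival-MN pairs
#'
#' Fits the through-origin proportionality F_MN = h <w> between the mean
#' lethal-lesion number <w> = -ln S and the MN frequency, pooled across
#' cell lines and radiation qualities (h cancels the quality dependence).
#' The default route is the package's Metropolis sampler, so the reported
#' SD is a posterior SD; a closed-form weighted least-squares estimate is
#' always returned alongside.
#'
#' @param pairs Data frame with columns `w` (-ln S, >= 0) and `mn`
#'   (MN per cell, >= 0); optional column `sd`.
#' @param config A [fit_config()]; the prior for `h` defaults to
#'   uniform(0, 1).
#' @param method `"mcmc"` (default) or `"wls"`.
#' @return List with `mean`, `sd`, `draws` (NULL for `"wls"`), `h_wls`,
#'   and `sigma` (noise SD used).
#' @export
estimate_h <- function(pairs, config = fit_config(), method = c("mcmc", "wls")) {
  method <- match.arg(method)
  if (!is.data.frame(pairs) || !all(c("w", "mn") %in% names(pairs)) ||
      nrow(pairs) < 2L)
    stop("pairs must be a data frame with columns w and mn (>= 2 rows)",
         call. = FALSE)
  if (any(pairs$w < 0) || any(pairs$mn < 0))
    stop("w and mn must be non-negative", call. = FALSE)
  if (all(pairs$w == 0))
    stop("degenerate-data error: all lethal-lesion numbers are zero",
         call. = FALSE)
  w <- pairs$w; mn <- pairs$mn
  h_wls <- sum(w * mn) / sum(w^2)
  if (!is.null(config$sigma)) {
    sig <- rep(config$sigma, length(w))
  } else if ("sd" %in% names(pairs) && all(is.finite(pairs$sd)) &&
             all(pairs$sd > 0)) {
    sig <- pairs$sd
  } else {
    sig <- rep(max(sqrt(sum((mn - h_wls * w)^2) / max(1, length(w) - 1)),
                   1e-6), length(w))
  }
  if (method == "wls") {
    vr <- 1 / sum(w^2 / sig^2)
    return(list(mean = h_wls, sd = sqrt(vr), draws = NULL, h_wls = h_wls,
                sigma = sig))
  }
  bounds <- config$priors[["h"]]
  set.seed(config$seed)
  n_total <- config$n_burn + config$n_samples
  h <- stats::runif(1, bounds[1], bounds[2])
  lpost <- function(h) sum(stats::dnorm(mn, h * w, sig, log = TRUE))
  lp <- lpost(h)
  draws <- numeric(config$n_samples)
  acc <- 0L
  for (it in seq_len(n_total)) {
    cand <- if (config$proposal == "independence")
      stats::runif(1, bounds[1], bounds[2])
    else h + stats::rnorm(1, 0, 0.02 * diff(bounds))
    if (cand >= bounds[1] && cand <= bounds[2]) {
      lpc <- lpost(cand)
      if (log(stats::runif(1)) < lpc - lp) {
        h <- cand; lp <- lpc
        if (it > config$n_burn) acc <- acc + 1L
      }
    }
    if (it > config$n_burn) draws[it - config$n_burn] <- h
  }
  if (acc == 0L)
    stop("diagnostics error: no accepted moves after burn-in in h fit",
         call. = FALSE)
  list(mean = mean(draws), sd = stats::sd(draws), draws = draws,
       h_wls = h_wls, sigma = sig, acceptance_rate = acc / config$n_samples)
}

#' Calibrate the domain radius against multi-LET survival data
#'
#' Deterministic grid search replicating the iterative manual loop used to
#' pin the domain radius: for each candidate r_d the z1D* of every dataset
#' is recomputed from its attached spectrum and the summed squared residual
#' on -ln S against the model at the supplied (alpha0, beta0) is recorded.
#' Ties break toward the smaller radius. Photon-only data leave z1D* ~ 0
#' and an essentially flat profile; a warning is raised in that case.
#'
#' @param datasets List of [dose_response()] survival datasets, each
#'   carrying a `spectrum`.
#' @param fit A `posterior_samples` object from [mcmc_fit()] (posterior
#'   means are used) or a named list/vector with `alpha0`, `beta0` and
#'   optionally `a_plus_c`.
#' @param rd_grid Candidate radii, um (non-empty, > 0).
#' @param rho,y0 Domain density (kg/m^3) and saturation parameter (keV/um).
#' @return List with `r_d` (argmin), `profile` (data frame of `r_d`,
#'   `rss`), and the parameter values used.
#' @export
calibrate_rd <- function(datasets, fit, rd_grid, rho = 1000, y0 = 150) {
  datasets <- as_dataset_list(datasets)
  if (!length(rd_grid)) stop("config error: empty r_d grid", call. = FALSE)
  if (any(rd_grid <= 0)) stop("config error: r_d grid must be > 0", call. = FALSE)
  if (inherits(fit, "posterior_samples")) {
    m <- colMeans(fit$draws)
    alpha0 <- m[[1]]; beta0 <- m[[2]]
    ac <- if ("a_plus_c" %in% colnames(fit$draws)) m[["a_plus_c"]] else
      if (!is.null(fit$config$a_plus_c)) fit$config$a_plus_c else 2
  } else {
    alpha0 <- fit[["alpha0"]]; beta0 <- fit[["beta0"]]
    ac <- if ("a_plus_c" %in% names(fit)) fit[["a_plus_c"]] else 2
  }
  rd_grid <- sort(rd_grid)
  ystars <- lapply(datasets, function(ds) {
    if (is.null(ds$spectrum))
      stop("every dataset must carry a spectrum for r_d calibration",
           call. = FALSE)
    compute_ystar(ds$spectrum, y0)
  })
  rss <- vapply(rd_grid, function(rd) {
    geom <- domain_geometry(r_d = rd, rho = rho, y0 = y0)
    tot <- 0
    for (k in seq_along(datasets)) {
      ds <- datasets[[k]]
      z <- compute_z1dstar(ystars[[k]], geom)
      Fv <- if (is.null(ds$schedule)) 1 else
        protraction_factor_schedule(ds$schedule, ac)
      pred <- (alpha0 + z * beta0) * ds$records$dose +
        Fv * beta0 * ds$records$dose^2
      tot <- tot + sum((-log(ds$records$value) - pred)^2)
    }
    tot
  }, numeric(1))
  signal <- sum(vapply(datasets, function(ds) sum(log(ds$records$value)^2),
                       numeric(1)))
  if (diff(range(rss)) <= 1e-3 * max(signal, 1e-12))
    warning("residual profile is flat: r_d is not identifiable ",
            "(photon-only or z1D*-insensitive data)", call. = FALSE)
  list(r_d = rd_grid[which.min(rss)],
       profile = data.frame(r_d = rd_grid, rss = rss),
       alpha0 = alpha0, beta0 = beta0, a_plus_c = ac)
}

#' Propagate posterior uncertainty to a prediction
#'
#' Evaluates a prediction function over every posterior draw and returns
#' the pointwise mean and an equal-tailed credible band.
#'
#' @param samples A `posterior_samples` object from [mcmc_fit()].
#' @param prediction_fn Function taking one named parameter vector (a draw)
#'   and returning a numeric vector (e.g. a survival or MN curve on a dose
#'   grid).
#' @param level Credible level, typically 0.68 or 0.95.
#' @param max_draws Optional cap on the number of draws evaluated (evenly
#'   thinned); default uses all draws.
#' @return List with `mean`, `lower`, `upper` (numeric vectors) and `level`.
#' @export
propagate_uncertainty <- function(samples, prediction_fn, level = 0.68,
                                  max_draws = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  d <- samples$draws
  if (!is.null(max_draws) && max_draws < nrow(d))
    d <- d[seq(1L, nrow(d), length.out = max_draws), , drop = FALSE]
  preds <- apply(d, 1L, function(th) prediction_fn(stats::setNames(th, colnames(d))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  a <- (1 - level) / 2
  list(mean = rowMeans(preds),
       lower = apply(preds, 1L, stats::quantile, probs = a),
       upper = apply(preds, 1L, stats::quantile, probs = 1 - a),
       level = level)
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot between observed and predicted values.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 values).
#' @return R^2; 1 for a perfect prediction, 0 for predicting the mean.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("observed and predicted must be equal-length with >= 2 values",
         call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("undefined-R2 error: observed values are all equal", call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}
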