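#' Read a lineal-energy spectrum file
#'
#' Accepts the two-column spectrum dialect: lineal energy y (keV/um) and a
#' density value, whitespace- or comma-separated, `#` comments, header row
#' optional. The density is `f(y)` by default; `dialect = "dy"` declares a
#' dose-weighted `d(y)` input, converted internally via f(y) ~ d(y)/y.
#' The spectrum is renormalized on load.
#'
#' @param path File path.
#' @param dialect `"fy"` (default) or `"dy"`.
#' @param meta Label; defaults to the file name.
#' @return An [mds_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("fy", "dy"), meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2L)
    stop("parse error: spectrum file needs at least 2 data rows", call. = FALSE)
  sep <- if (any(grepl(",", lines[idx]))) "," else ""
  parse_row <- function(i) {
    parts <- if (sep == ",") strsplit(lines[i], ",")[[1]] else
      strsplit(trimws(lines[i]), "\\s+")[[1]]
    suppressWarnings(as.numeric(trimws(parts)))
  }
  first <- parse_row(idx[1])
  if (all(is.na(first))) idx <- idx[-1]  # header row
  vals <- lapply(idx, parse_row)
  bad <- idx[vapply(vals, function(v) length(v) < 2L || any(is.na(v[1:2])),
                    logical(1))]
  if (length(bad))
    stop("parse error: malformed spectrum row(s) at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  y <- vapply(vals, `[`, numeric(1), 1L)
  f <- vapply(vals, `[`, numeric(1), 2L)
  if (any(diff(y) <= 0))
    stop("dialect error: lineal-energy column must be strictly increasing",
         call. = FALSE)
  mds_spectrum(y, f, meta = if (is.null(meta)) basename(path) else meta,
               dialect = dialect)
}

#' Write a lineal-energy spectrum file
#'
#' Emits the same two-column dialect that [read_spectrum()] accepts, with
#' the label as a `#` comment. Round-tripping preserves y* to near machine
#' precision.
#'
#' @param spectrum An [mds_spectrum()].
#' @param path Output path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "mds_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#", spectrum$meta), "# y_keV_um  f_y"), con)
  writeLines(sprintf("%.17g %.17g", spectrum$y_grid, spectrum$density), con)
  invisible(path)
}

#' Read a dose-response dataset CSV
#'
#' Expects columns `dose_Gy` and `value`; optional `sd`, `n_rep`,
#' `endpoint` (constant per file), `quality_label`, `schedule_label`.
#' Rows violating the endpoint's range (e.g. survival outside (0, 1]) are
#' rejected with their row numbers.
#'
#' @param path CSV path.
#' @param endpoint Endpoint override; default taken from the `endpoint`
#'   column or `"survival"`.
#' @param quality,schedule Optional [radiation_quality()] /
#'   [irradiation_schedule()] to attach (labels in the file are
#'   informative only).
#' @return A [dose_response()].
#' @export
read_dose_response <- function(path, endpoint = NULL,
                               quality = radiation_quality(0),
                               schedule = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  if (!all(c("dose_Gy", "value") %in% names(df)))
    stop("parse error: columns dose_Gy and value are required", call. = FALSE)
  if (is.null(endpoint))
    endpoint <- if ("endpoint" %in% names(df)) as.character(df$endpoint[1]) else
      "survival"
  lab <- if ("quality_label" %in% names(df)) as.character(df$quality_label[1]) else
    basename(path)
  dose_response(df$dose_Gy, df$value,
                sd = if ("sd" %in% names(df)) df$sd else NULL,
                n_rep = if ("n_rep" %in% names(df)) df$n_rep else NULL,
                endpoint = endpoint, quality = quality, schedule = schedule,
                label = lab)
}

#' Write a dose-response dataset CSV
#'
#' @param dataset A [dose_response()].
#' @param path Output path.
#' @export
write_dose_response <- function(dataset, path) {
  stopifnot(inherits(dataset, "dose_response"))
  df <- dataset$records
  names(df)[1] <- "dose_Gy"
  df$endpoint <- dataset$endpoint
  df$quality_label <- dataset$quality$label
  df$schedule_label <- if (is.null(dataset$schedule)) "acute" else
    dataset$schedule$label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cell parameters from JSON or YAML
#'
#' Keys: `alpha0`, `beta0`, `a_plus_c`, `r_d`, `h` (or `h_mn`), optional
#' `label`. The format is chosen by file extension.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return A [cell_parameters()].
#' @export
read_cell_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  h <- if (!is.null(x$h_mn)) x$h_mn else x$h
  if (is.null(x$alpha0) || is.null(x$beta0) || is.null(x$a_plus_c) ||
      is.null(h))
    stop("parse error: alpha0, beta0, a_plus_c and h are required",
         call. = FALSE)
  cell_parameters(x$alpha0, x$beta0, x$a_plus_c,
                  r_d = if (is.null(x$r_d)) 0.42 else x$r_d,
                  h_mn = h,
                  label = if (is.null(x$label)) "" else x$label)
}

#' Read an irradiation schedule CSV
#'
#' Columns: `start_h`, `duration_h`, `doserate_Gy_per_h`.
#'
#' @param path CSV path.
#' @param label Schedule label; defaults to the file name.
#' @return An [irradiation_schedule()].
#' @export
read_schedule <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("start_h", "duration_h", "doserate_Gy_per_h")
  if (!all(need %in% names(df)))
    stop("parse error: columns ", paste(need, collapse = ", "),
         " are required", call. = FALSE)
  irradiation_schedule(df$start_h, df$duration_h, df$doserate_Gy_per_h,
                       label = if (is.null(label)) basename(path) else label)
}

# tiny polynomial rolling hash (kept in double precision, mod 2^31) so
# reports can record a config fingerprint without external dependencies
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a fit report JSON
#'
#' Serializes posterior summaries, acceptance rate, seed, a config
#' fingerprint and the package version, so a run can be reproduced
#' bit-for-bit from its artifact.
#'
#' @param fit A `posterior_samples` object from [mcmc_fit()].
#' @param path Output JSON path.
#' @param extra Optional named list merged into the report.
#' @return The report list, invisibly.
#' @export
write_fit_report <- function(fit, path, extra = list()) {
  stopifnot(inherits(fit, "posterior_samples"))
  s <- summary(fit)
  report <- c(list(
    package = "imkmn",
    version = as.character(utils::packageVersion("imkmn")),
    model_kind = fit$model_kind,
    posterior = cbind(parameter = rownames(s), s),
    acceptance_rate = fit$acceptance_rate,
    seed = fit$config$seed,
    n_burn = fit$config$n_burn,
    n_samples = fit$config$n_samples,
    proposal = fit$config$proposal,
    config_hash = config_hash(fit$config)
  ), extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
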