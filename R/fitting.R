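# Fitting model heating curves to measured temperature rises.
#
# The models predict the relative temperature rise as a function of lead
# length only up to one overall scale (SEM, TLM with fixed gamma) or a
# scale plus the reflection coefficient (TLM with free gamma). The scale
# has a closed-form least-squares solution; gamma is profiled over
# [0, 1]. Models are compared by RMSE and by the ordinary-least-squares
# form of the AIC, which penalises the extra free parameter.

#' Build a temperature-measurement table
#'
#' One row per wire: lead length, measured maximum temperature rise,
#' transmit-gain (TG) readings and the per-wire error components. TG is
#' the scanner RF calibration in 0.1 dB counts; 30 counts correspond to
#' a factor of two in RF power.
#'
#' @param wire_length_m Lead lengths in m, > 0.
#' @param delta_T_C Measured temperature rises in deg C (small values
#'   may be slightly negative under noise).
#' @param tg_aps Mean auto-prescan TG per wire, counts.
#' @param tg_aps_sd SD of the auto-prescan TG repeats, counts
#'   (default 0).
#' @param probe_diff_C Between-probe temperature difference, deg C
#'   (default 0).
#' @param baseline_sd_C Baseline temperature SD, deg C (default 0).
#' @return A data frame of class `temperature_measurements`.
#' @export
temperature_measurements <- function(wire_length_m, delta_T_C, tg_aps,
                                     tg_aps_sd = 0, probe_diff_C = 0,
                                     baseline_sd_C = 0) {
  n <- length(wire_length_m)
  if (any(wire_length_m <= 0)) stop("`wire_length_m` must be > 0", call. = FALSE)
  if (length(delta_T_C) != n || length(tg_aps) != n)
    stop("`delta_T_C` and `tg_aps` must match `wire_length_m` in length",
         call. = FALSE)
  df <- data.frame(wire_length_m = wire_length_m, delta_T_C = delta_T_C,
                   tg_aps = tg_aps,
                   tg_aps_sd = rep_len(tg_aps_sd, n),
                   probe_diff_C = rep_len(probe_diff_C, n),
                   baseline_sd_C = rep_len(baseline_sd_C, n))
  class(df) <- c("temperature_measurements", "data.frame")
  df
}

#' Transmit-gain correction of a measured temperature rise
#'
#' Wires of different length load the coil differently, so auto prescan
#' assigns each wire a slightly different transmit gain. The correction
#' `dTc = dT * 10^((TG_APS - TG_ref) / 100)` rescales every measurement
#' to the RF power of a common reference wire (TG counts are 0.1 dB of
#' power, hence the factor 100 = 10 dB per decade).
#'
#' @param delta_T Measured temperature rise(s), deg C.
#' @param tg_aps Per-wire auto-prescan TG, counts.
#' @param tg_ref Reference TG, counts.
#' @return Corrected temperature rise(s), deg C.
#' @examples
#' tg_correct(10, 150, 120)  # 30 counts ~ factor 2 in power
#' @export
tg_correct <- function(delta_T, tg_aps, tg_ref) {
  delta_T * 10^((tg_aps - tg_ref) / 100)
}

#' Root-sum-square combination of measurement error components
#'
#' Combines the probe-to-probe difference, the TG-variation-induced
#' temperature error and the baseline SD into a single per-measurement
#' error.
#'
#' @param probe_diff,tg_err,baseline_sd Non-negative error components,
#'   deg C (vectorised).
#' @return Combined error(s), deg C.
#' @examples
#' combined_error(3, 0, 4)  # 5
#' @export
combined_error <- function(probe_diff, tg_err, baseline_sd) {
  if (any(probe_diff < 0) || any(tg_err < 0) || any(baseline_sd < 0))
    stop("error components must be >= 0", call. = FALSE)
  sqrt(probe_diff^2 + tg_err^2 + baseline_sd^2)
}

#' Temperature error induced by transmit-gain variation
#'
#' First-order propagation of the TG repeat SD through the correction
#' `dTc = dT * 10^((TG - TG_ref)/100)`:
#' `sigma_dT = dTc * ln(10)/100 * sigma_TG`.
#'
#' @param delta_T_corrected TG-corrected temperature rise(s), deg C.
#' @param tg_aps_sd SD of the TG repeats, counts.
#' @return Error component(s), deg C.
#' @export
tg_error_component <- function(delta_T_corrected, tg_aps_sd) {
  abs(delta_T_corrected) * log(10) / 100 * tg_aps_sd
}

#' Per-measurement combined errors for a measurement table
#'
#' @param data A [temperature_measurements()] table.
#' @param tg_ref Reference TG in counts; default the first row's
#'   `tg_aps`.
#' @return Numeric vector of combined errors, deg C.
#' @export
measurement_errors <- function(data, tg_ref = data$tg_aps[1]) {
  dtc <- tg_correct(data$delta_T_C, data$tg_aps, tg_ref)
  combined_error(data$probe_diff_C,
                 tg_error_component(dtc, data$tg_aps_sd),
                 data$baseline_sd_C)
}

#' Ordinary-least-squares Akaike information criterion
#'
#' `AIC = n ln(RSS/n) + 2 (K + 1)`, where `K` counts the model's free
#' parameters and the `+1` accounts for the residual variance. Used only
#' to rank models fitted to the same data; lower is better.
#'
#' @param rss Residual sum of squares, > 0 (squared deg C).
#' @param n Number of observations; must exceed `k_params + 2`.
#' @param k_params Number of free model parameters.
#' @return AIC value (`-Inf` with a warning when `rss = 0`).
#' @export
aic_ols <- function(rss, n, k_params) {
  if (n <= k_params + 2)
    stop("AIC requires n > k_params + 2", call. = FALSE)
  if (rss < 0) stop("`rss` must be >= 0", call. = FALSE)
  if (rss == 0) {
    warning("zero residual sum of squares; AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n) + 2 * (k_params + 1)
}

#' Result of fitting a model curve to temperature data
#'
#' @param scale Fitted scale, deg C per relative temperature-rise unit.
#' @param rmse Root mean square error, deg C (1/n normalisation).
#' @param aic OLS-form AIC.
#' @param n_free_params 1 (scale only) or 2 (scale and gamma).
#' @param gamma Fitted reflection coefficient, or `NA`.
#' @param model Optional [transfer_model()] used for the predictions.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(scale, rmse, aic, n_free_params, gamma = NA,
                       model = NULL) {
  stopifnot(rmse >= 0, n_free_params %in% c(1, 2))
  structure(list(scale = scale, rmse = rmse, aic = aic,
                 n_free_params = n_free_params, gamma = gamma, model = model),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  g <- if (is.na(x$gamma)) "" else sprintf(", gamma = %.4f", x$gamma)
  cat(sprintf("<fit_result> scale = %.4g%s, RMSE = %.3f C, AIC = %.2f (%d free param%s)\n",
              x$scale, g, x$rmse, x$aic, x$n_free_params,
              if (x$n_free_params > 1) "s" else ""))
  invisible(x)
}

#' Least-squares scale factor between model predictions and data
#'
#' Closed-form minimiser of the RMSE over a single multiplicative scale:
#' `c = sum(y p) / sum(p^2)`, `RMSE = sqrt(mean((y - c p)^2))`.
#'
#' @param predictions Model relative temperature rises at the data
#'   lengths (not all zero).
#' @param observations TG-corrected measured temperature rises, deg C.
#' @param n_free_params Parameter count charged to the AIC (default 1;
#'   pass 2 when the predictions already consumed a fitted gamma).
#' @return A [fit_result()].
#' @export
fit_scale <- function(predictions, observations, n_free_params = 1) {
  if (length(predictions) != length(observations) || length(observations) < 2)
    stop("need >= 2 matching prediction/observation pairs", call. = FALSE)
  sp2 <- sum(predictions^2)
  if (sp2 == 0)
    stop("degenerate fit: model predictions are all zero", call. = FALSE)
  sc <- sum(observations * predictions) / sp2
  res <- observations - sc * predictions
  rss <- sum(res^2)
  fit_result(scale = sc, rmse = sqrt(rss / length(observations)),
             aic = aic_ols(rss, length(observations), n_free_params),
             n_free_params = n_free_params)
}

#' Fit reflection coefficient and scale of the transmission line model
#'
#' Profiles the real reflection coefficient over `[0, 1]` (grid step
#' `1e-3` followed by golden-section refinement of the bracketing
#' interval), fitting the scale in closed form at each gamma, and
#' returns the global RMSE minimiser with `n_free_params = 2`.
#'
#' @param k Conductor [wavenumber()].
#' @param lengths Lead lengths in m (>= 3 values).
#' @param observations TG-corrected temperature rises, deg C.
#' @param E_abs Constant field magnitude used for the predictions.
#' @return A [fit_result()] with `gamma` set and `model` carrying the
#'   fitted [transfer_model()].
#' @export
fit_gamma_and_scale <- function(k, lengths, observations, E_abs = 1) {
  stopifnot(inherits(k, "wavenumber"))
  if (length(lengths) < 3 || length(lengths) != length(observations))
    stop("need >= 3 matching length/observation pairs", call. = FALSE)
  rmse_at <- function(g) {
    p <- delta_T_tlm(E_abs, k, g, lengths)
    sp2 <- sum(p^2)
    sc <- sum(observations * p) / sp2
    sqrt(mean((observations - sc * p)^2))
  }
  grid <- seq(0, 1, by = 1e-3)
  vals <- vapply(grid, rmse_at, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  g <- if (lo == hi) lo else stats::optimize(rmse_at, c(lo, hi), tol = 1e-8)$minimum
  if (rmse_at(lo) < rmse_at(g)) g <- lo   # guard grid-edge minima (g = 0 or 1)
  if (rmse_at(hi) < rmse_at(g)) g <- hi
  p <- delta_T_tlm(E_abs, k, g, lengths)
  fit <- fit_scale(p, observations, n_free_params = 2)
  fit$gamma <- g
  fit$model <- transfer_model("tlm", k, gamma = g)
  fit
}

#' Fit and rank several transfer models on one data set
#'
#' TG-corrects the measurements, fits each requested model and returns a
#' ranked summary (by AIC). `"sem"` and `"tlm_open"` (gamma fixed at 1)
#' fit the scale only; `"tlm"` additionally profiles gamma.
#'
#' @param data A [temperature_measurements()] table.
#' @param k Conductor [wavenumber()].
#' @param models Character subset of `c("sem", "tlm", "tlm_open")`.
#' @param tg_ref Reference TG; default the first row's `tg_aps`.
#' @return A data frame with one row per model: `model`, `gamma`,
#'   `scale`, `rmse_C`, `aic`, `n_free_params`, `d_res_m`, ordered by
#'   AIC. The individual [fit_result()] objects are attached as
#'   attribute `"fits"`.
#' @export
fit_models <- function(data, k, models = c("sem", "tlm", "tlm_open"),
                       tg_ref = data$tg_aps[1]) {
  stopifnot(inherits(data, "data.frame"), inherits(k, "wavenumber"))
  models <- match.arg(models, several.ok = TRUE)
  y <- tg_correct(data$delta_T_C, data$tg_aps, tg_ref)
  d <- data$wire_length_m
  fits <- list()
  for (m in models) {
    fits[[m]] <- switch(m,
      sem = {
        f <- fit_scale(delta_T_sem(1, k, d), y)
        f$model <- transfer_model("sem", k)
        f
      },
      tlm_open = {
        f <- fit_scale(delta_T_tlm(1, k, 1, d), y)
        f$gamma <- 1
        f$model <- transfer_model("tlm", k, gamma = 1)
        f
      },
      tlm = fit_gamma_and_scale(k, d, y))
  }
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm,
               gamma = if (is.na(f$gamma)) NA_real_ else f$gamma,
               scale = f$scale, rmse_C = f$rmse, aic = f$aic,
               n_free_params = f$n_free_params,
               d_res_m = resonant_length(f$model))
  }))
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Read / write measurement tables as CSV
#'
#' CSV header: `length_cm, delta_T_C, tg_aps, tg_aps_sd, probe_diff_C,
#' baseline_sd_C` (lengths on disk in cm, the usual bench convention;
#' stored in m internally).
#'
#' @param path CSV file path.
#' @return A [temperature_measurements()] table (read) or `path`
#'   (write).
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path)
  need <- c("length_cm", "delta_T_C", "tg_aps")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("measurement CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in intersect(names(df), c("length_cm", "delta_T_C", "tg_aps",
                                     "tg_aps_sd", "probe_diff_C",
                                     "baseline_sd_C"))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad <- which(!is.finite(df$length_cm) | !is.finite(df$delta_T_C) |
               !is.finite(df$tg_aps))
  if (length(bad) > 0)
    stop("malformed measurement CSV at data line ", bad[1], call. = FALSE)
  opt <- function(col) if (col %in% names(df)) df[[col]] else 0
  temperature_measurements(df$length_cm / 100, df$delta_T_C, df$tg_aps,
                           opt("tg_aps_sd"), opt("probe_diff_C"),
                           opt("baseline_sd_C"))
}

#' @rdname read_measurements
#' @param data A [temperature_measurements()] table.
#' @export
write_measurements <- function(data, path) {
  stopifnot(inherits(data, "data.frame"))
  df <- data.frame(length_cm = data$wire_length_m * 100,
                   delta_T_C = data$delta_T_C, tg_aps = data$tg_aps,
                   tg_aps_sd = data$tg_aps_sd,
                   probe_diff_C = data$probe_diff_C,
                   baseline_sd_C = data$baseline_sd_C)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
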