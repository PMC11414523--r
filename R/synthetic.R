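# Synthetic temperature-rise measurement sets. The generator mirrors the
# bench protocol: a set of wires of increasing length, each with its own
# auto-prescan transmit gain (mean of four repeats), a measured maximum
# temperature rise scaled by the per-wire RF power, and additive
# thermometry noise. Applying tg_correct() with the stored TG means
# inverts the power perturbation exactly, so the noiseless round trip
# recovers the generating scale (and reflection coefficient).

#' Generate synthetic temperature measurements from a transfer model
#'
#' Draws, for each requested length, four auto-prescan TG repeats around
#' `tg_ref` (SD `tg_spread`), stores their mean and SD, and produces
#' `dT = scale * dT_model(d) * 10^(-(TG_mean - tg_ref)/100) + e`,
#' `e ~ N(0, noise_sd)`. Probe-difference and baseline error columns are
#' filled with values on the scale of the thermometry noise.
#'
#' @param model A [transfer_model()].
#' @param scale Scale from relative model units to deg C.
#' @param lengths Lead lengths in m.
#' @param noise_sd Additive measurement noise SD, deg C (>= 0).
#' @param tg_spread SD of a single TG reading, counts (>= 0).
#' @param seed Integer seed; the output is reproducible given the seed.
#' @param tg_ref Reference TG, counts (default 120).
#' @param E_abs Constant field magnitude for the model curve.
#' @return A [temperature_measurements()] table.
#' @examples
#' k <- wavenumber(6.7454, -0.6840)
#' m <- transfer_model("tlm", k, gamma = 0.25)
#' synthetic_measurements(m, 50, seq(0.05, 0.5, length.out = 15),
#'                        noise_sd = 0.5, tg_spread = 2, seed = 1)
#' @export
synthetic_measurements <- function(model, scale, lengths, noise_sd = 0,
                                   tg_spread = 0, seed = NULL, tg_ref = 120,
                                   E_abs = 1) {
  stopifnot(inherits(model, "transfer_model"))
  if (noise_sd < 0 || tg_spread < 0)
    stop("`noise_sd` and `tg_spread` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(lengths)
  reps <- matrix(stats::rnorm(4 * n, mean = tg_ref, sd = tg_spread), nrow = 4)
  tg_mean <- colMeans(reps)
  tg_sd <- apply(reps, 2, stats::sd)
  truth <- scale * delta_T(model, lengths, E_abs)
  dt <- truth * 10^(-(tg_mean - tg_ref) / 100) + stats::rnorm(n, 0, noise_sd)
  temperature_measurements(
    wire_length_m = lengths,
    delta_T_C = dt,
    tg_aps = tg_mean,
    tg_aps_sd = tg_sd,
    probe_diff_C = abs(stats::rnorm(n, 0, noise_sd / 2)),
    baseline_sd_C = rep(noise_sd / 4, n))
}
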