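# Transfer functions and lead-tip voltage / temperature-rise curves.
#
# The lead-tip voltage is the line integral of the tangential incident
# electric field along the lead, weighted by a complex transfer function
# h(l), with l the arc length measured from the lead tip:
#
#   V = integral_0^d h(l) Et(l) dl,     dT proportional to |V|^2.
#
# Two model families are implemented:
#   SEM  h(l) = e^{-ikl}                       (simple exponential model)
#   TLM  h(l) = e^{-ikl} (1 - G e^{-2ik(d-l)}) / (1 - G e^{-2ikd})
# where G is the reflection coefficient at the capped (IPG) end. Both
# satisfy h(0) = 1; the TLM reduces to the SEM at G = 0. For a constant
# field both integrals have closed forms, used throughout for speed and
# as oracles for the numerical line integral.

TLM_DENOM_TOL <- 1e-14

#' Transfer model descriptor
#'
#' Bundles a model family (`"sem"` or `"tlm"`), the conductor
#' [wavenumber()] and, for the transmission line model, the reflection
#' coefficient at the capped end. `form = "ipg"` selects the
#' IPG-referenced variant of the transmission-line weight (arc length
#' measured from the capped end), which differs from the tip-referenced
#' form for asymmetric fields but yields the same `|V|` for symmetric
#' ones.
#'
#' @param kind `"sem"` or `"tlm"`.
#' @param k A [wavenumber()].
#' @param gamma Reflection coefficient, `|gamma| <= 1` (may be complex);
#'   ignored by the SEM. Default 1 (electrically open end).
#' @param form `"tip"` (default) or `"ipg"`; TLM only.
#' @return An object of class `transfer_model`.
#' @examples
#' k <- wavenumber(12.8679, -1.6601)
#' transfer_model("tlm", k, gamma = 1)
#' @export
transfer_model <- function(kind = c("sem", "tlm"), k, gamma = 1,
                           form = c("tip", "ipg")) {
  kind <- match.arg(kind)
  form <- match.arg(form)
  stopifnot(inherits(k, "wavenumber"))
  if (Mod(gamma) > 1 + 1e-12)
    stop("|gamma| must be <= 1 (passive termination)", call. = FALSE)
  structure(list(kind = kind, k = k, gamma = gamma, form = form),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  if (x$kind == "sem") {
    cat(sprintf("<transfer_model> SEM, k = (%.4f %+.4fi) rad/m\n", x$k$kR, x$k$kI))
  } else {
    cat(sprintf("<transfer_model> TLM (%s form), k = (%.4f %+.4fi) rad/m, gamma = %s\n",
                x$form, x$k$kR, x$k$kI, format(x$gamma)))
  }
  invisible(x)
}

#' Simple exponential transfer function
#'
#' `h(l) = e^{-ikl}`. With `kI <= 0` this has `|h| <= 1` and decays
#' monotonically with distance from the lead tip.
#'
#' @param k A [wavenumber()].
#' @param l Arc length(s) from the lead tip in m, >= 0.
#' @return Complex vector, same length as `l`.
#' @export
sem_transfer <- function(k, l) {
  stopifnot(inherits(k, "wavenumber"))
  if (any(l < 0)) stop("`l` must be >= 0", call. = FALSE)
  exp(-1i * as.complex(k) * l)
}

#' Transmission line transfer function
#'
#' `h(l) = e^{-ikl} (1 - gamma e^{-2ik(d-l)}) / (1 - gamma e^{-2ikd})`
#' for a lead of total length `d` terminated with reflection coefficient
#' `gamma` at the capped end. Satisfies `h(0) = 1` and reduces to
#' [sem_transfer()] at `gamma = 0`.
#'
#' @param k A [wavenumber()].
#' @param gamma Reflection coefficient (complex allowed, `|gamma| <= 1`).
#' @param l Arc length(s) from the lead tip in m, `0 <= l <= d`.
#' @param d Total lead length in m, > 0.
#' @return Complex vector, same length as `l`.
#' @export
tlm_transfer <- function(k, gamma, l, d) {
  stopifnot(inherits(k, "wavenumber"), length(d) == 1, d > 0)
  if (any(l < 0) || any(l > d + 1e-12))
    stop("`l` must lie in [0, d]", call. = FALSE)
  kk <- as.complex(k)
  denom <- 1 - gamma * exp(-2i * kk * d)
  if (Mod(denom) < TLM_DENOM_TOL)
    stop("transmission-line transfer function is singular: ",
         "1 - gamma*e^{-2ikd} vanishes (lossless resonance)", call. = FALSE)
  exp(-1i * kk * l) * (1 - gamma * exp(-2i * kk * (d - l))) / denom
}

# IPG-referenced transmission-line weight: arc length parameter measured
# from the capped end. Not normalised to h(0) = 1; used for symmetry
# diagnostics of the numerical line integral.
.tlm_transfer_ipg <- function(k, gamma, l, d) {
  stopifnot(inherits(k, "wavenumber"), length(d) == 1, d > 0)
  kk <- as.complex(k)
  denom <- 1 - gamma * exp(-2i * kk * d)
  if (Mod(denom) < TLM_DENOM_TOL)
    stop("transmission-line transfer function is singular", call. = FALSE)
  exp(-1i * kk * (d - l)) * (1 - gamma * exp(-2i * kk * l)) / denom
}

# Evaluate the transfer function of a model at arc lengths l for a lead
# of length d.
.transfer_at <- function(model, l, d) {
  stopifnot(inherits(model, "transfer_model"))
  if (model$kind == "sem") return(sem_transfer(model$k, l))
  if (model$form == "ipg") .tlm_transfer_ipg(model$k, model$gamma, l, d)
  else tlm_transfer(model$k, model$gamma, l, d)
}

#' Closed-form lead-tip voltage, simple exponential model
#'
#' For a constant tangential field `E` along a straight lead of length
#' `d`, the line integral of `E e^{-ikl}` evaluates to
#' `V = E (e^{-ikd} - 1) / (-ik)`. The degenerate `k = 0` case (unity
#' transfer function) takes the analytic limit `V = E d`.
#'
#' @param E Complex constant tangential field, V/m.
#' @param k A [wavenumber()].
#' @param d Lead length(s) in m, >= 0 (vectorised).
#' @return Complex voltage(s), V.
#' @export
closed_form_voltage_sem <- function(E, k, d) {
  stopifnot(inherits(k, "wavenumber"))
  if (any(d < 0)) stop("`d` must be >= 0", call. = FALSE)
  kk <- as.complex(k)
  if (Mod(kk) == 0) return(E * d + 0i)
  E * (exp(-1i * kk * d) - 1) / (-1i * kk)
}

#' Closed-form lead-tip voltage, transmission line model
#'
#' For a constant tangential field the transmission-line integral
#' factorises as
#' `V = E (1 - e^{-ikd}) (1 - gamma e^{-ikd}) / (ik (1 - gamma e^{-2ikd}))`.
#' Reduces to [closed_form_voltage_sem()] at `gamma = 0`.
#'
#' @inheritParams closed_form_voltage_sem
#' @param gamma Reflection coefficient (complex allowed, `|gamma| <= 1`).
#' @return Complex voltage(s), V.
#' @export
closed_form_voltage_tlm <- function(E, k, gamma, d) {
  stopifnot(inherits(k, "wavenumber"))
  if (any(d < 0)) stop("`d` must be >= 0", call. = FALSE)
  kk <- as.complex(k)
  if (Mod(kk) == 0) return(E * d + 0i)
  ph <- exp(-1i * kk * d)
  denom <- 1 - gamma * ph^2
  if (any(Mod(denom) < TLM_DENOM_TOL & d > 0))
    stop("transmission-line voltage is singular: 1 - gamma*e^{-2ikd} vanishes",
         call. = FALSE)
  out <- E * (1 - ph) * (1 - gamma * ph) / (1i * kk * denom)
  out[d == 0] <- 0 + 0i   # analytic limit of the 0/0 form at gamma = 1
  out
}

#' Relative lead-tip temperature rise, simple exponential model
#'
#' Closed form for a constant field:
#' `dT = (E^2/|k|^2) * (1 + e^{2 kI d} - 2 e^{kI d} cos(kR d))`,
#' equal to `|closed_form_voltage_sem()|^2`. The proportionality
#' constant relating `|V|^2` to degrees Celsius is fixed at 1 here;
#' absolute scaling is fitted in [fit_scale()].
#'
#' @param E_abs Field magnitude, V/m.
#' @param k A [wavenumber()].
#' @param d Lead length(s) in m, >= 0 (vectorised).
#' @return Non-negative relative temperature rise(s), arbitrary units.
#' @export
delta_T_sem <- function(E_abs, k, d) {
  stopifnot(inherits(k, "wavenumber"))
  if (any(d < 0)) stop("`d` must be >= 0", call. = FALSE)
  k2 <- k$kR^2 + k$kI^2
  if (k2 == 0) return(E_abs^2 * d^2)
  A <- exp(k$kI * d)
  E_abs^2 / k2 * (1 + A^2 - 2 * A * cos(k$kR * d))
}

#' Relative lead-tip temperature rise, transmission line model
#'
#' Closed form for a constant field and real reflection coefficient,
#' evaluated entirely in real arithmetic:
#' \deqn{\Delta T = \frac{E^2}{|k|^2}\,
#'   \frac{(1 + A^2 - 2Ac)(1 + \Gamma^2 A^2 - 2\Gamma A c)}
#'        {1 + \Gamma^2 A^4 - 2 \Gamma A^2 \cos(2 k_R d)}}
#' with `A = e^{kI d}` and `c = cos(kR d)`; algebraically identical to
#' `|closed_form_voltage_tlm()|^2`. A complex `gamma` is routed through
#' the complex closed-form voltage instead.
#'
#' @inheritParams delta_T_sem
#' @param gamma Reflection coefficient; real for the closed form,
#'   complex values fall back to `|V|^2`.
#' @return Non-negative relative temperature rise(s), arbitrary units.
#' @export
delta_T_tlm <- function(E_abs, k, gamma, d) {
  stopifnot(inherits(k, "wavenumber"))
  if (any(d < 0)) stop("`d` must be >= 0", call. = FALSE)
  if (is.complex(gamma) && Im(gamma) != 0) {
    return(Mod(closed_form_voltage_tlm(E_abs + 0i, k, gamma, d))^2)
  }
  gamma <- Re(gamma)
  k2 <- k$kR^2 + k$kI^2
  if (k2 == 0) return(E_abs^2 * d^2)
  A <- exp(k$kI * d)
  c1 <- cos(k$kR * d)
  denom <- 1 + gamma^2 * A^4 - 2 * gamma * A^2 * cos(2 * k$kR * d)
  if (any(denom < TLM_DENOM_TOL^2 & d > 0))
    stop("transmission-line temperature rise is singular at this length",
         call. = FALSE)
  num <- (1 + A^2 - 2 * A * c1) * (1 + gamma^2 * A^2 - 2 * gamma * A * c1)
  out <- E_abs^2 / k2 * num / denom
  out[d == 0] <- 0   # analytic limit of the 0/0 form at gamma = 1
  out
}

#' Relative temperature rise for a transfer model
#'
#' Dispatches to [delta_T_sem()] or [delta_T_tlm()] according to the
#' model kind.
#'
#' @param model A [transfer_model()].
#' @param d Lead length(s) in m, >= 0.
#' @param E_abs Constant field magnitude, V/m (default 1).
#' @return Non-negative relative temperature rise(s).
#' @export
delta_T <- function(model, d, E_abs = 1) {
  stopifnot(inherits(model, "transfer_model"))
  if (model$kind == "sem") delta_T_sem(E_abs, model$k, d)
  else delta_T_tlm(E_abs, model$k, model$gamma, d)
}

#' Heating curve: relative temperature rise versus lead length
#'
#' Evaluates `|V|` and the relative temperature rise of a model over a
#' vector of lead lengths under a constant field.
#'
#' @param model A [transfer_model()].
#' @param lengths Strictly increasing lead lengths in m.
#' @param E_abs Constant field magnitude, V/m.
#' @return A data frame of class `heating_curve` with columns
#'   `length_m`, `abs_voltage`, `relative_delta_T`, and the model stored
#'   in attribute `"model"`.
#' @export
heating_curve <- function(model, lengths, E_abs = 1) {
  stopifnot(inherits(model, "transfer_model"))
  if (length(lengths) < 1 || any(diff(lengths) <= 0))
    stop("`lengths` must be strictly increasing", call. = FALSE)
  if (any(lengths < 0)) stop("`lengths` must be >= 0", call. = FALSE)
  v <- if (model$kind == "sem") {
    closed_form_voltage_sem(E_abs + 0i, model$k, lengths)
  } else {
    closed_form_voltage_tlm(E_abs + 0i, model$k, model$gamma, lengths)
  }
  out <- data.frame(length_m = lengths,
                    abs_voltage = Mod(v),
                    relative_delta_T = delta_T(model, lengths, E_abs))
  attr(out, "model") <- model
  class(out) <- c("heating_curve", "data.frame")
  out
}

#' Write a heating curve to CSV or JSON
#'
#' CSV carries the numeric columns only; JSON additionally records the
#' model descriptor (kind, wavenumber, reflection coefficient).
#'
#' @param curve A [heating_curve()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default from file extension).
#' @return `path`, invisibly.
#' @export
write_heating_curve <- function(curve, path, format = NULL) {
  stopifnot(inherits(curve, "heating_curve"))
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  } else {
    m <- attr(curve, "model")
    jsonlite::write_json(
      list(model = list(kind = m$kind, kR = m$k$kR, kI = m$k$kI,
                        gamma_re = Re(m$gamma), gamma_im = Im(m$gamma)),
           curve = as.data.frame(curve)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a heating curve written by [write_heating_curve()]
#'
#' @param path CSV file with columns `length_m`, `abs_voltage`,
#'   `relative_delta_T`.
#' @return A data frame.
#' @export
read_heating_curve <- function(path) {
  utils::read.csv(path)
}

#' Lead-tip voltage by numerical line integration
#'
#' Discrete midpoint-rule approximation of the voltage integral for an
#' arbitrary wire path through a sampled (or constant) complex vector
#' field: `V = sum_i h(l_i) Et_i |dl_i|`, with `l_i` the arc length of
#' the i-th segment midpoint measured from the lead tip (the first path
#' point) and `Et_i` the tangential field component at that midpoint.
#' Path segments longer than `max_segment` are subdivided first.
#'
#' @param field An [efield_grid()], or a complex length-3 vector giving
#'   a spatially constant field (V/m).
#' @param path A [wire_path()].
#' @param model A [transfer_model()].
#' @param max_segment Maximum segment length in m used for the midpoint
#'   rule (default 1 mm).
#' @return Complex voltage, V.
#' @export
numerical_voltage <- function(field, path, model, max_segment = 1e-3) {
  stopifnot(inherits(path, "wire_path"), inherits(model, "transfer_model"))
  path <- refine_path(path, max_segment)
  seg <- path_segments(path)
  et <- tangential_component(field, path)
  h <- .transfer_at(model, seg$mid_arclength, total_length(path))
  sum(h * et * seg$length)
}
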