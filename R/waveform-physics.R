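#' Gas constants for reflected-pressure calculations
#'
#' Bundles the specific heat ratio of the driven gas and the ambient
#' atmospheric pressure used by the normal-shock reflection relation.
#'
#' @param gamma Specific heat ratio (dimensionless). Must exceed 1.
#'   Default 1.4 (air).
#' @param p0 Ambient atmospheric pressure in psi. Must be positive.
#'   Default 14.7 psi.
#'
#' @return An object of class `gas_constants`.
#' @export
#' @examples
#' gas_constants()           # air at sea level
#' gas_constants(gamma = 5/3, p0 = 14.7)  # monatomic driver gas
gas_constants <- function(gamma = 1.4, p0 = 14.7) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(p0), length(p0) == 1L, is.finite(p0))
  if (gamma <= 1) stop("`gamma` must be > 1 (got ", gamma, ")")
  if (p0 <= 0) stop("`p0` must be > 0 psi (got ", p0, ")")
  structure(list(gamma = gamma, p0 = p0), class = "gas_constants")
}

#' Friedlander waveform parameters
#'
#' The modified Friedlander form describes an ideal free-field blast pulse:
#' an instantaneous rise to peak overpressure at the onset time, followed by
#' an exponentially modified linear decay that crosses zero at the end of the
#' positive phase and goes negative (underpressure) beyond it.
#'
#' @param peak_overpressure Peak overpressure in psi (> 0).
#' @param positive_duration Positive-phase duration in ms (> 0).
#' @param decay_constant Dimensionless decay constant (>= 0). Zero gives a
#'   triangular pulse; values near 1 reproduce typical shock-tube pulses.
#' @param onset_time Wave arrival time in ms.
#'
#' @return An object of class `friedlander_params`.
#' @export
#' @examples
#' friedlander_params(19.18, 1.99, decay_constant = 1)
friedlander_params <- function(peak_overpressure, positive_duration,
                               decay_constant = 1, onset_time = 0) {
  stopifnot(is.numeric(peak_overpressure), length(peak_overpressure) == 1L,
            is.numeric(positive_duration), length(positive_duration) == 1L,
            is.numeric(decay_constant), length(decay_constant) == 1L,
            is.numeric(onset_time), length(onset_time) == 1L,
            is.finite(peak_overpressure), is.finite(positive_duration),
            is.finite(decay_constant), is.finite(onset_time))
  if (peak_overpressure <= 0) stop("`peak_overpressure` must be > 0 psi")
  if (positive_duration <= 0) stop("`positive_duration` must be > 0 ms")
  if (decay_constant < 0) stop("`decay_constant` must be >= 0")
  structure(list(peak_overpressure = peak_overpressure,
                 positive_duration = positive_duration,
                 decay_constant = decay_constant,
                 onset_time = onset_time),
            class = "friedlander_params")
}

#' Evaluate the Friedlander waveform
#'
#' Computes `P(t) = Pmax * (1 - tau/t+) * exp(-b * tau / t+)` for
#' `tau = t - t0 >= 0` and 0 before onset, where `Pmax` is the peak
#' overpressure, `t+` the positive-phase duration and `b` the dimensionless
#' decay constant.
#'
#' @param params A [friedlander_params()] object.
#' @param t Time(s) in ms; vectorized.
#'
#' @return Pressure(s) in psi, same length as `t`.
#' @export
#' @examples
#' p <- friedlander_params(19.18, 1.99, 1)
#' friedlander_pressure(p, 0)      # peak at onset
#' friedlander_pressure(p, 1.99)   # zero at end of positive phase
friedlander_pressure <- function(params, t) {
  stopifnot(inherits(params, "friedlander_params"), is.numeric(t))
  if (any(!is.finite(t))) stop("`t` must be finite")
  tau <- t - params$onset_time
  u <- tau / params$positive_duration
  out <- params$peak_overpressure * (1 - u) * exp(-params$decay_constant * u)
  out[tau < 0] <- 0
  out
}

#' Closed-form positive impulse of a Friedlander pulse
#'
#' The positive impulse is the area under the overpressure curve over the
#' positive phase. For the modified Friedlander form it has the closed form
#' `Pmax * t+ * (1/b - (1 - exp(-b)) / b^2)`, with limit `Pmax * t+ / 2`
#' (a triangle) as `b -> 0`.
#'
#' @param params A [friedlander_params()] object.
#'
#' @return Positive impulse in psi*ms.
#' @export
#' @examples
#' analytic_positive_impulse(friedlander_params(19.18, 1.99, 1))  # ~14.04
analytic_positive_impulse <- function(params) {
  stopifnot(inherits(params, "friedlander_params"))
  b <- params$decay_constant
  # series fallback near b = 0: 1/2 - b/6 + b^2/24 avoids 0/0
  shape <- if (b < 1e-6) 0.5 - b / 6 + b^2 / 24 else 1 / b - (1 - exp(-b)) / b^2
  params$peak_overpressure * params$positive_duration * shape
}

#' Normal-reflection overpressure
#'
#' Reflected overpressure experienced by a rigid surface facing the incident
#' wave, from the normal-shock (Rankine-Hugoniot) reflection relation:
#' `Pref = 2*dP + (gamma + 1) * dP^2 / ((gamma - 1) * dP + 2 * gamma * P0)`.
#' For air (gamma = 1.4) this is `2*dP + 6*dP^2 / (7*P0 + dP)`. The
#' reflection factor `Pref/dP` runs from 2 (acoustic limit) to 8 (strong
#' shock) for air.
#'
#' @param delta_p Static (side-on) overpressure in psi; vectorized, >= 0.
#' @param gas A [gas_constants()] object.
#'
#' @return Reflected overpressure(s) in psi.
#' @export
#' @examples
#' reflected_pressure(20.88)  # ~62.89 psi at sea level
reflected_pressure <- function(delta_p, gas = gas_constants()) {
  stopifnot(is.numeric(delta_p), inherits(gas, "gas_constants"))
  if (any(!is.finite(delta_p)) || any(delta_p < 0))
    stop("`delta_p` must be finite and >= 0 psi")
  g <- gas$gamma
  2 * delta_p + (g + 1) * delta_p^2 / ((g - 1) * delta_p + 2 * g * gas$p0)
}
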